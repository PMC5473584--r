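---
title: "The MMTF codec stack: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MMTF codec stack: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtfr)
```

## The representation

MMTF stores a macromolecular structure as flat columns rather than nested
objects: all x-coordinates together, all B-factors together, one entry per
atom in file order. Hierarchy (models → chains → groups → atoms) is
recovered from three count vectors — chains per model, groups per chain,
and the per-residue atom counts implied by the group dictionary — which
`decode_structure()` turns into offset tables. Traversal is then index
arithmetic; no per-atom objects are ever materialized unless a caller asks
for them.

The columns are made compressible by a small set of composable transforms:

* **Fixed-point quantization.** Reals are multiplied by a power-of-ten
  divisor and rounded to the nearest integer. In the `full` profile the
  divisors are 1000 for coordinates (0.001 Å), 100 for B-factors (0.01 Å²)
  and 100 for occupancies; in the `reduced` profile all three are 10
  (0.1 precision). Encoding is exactly lossless for inputs already on the
  divisor grid — which archival coordinates, printed with three decimals,
  are — and bounded by half a quantum, `1/(2·divisor)`, otherwise.
* **Delta encoding.** Bonded atoms sit ~1.2–1.8 Å apart, so successive
  quantized coordinates differ by a few thousand at most; storing
  differences shrinks the dynamic range by orders of magnitude.
* **Run-length encoding.** Occupancy columns are almost always constant
  1.0, serial-number deltas constant 1; both collapse to a single
  `(value, count)` pair.
* **Recursive indexing.** Deltas occasionally overflow the 16-bit range
  (chain breaks, lattice translations). Such a value is emitted as a run
  of saturated boundary values (32,767 or −32,768) plus one terminal
  non-boundary remainder whose sum restores it; everything else passes
  through one-to-one.

Every encoded column is a binary record: codec type, decoded length and a
codec parameter as three big-endian int32s, then the payload. The fifteen
numbered codec strategies follow the public format specification v1.0, so
records produced here are byte-compatible with the reference decoders (the
test suite pins several records against byte strings frozen from an
independent implementation). The whole document is a MessagePack v5 map,
optionally gzip-wrapped; the package carries its own MessagePack subset
because no R MessagePack binding is available in the supported dependency
set.

## Numerical and edge-case choices

**Rounding ties.** The format prescription is only "round to the nearest
integer". We round half away from zero: it is symmetric in sign and matches
the convention of fixed-column structure files. Because binary doubles
cannot represent most decimal fractions, the scaled value is pre-rounded at
the 6th decimal so inputs behave as their decimal reading (`1.0005 * 1000`
encodes to 1001, not 1000). Flagged for interoperability testing: a decoder
that re-encodes with banker's rounding would differ on exact `.5` ties only.

**Recursive-index termination.** The decoder's only stop signal is a
non-boundary element, so a value that is an exact sum of boundary values
(32,767 itself, say) is followed by an explicit 0. This is forced by
decoder unambiguity, not stated by the format description. An 8-bit variant
with boundaries [−128, 127] backs the two int8 codecs of the public table.

**Integer carrier.** Columns are carried as R doubles, not R integers,
because R's integer type cannot represent −2³¹ (it is the `NA` sentinel).
Byte packing is done with explicit two's-complement arithmetic; every
encoder checks the signed 32-bit range and reports the offending index.

**Required vs optional fields.** Structural-model columns and counts are
required; crystallographic metadata, resolution, R-factors, NCS operators,
secondary structure, alternate locations, insertion codes, occupancies,
B-factors and serials are optional. Absent columns decode to documented
defaults: blanks for char columns, 0 for B-factors, −1 for secondary
structure and sequence indices, serials 1…n, and occupancy 1.0 (an absent
occupancy column means "not measured", and 1.0 — not 0 — is the only
chemically neutral reading). Unknown top-level keys are preserved
round-trip for forward compatibility; major-version mismatches are errors,
minor/patch drift a warning.

**Secondary structure** is transported as the 8-state integer alphabet
(−1 = undefined) when a caller supplies it; the package never computes it.
Metal coordination and hydrogen bonds are likewise out of scope — there is
no agreed standard for either.

## The encoder pipeline

`encode_structure()` builds the group dictionary by *signature*: residue
name plus the ordered atom-name/element/charge lists and the bond set.
Residues sharing a signature share one entry; a residue whose atoms appear
in a nonstandard order gets its own entry — less compact, never corrupt.
Intra-residue bonds come from component templates (Chemical Component
Dictionary format); a missing template yields an empty bond list and one
warning per component.

Inter-group bonds are the union of author-supplied covalent links
(disulfides, ligand attachments from `struct_conn` / SSBOND / CONECT) and
inferred backbone links between consecutive polymer residues of a chain.
Inference is gated by distance sanity caps — C–N below 2.0 Å, O3′–P below
2.2 Å — so chain breaks are not bridged. All stored bonds count toward
`numBonds`, inferred or not.

The `reduced` profile keeps exactly the Cα of each polypeptide residue
(name `CA`, element C), the P of each nucleotide, and all atoms of
non-polymer groups, hydrogens included — a literal reading of the profile
definition. Waters are removed entirely: they are neither polymer nor
informative at Cα scale. A polymer residue lacking its representative atom
is dropped with a warning rather than an error, since terminal nucleotides
legitimately lack a phosphate. Occupancies and B-factors are kept for
retained atoms only. The operation is idempotent.

**Entity bookkeeping.** mmCIF input keeps its declared entities and splits
chains on `label_asym_id` (the internal chain id), with `auth_asym_id` as
the author-facing chain name. PDB input has no entity records, so the
encoder derives one entity per author chain, typed by residue-name
classification (polymer / water / non-polymer). Archive-style splitting of
mixed author chains into per-entity chains is *not* reproduced; files
produced from PDB input are self-consistent but will not be chain-for-chain
identical to archive-served files of the same entry.

## What the synthetic generator emulates

`make_structure()` exists so every code path is exercisable offline. It
reproduces the *statistical shape* the codecs exploit: successive-atom
steps drawn near bond scale (mean 1.5 Å, sd 0.2), B-factors as a bounded
random walk rounded to the 0.01 grid, occupancies constant 1.0 unless a
mixed pattern is requested, grid-aligned (0.001 Å) coordinates so the full
profile is provably exact. The heavy-tail option injects rare 40–80 Å
jumps to force recursive-index continuation groups. Options add alternate
locations, insertion codes, ligands (a synthetic 12-atom component, LG1)
and waters. The same seed yields byte-identical structures, and the
generator saves and restores the caller's RNG state.

What it does **not** emulate: real stereochemistry (no sterics, no
torsional statistics), crystallographic symmetry, biological assemblies,
alternate-conformer correlation, or archive chain-splitting conventions. A
green round-trip test therefore establishes codec and schema correctness,
not chemical plausibility — and byte-compatibility with archive files
rests on the frozen cross-implementation records, not on the generator.

The bundled component dictionary (`inst/extdata/components-synthetic.cif`)
is a hand-written, clearly-labelled stand-in for the archival CCD: GLY,
ALA, SER (with polar/backbone hydrogens so its dictionary entry has a
realistic bond set), CYS, uridine, water and LG1.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `full` coordinate divisor | 1000 | quanta/Å | archival 3-decimal precision, lossless |
| `full` B-factor / occupancy divisor | 100 | quanta/unit | archival 2-decimal precision |
| `reduced` divisors | 10 | quanta/unit | 0.1 precision, visually lossless at ribbon scale |
| backbone C–N cap | 2.0 | Å | peptide bond ≈ 1.33 Å; cap rejects chain breaks |
| backbone O3′–P cap | 2.2 | Å | phosphodiester ≈ 1.6 Å |
| string field width | 4 | bytes | chain identifiers, zero-padded |
| generator step | N(1.5, 0.2) | Å | covalent bond scale |

## Known limitations

* PDB dialect is strict fixed-column; hybrid-36 serials beyond 99,999
  atoms are rejected with a clear error, mirroring the format's own limit.
* mmCIF coverage is the category subset the format needs (`atom_site`,
  `struct_conn`, cell/symmetry/entity/refine/struct); it is not a general
  CIF library, and assemblies/NCS operators are transported only when a
  caller supplies them.
* Codec 11's payload width is taken from the public specification table
  (int16); it is unused by the encoder and untestable against the format
  description alone.
* All-conformer alternate locations are retained as distinct atoms; how
  alt-loc groups interact with dictionary signatures in archive practice
  varies, and files with exotic alt-loc layouts will simply grow extra
  dictionary entries.
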