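# Independent brute-force oracles for the codec primitives. Deliberately
# naive (explicit loops, no shared code with the implementation) so they can
# arbitrate round-trip behaviour.

oracle_prefix_sum <- function(deltas) {
  out <- numeric(length(deltas))
  acc <- 0
  for (i in seq_along(deltas)) {
    acc <- acc + deltas[i]
    out[i] <- acc
  }
  out
}

oracle_rle_expand <- function(pairs) {
  out <- numeric(0)
  i <- 1L
  while (i < length(pairs)) {
    out <- c(out, rep(pairs[i], pairs[i + 1L]))
    i <- i + 2L
  }
  out
}

# Sum-of-groups reassembly: accumulate while the element is saturated.
oracle_rix_decode <- function(small, width = 16L) {
  up <- if (width == 16L) 32767 else 127
  lo <- if (width == 16L) -32768 else -128
  out <- numeric(0)
  acc <- 0
  for (v in small) {
    acc <- acc + v
    if (v != up && v != lo) {
      out <- c(out, acc)
      acc <- 0
    }
  }
  out
}

random_int_column <- function(n, lim = 1e6) {
  round(stats::runif(n, -lim, lim))
}

# A raw structure with a hand-placed backbone so inferred-bond geometry is
# under the test's control: consecutive residues 1.33 A apart at the C/N
# junction.
peptide_fixture <- function(res_names = c("GLY", "ALA", "SER"), chain_id = "A") {
  tpls <- mmtf_templates()
  atoms <- NULL
  groups <- NULL
  serial <- 0
  for (ri in seq_along(res_names)) {
    tpl <- tpls[[res_names[ri]]]
    n <- length(tpl$atom_names)
    base_x <- (ri - 1) * 3.0
    offs <- seq(0, by = 0.4, length.out = n)
    # place C at +2.0 and the next residue's N at +3.0: C-N distance 1.0 + dy
    x <- base_x + offs
    x[tpl$atom_names == "C"] <- base_x + 2.0
    x[tpl$atom_names == "N"] <- base_x + 0.0
    if (ri > 1) x[tpl$atom_names == "N"] <- base_x  # 1.0 A from previous C
    atoms <- rbind(atoms, data.frame(
      group = ri, name = tpl$atom_names, element = tpl$elements,
      x = x, y = 0, z = 0, occupancy = 1, b_factor = 10 + ri,
      alt_loc = "", serial = serial + seq_len(n),
      formal_charge = tpl$formal_charges, stringsAsFactors = FALSE))
    serial <- serial + n
    groups <- rbind(groups, data.frame(chain = 1L, name = res_names[ri],
                                       group_id = ri, ins_code = "",
                                       stringsAsFactors = FALSE))
  }
  chains <- data.frame(model = 1L, chain_id = chain_id, chain_name = chain_id,
                       stringsAsFactors = FALSE)
  raw_structure(atoms, groups, chains)
}

hex_bytes <- function(r) paste(format(r), collapse = "")
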