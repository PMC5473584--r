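#' @title Deterministic synthetic structures
#'
#' @description
#' A seeded generator of synthetic macromolecular structures used to
#' exercise every code path -- multiple models and chains, polymers and
#' ligands, waters, alternate locations, insertion codes, and coordinate
#' steps large enough to force recursive-index continuation groups --
#' without downloading anything. Successive-atom coordinate steps are drawn
#' near covalent-bond scale (about 1.5 A) by default, which is what keeps
#' delta plus recursive-index encoding at one element per value in real
#' files; the heavy-tail option injects rare jumps beyond 32.767 A to force
#' multi-element groups. No physical realism is attempted beyond that
#' statistical shape.
#'
#' @name fixtures
NULL

.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic structure
#'
#' @param seed integer RNG seed; the same spec always yields a byte-identical
#'   structure.
#' @param n_models number of models (same topology, fresh coordinates).
#' @param chains_per_model polymer chains per model.
#' @param residues_per_chain residues per polymer chain.
#' @param vocabulary residue names drawn from the bundled templates.
#' @param n_ligands LG1 ligand groups (12 atoms each) per model.
#' @param n_waters water groups per model.
#' @param step_mean mean coordinate step between successive atoms, Angstrom.
#' @param heavy_tail inject at least one step beyond 32.767 A so the
#'   quantized delta overflows 16 bits.
#' @param occupancy `"constant"` (all 1.0) or `"mixed"` (0.01-grid values).
#' @param b_factor_scale random-walk step of the B-factor column.
#' @param alt_locs duplicate one side-chain atom as an A/B alternate pair.
#' @param ins_codes give one residue an insertion code.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_models = 1L, chains_per_model = 1L,
                         residues_per_chain = 5L,
                         vocabulary = c("GLY", "ALA", "SER"),
                         n_ligands = 0L, n_waters = 0L,
                         step_mean = 1.5, heavy_tail = FALSE,
                         occupancy = c("constant", "mixed"),
                         b_factor_scale = 0.5,
                         alt_locs = FALSE, ins_codes = FALSE) {
  occupancy <- match.arg(occupancy)
  stopifnot(n_models >= 0, chains_per_model >= 0, residues_per_chain >= 0,
            n_ligands >= 0, n_waters >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic raw structure
#'
#' @param spec a [fixture_spec()].
#' @return an `mmtf_raw` structure that always passes
#'   [check_raw_structure()] and encodes cleanly under both profiles.
#' @export
make_structure <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  templates <- mmtf_templates()
  .with_seed(spec$seed, {
    chain_rows <- list(); group_rows <- list(); atom_cols <- list()
    n_chains <- 0L; n_groups <- 0L
    add_chain <- function(model, id) {
      n_chains <<- n_chains + 1L
      chain_rows[[n_chains]] <<- list(model = model, chain_id = id, chain_name = id)
      n_chains
    }
    add_atoms <- function(df) atom_cols[[length(atom_cols) + 1L]] <<- df

    # residue names are fixed by the seed once, shared across models
    res_names <- if (spec$residues_per_chain > 0L && spec$chains_per_model > 0L) {
      matrix(sample(spec$vocabulary, spec$chains_per_model * spec$residues_per_chain,
                    replace = TRUE),
             nrow = spec$chains_per_model)
    } else matrix(character(0), nrow = 0L)

    for (mi in seq_len(spec$n_models)) {
      serial <- 0L
      pos <- c(0, 0, 0)
      bfac <- 20
      step_one <- function() {
        jump <- spec$heavy_tail && stats::runif(1) < 0.005
        len <- if (jump) stats::runif(1, 40, 80) else abs(stats::rnorm(1, spec$step_mean, 0.2))
        dir <- stats::rnorm(3)
        pos <<- pos + len * dir / sqrt(sum(dir^2))
        round(pos, 3)
      }
      occ_one <- function() {
        if (spec$occupancy == "constant") 1 else sample(c(1, 0.5, 0.25), 1L)
      }
      bf_one <- function() {
        bfac <<- max(0, bfac + stats::rnorm(1, 0, spec$b_factor_scale))
        round(bfac, 2)
      }
      emit_group <- function(chain_idx, name, group_id, ins_code = "",
                             alt_dup = FALSE) {
        n_groups <<- n_groups + 1L
        group_rows[[n_groups]] <<- list(chain = chain_idx, name = name,
                                        group_id = group_id, ins_code = ins_code)
        tpl <- templates[[name]]
        anames <- tpl$atom_names; elems <- tpl$elements; chg <- tpl$formal_charges
        alt <- rep("", length(anames))
        if (alt_dup && length(anames) >= 5L) {
          k <- 5L  # duplicate the fifth atom (a side-chain position)
          anames <- append(anames, anames[k], after = k)
          elems <- append(elems, elems[k], after = k)
          chg <- append(chg, chg[k], after = k)
          alt <- rep("", length(anames)); alt[k] <- "A"; alt[k + 1L] <- "B"
        }
        coords <- t(vapply(seq_along(anames), function(i) step_one(), numeric(3)))
        occ <- vapply(seq_along(anames), function(i) occ_one(), numeric(1))
        if (any(alt != "")) occ[alt != ""] <- 0.5
        bf <- vapply(seq_along(anames), function(i) bf_one(), numeric(1))
        add_atoms(data.frame(
          group = n_groups, name = anames, element = elems,
          x = coords[, 1], y = coords[, 2], z = coords[, 3],
          occupancy = occ, b_factor = bf, alt_loc = alt,
          serial = serial + seq_along(anames), formal_charge = chg,
          stringsAsFactors = FALSE))
        serial <<- serial + length(anames)
      }

      for (ci in seq_len(spec$chains_per_model)) {
        chain_idx <- add_chain(mi, LETTERS[ci])
        pos <- pos + c(10, 0, 0)
        for (ri in seq_len(spec$residues_per_chain)) {
          ins <- if (spec$ins_codes && ri == 2L && spec$residues_per_chain >= 2L) "A" else ""
          gid <- if (nzchar(ins)) ri - 1L else ri
          emit_group(chain_idx, res_names[ci, ri], gid, ins,
                     alt_dup = spec$alt_locs && ri == 1L)
        }
      }
      if (spec$n_ligands > 0L) {
        lig_chain <- add_chain(mi, "L")
        for (k in seq_len(spec$n_ligands)) {
          pos <- pos + c(0, 10, 0)
          emit_group(lig_chain, "LG1", k)
        }
      }
      if (spec$n_waters > 0L) {
        wat_chain <- add_chain(mi, "W")
        for (k in seq_len(spec$n_waters)) {
          pos <- pos + c(0, 0, 8)
          emit_group(wat_chain, "HOH", k)
        }
      }
    }
    chains <- do.call(rbind, lapply(chain_rows, function(r) {
      data.frame(model = r$model, chain_id = r$chain_id, chain_name = r$chain_name,
                 stringsAsFactors = FALSE)
    })) %||% data.frame(model = integer(0), chain_id = character(0),
                        chain_name = character(0))
    groups <- do.call(rbind, lapply(group_rows, function(r) {
      data.frame(chain = r$chain, name = r$name, group_id = r$group_id,
                 ins_code = r$ins_code, stringsAsFactors = FALSE)
    })) %||% data.frame(chain = integer(0), name = character(0),
                        group_id = numeric(0), ins_code = character(0))
    atoms <- do.call(rbind, atom_cols)
    if (is.null(atoms)) {
      atoms <- data.frame(group = integer(0), name = character(0),
                          element = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), occupancy = numeric(0),
                          b_factor = numeric(0), alt_loc = character(0),
                          serial = numeric(0), formal_charge = numeric(0))
    }
    raw_structure(atoms, groups, chains, n_models = spec$n_models,
                  metadata = list(structureId = "SYNT",
                                  title = "synthetic structure"))
  })
}

#' Worked-example columns for the codec pipelines
#'
#' The three canonical inputs of the columnar-encoding walk-through:
#' 2,000 occupancy values of 1.0; atom serial numbers 1..2000; and a
#' coordinate stream whose quantized (x1000) deltas begin 32,867, 2,001
#' and 1,053 -- the first of which overflows the 16-bit range and must be
#' decomposed by recursive indexing.
#'
#' @return named list with `occupancies`, `serials` and `coordinates`.
#' @export
make_worked_example_columns <- function() {
  deltas <- c(32867, 2001, 1053)
  list(
    occupancies = rep(1.0, 2000L),
    serials = as.numeric(1:2000),
    coordinates = cumsum(deltas) / 1000
  )
}

# ---- plain-text emitters (fixture support for the parser tests) --------

# Render a raw structure as fixed-column PDB lines.
write_pdb_text <- function(raw) {
  a <- raw$atoms; g <- raw$groups; ch <- raw$chains
  out <- character(0)
  multi <- raw$n_models > 1L
  for (mi in seq_len(raw$n_models)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", mi))
    for (ci in which(ch$model == mi)) {
      for (gi in which(g$chain == ci)) {
        rows <- which(a$group == gi)
        het <- classify_group(g$name[gi]) %in% c("water", "non-polymer")
        for (r in rows) {
          nm <- a$name[r]
          nm_f <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
          chg <- a$formal_charge[r]
          chg_f <- if (chg > 0) sprintf("%d+", chg) else if (chg < 0) sprintf("%d-", -chg) else "  "
          out <- c(out, sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
                                if (het) "HETATM" else "ATOM", a$serial[r], nm_f,
                                a$alt_loc[r], g$name[gi], ch$chain_id[ci],
                                g$group_id[gi], g$ins_code[gi],
                                a$x[r], a$y[r], a$z[r], a$occupancy[r], a$b_factor[r],
                                a$element[r], chg_f))
        }
      }
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  out
}

# Render a raw structure as a minimal mmCIF atom_site loop.
write_mmcif_text <- function(raw) {
  a <- raw$atoms; g <- raw$groups; ch <- raw$chains
  out <- c("data_synthetic", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.pdbx_PDB_model_num")
  q <- function(x) ifelse(grepl("'", x), sprintf("\"%s\"", x), sprintf("'%s'", x))
  for (mi in seq_len(raw$n_models)) {
    for (ci in which(ch$model == mi)) {
      for (gi in which(g$chain == ci)) {
        rows <- which(a$group == gi)
        het <- classify_group(g$name[gi]) %in% c("water", "non-polymer")
        for (r in rows) {
          out <- c(out, paste(
            if (het) "HETATM" else "ATOM", a$serial[r], a$element[r],
            q(a$name[r]),
            if (nzchar(a$alt_loc[r])) a$alt_loc[r] else ".",
            g$name[gi], ch$chain_id[ci], ch$chain_name[ci], g$group_id[gi],
            if (nzchar(g$ins_code[gi])) g$ins_code[gi] else "?",
            sprintf("%.3f", a$x[r]), sprintf("%.3f", a$y[r]), sprintf("%.3f", a$z[r]),
            sprintf("%.2f", a$occupancy[r]), sprintf("%.2f", a$b_factor[r]),
            a$formal_charge[r], mi))
        }
      }
    }
  }
  c(out, "#")
}
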