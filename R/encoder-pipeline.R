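#' @title Encoder pipeline: from parsed structures to MMTF documents
#'
#' @description
#' End-to-end encoding: starting from a parsed structure, build the
#' group-type dictionary, attach inter-group bonds (author-supplied covalent
#' links plus inferred backbone links), extract flat columns, choose the
#' codec for each field and emit a validated document under the `full`
#' (lossless, 0.001 A coordinates / 0.01 B-factors) or `reduced` (lossy,
#' 0.1 precision, C-alpha / P / non-polymer atom subset) profile.
#'
#' @name encoder-pipeline
NULL

#' Construct a raw (parser-level) structure
#'
#' The intermediate representation produced by the file readers and the
#' synthetic generator, consumed by [encode_structure()]. Atoms are stored
#' flat and are reordered to be contiguous per group.
#'
#' @param atoms data.frame with columns `group` (1-based index into
#'   `groups`), `name`, `element`, `x`, `y`, `z`, `occupancy`, `b_factor`,
#'   `alt_loc`, `serial`, `formal_charge`.
#' @param groups data.frame with columns `chain` (1-based index into
#'   `chains`), `name`, `group_id` (author residue number), `ins_code`.
#' @param chains data.frame with columns `model` (1-based), `chain_id`,
#'   `chain_name`.
#' @param n_models number of models; defaults to the maximum model index.
#' @param inter_bonds data.frame (`atom1`, `atom2`, `order`) of explicit
#'   covalent links, 0-based global atom indices; may be `NULL`.
#' @param entities optional list of entity records
#'   (`description`, `type`, `sequence`, `chain_indices` 0-based).
#' @param sec_struct optional per-group secondary-structure codes
#'   (8-state integers, -1 undefined). Transported, never computed.
#' @param metadata named list of document metadata (structureId, title,
#'   dates, experimentalMethods, spaceGroup, unitCell, resolution, rFree,
#'   rWork, ...).
#' @return an object of class `mmtf_raw`.
#' @export
raw_structure <- function(atoms, groups, chains, n_models = NULL,
                          inter_bonds = NULL, entities = NULL,
                          sec_struct = NULL, metadata = list()) {
  stopifnot(is.data.frame(atoms), is.data.frame(groups), is.data.frame(chains))
  if (nrow(atoms) > 0L && is.unsorted(atoms$group)) {
    ord <- order(atoms$group)
    atoms <- atoms[ord, , drop = FALSE]
    if (!is.null(inter_bonds) && nrow(inter_bonds) > 0L) {
      remap <- integer(nrow(atoms)); remap[ord] <- seq_len(nrow(atoms))
      inter_bonds$atom1 <- remap[inter_bonds$atom1 + 1L] - 1L
      inter_bonds$atom2 <- remap[inter_bonds$atom2 + 1L] - 1L
    }
  }
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, groups = groups, chains = chains,
                      n_models = n_models %||% if (nrow(chains) > 0L) max(chains$model) else 0L,
                      inter_bonds = inter_bonds %||% data.frame(atom1 = numeric(0), atom2 = numeric(0), order = numeric(0)),
                      entities = entities, sec_struct = sec_struct,
                      metadata = metadata),
                 class = "mmtf_raw")
  check_raw_structure(s)
  s
}

#' Integrity checks on a raw structure
#'
#' @param raw an `mmtf_raw`.
#' @return `raw`, invisibly; stops on violations.
#' @export
check_raw_structure <- function(raw) {
  a <- raw$atoms; g <- raw$groups; ch <- raw$chains
  if (nrow(a) > 0L) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      stop("mmtf integrity error: non-finite coordinate", call. = FALSE)
    if (any(a$group < 1L | a$group > nrow(g)))
      stop("mmtf integrity error: atom references a missing group", call. = FALSE)
    model_of_atom <- ch$model[g$chain[a$group]]
    if (any(tapply(a$serial, model_of_atom, anyDuplicated) > 0))
      stop("mmtf integrity error: duplicate atom serial within a model", call. = FALSE)
  }
  if (nrow(g) > 0L && any(g$chain < 1L | g$chain > nrow(ch)))
    stop("mmtf integrity error: group references a missing chain", call. = FALSE)
  b <- raw$inter_bonds
  if (nrow(b) > 0L && any(c(b$atom1, b$atom2) < 0 | c(b$atom1, b$atom2) >= nrow(a)))
    stop("mmtf integrity error: bond record references a missing atom", call. = FALSE)
  invisible(raw)
}

#' @export
print.mmtf_raw <- function(x, ...) {
  cat(sprintf("raw structure: %d model(s), %d chain(s), %d group(s), %d atom(s), %d explicit bond(s)\n",
              x$n_models, nrow(x$chains), nrow(x$groups), nrow(x$atoms), nrow(x$inter_bonds)))
  invisible(x)
}

#' Encoding profiles
#'
#' `full`: all atoms, coordinates at 0.001 A (divisor 1000), B-factors at
#' 0.01 (divisor 100), occupancies at 0.01 (divisor 100). `reduced`:
#' C-alpha of each polypeptide group, P of each polynucleotide group, all
#' atoms of non-polymer groups, waters removed; 0.1 precision throughout
#' (divisor 10).
#'
#' @param name `"full"` or `"reduced"`.
#' @return list with the profile's divisors and name.
#' @export
encoding_profile <- function(name = c("full", "reduced")) {
  name <- match.arg(name)
  if (name == "full") {
    list(name = "full", coord_divisor = 1000L, b_factor_divisor = 100L, occupancy_divisor = 100L)
  } else {
    list(name = "reduced", coord_divisor = 10L, b_factor_divisor = 10L, occupancy_divisor = 10L)
  }
}

# ---- group dictionary ---------------------------------------------------

#' Build the group-type dictionary
#'
#' One dictionary entry per unique signature (group name plus the ordered
#' atom name / element / formal charge lists and the resulting bond set);
#' instances sharing a signature share an index. Residues whose atom order
#' deviates get their own entry rather than a corrupt mapping. Intra-residue
#' bonds and orders come from the component template when one is available;
#' otherwise the bond list is empty and a warning is logged once per
#' component.
#'
#' @param raw an `mmtf_raw`.
#' @param templates named list of component templates
#'   (see [read_component_dictionary()]); `NULL` for the bundled dictionary.
#' @return list with `dictionary` (list of [group_type()] entries) and
#'   `indices` (0-based per-group dictionary indices).
#' @export
build_group_dictionary <- function(raw, templates = NULL) {
  if (is.null(templates)) templates <- mmtf_templates()
  g <- raw$groups; a <- raw$atoms
  atom_rows <- split(seq_len(nrow(a)), factor(a$group, levels = seq_len(nrow(g))))
  missing_tpl <- character(0)

  entries <- vector("list", nrow(g))
  sigs <- character(nrow(g))
  for (gi in seq_len(nrow(g))) {
    rows <- atom_rows[[gi]]
    nm <- g$name[gi]
    anames <- a$name[rows]
    elems <- a$element[rows]
    tpl <- templates[[nm]]
    if (is.null(tpl)) {
      if (!(nm %in% missing_tpl)) missing_tpl <- c(missing_tpl, nm)
      charges <- a$formal_charge[rows]
      bond_atoms <- numeric(0); bond_orders <- numeric(0)
    } else {
      charges <- tpl$formal_charges[match(anames, tpl$atom_names)]
      charges[is.na(charges)] <- a$formal_charge[rows][is.na(charges)]
      keep <- tpl$bond_atom1 %in% anames & tpl$bond_atom2 %in% anames
      i1 <- match(tpl$bond_atom1[keep], anames) - 1L
      i2 <- match(tpl$bond_atom2[keep], anames) - 1L
      bond_atoms <- as.numeric(rbind(i1, i2))
      bond_orders <- tpl$bond_orders[keep]
    }
    entries[[gi]] <- group_type(
      group_name = nm,
      single_letter_code = single_letter_code(nm),
      chem_comp_type = if (!is.null(tpl) && !is.null(tpl$chem_comp_type)) tpl$chem_comp_type else unname(chem_comp_type_for(nm)),
      atom_names = anames, elements = elems, formal_charges = charges,
      intra_bond_atoms = bond_atoms, intra_bond_orders = bond_orders
    )
    sigs[gi] <- paste(nm, paste(anames, collapse = ","), paste(elems, collapse = ","),
                      paste(charges, collapse = ","), paste(bond_atoms, collapse = ","),
                      paste(bond_orders, collapse = ","), sep = "|")
  }
  if (length(missing_tpl) > 0L) {
    warning(sprintf("no component template for %s; intra-residue bonds left empty",
                    paste(missing_tpl, collapse = ", ")), call. = FALSE)
  }
  first <- !duplicated(sigs)
  dict <- entries[first]
  indices <- match(sigs, sigs[first]) - 1L
  list(dictionary = dict, indices = indices)
}

# ---- inter-group bonds --------------------------------------------------

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Collect inter-group bonds
#'
#' Author-supplied covalent links (disulfides, ligand-polymer attachments)
#' plus inferred backbone links between consecutive polymer groups of one
#' chain: peptide C-N (accepted below 2.0 A) and phosphodiester O3'-P
#' (below 2.2 A). The distance caps stop bonds from being drawn across
#' chain breaks. Deduplicated and undirected.
#'
#' @param raw an `mmtf_raw`.
#' @return data.frame (`atom1`, `atom2`, `order`), 0-based atom indices.
#' @export
attach_inter_group_bonds <- function(raw) {
  check_raw_structure(raw)
  a <- raw$atoms; g <- raw$groups
  bonds <- raw$inter_bonds[, c("atom1", "atom2", "order"), drop = FALSE]

  cls <- classify_group(g$name)
  atom_rows <- split(seq_len(nrow(a)), factor(a$group, levels = seq_len(nrow(g))))
  find_atom <- function(gi, nm) {
    rows <- atom_rows[[gi]]
    rows[match(nm, a$name[rows])]
  }
  for (ci in seq_len(nrow(raw$chains))) {
    gis <- which(g$chain == ci)
    if (length(gis) < 2L) next
    for (k in seq_len(length(gis) - 1L)) {
      g1 <- gis[k]; g2 <- gis[k + 1L]
      if (cls[g1] == "polypeptide" && cls[g2] == "polypeptide") {
        i <- find_atom(g1, "C"); j <- find_atom(g2, "N"); cap <- 2.0
      } else if (cls[g1] == "polynucleotide" && cls[g2] == "polynucleotide") {
        i <- find_atom(g1, "O3'"); j <- find_atom(g2, "P"); cap <- 2.2
      } else next
      if (is.na(i) || is.na(j)) next
      d <- .dist3(c(a$x[i], a$y[i], a$z[i]), c(a$x[j], a$y[j], a$z[j]))
      if (d < cap) {
        bonds <- rbind(bonds, data.frame(atom1 = i - 1L, atom2 = j - 1L, order = 1))
      }
    }
  }
  if (nrow(bonds) > 0L) {
    lo <- pmin(bonds$atom1, bonds$atom2)
    hi <- pmax(bonds$atom1, bonds$atom2)
    keep <- !duplicated(paste(lo, hi))
    bonds <- data.frame(atom1 = lo[keep], atom2 = hi[keep], order = bonds$order[keep])
  }
  rownames(bonds) <- NULL
  bonds
}

# ---- reduced profile ----------------------------------------------------

#' Reduce a structure to the lossy-profile atom subset
#'
#' Keeps exactly the C-alpha atom of each polypeptide group, the P atom of
#' each polynucleotide group and all atoms of non-polymer groups; removes
#' water groups entirely. Polymer groups lacking their representative atom
#' are dropped with a warning. Idempotent.
#'
#' @param raw an `mmtf_raw`.
#' @return a reduced `mmtf_raw`.
#' @export
reduce_structure <- function(raw) {
  a <- raw$atoms; g <- raw$groups
  cls <- classify_group(g$name)
  cls_atom <- cls[a$group]
  keep_atom <- (cls_atom == "polypeptide" & a$name == "CA" & a$element == "C") |
               (cls_atom == "polynucleotide" & a$name == "P") |
               (cls_atom == "non-polymer")

  kept_groups <- sort(unique(a$group[keep_atom]))
  dropped_poly <- setdiff(which(cls %in% c("polypeptide", "polynucleotide")), kept_groups)
  if (length(dropped_poly) > 0L) {
    warning(sprintf("reduced profile: dropped %d polymer group(s) lacking a representative atom",
                    length(dropped_poly)), call. = FALSE)
  }

  old_atom_keep <- which(keep_atom)
  atoms <- a[old_atom_keep, , drop = FALSE]
  group_map <- match(seq_len(nrow(g)), kept_groups)     # old group -> new index
  atoms$group <- group_map[atoms$group]
  groups <- g[kept_groups, , drop = FALSE]
  rownames(atoms) <- rownames(groups) <- NULL

  b <- raw$inter_bonds
  if (nrow(b) > 0L) {
    atom_map <- match(seq_len(nrow(a)), old_atom_keep)  # old 1-based -> new 1-based
    n1 <- atom_map[b$atom1 + 1L]; n2 <- atom_map[b$atom2 + 1L]
    ok <- !is.na(n1) & !is.na(n2)
    b <- data.frame(atom1 = n1[ok] - 1L, atom2 = n2[ok] - 1L, order = b$order[ok])
  }
  sec <- raw$sec_struct
  if (!is.null(sec)) sec <- sec[kept_groups]

  raw_structure(atoms, groups, raw$chains, n_models = raw$n_models,
                inter_bonds = b, entities = raw$entities,
                sec_struct = sec, metadata = raw$metadata)
}

# ---- entity bookkeeping -------------------------------------------------

# One entity per chain when the parser supplied none. A chain holding any
# polymer groups is a polymer entity whose sequence is the single-letter
# string of its polymer groups; water-only chains are "water"; the rest
# "non-polymer".
.derive_entities <- function(raw) {
  g <- raw$groups
  cls <- classify_group(g$name)
  lapply(seq_len(nrow(raw$chains)), function(ci) {
    gis <- which(g$chain == ci)
    poly <- gis[cls[gis] %in% c("polypeptide", "polynucleotide")]
    if (length(poly) > 0L) {
      list(description = "", type = "polymer",
           sequence = paste(single_letter_code(g$name[poly]), collapse = ""),
           chain_indices = ci - 1)
    } else if (length(gis) > 0L && all(cls[gis] == "water")) {
      list(description = "", type = "water", sequence = "", chain_indices = ci - 1)
    } else {
      list(description = "", type = "non-polymer", sequence = "", chain_indices = ci - 1)
    }
  })
}

# 0-based index of each group within its entity sequence; -1 for
# non-polymer groups and groups of non-polymer entities.
.sequence_indices <- function(raw, entities) {
  g <- raw$groups
  cls <- classify_group(g$name)
  out <- rep(-1, nrow(g))
  chain_entity <- rep(NA_integer_, nrow(raw$chains))
  for (ei in seq_along(entities)) {
    chain_entity[entities[[ei]]$chain_indices + 1] <- ei
  }
  for (ci in seq_len(nrow(raw$chains))) {
    ei <- chain_entity[ci]
    if (is.na(ei) || entities[[ei]]$type != "polymer") next
    gis <- which(g$chain == ci)
    poly <- gis[cls[gis] %in% c("polypeptide", "polynucleotide")]
    out[poly] <- seq_along(poly) - 1
  }
  out
}

# ---- encoding -----------------------------------------------------------

#' Encode a raw structure into an MMTF document
#'
#' Extracts flat columns in atom order and applies the per-field codecs:
#' coordinates and B-factors as fixed-point + delta + recursive indexing
#' (codec 10), occupancies as fixed-point + run-length (codec 9), serials,
#' residue numbers and sequence indices as delta + run-length (codec 8),
#' char columns run-length (codec 6), chain identifiers as fixed-width
#' strings (codec 5), dictionary indices and inter-group bond atoms as
#' plain int32 (codec 4), bond orders and secondary structure as int8
#' (codec 2). The produced document always passes [validate_mmtf()].
#'
#' @param raw an `mmtf_raw`.
#' @param profile `"full"`, `"reduced"`, or an [encoding_profile()] list.
#' @param templates component templates for [build_group_dictionary()].
#' @param producer producer string written into the document (fixed by
#'   default so conversion is deterministic).
#' @return an `mmtf_document`.
#' @export
encode_structure <- function(raw, profile = "full", templates = NULL,
                             producer = .MMTF_PRODUCER) {
  stopifnot(inherits(raw, "mmtf_raw"))
  if (is.character(profile)) profile <- encoding_profile(profile)
  if (profile$name == "reduced") raw <- reduce_structure(raw)
  check_raw_structure(raw)

  a <- raw$atoms; g <- raw$groups; ch <- raw$chains
  bonds <- attach_inter_group_bonds(raw)
  dict <- build_group_dictionary(raw, templates)
  entities <- raw$entities %||% .derive_entities(raw)
  seq_idx <- .sequence_indices(raw, entities)

  intra_counts <- vapply(dict$dictionary, function(e) length(e$intra_bond_orders), numeric(1))
  num_bonds <- nrow(bonds) + sum(intra_counts[dict$indices + 1L])

  groups_per_chain <- as.numeric(table(factor(g$chain, levels = seq_len(nrow(ch)))))
  chains_per_model <- as.numeric(table(factor(ch$model, levels = seq_len(raw$n_models))))

  md <- raw$metadata
  fields <- list(
    mmtfVersion = .MMTF_VERSION,
    mmtfProducer = producer,
    structureId = md$structureId, title = md$title,
    depositionDate = md$depositionDate, releaseDate = md$releaseDate,
    experimentalMethods = md$experimentalMethods,
    spaceGroup = md$spaceGroup, unitCell = md$unitCell,
    ncsOperatorList = md$ncsOperatorList,
    resolution = md$resolution, rFree = md$rFree, rWork = md$rWork,
    bioAssemblyList = md$bioAssemblyList,
    entityList = entities,
    numModels = as.integer(raw$n_models),
    numChains = nrow(ch), numGroups = nrow(g), numAtoms = nrow(a),
    numBonds = num_bonds,
    chainsPerModel = chains_per_model,
    groupsPerChain = groups_per_chain,
    groupList = dict$dictionary,
    chainIdList = encode_column(ch$chain_id, 5L, 4L),
    chainNameList = encode_column(ch$chain_name, 5L, 4L),
    groupTypeList = encode_column(dict$indices, 4L),
    groupIdList = encode_column(g$group_id, 8L),
    insCodeList = encode_column(g$ins_code, 6L),
    altLocList = encode_column(a$alt_loc, 6L),
    sequenceIndexList = encode_column(seq_idx, 8L),
    xCoordList = encode_column(a$x, 10L, profile$coord_divisor),
    yCoordList = encode_column(a$y, 10L, profile$coord_divisor),
    zCoordList = encode_column(a$z, 10L, profile$coord_divisor),
    bFactorList = encode_column(a$b_factor, 10L, profile$b_factor_divisor),
    occupancyList = encode_column(a$occupancy, 9L, profile$occupancy_divisor),
    atomIdList = encode_column(a$serial, 8L)
  )
  if (!is.null(raw$sec_struct)) {
    fields$secStructList <- encode_column(raw$sec_struct, 2L)
  }
  if (nrow(bonds) > 0L) {
    fields$bondAtomList <- encode_column(as.numeric(t(as.matrix(bonds[, c("atom1", "atom2")]))), 4L)
    fields$bondOrderList <- encode_column(bonds$order, 2L)
  } else {
    fields$bondAtomList <- encode_column(numeric(0), 4L)
    fields$bondOrderList <- encode_column(numeric(0), 2L)
  }
  fields <- Filter(Negate(is.null), fields)
  doc <- mmtf_document(fields)
  violations <- validate_mmtf(doc)
  if (length(violations) > 0L) {
    stop(paste0("mmtf schema error (encoder produced an inconsistent document):\n  ",
                paste(violations, collapse = "\n  ")), call. = FALSE)
  }
  doc
}
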