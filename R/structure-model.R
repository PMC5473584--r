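#' @title Decoded structures and hierarchical traversal
#'
#' @description
#' A decoded structure keeps the flat columnar layout of the file -- all
#' x-coordinates together, all B-factors together, and so on -- plus derived
#' offset tables that make hierarchical traversal (models -> chains ->
#' groups -> atoms) a matter of index arithmetic rather than nested objects.
#'
#' @name structure-model
NULL

#' Construct a group dictionary entry
#'
#' One entry per unique residue type: atom names, elements, formal charges
#' and the intra-residue bonds with their orders, stored once and referenced
#' by index from every instance of the residue.
#'
#' @param group_name component code (e.g. "SER").
#' @param single_letter_code one-character code ("?" when none applies).
#' @param chem_comp_type Chemical Component Dictionary type string.
#' @param atom_names,elements,formal_charges parallel per-atom vectors.
#' @param intra_bond_atoms flat pairs of 0-based indices into `atom_names`.
#' @param intra_bond_orders bond orders in 1..4, one per pair.
#' @return an object of class `mmtf_group_type`.
#' @export
group_type <- function(group_name, single_letter_code = "?",
                       chem_comp_type = "NON-POLYMER",
                       atom_names = character(0), elements = character(0),
                       formal_charges = numeric(0),
                       intra_bond_atoms = numeric(0),
                       intra_bond_orders = numeric(0)) {
  stopifnot(length(atom_names) == length(elements),
            length(atom_names) == length(formal_charges),
            length(intra_bond_atoms) == 2L * length(intra_bond_orders))
  structure(list(group_name = group_name,
                 single_letter_code = single_letter_code,
                 chem_comp_type = chem_comp_type,
                 atom_names = as.character(atom_names),
                 elements = as.character(elements),
                 formal_charges = as.numeric(formal_charges),
                 intra_bond_atoms = as.numeric(intra_bond_atoms),
                 intra_bond_orders = as.numeric(intra_bond_orders)),
            class = "mmtf_group_type")
}

#' Decode an MMTF document into flat structure data
#'
#' Decodes every columnar field through the codec registry and computes the
#' offset tables: first atom index per group, first group index per chain,
#' first chain index per model (all 0-based, closed below / open above).
#'
#' @param doc an `mmtf_document`.
#' @return an object of class `mmtf_structure`: a list of decoded columns,
#'   the group dictionary, metadata and offset tables.
#' @export
decode_structure <- function(doc) {
  stopifnot(inherits(doc, "mmtf_document"))
  col <- function(f) {
    v <- mmtf_column(doc, f)
    attributes(v) <- NULL   # drop codec bookkeeping from the data columns
    v
  }

  dict <- doc$groupList
  group_types <- col("groupTypeList")
  atoms_per_group <- if (length(dict) > 0L && length(group_types) > 0L) {
    vapply(dict, function(g) length(g$atom_names), numeric(1))[group_types + 1L]
  } else numeric(0)

  s <- list(
    num_models = doc$numModels, num_chains = doc$numChains,
    num_groups = doc$numGroups, num_atoms = doc$numAtoms,
    num_bonds = doc$numBonds,
    chains_per_model = doc$chainsPerModel,
    groups_per_chain = doc$groupsPerChain,
    chain_ids = col("chainIdList"),
    chain_names = col("chainNameList"),
    group_types = group_types,
    group_ids = col("groupIdList"),
    ins_codes = col("insCodeList"),
    alt_locs = col("altLocList"),
    sequence_indices = col("sequenceIndexList"),
    sec_struct = col("secStructList"),
    x = col("xCoordList"), y = col("yCoordList"), z = col("zCoordList"),
    b_factors = col("bFactorList"),
    occupancies = col("occupancyList"),
    atom_ids = col("atomIdList"),
    inter_bond_atoms = col("bondAtomList"),
    inter_bond_orders = col("bondOrderList"),
    group_dictionary = dict,
    entities = doc$entityList,
    bio_assemblies = doc$bioAssemblyList,
    metadata = doc[intersect(.mmtf_scalar_fields, names(doc))],
    unit_cell = doc$unitCell,
    space_group = doc$spaceGroup,
    atoms_per_group = atoms_per_group,
    group_atom_offset = c(0, cumsum(atoms_per_group))[seq_len(max(doc$numGroups, 0) + 1L)],
    chain_group_offset = c(0, cumsum(doc$groupsPerChain)),
    model_chain_offset = c(0, cumsum(doc$chainsPerModel))
  )
  class(s) <- "mmtf_structure"
  s
}

#' @export
print.mmtf_structure <- function(x, ...) {
  cat(write_summary(x), sep = "\n")
  invisible(x)
}

#' Depth-first traversal of the structure hierarchy
#'
#' Visits models in file order, each model's chains, each chain's groups and
#' each group's atoms in dictionary order, invoking the supplied callbacks.
#' Chain callbacks receive both the internal chain id and the author chain
#' name, plus the chain's group count; group callbacks the author residue
#' number, group name and dictionary type index; atom callbacks name,
#' element, coordinates and serial.
#'
#' @param structure an `mmtf_structure`.
#' @param model,chain,group,atom optional callback functions; see Details.
#' @return invisibly, a list of visit counts
#'   (`models`, `chains`, `groups`, `atoms`).
#' @details Callback signatures:
#' \itemize{
#'   \item `model(model_index)` -- 0-based model index.
#'   \item `chain(model_index, chain_index, chain_id, chain_name, n_groups)`
#'   \item `group(chain_index, group_index, group_id, group_name, group_type)`
#'   \item `atom(group_index, atom_index, name, element, x, y, z, serial)`
#' }
#' All indices are 0-based global indices, matching the file's own bond and
#' dictionary references.
#' @export
traverse <- function(structure, model = NULL, chain = NULL,
                     group = NULL, atom = NULL) {
  stopifnot(inherits(structure, "mmtf_structure"))
  s <- structure
  counts <- c(models = 0, chains = 0, groups = 0, atoms = 0)
  dict_names <- vapply(s$group_dictionary, function(g) g$group_name, character(1))
  for (mi in seq_len(s$num_models)) {
    counts["models"] <- counts["models"] + 1
    if (!is.null(model)) model(mi - 1L)
    ch_lo <- s$model_chain_offset[mi] + 1L
    ch_hi <- s$model_chain_offset[mi + 1L]
    for (ci in seq_len(ch_hi - ch_lo + 1L) + ch_lo - 1L) {
      if (ci > ch_hi) break
      counts["chains"] <- counts["chains"] + 1
      g_lo <- s$chain_group_offset[ci] + 1L
      g_hi <- s$chain_group_offset[ci + 1L]
      if (!is.null(chain)) {
        chain(mi - 1L, ci - 1L, s$chain_ids[ci], s$chain_names[ci], g_hi - g_lo + 1L)
      }
      for (gi in seq_len(g_hi - g_lo + 1L) + g_lo - 1L) {
        if (gi > g_hi) break
        counts["groups"] <- counts["groups"] + 1
        gt <- s$group_types[gi]
        if (!is.null(group)) {
          group(ci - 1L, gi - 1L, s$group_ids[gi], dict_names[gt + 1L], gt)
        }
        a_lo <- s$group_atom_offset[gi] + 1L
        a_hi <- s$group_atom_offset[gi + 1L]
        entry <- s$group_dictionary[[gt + 1L]]
        for (ai in seq_len(a_hi - a_lo + 1L) + a_lo - 1L) {
          if (ai > a_hi) break
          counts["atoms"] <- counts["atoms"] + 1
          if (!is.null(atom)) {
            atom(gi - 1L, ai - 1L, entry$atom_names[ai - a_lo + 1L],
                 entry$elements[ai - a_lo + 1L],
                 s$x[ai], s$y[ai], s$z[ai], s$atom_ids[ai])
          }
        }
      }
    }
  }
  invisible(as.list(counts))
}

#' Reconstruct the complete bond list
#'
#' The union of (a) each group instance's intra-residue bonds from the
#' dictionary, offset by the instance's first atom index, and (b) the
#' inter-group bond column. The total equals `num_bonds`.
#'
#' @param structure an `mmtf_structure`.
#' @return data.frame with 0-based `atom1`, `atom2` and `order` columns.
#' @export
reconstruct_bonds <- function(structure) {
  stopifnot(inherits(structure, "mmtf_structure"))
  s <- structure
  a1 <- list(); a2 <- list(); ord <- list()
  for (gi in seq_len(s$num_groups)) {
    entry <- s$group_dictionary[[s$group_types[gi] + 1L]]
    nb <- length(entry$intra_bond_orders)
    if (nb == 0L) next
    off <- s$group_atom_offset[gi]
    idx <- entry$intra_bond_atoms + off
    a1[[length(a1) + 1L]] <- idx[seq(1L, 2L * nb, by = 2L)]
    a2[[length(a2) + 1L]] <- idx[seq(2L, 2L * nb, by = 2L)]
    ord[[length(ord) + 1L]] <- entry$intra_bond_orders
  }
  inter <- s$inter_bond_atoms
  if (length(inter) > 0L) {
    a1[[length(a1) + 1L]] <- inter[seq(1L, length(inter), by = 2L)]
    a2[[length(a2) + 1L]] <- inter[seq(2L, length(inter), by = 2L)]
    o <- s$inter_bond_orders
    if (length(o) == 0L) o <- rep(1, length(inter) / 2L)
    ord[[length(ord) + 1L]] <- o
  }
  bonds <- data.frame(atom1 = unlist(a1, use.names = FALSE) %||% numeric(0),
                      atom2 = unlist(a2, use.names = FALSE) %||% numeric(0),
                      order = unlist(ord, use.names = FALSE) %||% numeric(0))
  if (nrow(bonds) > 0L &&
      (any(bonds$atom1 < 0 | bonds$atom1 >= s$num_atoms) ||
       any(bonds$atom2 < 0 | bonds$atom2 >= s$num_atoms))) {
    stop("mmtf integrity error: bond references an atom index outside the structure", call. = FALSE)
  }
  if (nrow(bonds) > 0L && any(bonds$atom1 == bonds$atom2)) {
    stop("mmtf integrity error: self-bond in bond list", call. = FALSE)
  }
  bonds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat per-atom context used by select_atoms (and the reducer).
.atom_context <- function(structure) {
  s <- structure
  group_of_atom <- rep(seq_len(s$num_groups), s$atoms_per_group)
  chain_of_group <- rep(seq_len(s$num_chains), s$groups_per_chain)
  model_of_chain <- rep(seq_len(s$num_models), s$chains_per_model)
  chain_of_atom <- chain_of_group[group_of_atom]
  names_list <- lapply(s$group_dictionary, function(g) g$atom_names)
  elems_list <- lapply(s$group_dictionary, function(g) g$elements)
  data.frame(
    atom = seq_len(s$num_atoms) - 1,
    name = unlist(names_list[s$group_types + 1L], use.names = FALSE),
    element = unlist(elems_list[s$group_types + 1L], use.names = FALSE),
    group = group_of_atom - 1,
    group_name = vapply(s$group_dictionary, function(g) g$group_name,
                        character(1))[s$group_types + 1L][group_of_atom],
    group_type = s$group_types[group_of_atom],
    chain = chain_of_atom - 1,
    chain_id = s$chain_ids[chain_of_atom],
    chain_name = s$chain_names[chain_of_atom],
    model = model_of_chain[chain_of_atom] - 1,
    stringsAsFactors = FALSE
  )
}

#' Select atoms by predicate on their context
#'
#' @param structure an `mmtf_structure`.
#' @param predicate function taking the atom-context data.frame (columns
#'   `atom`, `name`, `element`, `group`, `group_name`, `group_type`,
#'   `chain`, `chain_id`, `chain_name`, `model`) and returning a logical
#'   vector over atoms.
#' @return ascending 0-based global atom indices of the selected atoms.
#' @examples
#' \dontrun{
#' select_atoms(s, function(ctx) ctx$name == "CA")
#' }
#' @export
select_atoms <- function(structure, predicate) {
  ctx <- .atom_context(structure)
  keep <- predicate(ctx)
  if (!is.logical(keep) || length(keep) != nrow(ctx)) {
    stop("mmtf type error: predicate must return one logical per atom", call. = FALSE)
  }
  ctx$atom[which(keep)]
}
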