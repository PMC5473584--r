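#' @title Fixed-column PDB reading
#'
#' @description
#' Strict fixed-column parsing of the legacy PDB format, covering the
#' ATOM/HETATM/MODEL/ENDMDL/TER/SSBOND/CONECT record subset. The format's
#' own limits apply: files beyond 99,999 atoms (hybrid-36 serials) are
#' rejected with a clear error rather than misread.
#'
#' @name io-pdb
NULL

.pdb_field <- function(lines, from, to) trimws(substr(lines, from, to))

.pdb_num <- function(lines, from, to, what, lineno) {
  s <- .pdb_field(lines, from, to)
  v <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(v) & nzchar(s))
  if (length(bad) > 0L) {
    stop(sprintf("mmtf parse error: malformed %s field at line %d ('%s')",
                 what, lineno[bad[1L]], s[bad[1L]]), call. = FALSE)
  }
  v
}

#' Read a PDB-format file into a raw structure
#'
#' @param text path to a file, a single string, or a character vector of
#'   lines.
#' @return an `mmtf_raw` structure. Models split on MODEL/ENDMDL; SSBOND
#'   records and CONECT records linking different groups become inter-group
#'   bonds; serials, alternate-location indicators and insertion codes are
#'   preserved.
#' @export
read_pdb <- function(text) {
  lines <- .as_lines(text)
  rec <- substr(lines, 1, 6)
  lineno <- seq_along(lines)

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  atom_lines <- lines[is_atom]
  atom_lineno <- lineno[is_atom]
  if (length(atom_lines) == 0L) {
    stop("mmtf format error: no ATOM/HETATM records in PDB input", call. = FALSE)
  }
  if (length(atom_lines) > 99999L) {
    stop("mmtf range error: more than 99,999 atoms cannot be represented in the PDB format", call. = FALSE)
  }

  # model index per line from MODEL/ENDMDL bracketing
  model_idx <- cumsum(rec == "MODEL ")
  if (max(model_idx) == 0L) model_idx <- model_idx + 1L
  model_idx[model_idx == 0L] <- 1L
  model <- model_idx[is_atom]

  serial <- .pdb_num(atom_lines, 7, 11, "atom serial", atom_lineno)
  if (any(is.na(serial))) {
    stop("mmtf parse error: blank or hybrid atom serial (hybrid-36 is unsupported)", call. = FALSE)
  }
  name <- .pdb_field(atom_lines, 13, 16)
  alt <- .pdb_field(atom_lines, 17, 17)
  res_name <- .pdb_field(atom_lines, 18, 20)
  chain <- .pdb_field(atom_lines, 22, 22)
  res_seq <- .pdb_num(atom_lines, 23, 26, "residue number", atom_lineno)
  icode <- .pdb_field(atom_lines, 27, 27)
  x <- .pdb_num(atom_lines, 31, 38, "x coordinate", atom_lineno)
  y <- .pdb_num(atom_lines, 39, 46, "y coordinate", atom_lineno)
  z <- .pdb_num(atom_lines, 47, 54, "z coordinate", atom_lineno)
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    stop("mmtf parse error: blank coordinate field", call. = FALSE)
  }
  occ <- .pdb_num(atom_lines, 55, 60, "occupancy", atom_lineno); occ[is.na(occ)] <- 1
  bfac <- .pdb_num(atom_lines, 61, 66, "B-factor", atom_lineno); bfac[is.na(bfac)] <- 0
  elem <- toupper(.pdb_field(atom_lines, 77, 78))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  chg_s <- .pdb_field(atom_lines, 79, 80)
  charge <- rep(0, length(chg_s))
  has_chg <- grepl("^[0-9][+-]$", chg_s)
  charge[has_chg] <- as.numeric(substr(chg_s[has_chg], 1, 1)) *
    ifelse(substr(chg_s[has_chg], 2, 2) == "-", -1, 1)

  chain_key <- paste(model, chain, sep = "\r")
  chain_f <- match(chain_key, unique(chain_key))
  group_key <- paste(chain_f, res_seq, icode, res_name, sep = "\r")
  group_f <- match(group_key, unique(group_key))

  first_of_chain <- !duplicated(chain_f)
  chains <- data.frame(model = model[first_of_chain],
                       chain_id = chain[first_of_chain],
                       chain_name = chain[first_of_chain],
                       stringsAsFactors = FALSE)
  first_of_group <- !duplicated(group_f)
  groups <- data.frame(chain = chain_f[first_of_group],
                       name = res_name[first_of_group],
                       group_id = res_seq[first_of_group],
                       ins_code = icode[first_of_group],
                       stringsAsFactors = FALSE)
  atoms <- data.frame(group = group_f, name = name, element = elem,
                      x = x, y = y, z = z, occupancy = occ, b_factor = bfac,
                      alt_loc = alt, serial = serial, formal_charge = charge,
                      stringsAsFactors = FALSE)

  inter <- data.frame(atom1 = numeric(0), atom2 = numeric(0), order = numeric(0))
  # SSBOND: disulfide between the SG atoms of two cysteines
  for (li in which(rec == "SSBOND")) {
    l <- lines[li]
    ch1 <- trimws(substr(l, 16, 16)); s1 <- suppressWarnings(as.numeric(substr(l, 18, 21)))
    ch2 <- trimws(substr(l, 30, 30)); s2 <- suppressWarnings(as.numeric(substr(l, 32, 35)))
    if (is.na(s1) || is.na(s2)) {
      stop(sprintf("mmtf parse error: malformed SSBOND record at line %d", li), call. = FALSE)
    }
    i <- which(chain == ch1 & res_seq == s1 & name == "SG")[1]
    j <- which(chain == ch2 & res_seq == s2 & name == "SG")[1]
    if (is.na(i) || is.na(j)) {
      stop(sprintf("mmtf integrity error: SSBOND at line %d references a missing SG atom", li), call. = FALSE)
    }
    inter <- rbind(inter, data.frame(atom1 = i - 1, atom2 = j - 1, order = 1))
  }
  # CONECT: keep pairs that cross a group boundary (intra-residue bonds come
  # from the component dictionary)
  for (li in which(rec == "CONECT")) {
    l <- lines[li]
    f <- suppressWarnings(as.numeric(c(substr(l, 7, 11), substr(l, 12, 16),
                                       substr(l, 17, 21), substr(l, 22, 26),
                                       substr(l, 27, 31))))
    f <- f[!is.na(f)]
    if (length(f) < 2L) next
    i <- match(f[1L], serial)
    for (sj in f[-1L]) {
      j <- match(sj, serial)
      if (is.na(i) || is.na(j)) {
        stop(sprintf("mmtf integrity error: CONECT at line %d references missing serial", li), call. = FALSE)
      }
      if (group_f[i] != group_f[j]) {
        inter <- rbind(inter, data.frame(atom1 = i - 1, atom2 = j - 1, order = 1))
      }
    }
  }
  if (nrow(inter) > 0L) {
    lo <- pmin(inter$atom1, inter$atom2); hi <- pmax(inter$atom1, inter$atom2)
    keep <- !duplicated(paste(lo, hi))
    inter <- data.frame(atom1 = lo[keep], atom2 = hi[keep], order = inter$order[keep])
  }

  md <- list()
  hdr <- which(rec == "HEADER")
  if (length(hdr) > 0L) {
    id <- trimws(substr(lines[hdr[1L]], 63, 66))
    if (nzchar(id)) md$structureId <- id
  }
  ttl <- which(rec == "TITLE ")
  if (length(ttl) > 0L) {
    md$title <- trimws(paste(trimws(substr(lines[ttl], 11, 80)), collapse = " "))
  }

  raw_structure(atoms, groups, chains, n_models = max(model),
                inter_bonds = inter, metadata = md)
}

#' Plain-text summary of a decoded structure
#'
#' The hierarchical print-out as a report: counts, metadata and per-chain
#' group counts in traversal order.
#'
#' @param structure an `mmtf_structure`.
#' @return character vector of report lines.
#' @export
write_summary <- function(structure) {
  stopifnot(inherits(structure, "mmtf_structure"))
  s <- structure
  out <- character(0)
  md <- s$metadata
  if (!is.null(md$structureId)) out <- c(out, sprintf("structure: %s", md$structureId))
  if (!is.null(md$title)) out <- c(out, sprintf("title: %s", md$title))
  out <- c(out,
           sprintf("models: %d", s$num_models),
           sprintf("chains: %d", s$num_chains),
           sprintf("groups: %d", s$num_groups),
           sprintf("atoms: %d", s$num_atoms),
           sprintf("bonds: %d", s$num_bonds))
  traverse(s,
    model = function(mi) out <<- c(out, sprintf("model %d", mi)),
    chain = function(mi, ci, id, nm, ng) {
      out <<- c(out, sprintf("  chain %s (%s): %d groups", id, nm, ng))
    })
  out
}
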