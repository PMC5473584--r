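#' @title Minimal CIF/mmCIF reading
#'
#' @description
#' A small STAR/CIF tokenizer and category reader scoped to the categories
#' this format needs: `atom_site`, `struct_conn`, `cell`, `symmetry`,
#' `entity`, `entity_poly`, `refine`, `struct`, plus `chem_comp_atom` /
#' `chem_comp_bond` for Chemical Component Dictionary templates. Unknown
#' categories are parsed and ignored.
#'
#' @name io-cif
NULL

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(readLines(x, warn = FALSE))
  if (length(x) == 1L && grepl("\n", x)) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  x
}

# Tokenize CIF lines into a character vector; quoted strings and ;-delimited
# text blocks become single tokens. Unquoted "." and "?" map to NA.
.cif_tokenize <- function(lines) {
  tokens <- character(0)
  i <- 1L
  n <- length(lines)
  rx <- "('([^']*)'|\"([^\"]*)\"|(\\S+))"
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, ";")) {
      block <- sub("^;", "", line)
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        block <- paste(block, lines[i], sep = "\n")
        i <- i + 1L
      }
      tokens <- c(tokens, block)
      i <- i + 1L
      next
    }
    m <- gregexpr(rx, line, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      raw_toks <- regmatches(line, gregexpr(rx, line, perl = TRUE))[[1]]
      for (tk in raw_toks) {
        if (startsWith(tk, "#")) break
        if (startsWith(tk, "'") || startsWith(tk, "\"")) {
          tokens <- c(tokens, substr(tk, 2L, nchar(tk) - 1L))
        } else if (tk == "." || tk == "?") {
          tokens <- c(tokens, NA_character_)
        } else {
          tokens <- c(tokens, tk)
        }
      }
    }
    i <- i + 1L
  }
  tokens
}

.is_tag <- function(tk) !is.na(tk) & startsWith(tk, "_")
.is_reserved <- function(tk) !is.na(tk) & (grepl("^(data_|loop_$|global_$|save_|stop_$)", tk, ignore.case = TRUE))

# Parse tokens into list(categories = list(<category> = data.frame),
# block = first data block name).
.cif_parse <- function(lines) {
  toks <- .cif_tokenize(.as_lines(lines))
  cats <- list()
  block <- NULL
  add_rows <- function(category, df) {
    if (is.null(cats[[category]])) {
      cats[[category]] <<- df
    } else {
      old <- cats[[category]]
      allc <- union(names(old), names(df))
      for (cn in setdiff(allc, names(old))) old[[cn]] <- NA_character_
      for (cn in setdiff(allc, names(df))) df[[cn]] <- NA_character_
      cats[[category]] <<- rbind(old[allc], df[allc])
    }
  }
  split_tag <- function(tag) {
    tag <- sub("^_", "", tag)
    parts <- strsplit(tag, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) c(parts, "value") else c(parts[1L], paste(parts[-1L], collapse = "."))
  }
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tk <- toks[i]
    if (is.na(tk)) { i <- i + 1L; next }
    if (grepl("^data_", tk, ignore.case = TRUE)) {
      if (is.null(block)) block <- sub("^data_", "", tk, ignore.case = TRUE)
      i <- i + 1L
    } else if (tolower(tk) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && .is_tag(toks[i])) { tags <- c(tags, toks[i]); i <- i + 1L }
      vals <- character(0)
      while (i <= n && !.is_tag(toks[i]) && !.is_reserved(toks[i])) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(tags) == 0L) next
      if (length(vals) %% length(tags) != 0L) {
        stop("mmtf parse error: CIF loop value count is not a multiple of its tag count", call. = FALSE)
      }
      parts <- vapply(tags, split_tag, character(2))
      category <- parts[1L, 1L]
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- parts[2L, ]
      add_rows(category, df)
    } else if (.is_tag(tk)) {
      if (i + 1L > n) stop("mmtf parse error: CIF tag without value", call. = FALSE)
      parts <- split_tag(tk)
      val <- toks[i + 1L]
      df <- stats::setNames(data.frame(x = val, stringsAsFactors = FALSE), parts[2L])
      category <- parts[1L]
      if (!is.null(cats[[category]]) && nrow(cats[[category]]) == 1L &&
          !(parts[2L] %in% names(cats[[category]]))) {
        cats[[category]][[parts[2L]]] <- val
      } else {
        add_rows(category, df)
      }
      i <- i + 2L
      next
    } else {
      i <- i + 1L  # stray value (e.g. after save_), skip
    }
  }
  list(categories = cats, block = block)
}

.num <- function(x) suppressWarnings(as.numeric(x))

.cif_col <- function(df, name, default = NA_character_) {
  if (!is.null(df) && name %in% names(df)) df[[name]] else rep(default, if (is.null(df)) 0L else nrow(df))
}

#' Read a PDBx/mmCIF file into a raw structure
#'
#' Maps `atom_site` rows to atoms (label_asym_id becomes the internal chain
#' id, auth_asym_id the author chain name; model numbers split models),
#' `struct_conn` covalent/disulfide rows to inter-group bonds, and the
#' cell/symmetry/entity/refine/struct categories to metadata when present.
#'
#' @param text path to a file, a single string, or a character vector of
#'   lines.
#' @return an `mmtf_raw` structure.
#' @export
read_mmcif <- function(text) {
  parsed <- .cif_parse(text)
  cats <- parsed$categories
  as_ <- cats$atom_site
  if (is.null(as_)) stop("mmtf format error: mmCIF input has no atom_site category", call. = FALSE)

  n <- nrow(as_)
  model <- .num(.cif_col(as_, "pdbx_PDB_model_num", "1")); model[is.na(model)] <- 1
  chain_id <- .cif_col(as_, "label_asym_id")
  chain_name <- .cif_col(as_, "auth_asym_id"); chain_name[is.na(chain_name)] <- chain_id[is.na(chain_name)]
  comp <- .cif_col(as_, "label_comp_id")
  seq_id <- .num(.cif_col(as_, "auth_seq_id"))
  if (all(is.na(seq_id))) seq_id <- .num(.cif_col(as_, "label_seq_id"))
  ins <- .cif_col(as_, "pdbx_PDB_ins_code"); ins[is.na(ins)] <- ""
  entity_id <- .cif_col(as_, "label_entity_id")

  # distinct models then file-order chains within model; groups are runs of
  # constant (chain, residue) within a chain
  model_f <- match(model, sort(unique(model)))
  chain_key <- paste(model_f, chain_id, sep = "\r")
  chain_f <- match(chain_key, unique(chain_key))
  group_key <- paste(chain_f, seq_id, ins, comp, sep = "\r")
  group_f <- match(group_key, unique(group_key))

  first_of_chain <- !duplicated(chain_f)
  chains <- data.frame(model = model_f[first_of_chain],
                       chain_id = chain_id[first_of_chain],
                       chain_name = chain_name[first_of_chain],
                       stringsAsFactors = FALSE)
  first_of_group <- !duplicated(group_f)
  groups <- data.frame(chain = chain_f[first_of_group],
                       name = comp[first_of_group],
                       group_id = seq_id[first_of_group],
                       ins_code = ins[first_of_group],
                       stringsAsFactors = FALSE)

  xyz <- lapply(c("Cartn_x", "Cartn_y", "Cartn_z"), function(f) {
    v <- .num(.cif_col(as_, f))
    if (any(is.na(v))) stop(sprintf("mmtf parse error: non-numeric %s in atom_site", f), call. = FALSE)
    v
  })
  occ <- .num(.cif_col(as_, "occupancy", "1")); occ[is.na(occ)] <- 1
  bfac <- .num(.cif_col(as_, "B_iso_or_equiv", "0")); bfac[is.na(bfac)] <- 0
  alt <- .cif_col(as_, "label_alt_id"); alt[is.na(alt)] <- ""
  serial <- .num(.cif_col(as_, "id")); if (all(is.na(serial))) serial <- seq_len(n)
  charge <- .num(.cif_col(as_, "pdbx_formal_charge", "0")); charge[is.na(charge)] <- 0
  elem <- toupper(.cif_col(as_, "type_symbol")); elem[is.na(elem)] <- ""

  atoms <- data.frame(group = group_f,
                      name = .cif_col(as_, "label_atom_id"),
                      element = elem,
                      x = xyz[[1]], y = xyz[[2]], z = xyz[[3]],
                      occupancy = occ, b_factor = bfac, alt_loc = alt,
                      serial = serial, formal_charge = charge,
                      stringsAsFactors = FALSE)

  # entities from entity / entity_poly, mapped through label_entity_id
  entities <- NULL
  if (!is.null(cats$entity) && !all(is.na(entity_id))) {
    ent <- cats$entity
    poly <- cats$entity_poly
    entities <- lapply(seq_len(nrow(ent)), function(i) {
      eid <- .cif_col(ent, "id")[i]
      type <- .cif_col(ent, "type")[i]
      if (is.na(type)) type <- "non-polymer"
      seqs <- ""
      if (!is.null(poly)) {
        row <- which(.cif_col(poly, "entity_id") == eid)
        if (length(row) == 1L) {
          s <- .cif_col(poly, "pdbx_seq_one_letter_code")[row]
          if (!is.na(s)) seqs <- gsub("[[:space:]]", "", s)
        }
      }
      ch_idx <- sort(unique(chain_f[entity_id == eid])) - 1
      desc <- .cif_col(ent, "pdbx_description")[i]
      list(description = if (is.na(desc)) "" else desc,
           type = type, sequence = seqs, chain_indices = ch_idx)
    })
    entities <- Filter(function(e) length(e$chain_indices) > 0L, entities)
    if (length(entities) == 0L) entities <- NULL
  }

  # struct_conn covalent links -> inter-group bonds
  inter <- data.frame(atom1 = numeric(0), atom2 = numeric(0), order = numeric(0))
  sc <- cats$struct_conn
  if (!is.null(sc)) {
    type <- tolower(.cif_col(sc, "conn_type_id"))
    rows <- which(grepl("^(covale|disulf)", type))
    find_atom <- function(asym, seqid, atom_name) {
      hit <- which(chain_id == asym & seq_id == .num(seqid) & atoms$name == atom_name)
      if (length(hit) == 0L) {
        stop(sprintf("mmtf integrity error: struct_conn references missing atom %s %s %s",
                     asym, seqid, atom_name), call. = FALSE)
      }
      hit[1L] - 1
    }
    for (r in rows) {
      a1 <- find_atom(.cif_col(sc, "ptnr1_label_asym_id")[r],
                      (.cif_col(sc, "ptnr1_auth_seq_id")[r] %|NA|% .cif_col(sc, "ptnr1_label_seq_id")[r]),
                      .cif_col(sc, "ptnr1_label_atom_id")[r])
      a2 <- find_atom(.cif_col(sc, "ptnr2_label_asym_id")[r],
                      (.cif_col(sc, "ptnr2_auth_seq_id")[r] %|NA|% .cif_col(sc, "ptnr2_label_seq_id")[r]),
                      .cif_col(sc, "ptnr2_label_atom_id")[r])
      ord <- .BOND_ORDER_WORDS[toupper(.cif_col(sc, "pdbx_value_order")[r] %|NA|% "SING")]
      if (is.na(ord)) ord <- 1
      inter <- rbind(inter, data.frame(atom1 = a1, atom2 = a2, order = unname(ord)))
    }
  }

  md <- list()
  if (!is.null(cats$struct)) {
    t <- .cif_col(cats$struct, "title")[1]
    if (!is.na(t)) md$title <- t
  }
  if (!is.null(cats$entry)) {
    id <- .cif_col(cats$entry, "id")[1]
    if (!is.na(id)) md$structureId <- id
  } else if (!is.null(parsed$block)) md$structureId <- parsed$block
  if (!is.null(cats$cell)) {
    uc <- .num(c(.cif_col(cats$cell, "length_a")[1], .cif_col(cats$cell, "length_b")[1],
                 .cif_col(cats$cell, "length_c")[1], .cif_col(cats$cell, "angle_alpha")[1],
                 .cif_col(cats$cell, "angle_beta")[1], .cif_col(cats$cell, "angle_gamma")[1]))
    if (!any(is.na(uc))) md$unitCell <- uc
  }
  if (!is.null(cats$symmetry)) {
    sg <- .cif_col(cats$symmetry, "space_group_name_H-M")[1]
    if (!is.na(sg)) md$spaceGroup <- sg
  }
  if (!is.null(cats$refine)) {
    rf <- .num(.cif_col(cats$refine, "ls_R_factor_R_free")[1])
    rw <- .num(.cif_col(cats$refine, "ls_R_factor_R_work")[1])
    res <- .num(.cif_col(cats$refine, "ls_d_res_high")[1])
    if (!is.na(rf)) md$rFree <- rf
    if (!is.na(rw)) md$rWork <- rw
    if (!is.na(res)) md$resolution <- res
  }
  if (!is.null(cats$exptl)) {
    meth <- .cif_col(cats$exptl, "method")
    meth <- meth[!is.na(meth)]
    if (length(meth) > 0L) md$experimentalMethods <- meth
  }

  raw_structure(atoms, groups, chains, n_models = max(model_f),
                inter_bonds = inter, entities = entities, metadata = md)
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Read Chemical Component Dictionary templates
#'
#' Parses `chem_comp_atom` and `chem_comp_bond` categories into one template
#' per component id; bond order words (SING/DOUB/TRIP/QUAD) map to 1-4.
#'
#' @param text path, string, or lines of CCD-style CIF content.
#' @return named list of component templates, each with `id`, `atom_names`,
#'   `elements`, `formal_charges`, `bond_atom1`, `bond_atom2`,
#'   `bond_orders`, `chem_comp_type`.
#' @export
read_component_dictionary <- function(text) {
  cats <- .cif_parse(text)$categories
  ca <- cats$chem_comp_atom
  if (is.null(ca)) stop("mmtf format error: no chem_comp_atom category in component dictionary", call. = FALSE)
  cb <- cats$chem_comp_bond
  cc <- cats$chem_comp

  comp_type <- NULL
  if (!is.null(cc) && "id" %in% names(cc) && "type" %in% names(cc)) {
    comp_type <- stats::setNames(.cif_col(cc, "type"), .cif_col(cc, "id"))
  }
  ids <- unique(.cif_col(ca, "comp_id"))
  templates <- lapply(ids, function(id) {
    rows <- which(.cif_col(ca, "comp_id") == id)
    anames <- .cif_col(ca, "atom_id")[rows]
    tpl <- list(
      id = id,
      atom_names = anames,
      elements = toupper(.cif_col(ca, "type_symbol")[rows]),
      formal_charges = { ch <- .num(.cif_col(ca, "charge")[rows]); ch[is.na(ch)] <- 0; ch },
      bond_atom1 = character(0), bond_atom2 = character(0), bond_orders = numeric(0),
      chem_comp_type = if (!is.null(comp_type) && id %in% names(comp_type)) unname(comp_type[id]) else NULL
    )
    if (!is.null(cb)) {
      brows <- which(.cif_col(cb, "comp_id") == id)
      if (length(brows) > 0L) {
        b1 <- .cif_col(cb, "atom_id_1")[brows]
        b2 <- .cif_col(cb, "atom_id_2")[brows]
        unknown <- setdiff(c(b1, b2), anames)
        if (length(unknown) > 0L) {
          stop(sprintf("mmtf integrity error: component %s bonds name unknown atom(s) %s",
                       id, paste(unknown, collapse = ", ")), call. = FALSE)
        }
        ords <- .BOND_ORDER_WORDS[toupper(.cif_col(cb, "value_order")[brows])]
        ords[is.na(ords)] <- 1
        tpl$bond_atom1 <- b1; tpl$bond_atom2 <- b2; tpl$bond_orders <- unname(ords)
      }
    }
    tpl
  })
  stats::setNames(templates, ids)
}

# Cache of the bundled synthetic component dictionary.
.mmtfr_env <- new.env(parent = emptyenv())

#' Bundled component templates
#'
#' The package ships a small hand-written component dictionary (synthetic;
#' not the archival CCD) covering the residue vocabulary of the synthetic
#' generator: GLY, ALA, SER, U, HOH and the 12-atom ligand LG1.
#'
#' @return named list of component templates.
#' @export
mmtf_templates <- function() {
  if (is.null(.mmtfr_env$templates)) {
    path <- system.file("extdata", "components-synthetic.cif", package = "mmtfr")
    .mmtfr_env$templates <- read_component_dictionary(path)
  }
  .mmtfr_env$templates
}
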