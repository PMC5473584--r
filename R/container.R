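#' @title The MMTF document container
#'
#' @description
#' The top level of an MMTF file is a MessagePack (version 5) map whose keys
#' are field names and whose values are either native MessagePack scalars and
#' arrays (metadata, counts, the group dictionary) or binary encoded records
#' (the columnar fields, see `codec-registry`). Files may be wrapped in gzip;
#' decompression is transparent on read. The format carries a semantic
#' version: major-version differences are incompatible, minor/patch drift
#' only warrants a warning.
#'
#' @name container
NULL

.MMTF_VERSION <- "1.0.0"
.MMTF_PRODUCER <- "mmtfr-1.0.0"

# Columnar fields: stored as binary encoded records (raw vectors in R).
.mmtf_column_fields <- c(
  "chainIdList", "chainNameList", "groupTypeList", "groupIdList",
  "insCodeList", "altLocList", "sequenceIndexList", "secStructList",
  "xCoordList", "yCoordList", "zCoordList", "bFactorList", "occupancyList",
  "atomIdList", "bondAtomList", "bondOrderList"
)

.mmtf_scalar_fields <- c(
  "mmtfVersion", "mmtfProducer", "structureId", "title",
  "depositionDate", "releaseDate", "spaceGroup", "resolution",
  "rFree", "rWork", "numModels", "numChains", "numGroups", "numAtoms",
  "numBonds"
)

.mmtf_array_fields <- c(
  "experimentalMethods", "unitCell", "ncsOperatorList", "entityList",
  "bioAssemblyList", "chainsPerModel", "groupsPerChain", "groupList"
)

.mmtf_required_fields <- c(
  "mmtfVersion", "numModels", "numChains", "numGroups", "numAtoms",
  "numBonds", "chainsPerModel", "groupsPerChain", "chainIdList",
  "groupTypeList", "groupIdList", "groupList",
  "xCoordList", "yCoordList", "zCoordList"
)

#' Construct an MMTF document
#'
#' Assembles a validated-on-demand document from named fields. Columnar
#' fields must already be binary encoded records (raw vectors), normally
#' produced by [encode_structure()]; this constructor only fills version and
#' producer defaults and tags the class.
#'
#' @param fields named list of document fields (camelCase keys of the MMTF
#'   format specification).
#' @param extras named list of unknown top-level keys to preserve round-trip.
#' @return an object of class `mmtf_document`.
#' @export
mmtf_document <- function(fields, extras = list()) {
  stopifnot(is.list(fields))
  if (is.null(fields$mmtfVersion)) fields$mmtfVersion <- .MMTF_VERSION
  if (is.null(fields$mmtfProducer)) fields$mmtfProducer <- .MMTF_PRODUCER
  structure(fields, extras = extras, class = "mmtf_document")
}

#' @export
print.mmtf_document <- function(x, ...) {
  cat(sprintf("MMTF document v%s (%s)\n", x$mmtfVersion, x$mmtfProducer))
  cat(sprintf("  models: %d  chains: %d  groups: %d  atoms: %d  bonds: %d\n",
              x$numModels, x$numChains, x$numGroups, x$numAtoms, x$numBonds))
  invisible(x)
}

# Decode one columnar field, falling back to a documented default when the
# optional column is absent: blanks for char columns, 0 for B-factors and
# secondary structure -1, occupancy 1.0, serials 1..n, sequence indices -1.
mmtf_column <- function(doc, name) {
  rec <- doc[[name]]
  if (!is.null(rec)) {
    return(tryCatch(decode_column(rec),
                    error = function(e) stop(sprintf("mmtf decode error in field %s: %s",
                                                     name, conditionMessage(e)), call. = FALSE)))
  }
  n_atoms <- doc$numAtoms
  n_groups <- doc$numGroups
  n_chains <- doc$numChains
  switch(name,
    bFactorList = rep(0, n_atoms),
    occupancyList = rep(1, n_atoms),
    atomIdList = seq_len(n_atoms),
    altLocList = rep("", n_atoms),
    insCodeList = rep("", n_groups),
    secStructList = rep(-1, n_groups),
    sequenceIndexList = rep(-1, n_groups),
    chainNameList = mmtf_column(doc, "chainIdList"),
    bondAtomList = numeric(0),
    bondOrderList = numeric(0),
    stop(sprintf("mmtf schema error: required field %s is absent", name), call. = FALSE)
  )
}

#' Serialize an MMTF document to MessagePack bytes
#'
#' @param doc an `mmtf_document`.
#' @param validate run [validate_mmtf()] first and fail on violations.
#' @return raw vector of MessagePack bytes.
#' @export
serialize_mmtf <- function(doc, validate = TRUE) {
  stopifnot(inherits(doc, "mmtf_document"))
  if (validate) {
    v <- validate_mmtf(doc)
    if (length(v) > 0L) {
      stop(paste0("mmtf schema error:\n  ", paste(v, collapse = "\n  ")), call. = FALSE)
    }
  }
  map <- list()
  for (key in names(doc)) {
    val <- doc[[key]]
    if (is.null(val)) next
    map[[key]] <-
      if (key %in% .mmtf_column_fields) val          # raw record -> bin
      else if (key %in% .mmtf_array_fields) .as_mp_array(key, val)
      else val                                       # scalar
  }
  extras <- attr(doc, "extras")
  for (key in setdiff(names(extras), names(map))) map[[key]] <- extras[[key]]
  mp_pack(map)
}

# Array-valued fields are forced to msgpack arrays even at length one.
.as_mp_array <- function(key, val) {
  if (key %in% c("entityList", "bioAssemblyList", "groupList", "ncsOperatorList")) {
    lapply(val, function(entry) {
      if (key == "ncsOperatorList") return(lapply(as.numeric(entry), identity))
      .entry_to_map(key, entry)
    })
  } else if (is.list(val)) {
    val
  } else {
    as.list(val)
  }
}

.entry_to_map <- function(key, entry) {
  if (key == "groupList") {
    list(
      groupName = entry$group_name,
      singleLetterCode = entry$single_letter_code,
      chemCompType = entry$chem_comp_type,
      atomNameList = as.list(entry$atom_names),
      elementList = as.list(entry$elements),
      formalChargeList = as.list(entry$formal_charges),
      bondAtomList = as.list(entry$intra_bond_atoms),
      bondOrderList = as.list(entry$intra_bond_orders)
    )
  } else if (key == "entityList") {
    list(
      description = entry$description,
      type = entry$type,
      sequence = entry$sequence,
      chainIndexList = as.list(entry$chain_indices)
    )
  } else { # bioAssemblyList
    list(
      name = entry$name,
      transformList = lapply(entry$transforms, function(tr) {
        list(chainIndexList = as.list(tr$chain_indices),
             matrix = as.list(as.numeric(tr$matrix)))
      })
    )
  }
}

.map_to_entry <- function(key, m) {
  if (key == "groupList") {
    group_type(
      group_name = m$groupName, single_letter_code = m$singleLetterCode,
      chem_comp_type = m$chemCompType,
      atom_names = as.character(unlist(m$atomNameList, use.names = FALSE)),
      elements = as.character(unlist(m$elementList, use.names = FALSE)),
      formal_charges = as.numeric(unlist(m$formalChargeList, use.names = FALSE)),
      intra_bond_atoms = as.numeric(unlist(m$bondAtomList, use.names = FALSE)),
      intra_bond_orders = as.numeric(unlist(m$bondOrderList, use.names = FALSE))
    )
  } else if (key == "entityList") {
    list(description = m$description, type = m$type, sequence = m$sequence,
         chain_indices = as.numeric(unlist(m$chainIndexList, use.names = FALSE)))
  } else {
    list(name = m$name,
         transforms = lapply(m$transformList, function(tr) {
           list(chain_indices = as.numeric(unlist(tr$chainIndexList, use.names = FALSE)),
                matrix = as.numeric(unlist(tr$matrix, use.names = FALSE)))
         }))
  }
}

#' Deserialize MessagePack bytes into an MMTF document
#'
#' Gzip wrapping (magic bytes `1f 8b`) is detected and removed
#' transparently. Unknown top-level keys are preserved in the document's
#' `extras` attribute; missing optional fields take documented defaults when
#' decoded; missing required fields raise a schema error.
#'
#' @param bytes raw vector (optionally gzipped MessagePack).
#' @param supported_version semver the running decoder implements.
#' @return an `mmtf_document`.
#' @export
deserialize_mmtf <- function(bytes, supported_version = .MMTF_VERSION) {
  if (!is.raw(bytes)) stop("mmtf format error: expected raw bytes", call. = FALSE)
  if (length(bytes) >= 2L && bytes[1L] == as.raw(0x1f) && bytes[2L] == as.raw(0x8b)) {
    bytes <- memDecompress(bytes, type = "gzip")
  }
  map <- mp_unpack(bytes)
  if (!is.list(map) || is.null(names(map))) {
    stop("mmtf format error: top level is not a MessagePack map", call. = FALSE)
  }
  known <- c(.mmtf_scalar_fields, .mmtf_array_fields, .mmtf_column_fields)
  fields <- list()
  extras <- list()
  for (key in names(map)) {
    val <- map[[key]]
    if (!(key %in% known)) { extras[[key]] <- val; next }
    fields[[key]] <-
      if (key %in% .mmtf_column_fields) as.raw(val)
      else if (key %in% c("entityList", "bioAssemblyList", "groupList")) {
        lapply(val, function(m) .map_to_entry(key, m))
      } else if (key == "ncsOperatorList") {
        lapply(val, function(op) as.numeric(unlist(op, use.names = FALSE)))
      } else if (key %in% .mmtf_array_fields) {
        as.numeric(unlist(val, use.names = FALSE))
      } else if (key %in% c("numModels", "numChains", "numGroups", "numAtoms", "numBonds")) {
        as.numeric(val)
      } else val
  }
  if (!is.null(fields$experimentalMethods)) {
    fields$experimentalMethods <- as.character(unlist(map$experimentalMethods, use.names = FALSE))
  }
  missing <- setdiff(.mmtf_required_fields, names(fields))
  if (length(missing) > 0L) {
    stop(sprintf("mmtf schema error: required field(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  verdict <- check_version(fields$mmtfVersion, supported_version)
  if (verdict$status == "incompatible") {
    stop(sprintf("mmtf version error: file version %s is incompatible with supported %s",
                 fields$mmtfVersion, supported_version), call. = FALSE)
  }
  if (verdict$status == "warning") {
    warning(sprintf("MMTF minor-version drift: file %s, decoder supports %s",
                    fields$mmtfVersion, supported_version), call. = FALSE)
  }
  mmtf_document(fields, extras = extras)
}

#' Read an MMTF file (optionally gzipped)
#'
#' @param path path to a `.mmtf` or `.mmtf.gz` file.
#' @param ... passed to [deserialize_mmtf()].
#' @return an `mmtf_document`.
#' @export
read_mmtf <- function(path, ...) {
  bytes <- readBin(path, "raw", n = file.size(path))
  deserialize_mmtf(bytes, ...)
}

#' Write an MMTF file
#'
#' @param doc an `mmtf_document`.
#' @param path output path; gzip wrapping defaults to paths ending in `.gz`.
#' @param gzip logical, wrap the MessagePack payload in gzip.
#' @return `path`, invisibly.
#' @export
write_mmtf <- function(doc, path, gzip = grepl("\\.gz$", path)) {
  bytes <- serialize_mmtf(doc)
  if (gzip) {
    # gzfile writes a true gzip stream (1f 8b magic); memCompress would
    # emit a bare zlib stream
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
  } else {
    writeBin(bytes, path)
  }
  invisible(path)
}

#' Validate document invariants
#'
#' Checks the cross-field consistency rules of the container schema
#' (count/column agreements, dictionary index bounds, bond accounting).
#' Violations are returned as data, not thrown.
#'
#' @param doc an `mmtf_document`.
#' @return character vector of violations; empty when the document is clean.
#' @export
validate_mmtf <- function(doc) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))

  missing <- setdiff(.mmtf_required_fields, names(doc))
  if (length(missing) > 0L) {
    return(sprintf("required field %s is absent", missing))
  }

  if (length(doc$chainsPerModel) != doc$numModels)
    say("chainsPerModel: length %d != numModels %d", length(doc$chainsPerModel), doc$numModels)
  if (sum(doc$chainsPerModel) != doc$numChains)
    say("chainsPerModel: sum %.0f != numChains %d", sum(doc$chainsPerModel), doc$numChains)
  if (length(doc$groupsPerChain) != doc$numChains)
    say("groupsPerChain: length %d != numChains %d", length(doc$groupsPerChain), doc$numChains)
  if (sum(doc$groupsPerChain) != doc$numGroups)
    say("groupsPerChain: sum %.0f != numGroups %d", sum(doc$groupsPerChain), doc$numGroups)

  cols <- tryCatch({
    lapply(stats::setNames(nm = intersect(.mmtf_column_fields, names(doc))),
           function(f) mmtf_column(doc, f))
  }, error = function(e) {
    say("%s", conditionMessage(e))
    NULL
  })
  if (is.null(cols)) return(v)

  per_atom <- c("xCoordList", "yCoordList", "zCoordList", "bFactorList",
                "occupancyList", "atomIdList", "altLocList")
  per_group <- c("groupTypeList", "groupIdList", "insCodeList",
                 "sequenceIndexList", "secStructList")
  per_chain <- c("chainIdList", "chainNameList")
  for (f in intersect(per_atom, names(cols))) {
    if (length(cols[[f]]) != doc$numAtoms)
      say("%s: decodes to %d values, expected numAtoms = %d", f, length(cols[[f]]), doc$numAtoms)
  }
  for (f in intersect(per_group, names(cols))) {
    if (length(cols[[f]]) != doc$numGroups)
      say("%s: decodes to %d values, expected numGroups = %d", f, length(cols[[f]]), doc$numGroups)
  }
  for (f in intersect(per_chain, names(cols))) {
    if (length(cols[[f]]) != doc$numChains)
      say("%s: decodes to %d values, expected numChains = %d", f, length(cols[[f]]), doc$numChains)
  }

  dict <- doc$groupList
  gt <- cols$groupTypeList
  if (!is.null(gt) && length(dict) > 0L) {
    if (any(gt < 0 | gt >= length(dict)))
      say("groupTypeList: index outside dictionary range [0, %d]", length(dict) - 1L)
  } else if (!is.null(gt) && length(gt) > 0L) {
    say("groupTypeList: non-empty but group dictionary is empty")
  }

  for (i in seq_along(dict)) {
    g <- dict[[i]]
    n <- length(g$atom_names)
    if (length(g$elements) != n || length(g$formal_charges) != n)
      say("groupList[%d]: atom_names/elements/formal_charges lengths differ", i)
    if (length(g$intra_bond_atoms) %% 2L != 0L)
      say("groupList[%d]: odd intra bond atom list", i)
    if (length(g$intra_bond_atoms) > 0L && any(g$intra_bond_atoms < 0 | g$intra_bond_atoms >= n))
      say("groupList[%d]: intra bond index outside [0, %d]", i, n - 1L)
    if (length(g$intra_bond_orders) > 0L && !all(g$intra_bond_orders %in% 1:4))
      say("groupList[%d]: bond order outside 1..4", i)
  }

  if (!is.null(gt) && length(dict) > 0L && !any(gt < 0 | gt >= length(dict))) {
    atoms_per_group <- vapply(dict, function(g) length(g$atom_names), numeric(1))
    total_atoms <- sum(atoms_per_group[gt + 1L])
    if (total_atoms != doc$numAtoms)
      say("group dictionary: per-group atom counts sum to %.0f, expected numAtoms = %d",
          total_atoms, doc$numAtoms)
    intra <- sum(vapply(dict, function(g) length(g$intra_bond_orders), numeric(1))[gt + 1L])
    inter <- length(cols$bondAtomList) / 2
    if (intra + inter != doc$numBonds)
      say("bond accounting: %0.f intra + %.0f inter != numBonds %d", intra, inter, doc$numBonds)
    if (!is.null(cols$bondAtomList) && length(cols$bondAtomList) > 0L) {
      if (any(cols$bondAtomList < 0 | cols$bondAtomList >= doc$numAtoms))
        say("bondAtomList: atom index outside [0, %d]", doc$numAtoms - 1L)
    }
  }
  v
}

#' Semantic-version compatibility check
#'
#' Files and decoders are compatible when their major versions agree;
#' minor/patch drift yields a warning verdict, a major mismatch an
#' incompatible one.
#'
#' @param found version string found in a file.
#' @param supported version string the decoder implements.
#' @return list with `status` ("compatible", "warning" or "incompatible"),
#'   `found` and `supported`.
#' @export
check_version <- function(found, supported = .MMTF_VERSION) {
  parse1 <- function(s) {
    m <- regmatches(s, regexec("^([0-9]+)\\.([0-9]+)(?:\\.([0-9]+))?$", s))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("mmtf format error: unparseable semantic version '%s'", s), call. = FALSE)
    }
    as.numeric(c(m[2], m[3], ifelse(is.na(m[4]) || m[4] == "", 0, m[4])))
  }
  a <- parse1(found); b <- parse1(supported)
  status <- if (a[1] != b[1]) "incompatible"
            else if (a[2] != b[2] || a[3] != b[3]) "warning"
            else "compatible"
  list(status = status, found = found, supported = supported)
}
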