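# Container schema: serialization identity, gzip wrapping, validation,
# semantic versioning.

decoded_fields <- function(doc) {
  cols <- intersect(mmtfr:::.mmtf_column_fields, names(doc))
  out <- lapply(stats::setNames(nm = cols), function(f) {
    v <- mmtfr:::mmtf_column(doc, f)
    attributes(v) <- NULL
    v
  })
  out$counts <- unlist(doc[c("numModels", "numChains", "numGroups", "numAtoms", "numBonds")])
  out$groupList <- doc$groupList
  out$entityList <- doc$entityList
  out
}

test_that("serialize/deserialize is the identity on validated documents", {
  for (spec in list(fixture_spec(seed = 1),
                    fixture_spec(seed = 2, n_models = 3, chains_per_model = 2,
                                 residues_per_chain = 4, n_ligands = 1, n_waters = 3,
                                 occupancy = "mixed", alt_locs = TRUE, ins_codes = TRUE))) {
    doc <- encode_structure(make_structure(spec))
    rt <- deserialize_mmtf(serialize_mmtf(doc))
    expect_equal(decoded_fields(rt), decoded_fields(doc))
    expect_identical(rt$mmtfVersion, doc$mmtfVersion)
    expect_identical(rt$structureId, doc$structureId)
    # and the byte stream itself is stable under a second pass
    expect_identical(serialize_mmtf(rt), serialize_mmtf(doc))
  }
})

test_that("a minimal one-atom document round-trips", {
  atoms <- data.frame(group = 1L, name = "O", element = "O", x = 1.5, y = -2.25,
                      z = 0, occupancy = 1, b_factor = 12.5, alt_loc = "",
                      serial = 1, formal_charge = 0, stringsAsFactors = FALSE)
  groups <- data.frame(chain = 1L, name = "HOH", group_id = 1, ins_code = "",
                       stringsAsFactors = FALSE)
  chains <- data.frame(model = 1L, chain_id = "A", chain_name = "A",
                       stringsAsFactors = FALSE)
  doc <- encode_structure(raw_structure(atoms, groups, chains))
  rt <- deserialize_mmtf(serialize_mmtf(doc))
  expect_equal(decoded_fields(rt), decoded_fields(doc))
  s <- decode_structure(rt)
  expect_equal(s$x, 1.5)
  expect_equal(s$num_atoms, 1)
})

test_that("optional-field absence is preserved and defaulted on decode", {
  doc <- encode_structure(make_structure(fixture_spec(seed = 3)))
  doc$bFactorList <- NULL
  doc$occupancyList <- NULL
  doc$altLocList <- NULL
  rt <- deserialize_mmtf(serialize_mmtf(doc))
  expect_false("bFactorList" %in% names(rt))
  s <- decode_structure(rt)
  expect_equal(s$b_factors, rep(0, s$num_atoms))
  expect_equal(s$occupancies, rep(1, s$num_atoms))
  expect_equal(s$alt_locs, rep("", s$num_atoms))
})

test_that("gzip wrapping commutes with serialization", {
  doc <- encode_structure(make_structure(fixture_spec(seed = 4, n_ligands = 1)))
  plain <- tempfile(fileext = ".mmtf")
  zipped <- tempfile(fileext = ".mmtf.gz")
  write_mmtf(doc, plain)
  write_mmtf(doc, zipped)
  raw_plain <- readBin(plain, "raw", n = file.size(plain))
  raw_zip <- readBin(zipped, "raw", n = file.size(zipped))
  expect_identical(raw_zip[1:2], as.raw(c(0x1f, 0x8b)))   # true gzip magic
  expect_lt(length(raw_zip), length(raw_plain))
  expect_equal(decoded_fields(read_mmtf(zipped)), decoded_fields(read_mmtf(plain)))
  unlink(c(plain, zipped))
})

test_that("unknown top-level keys are preserved round-trip", {
  doc <- encode_structure(make_structure(fixture_spec(seed = 5)))
  attr(doc, "extras") <- list(futureKey = list(1, 2, "three"))
  rt <- deserialize_mmtf(serialize_mmtf(doc))
  ex <- attr(rt, "extras")
  expect_equal(ex$futureKey[[3]], "three")
  # and survives another pass
  rt2 <- deserialize_mmtf(serialize_mmtf(rt))
  expect_equal(attr(rt2, "extras")$futureKey[[1]], 1)
})

test_that("schema violations are reported as data", {
  doc <- encode_structure(make_structure(fixture_spec(seed = 6, chains_per_model = 2)))
  expect_length(validate_mmtf(doc), 0L)

  bad <- doc
  bad$chainsPerModel <- c(bad$chainsPerModel[-1], 99)
  v <- validate_mmtf(bad)
  expect_true(any(grepl("chainsPerModel", v)))

  bad2 <- doc
  ngt <- length(bad2$groupList)
  bad2$groupTypeList <- encode_column(rep(ngt, doc$numGroups), 4L)  # off by one
  v2 <- validate_mmtf(bad2)
  expect_true(any(grepl("dictionary range", v2)))

  bad3 <- doc
  bad3$xCoordList <- NULL
  expect_error(serialize_mmtf(bad3), "required field")
})

test_that("deserializing non-MessagePack or field-less maps fails cleanly", {
  expect_error(deserialize_mmtf(as.raw(c(0x00, 0x01))), "format error")
  orphan <- mmtfr:::mp_pack(list(mmtfVersion = "1.0.0", numAtoms = 1))
  expect_error(deserialize_mmtf(orphan), "required field")
})

test_that("semantic versioning gates decoding", {
  expect_equal(check_version("1.0.0", "1.0.0")$status, "compatible")
  expect_equal(check_version("1.0.0", "1.1.0")$status, "warning")
  expect_equal(check_version("2.0.0", "1.1.0")$status, "incompatible")
  expect_error(check_version("abc", "1.0.0"), "unparseable")

  doc <- encode_structure(make_structure(fixture_spec(seed = 8)))
  doc$mmtfVersion <- "2.4.0"
  bytes <- serialize_mmtf(doc)
  expect_error(deserialize_mmtf(bytes), "version error")
  doc$mmtfVersion <- "1.1.0"
  expect_warning(deserialize_mmtf(serialize_mmtf(doc)), "minor-version drift")
})
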