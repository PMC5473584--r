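# Dictionary building, bond attachment, profile reduction and end-to-end
# encoding.

test_that("identical residues collapse to one dictionary entry", {
  raw <- make_structure(fixture_spec(seed = 1, residues_per_chain = 10,
                                     vocabulary = "ALA"))
  d <- build_group_dictionary(raw)
  expect_length(d$dictionary, 1L)
  expect_equal(d$indices, rep(0, 10))
  entry <- d$dictionary[[1]]
  expect_equal(entry$group_name, "ALA")
  expect_equal(entry$single_letter_code, "A")
})

test_that("the serine entry carries its template chemistry", {
  d <- build_group_dictionary(peptide_fixture("SER"))
  entry <- d$dictionary[[1]]
  tpl <- mmtf_templates()$SER
  expect_equal(entry$atom_names, tpl$atom_names)
  expect_equal(entry$elements, tpl$elements)
  expect_equal(length(entry$intra_bond_orders), length(tpl$bond_orders))
  expect_true(all(entry$intra_bond_orders %in% 1:4))
  # bonds point at the right atoms: CB-OG must be present
  pairs <- matrix(entry$intra_bond_atoms, ncol = 2, byrow = TRUE)
  names_of <- function(i) entry$atom_names[i + 1]
  bond_names <- apply(pairs, 1, function(p) paste(sort(names_of(p)), collapse = "-"))
  expect_true("CB-OG" %in% bond_names)
})

test_that("atom-order exceptions get their own dictionary entries", {
  raw <- peptide_fixture(c("ALA", "ALA"))
  # swap two atoms of the second alanine
  rows <- which(raw$atoms$group == 2)
  raw$atoms[rows[1:2], ] <- raw$atoms[rows[2:1], ]
  d <- build_group_dictionary(raw)
  expect_length(d$dictionary, 2L)
  expect_equal(d$indices, c(0, 1))
})

test_that("unknown components yield empty bond lists with a warning", {
  raw <- peptide_fixture("ALA")
  raw$groups$name <- "ZZZ"
  expect_warning(d <- build_group_dictionary(raw), "no component template for ZZZ")
  expect_length(d$dictionary[[1]]$intra_bond_orders, 0L)
})

test_that("backbone bonds are inferred between consecutive polymer groups", {
  pep <- peptide_fixture(c("GLY", "ALA", "SER"))
  bonds <- attach_inter_group_bonds(pep)
  expect_equal(nrow(bonds), 2L)          # two C-N links for three residues
  # a duplicate explicit record of an inferred bond is stored once
  pep2 <- peptide_fixture(c("GLY", "ALA"))
  b0 <- attach_inter_group_bonds(pep2)
  pep2$inter_bonds <- rbind(b0, b0)
  expect_equal(nrow(attach_inter_group_bonds(pep2)), 1L)
})

test_that("explicit disulfide records become single inter-group bonds", {
  cys2 <- peptide_fixture(c("CYS", "CYS"))
  sg <- which(cys2$atoms$name == "SG") - 1
  cys2$inter_bonds <- data.frame(atom1 = sg[1], atom2 = sg[2], order = 1)
  bonds <- attach_inter_group_bonds(cys2)
  ss <- bonds[bonds$atom1 == min(sg) & bonds$atom2 == max(sg), ]
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$order, 1)
})

test_that("reduction keeps C-alpha / P / non-polymer atoms and drops waters", {
  raw <- make_structure(fixture_spec(seed = 9, residues_per_chain = 5,
                                     n_ligands = 1, n_waters = 4))
  red <- reduce_structure(raw)
  expect_equal(nrow(red$atoms), 5 + 12)           # 5 CA + 12-atom ligand
  expect_true(all(red$atoms$name[1:5] == "CA"))
  expect_false(any(red$groups$name == "HOH"))
  # idempotence
  red2 <- reduce_structure(red)
  expect_equal(red2$atoms, red$atoms)
  expect_equal(red2$groups, red$groups)

  # a polypeptide group lacking CA is dropped with a warning
  noca <- peptide_fixture(c("GLY", "ALA"))
  noca$atoms <- noca$atoms[!(noca$atoms$group == 2 & noca$atoms$name == "CA"), ]
  expect_warning(r <- reduce_structure(noca), "lacking a representative atom")
  expect_equal(nrow(r$atoms), 1L)

  # nucleotide chains reduce to their P atoms
  u3 <- make_structure(fixture_spec(seed = 10, residues_per_chain = 3,
                                    vocabulary = "U"))
  expect_equal(nrow(reduce_structure(u3)$atoms), 3L)
})

test_that("full-profile encoding is exact on grid-aligned inputs", {
  raw <- make_structure(fixture_spec(seed = 11, n_models = 2, chains_per_model = 2,
                                     residues_per_chain = 4, n_ligands = 1,
                                     occupancy = "mixed"))
  s <- decode_structure(encode_structure(raw, "full"))
  expect_identical(s$x, raw$atoms$x)
  expect_identical(s$y, raw$atoms$y)
  expect_identical(s$z, raw$atoms$z)
  expect_identical(s$b_factors, raw$atoms$b_factor)
  expect_identical(s$occupancies, raw$atoms$occupancy)
  expect_equal(s$atom_ids, raw$atoms$serial)
  expect_equal(s$group_ids, raw$groups$group_id)
  # dictionary expansion reproduces every group's atoms in order
  names_list <- lapply(s$group_dictionary, function(g) g$atom_names)
  expect_equal(unlist(names_list[s$group_types + 1], use.names = FALSE),
               raw$atoms$name)
})

test_that("reduced-profile coordinates stay within the 0.05 A half-quantum", {
  raw <- make_structure(fixture_spec(seed = 12, residues_per_chain = 30))
  red <- reduce_structure(raw)
  s <- decode_structure(encode_structure(raw, "reduced"))
  expect_equal(s$num_atoms, nrow(red$atoms))
  expect_lte(max(abs(s$x - red$atoms$x)), 0.05)
  expect_lte(max(abs(s$b_factors - red$atoms$b_factor)), 0.05)
  expect_lte(s$num_atoms, nrow(raw$atoms))
})

test_that("constant occupancy columns collapse to one run-length pair", {
  raw <- make_structure(fixture_spec(seed = 13, residues_per_chain = 6))
  doc <- encode_structure(raw)
  u <- unpack_record(doc$occupancyList)
  expect_equal(u$values, c(100, nrow(raw$atoms)))
})

test_that("encoder output always validates", {
  for (i in 1:3) {
    raw <- make_structure(fixture_spec(seed = 20 + i, n_models = i,
                                       chains_per_model = i, residues_per_chain = 3,
                                       n_ligands = 1, heavy_tail = i == 2))
    expect_length(validate_mmtf(encode_structure(raw, "full")), 0L)
    expect_length(validate_mmtf(encode_structure(raw, "reduced")), 0L)
  }
})

test_that("coordinate overflow is rejected with a range error", {
  raw <- peptide_fixture("GLY")
  raw$atoms$x[1] <- 3e6   # * 1000 overflows int32
  expect_error(encode_structure(raw), "range error")
})
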