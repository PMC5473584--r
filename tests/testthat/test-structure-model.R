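# Decoded structures: offsets, traversal, bond reconstruction, selection.

test_that("offset tables follow the counts", {
  s1 <- decode_structure(encode_structure(make_structure(
    fixture_spec(seed = 1, n_models = 1, chains_per_model = 1, residues_per_chain = 1))))
  expect_equal(s1$model_chain_offset, c(0, 1))
  expect_equal(s1$chain_group_offset, c(0, 1))
  expect_equal(s1$group_atom_offset[1], 0)

  s2 <- decode_structure(encode_structure(make_structure(
    fixture_spec(seed = 2, n_models = 2, chains_per_model = 3, residues_per_chain = 2))))
  expect_equal(s2$model_chain_offset, c(0, 3, 6))
  expect_true(!is.unsorted(s2$group_atom_offset))
  expect_equal(s2$group_atom_offset[length(s2$group_atom_offset)], s2$num_atoms)
})

test_that("traversal visits the hierarchy depth-first with the printed fields", {
  # two chains with different group counts: a 3-residue polymer plus a
  # 2-ligand chain
  raw2 <- make_structure(fixture_spec(seed = 3, chains_per_model = 1,
                                      residues_per_chain = 3, n_ligands = 2))
  s <- decode_structure(encode_structure(raw2))
  chain_groups <- c(); chain_ids <- c(); model_idx <- c()
  atom_order <- c()
  counts <- traverse(s,
    model = function(mi) model_idx <<- c(model_idx, mi),
    chain = function(mi, ci, id, nm, ng) {
      chain_ids <<- c(chain_ids, id); chain_groups <<- c(chain_groups, ng)
    },
    atom = function(gi, ai, name, element, x, y, z, serial) {
      atom_order <<- c(atom_order, ai)
    })
  expect_equal(model_idx, 0)
  expect_equal(chain_ids, c("A", "L"))
  expect_equal(chain_groups, c(3, 2))
  expect_equal(atom_order, seq_len(s$num_atoms) - 1)  # column order, each once
  expect_equal(counts, list(models = 1, chains = 2, groups = 5, atoms = s$num_atoms))
})

test_that("visit counts equal the stored totals on randomized fixtures", {
  set.seed(30)
  for (i in 1:5) {
    spec <- fixture_spec(seed = i, n_models = sample(1:3, 1),
                         chains_per_model = sample(1:3, 1),
                         residues_per_chain = sample(1:5, 1),
                         n_ligands = sample(0:2, 1), n_waters = sample(0:2, 1))
    s <- decode_structure(encode_structure(make_structure(spec)))
    counts <- traverse(s)
    expect_equal(counts$models, s$num_models)
    expect_equal(counts$chains, s$num_chains)
    expect_equal(counts$groups, s$num_groups)
    expect_equal(counts$atoms, s$num_atoms)
  }
})

test_that("bond reconstruction unions dictionary and inter-group bonds", {
  # one serine: intra bonds exactly as the dictionary entry lists them
  ser <- peptide_fixture("SER")
  s <- decode_structure(encode_structure(ser))
  bonds <- reconstruct_bonds(s)
  tpl <- mmtf_templates()$SER
  expect_equal(nrow(bonds), length(tpl$bond_orders))
  expect_equal(nrow(bonds), s$num_bonds)
  entry <- s$group_dictionary[[s$group_types[1] + 1]]
  pairs <- matrix(entry$intra_bond_atoms, ncol = 2, byrow = TRUE)
  expect_equal(bonds$atom1, pairs[, 1])  # offset 0 for the first group
  expect_equal(bonds$atom2, pairs[, 2])

  # two-residue peptide: both groups' intra bonds plus one crossing bond
  pep <- peptide_fixture(c("GLY", "ALA"))
  s2 <- decode_structure(encode_structure(pep))
  b2 <- reconstruct_bonds(s2)
  expect_equal(nrow(b2), s2$num_bonds)
  gly_atoms <- 0:3
  crossing <- b2[(b2$atom1 %in% gly_atoms) != (b2$atom2 %in% gly_atoms), ]
  expect_equal(nrow(crossing), 1L)      # the inferred peptide C-N link
})

test_that("num_bonds accounting holds on randomized fixtures", {
  for (i in 1:4) {
    spec <- fixture_spec(seed = 100 + i, chains_per_model = 2,
                         residues_per_chain = 4, n_ligands = 1)
    s <- decode_structure(encode_structure(make_structure(spec)))
    expect_equal(nrow(reconstruct_bonds(s)), s$num_bonds)
  }
})

test_that("select_atoms filters on atom context", {
  s <- decode_structure(encode_structure(peptide_fixture(c("GLY", "ALA", "SER"))))
  all_idx <- select_atoms(s, function(ctx) rep(TRUE, nrow(ctx)))
  expect_equal(all_idx, seq_len(s$num_atoms) - 1)
  ca <- select_atoms(s, function(ctx) ctx$name == "CA")
  expect_length(ca, 3L)
  p <- function(ctx) ctx$element == "O"
  notp <- function(ctx) ctx$element != "O"
  expect_equal(length(select_atoms(s, p)) + length(select_atoms(s, notp)), s$num_atoms)
  expect_error(select_atoms(s, function(ctx) 1:3), "one logical per atom")
})
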