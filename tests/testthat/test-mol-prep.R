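# Compound preprocessing: perception, hydrogen completion, canonical
# ordering, components, topological distances, stereo assignment.

test_that("hybridisation, SSSR and aromaticity are perceived", {
  m <- fix_mol("C")
  expect_equal(m$atoms$hyb[1], "sp3")

  b <- fix_mol("c1ccccc1")
  expect_length(b$sssr, 1)
  expect_length(b$sssr[[1]], 6)
  expect_true(all(b$atoms$aromatic[1:6]))
  expect_true(all(b$bonds$aromatic[b$bonds$in_ring]))

  n <- fix_mol("c1ccc2ccccc2c1")
  expect_length(n$sssr, 2)   # bonds - atoms + 1 = 11 - 10 + 1

  # kekule input is re-perceived as aromatic
  k <- preprocess(parse_smiles("C1=CC=CC=C1")[[1]])
  expect_true(all(k$atoms$aromatic[1:6]))

  nitrile <- fix_mol("CC#N")
  expect_equal(nitrile$atoms$hyb[2:3], c("sp", "sp"))
})

test_that("impossible valences are rejected with a diagnostic", {
  bad <- mol_graph(
    data.frame(element = c("C", "H", "H", "H", "H", "H"), charge = 0L,
               nH = 0L, aromatic = FALSE),
    data.frame(i = rep(1L, 5), j = 2:6, order = 1L, aromatic = FALSE))
  expect_error(perceive_atom_properties(bad), "impossible valence")
})

test_that("hydrogen completion preserves heavy atoms, charges and bonds", {
  m <- add_missing_hydrogens(perceive_atom_properties(parse_smiles("C")[[1]]))
  expect_equal(sum(m$atoms$element == "H"), 4)

  am <- add_missing_hydrogens(perceive_atom_properties(parse_smiles("[NH4+]")[[1]]))
  expect_equal(sum(am$atoms$element == "H"), 4)
  expect_equal(sum(am$atoms$charge), 1)

  bz <- fix_mol("c1ccccc1")
  expect_equal(sum(bz$atoms$element == "H"), 6)

  raw <- perceive_atom_properties(parse_smiles("CC(=O)[O-]")[[1]])
  done <- add_missing_hydrogens(raw)
  heavy_raw <- raw$atoms$element[raw$atoms$element != "H"]
  heavy_done <- done$atoms$element[done$atoms$element != "H"]
  expect_equal(heavy_done, heavy_raw)
  expect_equal(sum(done$atoms$charge), sum(raw$atoms$charge))
  expect_equal(done$bonds$order[seq_len(nrow(raw$bonds))], raw$bonds$order)
})

test_that("components are labelled by reachability", {
  expect_equal(n_components(fix_mol("CC(=O)[O-].[Na+]")), 2)
  expect_equal(n_components(fix_mol("CCO")), 1)
  expect_equal(n_components(fix_mol("C.O.N")), 3)
})

test_that("topological distances match a Floyd-Warshall oracle", {
  m <- fix_mol("CCC")
  td <- topological_distances(m)
  expect_equal(td[1, 3], 2L)
  expect_equal(td[1, 1], 0L)

  ch <- fix_mol("C1CCCCC1")
  tdc <- topological_distances(ch)
  expect_equal(tdc[1, 4], 3L)  # shorter arc around the ring

  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    edges <- random_connected_graph(n)
    g <- perceive_components(graph_to_mol(n, edges))
    td <- topological_distances(g)
    fw <- floyd_warshall(n, edges)
    expect_equal(unname(td), unname(fw), ignore_attr = TRUE)
    expect_true(isSymmetric(unname(td * 1.0)))
  }
})

test_that("canonical ordering is input-order invariant and idempotent", {
  perms <- c("CCCC", "C(C)CC", "C(CC)C")
  keys <- vapply(perms, function(s) {
    m <- canonicalize(fix_mol(s))
    paste(m$atoms$element,
          vapply(seq_len(n_atoms(m)), function(a) {
            sum(m$bonds$i == a | m$bonds$j == a)
          }, 0L), collapse = "|")
  }, "")
  expect_true(all(keys == keys[1]))

  m <- fix_mol("CC(=O)Nc1ccccc1O")
  once <- canonicalize(m)
  twice <- canonicalize(once)
  expect_identical(once$atoms$element, twice$atoms$element)
  expect_identical(once$bonds, twice$bonds)

  # non-isomorphic graphs keep distinct canonical forms
  eth <- canonicalize(fix_mol("CCO"))
  dme <- canonicalize(fix_mol("COC"))
  expect_false(identical(eth$bonds, dme$bonds) &&
               identical(eth$atoms$element, dme$atoms$element))
})

test_that("preprocessing is permutation-invariant under canonicalization", {
  variants <- c("CC(=O)Nc1ccccc1", "c1ccc(NC(C)=O)cc1", "O=C(C)Nc1ccccc1")
  sers <- vapply(variants, function(s) {
    m <- preprocess(parse_smiles(s)[[1]], canonical = TRUE)
    paste(paste(m$atoms$element, collapse = ""),
          paste(m$bonds$i, m$bonds$j, m$bonds$order, collapse = ";"))
  }, "")
  expect_true(all(sers == sers[1]))
})

test_that("stereo assignment: retention, trans default, unspecified centres", {
  # undefined 2-butene geometry gets trans of the bulky substituents
  bu <- fix_mol("CC=CC")
  expect_equal(nrow(bu$stereo_bonds), 1)
  expect_equal(bu$stereo_bonds$config, "trans")
  expect_false(bu$stereo_bonds$specified)

  # defined cis input is retained
  z <- fix_mol("C/C=C\\C")
  expect_equal(z$stereo_bonds$config[z$stereo_bonds$specified], "cis")

  # undefined tetrahedral centre stays unspecified
  un <- fix_mol("CC(N)C(=O)O")
  expect_equal(nrow(un$stereo_atoms), 0)

  # defined centre carries a parity and the CIP label from input
  s <- fix_mol("C[C@H](N)C(=O)O")
  expect_equal(nrow(s$stereo_atoms), 1)
  expect_equal(s$stereo_atoms$cip, "S")

  # symmetric double bond (isobutylene) is not stereogenic
  iso <- fix_mol("CC(C)=C")
  expect_equal(nrow(iso$stereo_bonds), 0)
})

test_that("morgan connectivity ranks bulkier substituents higher", {
  m <- fix_mol("CC(C)(C)C=CC")   # tert-butyl side vs methyl side
  cv <- morgan_connectivity(m)
  tbu_c <- 2  # quaternary carbon
  met_c <- 7  # terminal methyl
  expect_gt(cv[tbu_c], cv[met_c])
})
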