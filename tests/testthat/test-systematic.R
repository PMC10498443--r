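# Fragmentation, classification, fragment conformers with the library,
# FCC enumeration.

test_that("fragmentation follows the shipped cutting rules", {
  ch <- fragment_molecule(fix_mol("C1CCCCC1"))
  expect_length(ch$fragments, 1)
  expect_equal(nrow(ch$link_bonds), 0)

  bp <- fragment_molecule(fix_mol("c1ccccc1-c1ccccc1"))
  expect_length(bp$fragments, 2)
  expect_equal(nrow(bp$link_bonds), 1)

  hx <- fragment_molecule(fix_mol("CCCCCC"))
  expect_equal(length(hx$fragments), nrow(hx$link_bonds) + 1)

  # terminal methyl rotors are not cut
  tol <- fragment_molecule(fix_mol("Cc1ccccc1"))
  expect_length(tol$fragments, 1)

  # amide bonds are cut and flagged
  am <- fragment_molecule(fix_mol("CCC(=O)NCC"))
  expect_true(any(am$link_bonds$amide))

  # fragments partition the molecule
  m <- fix_mol("NCC(=O)OC1CCNCC1")
  fr <- fragment_molecule(m)
  all_atoms <- sort(unlist(fr$fragments))
  expect_equal(all_atoms, seq_len(n_atoms(m)))
  # every link bond joins two different fragments
  expect_true(all(fr$link_bonds$frag_a != fr$link_bonds$frag_b))
})

test_that("fragments are classified by rings and internal rotors", {
  m <- fragment_molecule(fix_mol("c1ccccc1-c1ccccc1"))
  expect_equal(classify_fragment(fix_mol("c1ccccc1-c1ccccc1"),
                                 m$fragments[[1]]), "rigid")

  cy <- fix_mol("C1CCCCC1CNC")
  fr <- fragment_molecule(cy)
  ring_frag <- fr$fragments[[which(vapply(fr$fragments, function(f) {
    any(cy$atoms$in_ring[f]) }, TRUE))]]
  expect_equal(classify_fragment(cy, ring_frag), "flexible_ring")

  # a propyl linker subset with an internal heavy-atom rotor classifies as
  # a flexible chain (full fragmentation would cut it further)
  pp <- fix_mol("c1ccccc1CCCc1ccccc1")
  adjp <- confsmith:::adjacency(pp)
  linker <- which(!pp$atoms$in_ring & pp$atoms$element == "C")
  linker_h <- unlist(lapply(linker, function(a) {
    adjp[[a]][pp$atoms$element[adjp[[a]]] == "H"]
  }))
  expect_equal(classify_fragment(pp, c(linker, linker_h)), "flexible_chain")
})

test_that("capped fragments complete cut valences with hydrogens", {
  m <- fix_mol("c1ccccc1-c1ccccc1")
  fr <- fragment_molecule(m)
  cf <- capped_fragment(m, fr$fragments[[1]], fr$link_bonds)
  caps <- attr(cf, "caps")
  expect_equal(nrow(caps), 1)
  expect_equal(cf$atoms$element[caps$local], "H")
  # capped phenyl is a valid, parametrizable molecule
  p <- parametrize(cf)
  expect_true(p$ok)
})

test_that("fragment conformer generation respects the class contract", {
  set.seed(31)
  m <- fix_mol("c1ccccc1-c1ccccc1")
  fr <- fragment_molecule(m)
  fp <- prepare_systematic(m, fr)
  lib <- fragment_library()
  cs <- fragment_conformers(attr(fp, "capped")[[1]], "rigid", fp[[1]], lib)
  expect_length(cs, 1)

  cy <- fix_mol("C1CCCCC1CNC")
  fry <- fragment_molecule(cy)
  fpy <- prepare_systematic(cy, fry)
  ring_k <- which(vapply(fry$fragments, function(f) any(cy$atoms$in_ring[f]),
                         TRUE))
  set.seed(32)
  csr <- fragment_conformers(attr(fpy, "capped")[[ring_k]], "flexible_ring",
                             fpy[[ring_k]], lib)
  expect_gte(length(csr), 2)   # chair + twist-boat family
})

test_that("the fragment library caches and is atom-order invariant", {
  set.seed(33)
  m <- fix_mol("c1ccccc1-c1ccccc1")
  fr <- fragment_molecule(m)
  fp <- prepare_systematic(m, fr)
  lib <- fragment_library()
  cs1 <- fragment_conformers(attr(fp, "capped")[[1]], "rigid", fp[[1]], lib)
  misses_before <- lib$misses
  cs2 <- fragment_conformers(attr(fp, "capped")[[2]], "rigid", fp[[2]], lib)
  expect_equal(lib$misses, misses_before)  # second phenyl is a cache hit
  expect_equal(lib$hits, 1L)
  expect_equal(length(cs1), length(cs2))

  # keys are invariant under atom permutation (library round trip)
  set.seed(34)
  for (rep in 1:10) {
    frag <- attr(fp, "capped")[[1]]
    perm <- sample(n_atoms(frag))
    permuted <- permute_mol(frag, perm)
    expect_equal(fragment_key(permuted)$key, fragment_key(frag)$key)
  }

  # persistence round trip
  f <- tempfile(fileext = ".json")
  save_fragment_library(lib, f)
  lib2 <- fragment_library(f)
  expect_setequal(ls(lib2$store), ls(lib$store))
})

test_that("FCC enumeration is energy-ordered, windowed and capped", {
  mk <- function(es) lapply(es, function(e) list(coords = NULL, energy = e))
  sets <- list(mk(c(0, 1)), mk(c(0, 1, 2)))
  fcc <- enumerate_fccs(sets, window = 100)
  expect_equal(nrow(fcc), 6)
  expect_true(all(diff(fcc$e_comb) >= 0))

  # window rule: threshold = min + 1.5 * window
  sets2 <- list(mk(c(0, 10)), mk(c(0, 10)))
  fcc2 <- enumerate_fccs(sets2, window = 5)
  expect_equal(nrow(fcc2), 1)   # only (0, 0); 10 > 0 + 7.5

  fcc3 <- enumerate_fccs(sets, window = 100, cap = 2L)
  expect_equal(nrow(fcc3), 2)
  expect_equal(fcc3$e_comb, sort(fcc3$e_comb))
  expect_equal(fcc3$e_comb, c(0, 1))

  # e_comb equals the recomputed member-energy sum
  for (r in seq_len(nrow(fcc))) {
    s <- sets[[1]][[fcc$i1[r]]]$energy + sets[[2]][[fcc$i2[r]]]$energy
    expect_equal(fcc$e_comb[r], s)
  }
})
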