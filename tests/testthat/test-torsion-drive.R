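# Torsion rules, symmetry reduction, fragment tree, incremental-energy
# merging and the driving loop.

test_that("torsion rule matching: fallback, precedence, amide restriction", {
  m <- fix_mol("CCCC")
  builtin <- load_torsion_library()
  libs <- list(builtin)
  p <- parametrize(m, torsion_smarts = confsmith:::torsion_library_smarts(libs))
  rule <- match_torsion_rules(m, c(2, 3), libs, p$smarts_matches)
  expect_true(is.na(rule$rule))
  expect_equal(rule$angles, c(60, 180, 300))

  # user library overrides the built-in entry for the same bond
  f <- tempfile()
  writeLines("[#6][CX4]!@[CX4][#6]\t0:10,90:10", f)
  user <- load_torsion_library(f)
  libs2 <- list(user, builtin)
  p2 <- parametrize(m, torsion_smarts = confsmith:::torsion_library_smarts(libs2))
  rule2 <- match_torsion_rules(m, c(2, 3), libs2, p2$smarts_matches)
  expect_equal(rule2$rule, 1)
  expect_equal(rule2$angles, c(0, 90))

  # amide C-N matches the planar entry
  am <- fix_mol("CCC(=O)NCC")
  pa <- parametrize(am, torsion_smarts = confsmith:::torsion_library_smarts(libs))
  fra <- fragment_molecule(am)
  amide_row <- which(fra$link_bonds$amide)[1]
  bond <- c(fra$link_bonds$a[amide_row], fra$link_bonds$b[amide_row])
  rule3 <- match_torsion_rules(am, bond, libs, pa$smarts_matches)
  expect_false(is.na(rule3$rule))
  expect_setequal(rule3$angles, c(0, 180))
})

test_that("tolerance-range expansion adds the interval endpoints", {
  rule <- list(angles = 180, tolerances = 20)
  expect_setequal(expand_tolerance_angles(rule, TRUE), c(160, 180, 200))
  expect_equal(expand_tolerance_angles(rule, FALSE), 180)
  rule2 <- list(angles = c(0, 180), tolerances = c(10, 10))
  expect_length(expand_tolerance_angles(rule2, TRUE), 6)
})

test_that("rotational symmetry collapses equivalent angles", {
  # phenyl side: twofold symmetry
  m <- fix_mol("CCc1ccccc1")
  fr <- fragment_molecule(m)
  bond <- c(fr$link_bonds$a[1], fr$link_bonds$b[1])
  ring_side <- fr$fragments[[which(vapply(fr$fragments, function(f) {
    any(m$atoms$aromatic[f]) }, TRUE))]]
  chain_side <- fr$fragments[[which(vapply(fr$fragments, function(f) {
    !any(m$atoms$aromatic[f]) }, TRUE))]]
  red <- reduce_symmetric_angles(m, bond, chain_side, ring_side,
                                 c(0, 90, 180, 270))
  expect_equal(red, c(0, 90))

  # trifluoromethyl side: threefold symmetry
  m2 <- fix_mol("FC(F)(F)CC")
  fr2 <- fragment_molecule(m2)
  bond2 <- c(fr2$link_bonds$a[1], fr2$link_bonds$b[1])
  cf3 <- fr2$fragments[[which(vapply(fr2$fragments, function(f) {
    any(m2$atoms$element[f] == "F") }, TRUE))]]
  other2 <- fr2$fragments[[which(vapply(fr2$fragments, function(f) {
    !any(m2$atoms$element[f] == "F") }, TRUE))]]
  red2 <- reduce_symmetric_angles(m2, bond2, cf3, other2, c(60, 180, 300))
  expect_equal(red2, 60)

  # asymmetric sides stay unchanged
  m3 <- fix_mol("CCOc1ccccc1N")
  fr3 <- fragment_molecule(m3)
  b3 <- c(fr3$link_bonds$a[1], fr3$link_bonds$b[1])
  fa <- fr3$fragments[[fr3$link_bonds$frag_a[1]]]
  fb <- fr3$fragments[[fr3$link_bonds$frag_b[1]]]
  expect_equal(reduce_symmetric_angles(m3, b3, fa, fb, c(60, 180, 300)),
               c(60, 180, 300))
})

test_that("fragment tree structure matches fragment and link counts", {
  one <- fix_mol("C1CCCCC1")
  fr1 <- fragment_molecule(one)
  t1 <- build_fragment_tree(one, fr1)
  expect_equal(t1$nodes[[t1$root]]$type, "leaf")

  tri <- fix_mol("c1ccccc1CCCc1ccccc1")  # ring - chain - ring
  fr3 <- fragment_molecule(tri)
  t3 <- build_fragment_tree(tri, fr3)
  types <- vapply(t3$nodes, function(n) n$type, "")
  expect_equal(sum(types == "leaf"), length(fr3$fragments))
  expect_equal(sum(types == "node"), nrow(fr3$link_bonds))
  # every link bond appears exactly once among internal nodes
  rows <- vapply(t3$nodes[types == "node"], function(n) n$link_row, 0L)
  expect_setequal(rows, seq_len(nrow(fr3$link_bonds)))
  # root covers all atoms
  expect_equal(sort(t3$nodes[[t3$root]]$atoms), seq_len(n_atoms(tri)))
})

test_that("incremental merge energies equal full recomputation", {
  # every driven candidate's incremental energy must match evaluating the
  # complete force field on the merged geometry
  for (smi in c("CCCC", "NCC(=O)OC1CCNCC1", "CC(=O)Nc1ccccc1",
                "c1ccccc1CCCc1ccccc1")) {
    out <- run_systematic(smi, seed = 41)
    expect_true(out$res$ok)
    for (c_ in out$res$conformers) {
      full <- mmff_energy(out$param, c_$coords)$total
      expect_lt(abs(c_$energy - full), 1e-3)
    }
  }
})

test_that("driving a single rigid fragment returns the fragment conformer", {
  out <- run_systematic("c1ccccc1", seed = 42)
  expect_true(out$res$ok)
  expect_length(out$res$conformers, 1)
})

test_that("butane yields three distinct conformers with anti as the minimum", {
  out <- run_systematic("CCCC", seed = 43)
  expect_true(out$res$ok)
  es <- vapply(out$res$conformers, function(c_) c_$energy, 0)
  expect_length(es, 3)
  best <- out$res$conformers[[which.min(es)]]
  d <- dihedral_angle(best$coords, 1, 2, 3, 4)
  expect_lt(min(abs(d - 180), abs(d - 180 + 360)), 15)

  # oracle: exhaustive evaluation of the three staggered angles says anti
  # is the minimum of the full force field
  full <- vapply(out$res$conformers, function(c_) {
    mmff_energy(out$param, c_$coords)$total
  }, 0)
  ds <- vapply(out$res$conformers, function(c_) {
    dihedral_angle(c_$coords, 1, 2, 3, 4)
  }, 0)
  anti_idx <- which.min(pmin(abs(ds - 180), abs(ds - 180 + 360),
                             abs(ds - 180 - 360)))
  expect_equal(which.min(full), anti_idx)
})

test_that("driven conformer energies respect the adaptive window", {
  out <- run_systematic("NCC(=O)OC1CCNCC1", seed = 44)
  es <- vapply(out$res$conformers, function(c_) c_$energy, 0)
  expect_true(all(es <= min(es) + 15 + 1e-9))
})

test_that("stereo descriptors survive torsion driving", {
  out <- run_systematic("C[C@H](F)c1ccccc1", seed = 45)
  expect_true(out$res$ok)
  for (c_ in out$res$conformers) {
    expect_true(all(check_stereo(out$mol, c_$coords)))
  }
})
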