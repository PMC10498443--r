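# Distance-geometry random conformer generation: bounds, volume
# constraints, embedding, hydrogen placement, refinement, stereo checks.

test_that("distance bounds follow the topological-distance rules", {
  m <- fix_mol("CCCCCC")   # n-hexane: has TD up to 5
  p <- fix_param("CCCCCC")
  td <- topological_distances(m)
  b <- build_distance_bounds(m, p, td)
  r0_cc <- p$bonds[which(p$bonds[, 1] == 1 & p$bonds[, 2] == 2), 4]

  row_bonded <- which(b$pairs[, 1] == 1 & b$pairs[, 2] == 2)
  expect_equal(b$pairs[row_bonded, 3], r0_cc)
  expect_equal(b$pairs[row_bonded, 4], r0_cc)

  # geminal: law of cosines from the two reference lengths and theta0
  row_gem <- which(b$pairs[, 1] == 1 & b$pairs[, 2] == 3)
  th <- p$angles[which(p$angles[, 1] %in% c(1, 3) & p$angles[, 2] == 2 &
                       p$angles[, 3] %in% c(1, 3)), 5]
  d_expect <- sqrt(2 * r0_cc^2 - 2 * r0_cc^2 * cos(th * pi / 180))
  expect_equal(b$pairs[row_gem, 3], d_expect, tolerance = 1e-9)

  # remote pair: covalent radius sum + 1.5 A safety spacing
  row_far <- which(b$pairs[, 1] == 1 & b$pairs[, 2] == 6)
  expect_equal(td[1, 6], 5L)
  expect_equal(b$pairs[row_far, 3], 2 * 0.76 + 1.5)
  expect_equal(b$pairs[row_far, 4], sum(p$bonds[, 4]))
})

test_that("volume constraints encode chirality sign and planarity", {
  s <- fix_mol("C[C@H](N)C(=O)O")
  v <- build_volume_constraints(s)
  chir <- v[abs(v[, 5]) == 0.5 | abs(v[, 6]) == 0.5, , drop = FALSE]
  expect_equal(nrow(chir), 1)
  expect_true((chir[1, 5] == 0.5 && chir[1, 6] == 1000) ||
              (chir[1, 5] == -1000 && chir[1, 6] == -0.5))

  fa <- fix_mol("C(=O)N")   # formamide: planar N
  vf <- build_volume_constraints(fa)
  planar <- vf[vf[, 5] == 0 & vf[, 6] == 0, , drop = FALSE]
  expect_gt(nrow(planar), 0)

  me <- fix_mol("C")
  expect_equal(nrow(build_volume_constraints(me)), 0)
})

test_that("embedding honours an exact pair constraint and volume signs", {
  set.seed(5)
  bounds <- list(pairs = matrix(c(1, 2, 1.54, 1.54), 1), atoms = 1:2)
  e <- dg_embed(bounds, matrix(0, 0, 6))
  expect_true(e$ok)
  expect_equal(sqrt(sum((e$coords[1, ] - e$coords[2, ])^2)), 1.54,
               tolerance = 1e-3)

  # 4-atom cluster with a demanded positive signed volume
  set.seed(6)
  pr <- t(combn(4, 2))
  bounds <- list(pairs = cbind(pr, 1.4, 2.6), atoms = 1:4)
  vols <- matrix(c(1, 2, 3, 4, 0.5, 1000), 1)
  e <- dg_embed(bounds, vols)
  expect_true(e$ok)
  v <- confsmith:::signed_volume(e$coords[1, ], e$coords[2, ],
                                 e$coords[3, ], e$coords[4, ])
  expect_gt(v, 0)
})

test_that("hydrogen placement produces ideal local geometry", {
  set.seed(8)
  m <- fix_mol("CC(C)C")  # isobutane: sp3 CH with 3 placed neighbours
  p <- fix_param("CC(C)C")
  g <- generate_random_conformer(m, p)
  expect_true(g$ok)
  # H on the methine carbon: H-C-C angles near tetrahedral
  adj <- confsmith:::adjacency(m)
  ch <- 2
  hs <- adj[[ch]][m$atoms$element[adj[[ch]]] == "H"]
  cs <- adj[[ch]][m$atoms$element[adj[[ch]]] == "C"]
  ang <- function(a, b, c_) {
    v1 <- g$coords[a, ] - g$coords[b, ]; v2 <- g$coords[c_, ] - g$coords[b, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  for (c_ in cs) expect_lt(abs(ang(hs[1], ch, c_) - 109.5), 8)

  # water: two hydrogens at the MMFF equilibrium angle
  w <- fix_mol("O")
  pw <- fix_param("O")
  co <- matrix(NA_real_, 3, 3)
  co[1, ] <- 0
  co2 <- place_hydrogens(w, pw, co)
  th0 <- pw$angles[1, 5]
  expect_lt(abs(ang2 <- {
    v1 <- co2[2, ] - co2[1, ]; v2 <- co2[3, ] - co2[1, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  } - th0), 5)

  # aromatic C-H lies in the ring plane
  set.seed(9)
  bz <- fix_mol("c1ccccc1")
  pb <- fix_param("c1ccccc1")
  gb <- generate_random_conformer(bz, pb)
  ring <- gb$coords[1:6, ]
  cen <- colMeans(ring)
  sv <- svd(sweep(ring, 2, cen))
  nrm <- sv$v[, 3]
  h1 <- gb$coords[which(bz$atoms$element == "H")[1], ]
  expect_lt(abs(sum((h1 - cen) * nrm)), 0.05)
})

test_that("refinement lowers the energy and restores reference bond lengths", {
  m <- fix_mol("CC")
  p <- fix_param("CC")
  set.seed(10)
  g <- generate_random_conformer(m, p)
  co <- g$coords
  axis <- co[2, ] - co[1, ]
  axis <- axis / sqrt(sum(axis^2))
  shift <- (2.0 - sqrt(sum((co[2, ] - co[1, ])^2))) * axis
  moved <- c(2, which(m$bonds$i == 2 & m$atoms$element[m$bonds$j] == "H" |
                      m$bonds$j == 2 & m$atoms$element[m$bonds$i] == "H"))
  adj <- confsmith:::adjacency(m)
  grp <- c(2, adj[[2]][m$atoms$element[adj[[2]]] == "H"])
  co[grp, ] <- sweep(co[grp, , drop = FALSE], 2, shift, `+`)
  e_in <- mmff_energy(p, co)$total
  r <- refine_conformer(p, co, "gradient_norm", 0.05)
  expect_lte(r$energy, e_in)
  cc <- sqrt(sum((r$coords[1, ] - r$coords[2, ])^2))
  r0 <- p$bonds[which(p$bonds[, 1] == 1 & p$bonds[, 2] == 2), 4]
  expect_lt(abs(cc - r0), 0.02)

  # refining an already-minimised structure changes little
  r2 <- refine_conformer(p, r$coords, "energy_delta", 0.001)
  expect_lt(abs(r2$energy - r$energy), 0.01)
})

test_that("stereo checks recompute parity and flip under mirror images", {
  set.seed(12)
  m <- fix_mol("C[C@H](N)C(=O)O")
  p <- fix_param("C[C@H](N)C(=O)O")
  g <- generate_random_conformer(m, p)
  expect_true(g$ok)
  expect_true(all(check_stereo(m, g$coords)))
  mirror <- g$coords
  mirror[, 1] <- -mirror[, 1]
  chk <- check_stereo(m, mirror)
  expect_false(chk[attr(chk, "what") == "atom"][1])

  # configured double bond with wrong-side coordinates fails the check
  set.seed(13)
  z <- fix_mol("C/C=C\\C")
  pz <- fix_param("C/C=C\\C")
  gz <- generate_random_conformer(z, pz)
  expect_true(all(check_stereo(z, gz$coords)))
  t <- fix_mol("C/C=C/C")
  expect_false(all(check_stereo(t, gz$coords, specified_only = TRUE)))
})

test_that("defined configurations survive repeated random generation", {
  m <- fix_mol("C[C@@H](O)CC")
  p <- fix_param("C[C@@H](O)CC")
  for (seed in 1:25) {
    set.seed(seed)
    g <- generate_random_conformer(m, p)
    expect_true(g$ok)
    expect_true(all(check_stereo(m, g$coords)))
  }
})

test_that("unsatisfiable constraints fail after exactly the trial cap", {
  m <- fix_mol("CCO")
  p <- fix_param("CCO")
  td <- topological_distances(m)
  b <- build_distance_bounds(m, p, td)
  # contradictory hook: demand a 1-2 distance both at bond length and at 9 A
  b$pairs <- rbind(b$pairs, c(1, 2, 9, 9))
  v <- build_volume_constraints(m, b$atoms)
  set.seed(14)
  g <- generate_random_conformer(m, p, td, bounds = b, volumes = v)
  expect_false(g$ok)
  expect_equal(g$trials, 10)
  expect_equal(g$failure, "embed")
})

test_that("fixed seeds reproduce embeddings exactly", {
  m <- fix_mol("CC(=O)NC1CCC(O)CC1")
  p <- fix_param("CC(=O)NC1CCC(O)CC1")
  set.seed(77)
  g1 <- generate_random_conformer(m, p)
  set.seed(77)
  g2 <- generate_random_conformer(m, p)
  expect_identical(g1$coords, g2$coords)
  expect_identical(g1$energy, g2$energy)
})
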