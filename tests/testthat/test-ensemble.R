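# Symmetry mappings, Kabsch RMSD, symmetry-aware minimum RMSD and greedy
# output selection.

test_that("automorphism counts match brute-force enumeration", {
  bz <- fix_mol("c1ccccc1")
  maps <- enumerate_symmetry_mappings(bz)
  expect_length(maps, 12)
  expect_equal(length(maps), brute_force_automorphisms(bz))
  # identity first
  expect_equal(maps[[1]], seq_len(6))

  np <- fix_mol("CC(C)(C)C")   # neopentane heavy skeleton
  maps_np <- enumerate_symmetry_mappings(np)
  expect_length(maps_np, 24)
  expect_equal(length(maps_np), brute_force_automorphisms(np))

  al <- fix_mol("C[C@H](N)C(=O)O")
  expect_length(enumerate_symmetry_mappings(al), 1)

  # the cap is honoured and reported
  capped <- enumerate_symmetry_mappings(bz, cap = 5L)
  expect_length(capped, 5)
  expect_true(attr(capped, "capped"))
})

test_that("kabsch superposition is exact on rigid motions and vs a grid oracle", {
  set.seed(51)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_rmsd(a, a), 0)

  th <- 0.7; ph <- 1.3
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
         rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  b <- sweep(a %*% rot, 2, c(1, -2, 0.5), `+`)
  expect_lt(kabsch_rmsd(a, b), 1e-6)

  # brute-force rotation-grid oracle on random pairs
  grid_rmsd <- function(a, b, n = 40) {
    ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
    best <- Inf
    set.seed(99)
    for (t in seq_len(5000)) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      R <- rbind(
        c(1 - 2*(q[3]^2 + q[4]^2), 2*(q[2]*q[3] - q[4]*q[1]), 2*(q[2]*q[4] + q[3]*q[1])),
        c(2*(q[2]*q[3] + q[4]*q[1]), 1 - 2*(q[2]^2 + q[4]^2), 2*(q[3]*q[4] - q[2]*q[1])),
        c(2*(q[2]*q[4] - q[3]*q[1]), 2*(q[3]*q[4] + q[2]*q[1]), 1 - 2*(q[2]^2 + q[3]^2)))
      r <- sqrt(sum((ca - cb %*% t(R))^2) / nrow(a))
      if (r < best) best <- r
    }
    best
  }
  for (rep in 1:3) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    exact <- kabsch_rmsd(a, b)
    approx <- grid_rmsd(a, b)
    expect_lte(exact, approx + 1e-9)     # closed form is the true minimum
    expect_lt(approx - exact, 0.05)      # random grid comes close
  }
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
})

test_that("symmetry-aware RMSD uses the best mapping", {
  set.seed(52)
  bz <- fix_mol("c1ccccc1")
  p <- fix_param("c1ccccc1")
  g <- generate_random_conformer(bz, p)
  # in-plane rotation by 60 degrees is a symmetry operation
  ring <- g$coords[1:6, ]
  cen <- colMeans(ring)
  sv <- svd(sweep(ring, 2, cen))
  nrm <- sv$v[, 3]
  rot <- confsmith:::rotation_about(nrm, pi / 3)
  co2 <- sweep(sweep(g$coords, 2, cen) %*% t(rot), 2, cen, `+`)
  maps <- enumerate_symmetry_mappings(bz)
  expect_lt(min_symmetry_rmsd(bz, g$coords, co2, maps), 0.05)

  # never worse than the identity mapping
  set.seed(53)
  g2 <- generate_random_conformer(bz, p)
  ident <- kabsch_rmsd(g$coords[1:6, ], g2$coords[1:6, ])
  expect_lte(min_symmetry_rmsd(bz, g$coords, g2$coords, maps), ident + 1e-12)

  # asymmetric molecule: equals the identity-mapping RMSD
  al <- fix_mol("C[C@H](N)C(=O)O")
  pal <- fix_param("C[C@H](N)C(=O)O")
  set.seed(54)
  h1 <- generate_random_conformer(al, pal)
  h2 <- generate_random_conformer(al, pal)
  heavy <- which(al$atoms$element != "H")
  expect_equal(min_symmetry_rmsd(al, h1$coords, h2$coords),
               kabsch_rmsd(h1$coords[heavy, ], h2$coords[heavy, ]))
})

test_that("greedy selection obeys threshold, window and size rules", {
  m <- fix_mol("CCCC")
  set.seed(55)
  base <- run_systematic("CCCC", seed = 55)
  cands <- base$res$conformers
  es <- vapply(cands, function(c_) c_$energy, 0)

  # duplicate of the minimum is rejected by the threshold rule
  dup <- cands[[which.min(es)]]
  dup$energy <- dup$energy + 0.3
  ens <- compile_output_ensemble(m, c(cands, list(dup)),
                                 selection_settings(rmsd_threshold = 0.3))
  sel_es <- vapply(ens$conformers, function(c_) c_$energy, 0)
  expect_false(any(abs(sel_es - dup$energy) < 1e-12))

  # size cap
  ens2 <- compile_output_ensemble(m, cands, selection_settings(n_max = 1L))
  expect_length(ens2$conformers, 1)
  expect_equal(ens2$conformers[[1]]$energy, min(es))

  # window exclusion
  far <- cands[[1]]
  far$energy <- min(es) + 15 + 1
  ens3 <- compile_output_ensemble(m, c(cands, list(far)),
                                  selection_settings(energy_window = 15))
  expect_true(all(vapply(ens3$conformers, function(c_) c_$energy, 0) <=
                  min(es) + 15))

  # empty candidate list is a molecule failure
  expect_error(compile_output_ensemble(m, list()), "no candidate")
})

test_that("ensemble invariants hold across generated molecules", {
  f <- make_fixtures("smallmol", 6, seed = 56)
  mols <- read_compounds(f)
  res <- generate_batch(mols, generation_settings(seed = 56))
  for (k in seq_along(res$ensembles)) {
    ens <- res$ensembles[[k]]
    if (is.null(ens)) next
    es <- vapply(ens$conformers, function(c_) c_$energy, 0)
    expect_true(all(diff(es) >= 0))
    expect_lte(length(es), 100)
    expect_true(all(es <= es[1] + 15 + 1e-9))
    if (length(es) > 1 && !ens$mapping_capped) {
      maps <- enumerate_symmetry_mappings(ens$mol)
      for (i in 1:(length(es) - 1)) for (j in (i + 1):length(es)) {
        expect_gte(min_symmetry_rmsd(ens$mol, ens$conformers[[i]]$coords,
                                     ens$conformers[[j]]$coords, maps),
                   0.5 - 1e-9)
      }
    }
  }
})
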