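# Benchmarking: best RMSD against references and summary tables.

test_that("best RMSD is zero for references drawn from the ensemble", {
  set.seed(81)
  out <- run_systematic("CC(=O)Nc1ccccc1", seed = 81)
  m <- out$mol
  ens <- compile_output_ensemble(m, out$res$conformers, selection_settings())
  ref <- ens$conformers[[length(ens$conformers)]]$coords
  expect_lt(best_rmsd(ens, ref), 1e-6)

  # under automorphic relabelling of the heavy atoms it is still zero
  maps <- enumerate_symmetry_mappings(m)
  nontrivial <- maps[[which(vapply(maps, function(p) {
    any(p != seq_along(p)) }, TRUE))[1]]]
  heavy <- attr(maps, "heavy")
  ref2 <- ref
  ref2[heavy, ] <- ref[heavy[nontrivial], ]
  expect_lt(best_rmsd(ens, ref2), 1e-6)
})

test_that("single-conformer best RMSD equals the pairwise minimum", {
  set.seed(82)
  m <- fix_mol("c1ccccc1")
  p <- fix_param("c1ccccc1")
  g1 <- generate_random_conformer(m, p)
  g2 <- generate_random_conformer(m, p)
  one <- list(list(coords = g1$coords, energy = g1$energy))
  expect_equal(best_rmsd(one, g2$coords, mol = m),
               min_symmetry_rmsd(m, g1$coords, g2$coords))
})

test_that("best RMSD never increases when conformers are appended", {
  set.seed(83)
  out <- run_systematic("CCCC", seed = 83)
  m <- out$mol
  ref <- out$res$conformers[[1]]$coords
  vals <- vapply(seq_along(out$res$conformers), function(k) {
    best_rmsd(out$res$conformers[seq_len(k)], ref, mol = m)
  }, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("a graph mismatch raises an error", {
  set.seed(84)
  out <- run_systematic("CCCC", seed = 84)
  expect_error(best_rmsd(out$res$conformers, matrix(0, 3, 3), mol = out$mol),
               "does not match")
})

test_that("summary statistics and percentile tables are correct", {
  recs <- data.frame(name = c("a", "b"), best_rmsd = c(0.4, 0.6),
                     n_conformers = c(3, 5), time = c(1, 2), status = "ok")
  s <- summarize_benchmark(recs, thresholds = c(0.5, 1.0))
  expect_equal(s$percentiles$percent, c(50, 100))

  recs2 <- data.frame(name = letters[1:3], best_rmsd = c(0.2, 0.4, 1.2),
                      n_conformers = 1, time = 1, status = "ok")
  s2 <- summarize_benchmark(recs2)
  expect_equal(s2$stats$mean_rmsd, 0.6)
  expect_equal(s2$stats$median_rmsd, 0.4)
  # percentile columns are non-decreasing in the threshold
  expect_true(all(diff(s2$percentiles$percent) >= 0))

  recs3 <- rbind(recs2, data.frame(name = "d", best_rmsd = NA,
                                   n_conformers = 0, time = 0,
                                   status = "failed:sampling"))
  s3 <- summarize_benchmark(recs3)
  expect_equal(s3$n_failed, 1)
  expect_equal(s3$stats$n, 3)

  s4 <- summarize_benchmark(recs3[recs3$status != "ok", , drop = FALSE])
  expect_null(s4$stats)
  expect_equal(s4$n_failed, 1)
})
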