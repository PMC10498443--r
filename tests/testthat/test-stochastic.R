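# Stochastic sampling: duplicate removal, loop exits, reproducibility.

test_that("energy-duplicate removal keeps one survivor per cluster", {
  mk <- function(es) lapply(es, function(e) list(coords = NULL, energy = e))
  out <- remove_energy_duplicates(mk(c(1.000, 1.005, 2.0)))
  expect_equal(vapply(out, function(c_) c_$energy, 0), c(1.000, 2.0))

  # chained gaps of 0.02 are all kept (pairwise window rule on neighbours)
  out2 <- remove_energy_duplicates(mk(c(1.000, 1.02, 1.04)))
  expect_length(out2, 3)

  expect_length(remove_energy_duplicates(list()), 0)

  # output is sorted ascending
  out3 <- remove_energy_duplicates(mk(c(3, 1, 2)))
  expect_equal(vapply(out3, function(c_) c_$energy, 0), c(1, 2, 3))
})

test_that("the sample cap limits generation cycles", {
  m <- fix_mol("CCO")
  p <- fix_param("CCO")
  set.seed(21)
  s <- stochastic_sample(m, p, stochastic_settings(max_samples = 5L,
                                                   check_period = 100L),
                         macrocyclic = FALSE)
  expect_lte(s$cycles, 5L)
})

test_that("all retained conformers sit inside the energy window", {
  m <- fix_mol("C1CCCCCC1")   # cycloheptane
  p <- fix_param("C1CCCCCC1")
  set.seed(22)
  s <- stochastic_sample(m, p, stochastic_settings(max_samples = 150L,
                                                   check_period = 50L,
                                                   energy_window = 5),
                         macrocyclic = FALSE)
  expect_true(s$ok)
  es <- vapply(s$conformers, function(c_) c_$energy, 0)
  expect_true(all(diff(es) >= 0))
  expect_true(all(es <= es[1] + 5))
})

test_that("a rigid molecule converges to one unique conformer", {
  m <- fix_mol("c1ccccc1")
  p <- fix_param("c1ccccc1")
  set.seed(23)
  s <- stochastic_sample(m, p, stochastic_settings(), macrocyclic = FALSE)
  expect_true(s$converged)
  expect_lt(s$cycles, 2000L)
  expect_length(s$conformers, 1)
})

test_that("fixed seeds reproduce the whole ensemble", {
  m <- fix_mol("C1CCCCC1")
  p <- fix_param("C1CCCCC1")
  run <- function() {
    set.seed(24)
    stochastic_sample(m, p, stochastic_settings(max_samples = 60L,
                                                check_period = 30L),
                      macrocyclic = FALSE)
  }
  s1 <- run(); s2 <- run()
  expect_equal(length(s1$conformers), length(s2$conformers))
  for (k in seq_along(s1$conformers)) {
    expect_identical(s1$conformers[[k]]$energy, s2$conformers[[k]]$energy)
    expect_identical(s1$conformers[[k]]$coords, s2$conformers[[k]]$coords)
  }
})
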