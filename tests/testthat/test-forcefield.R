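# Decomposed MMFF94 evaluation: term counts, variant behaviour, agreement
# with the reference engine, gradients, rigid-motion invariance.

random_geometry <- function(mol, seed = 1, sd = 0.08) {
  set.seed(seed)
  p <- parametrize(mol)
  g <- generate_random_conformer(mol, p)
  stopifnot(g$ok)
  g$coords + matrix(rnorm(length(g$coords), sd = sd), ncol = 3)
}

test_that("ethane is typed with the expected term counts", {
  p <- fix_param("CC")
  expect_equal(nrow(p$bonds), 7)     # 1 C-C + 6 C-H
  expect_equal(nrow(p$tors), 9)      # H-C-C-H torsions
})

test_that("the no-electrostatics variant zeroes exactly the coulomb term", {
  full <- fix_param("CC(=O)NC")
  ne <- fix_param("CC(=O)NC", no_estat = TRUE)
  co <- random_geometry(fix_mol("CC(=O)NC"), seed = 3)
  e_full <- mmff_energy(full, co)
  e_ne <- mmff_energy(ne, co)
  expect_equal(e_ne$electrostatic, 0)
  expect_equal(e_ne$total, e_full$total - e_full$electrostatic,
               tolerance = 1e-10)
})

test_that("total energy equals the category sum and matches the reference engine", {
  smis <- c("CCO", "CC(=O)NC1CCC(O)CC1", "c1ccccc1CC(N)C(=O)O",
            "CC#N", "C[N+](C)(C)C", "O=S(=O)(N)c1ccc(Cl)cc1")
  for (smi in smis) {
    m <- fix_mol(smi)
    for (variant in c("MMFF94s", "MMFF94")) {
      p <- parametrize(m, variant = variant)
      co <- random_geometry(m, seed = 5)
      e <- mmff_energy(p, co)
      cats <- e$stretching + e$bending + e$stretch_bend + e$out_of_plane +
              e$torsion + e$vdw + e$electrostatic
      expect_equal(e$total, cats, tolerance = 1e-12)
      ref <- rdkit_mmff_total(m, co, variant)
      expect_lt(abs(e$total - ref), 1e-3)
    }
  }
})

test_that("analytic gradient matches central finite differences", {
  for (smi in c("CCO", "CC(=O)N", "c1ccoc1C")) {
    m <- fix_mol(smi)
    p <- parametrize(m)
    co <- random_geometry(m, seed = 7)
    g <- mmff_gradient(p, co)
    h <- 1e-5
    num <- matrix(0, nrow(co), 3)
    for (a in seq_len(nrow(co))) for (t in 1:3) {
      up <- co; up[a, t] <- up[a, t] + h
      dn <- co; dn[a, t] <- dn[a, t] - h
      num[a, t] <- (mmff_energy(p, up)$total - mmff_energy(p, dn)$total) / (2 * h)
    }
    expect_lt(max(abs(g - num)), 1e-4)
  }
})

test_that("diatomic-like stretch forces are equal and opposite on the bond axis", {
  p <- fix_param("CC")
  m <- fix_mol("CC")
  set.seed(2)
  g0 <- generate_random_conformer(m, p)
  co <- g0$coords
  # stretch the C-C bond
  axis <- co[2, ] - co[1, ]
  axis <- axis / sqrt(sum(axis^2))
  co[2, ] <- co[2, ] + 0.4 * axis
  hs1 <- which(m$bonds$i == 1 | m$bonds$j == 1)
  # isolate the C-C stretch term
  q <- p
  q$angles <- q$angles[0, , drop = FALSE]; q$sb <- q$sb[0, , drop = FALSE]
  q$oop <- q$oop[0, , drop = FALSE]; q$tors <- q$tors[0, , drop = FALSE]
  q$nb <- q$nb[0, , drop = FALSE]
  cc <- which(q$bonds[, 1] == 1 & q$bonds[, 2] == 2 |
              q$bonds[, 1] == 2 & q$bonds[, 2] == 1)
  q$bonds <- q$bonds[cc, , drop = FALSE]
  g <- mmff_gradient(q, co)
  expect_equal(g[1, ], -g[2, ], tolerance = 1e-9)
  cr <- confsmith:::pracma_cross(g[1, ], axis)
  expect_lt(sqrt(sum(cr^2)), 1e-8)
})

test_that("energy is invariant under rigid rotation and translation", {
  m <- fix_mol("CC(=O)NC1CCC(O)CC1")
  p <- fix_param("CC(=O)NC1CCC(O)CC1")
  co <- random_geometry(m, seed = 11)
  e0 <- mmff_energy(p, co)$total
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- sweep(co %*% rot, 2, c(3.2, -1.1, 0.7), `+`)
  expect_lt(abs(mmff_energy(p, co2)$total - e0), 1e-8)
})

test_that("coincident nonbonded atoms give a large finite penalty", {
  m <- fix_mol("CCCC")
  p <- fix_param("CCCC")
  co <- random_geometry(m, seed = 13)
  co[4, ] <- co[1, ]   # TD = 3 pair collapses
  e <- mmff_energy(p, co)
  expect_true(is.finite(e$total))
  expect_gt(e$vdw, 1e3)
})

test_that("parametrization failures name the problem and batch positions", {
  mols <- lapply(parse_smiles(c("CCO", "B(O)(O)O")), preprocess)
  ps <- parametrize(mols)
  expect_true(ps[[1]]$ok)
  expect_false(ps[[2]]$ok)
  expect_match(ps[[2]]$error, "MMFF94|coverage")
})

test_that("torsion overrides replace matching atom-type quadruples", {
  p <- fix_param("CCCC")
  f <- tempfile()
  # override the C-C-C-C torsion (MMFF type 1 throughout)
  writeLines("1 1 1 1  0.5 0.25 0.125", f)
  q <- apply_torsion_overrides(p, load_torsion_overrides(f))
  at <- q$atom_types
  cc <- which(apply(q$tors[, 1:4, drop = FALSE], 1, function(idx) {
    all(at[idx] == 1)
  }))
  expect_true(length(cc) >= 1)
  expect_true(all(q$tors[cc, 5] == 0.5))
  expect_true(all(q$tors[cc, 7] == 0.125))
  # empty file leaves everything unchanged
  writeLines("# nothing", f)
  expect_identical(apply_torsion_overrides(p, load_torsion_overrides(f))$tors,
                   p$tors)
})
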