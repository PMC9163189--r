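# Polymorph clustering, ranking, and cluster-overlap scoring.

make_p21_structure <- function(frac = c(0.13, 0.21, 0.34),
                               angles = c(25, 50, 75),
                               cell = c(4.6, 5.2, 5.4, 102)) {
  mon <- fixture_monomers("triatomic")
  crystal(lattice(cell[1], cell[2], cell[3], beta = cell[4]), "P21",
          list(list(monomer = mon, frac = frac,
                    quat = euler_to_quat(angles[1], angles[2], angles[3]))))
}

test_that("exact duplicates collapse to one cluster; distinct stay apart", {
  s1 <- make_p21_structure()
  s2 <- make_p21_structure()                           # identical
  s3 <- make_p21_structure(frac = c(0.4, 0.1, 0.6),
                           angles = c(80, 10, 120),
                           cell = c(5.4, 4.4, 6.0, 95)) # different packing
  ps <- polymorph_set(list(s1, s2, s3), c(-10, -10, -9.9))
  ps <- cluster_structures(ps)
  expect_identical(ps$table$cluster[1], ps$table$cluster[2])
  expect_false(ps$table$cluster[3] == ps$table$cluster[1])
})

test_that("the same crystal in a re-based cell clusters with the original", {
  s1 <- make_p21_structure()
  ## re-describe on a sheared basis (P1, a' = a + c)
  p1 <- as_p1(s1)
  A <- lattice_matrix(p1$lattice)
  Tm <- rbind(c(1, 0, 1), c(0, 1, 0), c(0, 0, 1))
  A2 <- Tm %*% A
  l2 <- cspff:::lattice_from_matrix(A2)
  ## transform molecule positions onto the new basis
  asu2 <- lapply(p1$asu, function(e) {
    X <- cspff:::asu_atoms(e, A)
    R <- solve(A2) %*% lattice_matrix(l2)   # rotate to canonical frame
    Xn <- X %*% R
    fit <- cspff:::fit_pose(e$monomer, Xn)
    f <- colSums((Xn %*% solve(lattice_matrix(l2))) * e$monomer$masses) /
      sum(e$monomer$masses)
    list(monomer = e$monomer, frac = f - floor(f), quat = fit$quat,
         invert = fit$invert)
  })
  s2 <- crystal(l2, "P1", asu2)
  ps <- cluster_structures(polymorph_set(list(s1, s2), c(-10, -10)))
  expect_identical(ps$table$cluster[1], ps$table$cluster[2])
})

test_that("clustering an already-clustered representative set is the identity", {
  s1 <- make_p21_structure()
  s3 <- make_p21_structure(frac = c(0.4, 0.1, 0.6), angles = c(80, 10, 120),
                           cell = c(5.4, 4.4, 6.0, 95))
  ps <- rank_polymorphs(cluster_structures(polymorph_set(list(s1, s3),
                                                         c(-10, -9.5))))
  reps <- match(ps$representatives, ps$table$id)
  ps2 <- cluster_structures(polymorph_set(ps$structures[reps],
                                          ps$table$energy[reps]))
  expect_identical(ps2$table$cluster, seq_along(reps))
})

test_that("ranking sorts by energy with density tie-breaks", {
  s <- make_p21_structure()
  ps <- polymorph_set(list(s, s, s), c(3, 1, 2))
  ps$table$cluster <- 1:3                  # treat as distinct
  ps <- rank_polymorphs(ps)
  expect_identical(ps$representatives, c(2L, 3L, 1L))
  expect_identical(ps$table$rank, c(3L, 1L, 2L))
  ## appending a higher-energy entry does not disturb existing order
  ps2 <- polymorph_set(list(s, s, s, s), c(3, 1, 2, 10))
  ps2$table$cluster <- 1:4
  ps2 <- rank_polymorphs(ps2)
  expect_identical(ps2$representatives[1:3], c(2L, 3L, 1L))
})

test_that("landscape table is rank-sorted with zero-based relative energies", {
  s <- make_p21_structure()
  ps <- polymorph_set(list(s, s, s), c(-9.5, -10, -9.9))
  ps$table$cluster <- 1:3
  ps <- rank_polymorphs(ps)
  land <- landscape_table(ps)
  expect_identical(nrow(land), 3L)
  expect_identical(land$rank, 1:3)
  expect_identical(land$rel_energy[1], 0)
  expect_equal(land$rel_energy, land$energy - min(land$energy))
  expect_true(all(diff(land$energy) >= 0))
})

test_that("overlap score vanishes for a structure against itself", {
  s <- make_p21_structure()
  ov <- rmsd_n(s, s, n = 12)
  expect_lt(ov$rmsd, 1e-6)
  expect_true(ov$matched)
})

test_that("overlap score is invariant under whole-crystal reorientation", {
  s <- make_p21_structure()
  ## as_p1 + pose refit effectively re-expresses the same crystal
  ov <- rmsd_n(as_p1(s), s, n = 12)
  expect_lt(ov$rmsd, 1e-6)
})

test_that("small perturbations give small but nonzero overlap scores", {
  mon <- fixture_monomers("triatomic")
  s <- make_p21_structure()
  set.seed(21)
  s2 <- s
  s2$asu[[1]]$frac <- s2$asu[[1]]$frac + rnorm(3, sd = 0.06 / 5)
  q <- quat_multiply(euler_to_quat(2.5, 1.5, 0), s2$asu[[1]]$quat)
  s2$asu[[1]]$quat <- q / sqrt(sum(q^2))
  ov <- rmsd_n(s2, s, n = 12)
  expect_gt(ov$rmsd, 1e-4)
  expect_lt(ov$rmsd, 0.45)
  expect_true(ov$matched)    # below the 0.8 Angstrom threshold
})

test_that("overlap score is symmetric for small clusters", {
  s1 <- make_p21_structure()
  s2 <- make_p21_structure(frac = c(0.14, 0.22, 0.35), angles = c(27, 49, 74))
  a <- rmsd_n(s1, s2, n = 6)$rmsd
  b <- rmsd_n(s2, s1, n = 6)$rmsd
  expect_equal(a, b, tolerance = 0.05)
})

test_that("mismatched molecules are rejected", {
  s1 <- make_p21_structure()
  other <- crystal(lattice(8, 8, 8), "P1",
                   list(list(monomer = fixture_monomers("diatomic"),
                             frac = c(0.2, 0.2, 0.2), quat = c(1, 0, 0, 0))))
  expect_error(rmsd_n(other, s1), "different molecules")
})
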