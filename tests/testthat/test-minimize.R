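# Rigid-body + cell minimization: convergence, symmetry preservation,
# staged protocol, batch behaviour.

lj_pair_ff <- function(A12 = 1e5, C6 = 1e3) {
  forcefield("lj1261", list("N:N" = pair_params(A12 = A12, C6 = C6)))
}

test_that("a single pair in a huge cell settles at the 12-6 minimum distance", {
  atom <- monomer("N", matrix(0, 1, 3))
  ff <- lj_pair_ff()
  s <- crystal(lattice(40, 40, 40), "P1",
               list(list(monomer = atom, frac = c(0.3, 0.3, 0.3),
                         quat = c(1, 0, 0, 0)),
                    list(monomer = atom, frac = c(0.3, 0.3, 0.3 + 3.4 / 40),
                         quat = c(1, 0, 0, 0))))
  res <- minimize_structure(ff, s, dof = c("pos"), maxit = 300, gtol = 1e-6)
  at <- cspff:::crystal_atoms(res$structure)
  d <- sqrt(sum((at$xyz[1, ] - at$xyz[2, ])^2))
  expect_equal(d, (2 * 1e5 / 1e3)^(1 / 6), tolerance = 1e-4)
})

test_that("restarting at a minimum leaves it unchanged", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  s <- crystal(lattice(4.6, 5.2, 5.4, beta = 102), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  r1 <- minimize_structure(ff, s, maxit = 250, cutoff = 10)
  r2 <- minimize_structure(ff, r1$structure, maxit = 50, cutoff = 10)
  expect_lt(abs(r2$final_energy - r1$final_energy), 1e-5)
})

test_that("minimization returns to a perturbed minimum (basin test)", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  s <- crystal(lattice(4.6, 5.2, 5.4, beta = 102), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  r1 <- minimize_structure(ff, s, maxit = 250, cutoff = 10)
  s2 <- r1$structure
  s2$lattice$a <- s2$lattice$a + 0.05
  s2$asu[[1]]$frac <- s2$asu[[1]]$frac + c(0.005, -0.005, 0.006)
  q <- quat_multiply(euler_to_quat(1, 0.5, 0), s2$asu[[1]]$quat)
  s2$asu[[1]]$quat <- q / sqrt(sum(q^2))
  r2 <- minimize_structure(ff, s2, maxit = 250, cutoff = 10, factr = 1e5)
  expect_lt(abs(r2$final_energy - r1$final_energy), 1e-3)
})

test_that("the space group is preserved exactly through minimization", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  s <- crystal(lattice(4.6, 5.2, 5.4, beta = 102), "P21/c",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  res <- minimize_structure(ff, s, maxit = 60, cutoff = 9)
  s2 <- res$structure
  expect_identical(s2$sg$symbol, "P21/c")
  expect_equal(s2$Z, 4)
  ## monoclinic constraints intact
  expect_equal(s2$lattice$alpha, 90)
  expect_equal(s2$lattice$gamma, 90)
  ## operators still map the expanded set onto itself: expansion from the
  ## asymmetric unit is self-consistent
  mols <- expand_symmetry(s2)
  expect_length(mols, 4)
})

test_that("minimization is deterministic", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  s <- crystal(lattice(4.8, 5.0, 5.6, beta = 99), "P21",
               list(list(monomer = mon, frac = c(0.17, 0.28, 0.40),
                         quat = euler_to_quat(10, 70, 30))))
  r1 <- minimize_structure(ff, s, maxit = 80, cutoff = 9)
  r2 <- minimize_structure(ff, s, maxit = 80, cutoff = 9)
  expect_identical(r1$final_energy, r2$final_energy)
  expect_identical(r1$structure$lattice, r2$structure$lattice)
})

test_that("staged minimization equals a single run when forms coincide", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  s <- crystal(lattice(4.8, 5.0, 5.6, beta = 99), "P21",
               list(list(monomer = mon, frac = c(0.17, 0.28, 0.40),
                         quat = euler_to_quat(10, 70, 30))))
  r1 <- staged_minimize(ff, ff, s, maxit = 60, cutoff = 9,
                        rough_args = list())
  r2 <- minimize_structure(ff, s, maxit = 60, cutoff = 9)
  expect_equal(r1$final_energy, r2$final_energy, tolerance = 1e-12)
  expect_false(isTRUE(r1$hole_collapse))
})

test_that("batched minimization equals element-wise calls and isolates failures", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  set.seed(3)
  structures <- lapply(1:4, function(i)
    cspff:::random_crystal(mon, spacegroup("P21")))
  cands <- structure(list(structures = structures,
                          meta = data.frame(id = 1:4, group = "P21")),
                     class = "cspff_candidates")
  batch <- minimize_set(ff, ff, cands, maxit = 40, cutoff = 9)
  for (i in 1:4) {
    single <- staged_minimize(ff, ff, structures[[i]], maxit = 40, cutoff = 9)
    expect_equal(batch$results[[i]]$final_energy, single$final_energy,
                 tolerance = 1e-12)
  }
  ## inject an unusable structure: the batch records it and goes on
  bad <- structures
  bad[[2]] <- "not a crystal"
  cands_bad <- structure(list(structures = bad,
                              meta = data.frame(id = 1:4, group = "P21")),
                         class = "cspff_candidates")
  batch2 <- minimize_set(ff, ff, cands_bad, maxit = 40, cutoff = 9)
  expect_false(batch2$table$ok[2])
  expect_true(all(batch2$table$ok[c(1, 3, 4)]))
  expect_equal(batch2$results[[3]]$final_energy,
               batch$results[[3]]$final_energy, tolerance = 1e-12)
})

test_that("energies never increase across the accepted trajectory", {
  mon <- fixture_monomers("triatomic")
  ff <- fixture_truth_ff("triatomic")
  set.seed(9)
  s <- cspff:::random_crystal(mon, spacegroup("P-1"))
  res <- minimize_structure(ff, s, maxit = 60, cutoff = 9)
  expect_lte(res$final_energy, res$initial_energy + 1e-9)
})
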