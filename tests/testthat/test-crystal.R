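# Crystal model: symmetry expansion, density, Ewald electrostatics,
# Niggli reduction, CIF round-trips.

test_that("symmetry expansion produces the group-order image count", {
  mon <- fixture_monomers("diatomic")
  mk <- function(sym) crystal(lattice(8, 9, 10, beta = if (sym == "P21/c") 100 else 90),
                              sym, list(list(monomer = mon,
                                             frac = c(0.13, 0.21, 0.34),
                                             quat = euler_to_quat(20, 40, 10))))
  expect_length(expand_symmetry(mk("P1")), 1)
  expect_length(expand_symmetry(mk("P212121")), 4)
  expect_length(expand_symmetry(mk("P21/c")), 4)
})

test_that("screw/glide images match hand-applied textbook operators", {
  mon <- fixture_monomers("diatomic")
  f0 <- c(0.13, 0.21, 0.34)
  s <- crystal(lattice(8, 9, 10, beta = 101), "P21/c",
               list(list(monomer = mon, frac = f0, quat = c(1, 0, 0, 0))))
  mols <- expand_symmetry(s)
  coms <- t(vapply(mols, `[[`, numeric(3), "com_frac"))
  expected <- rbind(
    f0,
    c(-f0[1], 0.5 + f0[2], 0.5 - f0[3]),
    -f0,
    c(f0[1], 0.5 - f0[2], 0.5 + f0[3]))
  expected <- expected - floor(expected)
  ## compare as sets
  for (i in 1:4) {
    d <- apply(expected, 1, function(e) {
      dd <- abs(coms[i, ] - e); dd <- pmin(dd, 1 - dd); sqrt(sum(dd^2))
    })
    expect_lt(min(d), 1e-8)
  }
})

test_that("special positions are rejected rather than silently doubled", {
  mon <- fixture_monomers("diatomic")
  s <- crystal(lattice(8, 9, 10), "P-1",
               list(list(monomer = mon, frac = c(0, 0, 0), quat = c(1, 0, 0, 0))))
  ## molecule at the inversion centre maps onto itself only if it is
  ## centrosymmetric; the diatomic is not, so expansion is fine -- use a
  ## symmetric single-atom monomer to trigger the special position
  atom <- monomer("N", matrix(0, 1, 3))
  s2 <- crystal(lattice(8, 9, 10), "P-1",
                list(list(monomer = atom, frac = c(0, 0, 0), quat = c(1, 0, 0, 0))))
  expect_error(expand_symmetry(s2), "special position")
  expect_length(expand_symmetry(s), 2)
})

test_that("density follows mass over volume", {
  w <- monomer(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0)),
               name = "water")
  s <- crystal(lattice(10, 10, 10), "P1",
               list(list(monomer = w, frac = c(.5, .5, .5), quat = c(1, 0, 0, 0))))
  expect_equal(density(s), 18.015 / (6.02214076e23 * 1e-21), tolerance = 1e-4)
  s2 <- crystal(lattice(20, 20, 20), "P1", s$asu)
  expect_equal(density(s2), density(s) / 8, tolerance = 1e-12)
  ## two molecules at fixed cell double it
  s3 <- crystal(lattice(10, 10, 10), "P1",
                c(s$asu, list(list(monomer = w, frac = c(.1, .2, .1),
                                   quat = c(1, 0, 0, 0)))))
  expect_equal(density(s3), 2 * density(s), tolerance = 1e-12)
})

test_that("Madelung constants emerge from the Ewald summation", {
  kC <- 1389.35458
  ff <- coulomb_only_ff()
  ## NaCl: M = 1.747565 per ion pair at nearest-neighbour distance a/2
  s <- ionic_crystal("nacl", a0 = 5.6)
  e <- lattice_energy_detail(ff, s, cutoff = 14)$energy
  expect_equal(-e * 2 * (5.6 / 2) / kC, 1.7475646, tolerance = 1e-5)
  ## CsCl: M = 1.762675 at d = a sqrt(3)/2
  s <- ionic_crystal("cscl", a0 = 4.1)
  e <- lattice_energy_detail(ff, s, cutoff = 14)$energy
  expect_equal(-e * 2 * (4.1 * sqrt(3) / 2) / kC, 1.7626747, tolerance = 1e-5)
  ## zincblende: M = 1.63806 at d = a sqrt(3)/4
  s <- ionic_crystal("zincblende", a0 = 5.4)
  e <- lattice_energy_detail(ff, s, cutoff = 14)$energy
  expect_equal(-e * 2 * (5.4 * sqrt(3) / 4) / kC, 1.6380550, tolerance = 1e-5)
})

test_that("non-neutral cells are rejected for Coulomb lattice sums", {
  ion <- monomer("Na", matrix(0, 1, 3), charges = 1)
  s <- crystal(lattice(6, 6, 6), "P1",
               list(list(monomer = ion, frac = c(0, 0, 0), quat = c(1, 0, 0, 0))))
  expect_error(lattice_energy_detail(coulomb_only_ff(), s), "neutral")
})

test_that("lattice energy is invariant under supercell re-description", {
  mon <- fixture_monomers("diatomic")
  ff <- fixture_truth_ff("diatomic")
  s <- crystal(lattice(4.2, 4.8, 5.1, beta = 98), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  e1 <- lattice_energy(ff, s, cutoff = 12)
  e2 <- lattice_energy(ff, supercell(s, c(2, 1, 1)), cutoff = 12)
  e3 <- lattice_energy(ff, as_p1(s), cutoff = 12)
  expect_equal(e2, e1, tolerance = 1e-6)
  expect_equal(e3, e1, tolerance = 1e-8)
})

test_that("dispersion converges with the real-space cutoff", {
  mon <- fixture_monomers("diatomic")
  ff <- fixture_truth_ff("diatomic")
  s <- crystal(lattice(4.2, 4.8, 5.1, beta = 98), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  e15 <- lattice_energy(ff, s, cutoff = 15)
  e25 <- lattice_energy(ff, s, cutoff = 25)
  expect_lt(abs(e15 - e25), 0.1)
})

test_that("Niggli reduction is canonical and volume-preserving", {
  l <- lattice(4, 5, 6, 85, 95, 100)
  r1 <- niggli_reduce(l)
  ## already reduced cells stay put
  r2 <- niggli_reduce(r1$lattice)
  expect_equal(unlist(r2$lattice), unlist(r1$lattice), tolerance = 1e-6)
  ## a' = a + b basis change reduces back to the same parameters
  A <- lattice_matrix(l)
  Tm <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1))
  l2 <- cspff:::lattice_from_matrix(Tm %*% A)
  r3 <- niggli_reduce(l2)
  expect_equal(unlist(r3$lattice), unlist(r1$lattice), tolerance = 1e-5)
  expect_equal(lattice_volume(r1$lattice), lattice_volume(l), tolerance = 1e-9)
  expect_equal(abs(det(r1$transform)), 1)
})

test_that("reduce_cell keeps the crystal identical", {
  mon <- fixture_monomers("diatomic")
  ff <- fixture_truth_ff("diatomic")
  s <- crystal(lattice(5.2, 4.8, 6.1, beta = 117), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  s2 <- reduce_cell(s)
  expect_equal(lattice_volume(s2$lattice) * s$Z / s2$Z,
               lattice_volume(s$lattice), tolerance = 1e-8)
  expect_equal(lattice_energy(ff, s2, cutoff = 12),
               lattice_energy(ff, s, cutoff = 12), tolerance = 1e-6)
})

test_that("min_contact matches a brute-force image search", {
  mon <- fixture_monomers("diatomic")
  s <- crystal(lattice(4.5, 5, 5.5, beta = 95), "P21",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(40, 30, 80))))
  at <- cspff:::crystal_atoms(s)
  A <- lattice_matrix(s$lattice)
  best <- Inf
  for (n1 in -2:2) for (n2 in -2:2) for (n3 in -2:2) {
    t3 <- as.vector(c(n1, n2, n3) %*% A)
    home <- n1 == 0 && n2 == 0 && n3 == 0
    for (i in seq_len(nrow(at$xyz))) for (j in seq_len(nrow(at$xyz))) {
      if (home && at$molid[i] == at$molid[j]) next
      best <- min(best, sqrt(sum((at$xyz[j, ] + t3 - at$xyz[i, ])^2)))
    }
  }
  expect_equal(min_contact(s), best, tolerance = 1e-10)
  expect_equal(min_contact(supercell(s, c(2, 1, 1))), best, tolerance = 1e-8)
})

test_that("CIF files round-trip structures", {
  mon <- fixture_monomers("diatomic")
  s <- crystal(lattice(6.2, 5.8, 7.1, beta = 104), "P21/c",
               list(list(monomer = mon, frac = c(0.13, 0.21, 0.34),
                         quat = euler_to_quat(25, 50, 75))))
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(s, path)
  s2 <- read_cif(path)
  expect_equal(unlist(s2$lattice), unlist(s$lattice), tolerance = 1e-5)
  expect_equal(s2$Z, s$Z)
  ## atom positions agree after expansion (compare sorted contact lists)
  expect_equal(structure_fingerprint(s2, 50), structure_fingerprint(s, 50),
               tolerance = 1e-4)
})

test_that("non-standard settings parse via their explicit operator lists", {
  ## P21/n: same group as P21/c in a different setting; operators listed
  lines <- c(
    "data_test",
    "_cell_length_a 7.0", "_cell_length_b 8.0", "_cell_length_c 9.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 99", "_cell_angle_gamma 90",
    "_symmetry_space_group_name_H-M 'P21/n'",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "'-x+1/2,y+1/2,-z+1/2'",
    "'-x,-y,-z'",
    "'x+1/2,-y+1/2,z+1/2'",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "N1 N 0.130 0.210 0.340",
    "O1 O 0.150 0.230 0.460")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, path)
  s <- read_cif(path)
  expect_equal(s$sg$order, 4)
  expect_equal(s$Z, 4)
  expect_identical(s$asu[[1]]$monomer$elements, c("N", "O"))
})

test_that("malformed CIF loops error with context", {
  lines <- c("data_x", "_cell_length_a 5", "_cell_length_b 5",
             "_cell_length_c 5", "loop_", "_atom_site_label",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "N1 0.1 0.2")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, path)
  expect_error(read_cif(path), "malformed loop_")
  expect_error(read_cif(withr::local_tempfile(fileext = ".cif")))
})
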