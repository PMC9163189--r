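# Independent oracle implementations used to check the package against a
# second, separately written code path.

# Tang-Toennies damping via direct series evaluation.
tt_ref <- function(n, delta, r) {
  x <- delta * r
  s <- sum(x^(0:n) / factorial(0:n))
  1 - exp(-x) * s
}

# Extended-form atom-atom energy, term by term.
pair_ext_ref <- function(p, qa, qb, r) {
  rep_term <- (1 + p[["a1"]] * r + p[["a2"]] * r^2) * exp(p[["alpha"]] - p[["beta"]] * r)
  wall <- p[["A12"]] / r^12
  d6 <- -tt_ref(6, p[["delta6"]], r) * p[["C6"]] / r^6
  d8 <- -tt_ref(8, p[["delta8"]], r) * p[["C8"]] / r^8
  coul <- tt_ref(1, p[["delta1"]], r) * 1389.35458 * qa * qb / r
  rep_term + wall + d6 + d8 + coul
}

# Brute-force double-loop dimer energy (any form).
dimer_ref <- function(ff, d) {
  xb <- sweep(d$monomerB$xyz %*% t(quat_to_matrix(d$quat)), 2, d$trans, "+")
  tot <- 0
  for (i in seq_along(d$monomerA$elements)) {
    for (j in seq_along(d$monomerB$elements)) {
      r <- sqrt(sum((d$monomerA$xyz[i, ] - xb[j, ])^2))
      key <- pair_key(d$monomerA$types[i], d$monomerB$types[j])
      p <- ff$pairs[[key]]
      qa <- d$monomerA$charges[i]; qb <- d$monomerB$charges[j]
      tot <- tot + switch(ff$form,
        extended = pair_ext_ref(p, qa, qb, r),
        exp61 = p[["A"]] * exp(-p[["beta"]] * r) - p[["C6"]] / r^6 +
          1389.35458 * qa * qb / r,
        lj1261 = p[["A12"]] / r^12 - p[["C6"]] / r^6 +
          1389.35458 * qa * qb / r)
    }
  }
  tot
}

# Direct real-space Coulomb lattice sum over expanding cubes of whole
# (charge-neutral) unit cells.
direct_coulomb_ref <- function(s, nshell = 8) {
  ## plain summation over whole unit cells in an expanding cube: every
  ## included cell is charge neutral, and once the cell description is
  ## dipole-free the remaining far field is traceless-quadrupole
  ## (~1/r^5), absolutely convergent.  The [0,1) wrapping used by the
  ## crystal object can leave an integer-lattice dipole, so ions are
  ## first shifted by whole lattice vectors until the dipole vanishes.
  at <- cspff:::crystal_atoms(s)
  A <- lattice_matrix(s$lattice)
  frac <- at$xyz %*% solve(A)
  for (pass in 1:50) {
    mu <- colSums(frac * at$charges)        # fractional dipole
    if (max(abs(mu)) < 1e-9) break
    moved <- FALSE
    for (d in 1:3) {
      if (abs(mu[d]) < 1e-9) next
      sgn <- sign(mu[d])
      ## shift one unit-charge-reachable ion by one lattice vector so
      ## that mu_d drops by exactly 1
      for (i in seq_len(nrow(frac))) {
        step <- -sgn / at$charges[i]
        if (abs(step) > 1.5) next           # only unit shifts
        if (abs(step - round(step)) > 1e-9) next
        frac[i, d] <- frac[i, d] + round(step)
        mu <- colSums(frac * at$charges)
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  stopifnot(max(abs(colSums(frac * at$charges))) < 1e-6)
  at$xyz <- frac %*% A
  kC <- 1389.35458
  N <- nshell
  nat <- nrow(at$xyz)
  e <- 0
  for (n1 in -N:N) for (n2 in -N:N) for (n3 in -N:N) {
    t3 <- as.vector(c(n1, n2, n3) %*% A)
    home <- all(c(n1, n2, n3) == 0)
    for (i in seq_len(nat)) for (j in seq_len(nat)) {
      if (home && at$molid[i] == at$molid[j]) next
      r <- sqrt(sum((at$xyz[j, ] + t3 - at$xyz[i, ])^2))
      e <- e + 0.5 * kC * at$charges[i] * at$charges[j] / r
    }
  }
  e / s$Z
}

# Toy ionic crystals from single-atom monomers.  nacl, perovskite and
# rutile admit dipole-free cell descriptions (their direct shell sums
# converge); cscl and zincblende have polar cell descriptions and are
# used only against literature Madelung constants.
ionic_crystal <- function(kind = c("nacl", "cscl", "zincblende",
                                   "perovskite", "rutile"), a0 = 5) {
  kind <- match.arg(kind)
  qcat <- if (kind %in% c("perovskite", "rutile")) 2 else 1
  cat1 <- monomer("Na", matrix(0, 1, 3), charges = qcat, name = "cation")
  an1 <- monomer("Cl", matrix(0, 1, 3), charges = -1, name = "anion")
  place <- function(m, f) list(monomer = m, frac = f, quat = c(1, 0, 0, 0))
  fcc <- list(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  l <- lattice(a0, a0, a0)
  asu <- switch(kind,
    nacl = c(lapply(fcc, place, m = cat1),
             lapply(list(c(.5, .5, .5), c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5)),
                    place, m = an1)),
    cscl = list(place(cat1, c(0, 0, 0)), place(an1, c(.5, .5, .5))),
    zincblende = c(lapply(fcc, place, m = cat1),
                   lapply(list(c(.25, .25, .25), c(.25, .75, .75),
                               c(.75, .25, .75), c(.75, .75, .25)),
                          place, m = an1)),
    perovskite = {
      catA <- monomer("Na", matrix(0, 1, 3), charges = 2, name = "catA")
      catB <- monomer("Na", matrix(0, 1, 3), charges = 4, name = "catB")
      anO <- monomer("Cl", matrix(0, 1, 3), charges = -2, name = "anO")
      list(place(catA, c(0, 0, 0)), place(catB, c(.5, .5, .5)),
           place(anO, c(.5, .5, 0)), place(anO, c(.5, 0, .5)),
           place(anO, c(0, .5, .5)))
    },
    rutile = {
      u <- 0.305
      l <- lattice(a0, a0, 0.644 * a0)
      c(lapply(list(c(0, 0, 0), c(.5, .5, .5)), place, m = cat1),
        lapply(list(c(u, u, 0), c(-u %% 1, -u %% 1, 0),
                    c(.5 + u, .5 - u, .5), c(.5 - u, .5 + u, .5)),
               place, m = an1))
    })
  crystal(l, "P1", asu)
}

coulomb_only_ff <- function() {
  forcefield("lj1261", list("Cl:Na" = pair_params(), "Na:Na" = pair_params(),
                            "Cl:Cl" = pair_params()))
}

# Shell-size extrapolation of the direct sum: the residual of the
# neutral-cell cube sum decays as an inverse power of the shell count, so
# a two-point Richardson step (exponent 2) removes the leading term.
direct_coulomb_extrapolated <- function(s, shells = c(5, 8)) {
  e <- vapply(shells, function(N) direct_coulomb_ref(s, N), 0)
  (e[2] * shells[2]^2 - e[1] * shells[1]^2) / (shells[2]^2 - shells[1]^2)
}
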