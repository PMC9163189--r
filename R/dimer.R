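#' Dimer configuration
#'
#' Monomer A sits in its body frame (centre of mass at the origin);
#' monomer B is rotated by a scalar-first quaternion and translated, so the
#' translation vector is B's centre of mass and the centre-of-mass
#' separation `R` is its norm.
#'
#' @param monomerA,monomerB [monomer()] objects.
#' @param quat scalar-first unit quaternion orienting B.
#' @param trans length-3 translation of B's centre of mass (Angstrom).
#' @param check if `TRUE`, reject configurations with intermolecular
#'   contacts below 0.1 Angstrom.
#' @return object of class `cspff_dimer`.
#' @export
dimer_config <- function(monomerA, monomerB, quat = c(1, 0, 0, 0),
                         trans = c(0, 0, 5), check = TRUE) {
  stopifnot(inherits(monomerA, "cspff_monomer"), inherits(monomerB, "cspff_monomer"))
  quat <- quat / sqrt(sum(quat^2))
  d <- structure(
    list(monomerA = monomerA, monomerB = monomerB,
         quat = as.numeric(quat), trans = as.numeric(trans)),
    class = "cspff_dimer"
  )
  if (check && min_dimer_distance(d) <= 0.1)
    stop("dimer has intermolecular contact <= 0.1 Angstrom")
  d
}

#' @export
print.cspff_dimer <- function(x, ...) {
  cat(sprintf("<dimer %s / %s, R = %.4f Angstrom, min contact %.3f Angstrom>\n",
              x$monomerA$name, x$monomerB$name, dimer_R(x), min_dimer_distance(x)))
  invisible(x)
}

#' Centre-of-mass separation of a dimer (Angstrom)
#' @param d a [dimer_config()].
#' @export
dimer_R <- function(d) sqrt(sum(d$trans^2))

dimer_xyzB <- function(d) {
  sweep(d$monomerB$xyz %*% t(quat_to_matrix(d$quat)), 2, d$trans, "+")
}

#' Shortest intermolecular atom-atom distance of a dimer (Angstrom)
#' @param d a [dimer_config()].
#' @export
min_dimer_distance <- function(d) {
  min(cross_distances(d$monomerA$xyz, dimer_xyzB(d)))
}

## Flat per-atom-pair view of a dimer: distances, charges, pair keys.
dimer_pairs <- function(d) {
  xb <- dimer_xyzB(d)
  rmat <- cross_distances(d$monomerA$xyz, xb)
  na <- n_atoms(d$monomerA); nb <- n_atoms(d$monomerB)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  list(
    r = as.vector(rmat),
    qa = d$monomerA$charges[ia],
    qb = d$monomerB$charges[ib],
    key = pair_key(d$monomerA$types[ia], d$monomerB$types[ib])
  )
}

## Evaluate one functional form on grouped pair data; returns the four
## physical components (elst, exch = repulsive wall, disp6, disp8).
.pair_components <- function(ff, key, qa, qb, r) {
  elst <- exch <- disp6 <- disp8 <- numeric(length(r))
  for (k in unique(key)) {
    idx <- key == k
    tt <- strsplit(k, ":", fixed = TRUE)[[1]]
    p <- ff_lookup(ff, tt[1], tt[2])
    rr <- r[idx]; qq <- qa[idx] * qb[idx]
    if (ff$form == "extended") {
      exch[idx] <- (1 + p[["a1"]] * rr + p[["a2"]] * rr^2) *
        exp(p[["alpha"]] - p[["beta"]] * rr) + p[["A12"]] / rr^12
      disp6[idx] <- -tang_toennies(6, p[["delta6"]], rr) * p[["C6"]] / rr^6
      disp8[idx] <- -tang_toennies(8, p[["delta8"]], rr) * p[["C8"]] / rr^8
      elst[idx] <- tang_toennies(1, p[["delta1"]], rr) * COULOMB_KJ * qq / rr
    } else if (ff$form == "exp61") {
      exch[idx] <- p[["A"]] * exp(-p[["beta"]] * rr)
      disp6[idx] <- -p[["C6"]] / rr^6
      elst[idx] <- COULOMB_KJ * qq / rr
    } else {
      exch[idx] <- p[["A12"]] / rr^12
      disp6[idx] <- -p[["C6"]] / rr^6
      elst[idx] <- COULOMB_KJ * qq / rr
    }
  }
  list(elst = sum(elst), exch = sum(exch), disp6 = sum(disp6), disp8 = sum(disp8))
}

#' Component-resolved two-body dimer interaction energy
#'
#' Sums every intermolecular atom-atom term of the force field and reports
#' the physically grouped pieces: damped electrostatics, the repulsive wall
#' (exponential and/or `1/r^12`), and the damped `1/r^6`, `1/r^8`
#' attractions.
#'
#' @param ff a [forcefield()].
#' @param d a [dimer_config()].
#' @return list with `elst`, `exch`, `disp6`, `disp8`, `total` (kJ/mol).
#' @export
dimer_energy_components <- function(ff, d) {
  pp <- dimer_pairs(d)
  comp <- .pair_components(ff, pp$key, pp$qa, pp$qb, pp$r)
  comp$total <- comp$elst + comp$exch + comp$disp6 + comp$disp8
  comp
}

#' Total two-body dimer interaction energy (kJ/mol)
#' @inheritParams dimer_energy_components
#' @export
dimer_interaction_energy <- function(ff, d) {
  dimer_energy_components(ff, d)$total
}

#' Damped charge-charge electrostatic energy of a dimer (kJ/mol)
#' @inheritParams dimer_energy_components
#' @export
electrostatic_energy <- function(ff, d) {
  dimer_energy_components(ff, d)$elst
}
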