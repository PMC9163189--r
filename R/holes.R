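## Hole detection: fitted exponential-repulsion potentials can turn over
## at very short range and dive below the physical minimum ("holes").
## A dense inward radial scan per orientation finds the physical well,
## then checks whether the energy ever drops back below it after the
## inner wall, and how high the protecting barrier is.

#' Scan a pair potential for short-range artefact minima
#'
#' For a set of relative orientations, the dimer energy is scanned on a
#' dense radial grid from beyond the van der Waals region inward.  The
#' global physical minimum is the deepest orientation well (outermost
#' local minimum along each ray).  An orientation carries a hole when,
#' at shorter range, its energy drops meaningfully below that global
#' minimum (by more than `max(1, 0.1 |E_phys|)` kJ/mol, so degenerate
#' wells do not false-trigger); the barrier is the highest energy met
#' along the approach before the drop, measured from the global minimum.
#' A monotone collapse (no protective bump at all) therefore reports a
#' barrier near zero rather than escaping detection.
#'
#' @param ff a [forcefield()].
#' @param mA,mB [monomer()] objects (carrying the charges to use).
#' @param n_orientations random orientations scanned (seeded).
#' @param r_grid radial grid of centre-of-mass separations (Angstrom),
#'   descending scan is taken care of internally.
#' @param barrier_min barriers below this (kJ/mol) are flagged unsafe.
#' @param r_physical centre-of-mass separation (Angstrom) above which a
#'   local minimum counts as a physical well; minima inside it are
#'   treated as part of the artefact region.
#' @param seed seed for the orientation draw.
#' @return data frame, one row per orientation: `hole`, `barrier`
#'   (kJ/mol, `Inf` when the ray never dives), `r_hole`, `flagged`.
#' @export
detect_holes <- function(ff, mA, mB, n_orientations = 24,
                         r_grid = seq(0.4, 12, by = 0.05),
                         barrier_min = 100, r_physical = 2.2, seed = 1L) {
  set.seed(seed)
  quats <- rbind(c(1, 0, 0, 0), random_quaternions(n_orientations - 1))
  dirs <- rbind(c(0, 0, 1),
                matrix(stats::rnorm(3 * (n_orientations - 1)), ncol = 3))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  r_grid <- sort(r_grid, decreasing = TRUE)   # scan inward
  curves <- lapply(seq_len(n_orientations), function(i) {
    V <- vapply(r_grid, function(R) {
      d <- dimer_config(mA, mB, quat = quats[i, ], trans = dirs[i, ] * R,
                        check = FALSE)
      if (min_dimer_distance(d) < 0.05) return(NA_real_)
      dimer_interaction_energy(ff, d)
    }, 0)
    ok <- !is.na(V)
    list(V = V[ok], r = r_grid[ok])
  })
  ## global physical minimum: deepest outermost well over all rays,
  ## counting only wells in the physical (van der Waals) region -- a
  ## collapsing ray's hole bottom must not masquerade as the reference
  well_of <- vapply(curves, function(cv) {
    imin <- which(diff(sign(diff(cv$V))) > 0) + 1
    imin <- imin[cv$r[imin] >= r_physical]
    if (!length(imin)) NA_real_ else cv$V[imin[1]]
  }, 0)
  if (all(is.na(well_of))) {
    out <- data.frame(hole = TRUE, barrier = 0, r_hole = NA_real_)[
      rep(1, n_orientations), ]
    out$flagged <- TRUE
    rownames(out) <- NULL
    return(out)
  }
  Ephys <- min(well_of, na.rm = TRUE)
  margin <- max(1, 0.1 * abs(Ephys))
  rows <- lapply(curves, function(cv) {
    below <- which(cv$V < Ephys - margin)
    if (!length(below))
      return(data.frame(hole = FALSE, barrier = Inf, r_hole = NA_real_))
    ifirst <- below[1]
    barrier <- max(cv$V[seq_len(ifirst)]) - Ephys
    data.frame(hole = TRUE, barrier = barrier, r_hole = cv$r[ifirst])
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$hole & out$barrier < barrier_min
  rownames(out) <- NULL
  out
}

#' Raise the short-range wall until holes sit behind a safe barrier
#'
#' When [detect_holes()] finds a hole behind a barrier lower than
#' `barrier_min`, every pair's `A12` is scaled up; the scale factor is
#' found by doubling until the constraint holds, then bisecting back.
#' Pairs with `A12 = 0` are seeded with a small wall first.
#'
#' @inheritParams detect_holes
#' @param max_doublings cap on the initial doubling search.
#' @return list with the (possibly modified) `forcefield`, the final
#'   `report` from [detect_holes()], and the `scale` applied.
#' @export
ensure_barrier <- function(ff, mA, mB, barrier_min = 100,
                           n_orientations = 24, seed = 1L,
                           max_doublings = 20, ...) {
  check <- function(f) {
    rep <- detect_holes(f, mA, mB, n_orientations = n_orientations,
                        barrier_min = barrier_min, seed = seed, ...)
    list(ok = !any(rep$flagged), report = rep)
  }
  r0 <- check(ff)
  if (r0$ok) return(list(forcefield = ff, report = r0$report, scale = 1))
  scale_A12 <- function(f, s) {
    f$pairs <- lapply(f$pairs, function(p) {
      if (p[["A12"]] <= 0) p[["A12"]] <- 10   # seed a wall
      p[["A12"]] <- p[["A12"]] * s
      p
    })
    f
  }
  lo <- 1; hi <- 2
  res_hi <- NULL
  for (i in seq_len(max_doublings)) {
    res_hi <- check(scale_A12(ff, hi))
    if (res_hi$ok) break
    lo <- hi; hi <- hi * 2
  }
  if (is.null(res_hi) || !res_hi$ok)
    stop("could not remove sub-barrier holes by scaling A12")
  ## bisect to within 10% of the smallest sufficient scale
  while (hi / lo > 1.1) {
    mid <- sqrt(lo * hi)
    if (check(scale_A12(ff, mid))$ok) hi <- mid else lo <- mid
  }
  ff2 <- scale_A12(ff, hi)
  fin <- check(ff2)
  list(forcefield = ff2, report = fin$report, scale = hi)
}
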