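## Synthetic reference oracle: stands in for quantum perturbation-theory
## dimer calculations.  A hidden ground-truth force field of the extended
## form produces component-resolved interaction energies (elst, exch,
## indx, dispx) at sampled dimer configurations, optionally with Gaussian
## noise per component.

#' Ground-truth oracle specification
#'
#' @param truth_ff extended-form [forcefield()] acting as the hidden
#'   reference potential.
#' @param noise_sigma standard deviation (kJ/mol) of independent Gaussian
#'   noise added to each of the four components; 0 for a noiseless oracle.
#' @param component_split how the damped attraction terms map onto the
#'   induction/dispersion components: `"n6_dispx"` (default) books the
#'   damped `C6` term as dispx and the damped `C8` term as indx;
#'   `"n8_dispx"` swaps them.  The fit uses their sum, so either split
#'   exercises it.
#' @param seed integer seed making the oracle reproducible.
#' @return object of class `cspff_oracle`.
#' @export
ground_truth <- function(truth_ff, noise_sigma = 0,
                         component_split = c("n6_dispx", "n8_dispx"),
                         seed = 1L) {
  stopifnot(inherits(truth_ff, "cspff_forcefield"),
            truth_ff$form == "extended", noise_sigma >= 0)
  structure(list(truth_ff = truth_ff, noise_sigma = noise_sigma,
                 component_split = match.arg(component_split),
                 seed = as.integer(seed)),
            class = "cspff_oracle")
}

#' Sample dimer configurations
#'
#' Orientations are uniform over SO(3); centre-of-mass separations are
#' stratified: 70% uniform over `R_range` (the interaction region) and
#' 30% log-spaced over `(R_range[2], 3 * R_range[2])` (asymptotic tail).
#' Configurations violating the minimum intermolecular contact are
#' rejected and redrawn.
#'
#' @param mA,mB [monomer()] objects.
#' @param n number of configurations.
#' @param seed integer seed.
#' @param R_range length-2 numeric, centre-of-mass separation range
#'   (Angstrom) of the interaction region.
#' @param min_contact smallest allowed intermolecular atom-atom distance
#'   (Angstrom).
#' @param max_attempts rejection-sampling cap per configuration.
#' @return list of [dimer_config()] objects.
#' @export
sample_dimer_configurations <- function(mA, mB, n, seed = 1L,
                                        R_range = c(2.5, 9),
                                        min_contact = 1.4,
                                        max_attempts = 10000L) {
  stopifnot(n >= 1, length(R_range) == 2, R_range[1] > 0,
            R_range[2] > R_range[1], min_contact > 0)
  set.seed(seed)
  n_core <- round(0.7 * n)
  n_tail <- n - n_core
  Rs <- c(stats::runif(n_core, R_range[1], R_range[2]),
          exp(stats::runif(n_tail, log(R_range[2]), log(3 * R_range[2]))))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      q <- as.vector(random_quaternions(1))
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      d <- tryCatch(
        dimer_config(mA, mB, quat = q, trans = u * Rs[i], check = FALSE),
        error = function(e) NULL)
      if (!is.null(d) && min_dimer_distance(d) >= min_contact) {
        out[[i]] <- d; ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not satisfy min_contact = %.2f Angstrom at R = %.2f after %d attempts",
        min_contact, Rs[i], max_attempts))
  }
  out
}

#' Evaluate the oracle on dimer configurations
#'
#' Splits the hidden potential into the four reference components:
#' `elst` = damped charge-charge part, `exch` = repulsive wall
#' (polynomial-prefactored exponential plus `A12/r^12`), and the damped
#' `C6`/`C8` attractions distributed over `indx`/`dispx` according to the
#' oracle's `component_split`.  Independent Gaussian noise of the oracle's
#' `noise_sigma` is added per component and the total re-summed, so the
#' component identity `total = elst + exch + indx + dispx` is exact.
#'
#' @param gt a [ground_truth()] oracle.
#' @param configs list of [dimer_config()] objects.
#' @param weights optional fit weights (default 1).
#' @return object of class `cspff_dataset`: list with `configs` and a
#'   data frame `energies` (columns `R`, `elst`, `exch`, `indx`, `dispx`,
#'   `total`, `weight`).
#' @export
evaluate_reference <- function(gt, configs, weights = NULL) {
  n <- length(configs)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  set.seed(gt$seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    comp <- dimer_energy_components(gt$truth_ff, configs[[i]])
    if (gt$component_split == "n6_dispx") {
      dispx <- comp$disp6; indx <- comp$disp8
    } else {
      dispx <- comp$disp8; indx <- comp$disp6
    }
    e <- c(elst = comp$elst, exch = comp$exch, indx = indx, dispx = dispx)
    if (gt$noise_sigma > 0)
      e <- e + stats::rnorm(4, sd = gt$noise_sigma)
    rows[[i]] <- c(R = dimer_R(configs[[i]]), e, total = sum(e),
                   weight = weights[i])
  }
  energies <- as.data.frame(do.call(rbind, rows))
  structure(list(configs = configs, energies = energies),
            class = "cspff_dataset")
}

#' @export
print.cspff_dataset <- function(x, ...) {
  cat(sprintf("<dimer reference dataset: %d configurations, R in [%.2f, %.2f] Angstrom>\n",
              nrow(x$energies), min(x$energies$R), max(x$energies$R)))
  invisible(x)
}

#' Merge reference datasets (deduplicating near-identical geometries)
#'
#' Two dimer configurations are considered duplicates when their sorted
#' intermolecular distance vectors agree within `tol` RMS.
#'
#' @param a,b `cspff_dataset` objects over the same monomers.
#' @param tol RMS tolerance (Angstrom).
#' @export
merge_datasets <- function(a, b, tol = 0.05) {
  siga <- lapply(a$configs, dimer_signature_cfg)
  keep <- logical(length(b$configs))
  for (i in seq_along(b$configs)) {
    sb <- dimer_signature_cfg(b$configs[[i]])
    dup <- any(vapply(siga, function(sa)
      length(sa) == length(sb) && sqrt(mean((sa - sb)^2)) < tol, TRUE))
    keep[i] <- !dup
    if (!dup) siga[[length(siga) + 1]] <- sb
  }
  structure(list(configs = c(a$configs, b$configs[keep]),
                 energies = rbind(a$energies, b$energies[keep, , drop = FALSE])),
            class = "cspff_dataset")
}

#' Noise-free radial scan of the oracle components
#'
#' @param gt a [ground_truth()] oracle.
#' @param mA,mB monomers.
#' @param quat orientation of B (fixed along the scan).
#' @param direction unit vector along which B's centre of mass moves.
#' @param R_list ascending centre-of-mass separations (Angstrom).
#' @return data frame with one row per R (`elst`, `exch`, `indx`,
#'   `dispx`, `total`, `min_contact`, `flagged`); rows whose contact falls
#'   below 0.1 Angstrom are flagged with `NA` energies rather than
#'   evaluated.
#' @export
radial_scan <- function(gt, mA, mB, quat = c(1, 0, 0, 0),
                        direction = c(0, 0, 1), R_list = seq(2, 12, 0.25)) {
  stopifnot(!is.unsorted(R_list))
  direction <- direction / sqrt(sum(direction^2))
  rows <- lapply(R_list, function(R) {
    d <- dimer_config(mA, mB, quat = quat, trans = direction * R, check = FALSE)
    mc <- min_dimer_distance(d)
    if (mc <= 0.1)
      return(data.frame(R = R, elst = NA, exch = NA, indx = NA, dispx = NA,
                        total = NA, min_contact = mc, flagged = TRUE))
    comp <- dimer_energy_components(gt$truth_ff, d)
    dispx <- if (gt$component_split == "n6_dispx") comp$disp6 else comp$disp8
    indx <- if (gt$component_split == "n6_dispx") comp$disp8 else comp$disp6
    data.frame(R = R, elst = comp$elst, exch = comp$exch, indx = indx,
               dispx = dispx, total = comp$total, min_contact = mc,
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a reference dataset as a delimited table
#'
#' One row per configuration: id, the quaternion and translation placing
#' monomer B, R, the four components, total and weight.  Monomer
#' geometries are not embedded; the reader takes them as arguments, which
#' keeps the format usable for external (real ab initio) datasets.
#'
#' @param ds a `cspff_dataset`.
#' @param path output TSV path.
#' @export
write_dataset <- function(ds, path) {
  pose <- t(vapply(ds$configs, function(d) c(d$quat, d$trans), numeric(7)))
  colnames(pose) <- c("qw", "qx", "qy", "qz", "tx", "ty", "tz")
  df <- cbind(id = seq_along(ds$configs), as.data.frame(pose), ds$energies)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference dataset written by [write_dataset()]
#' @param path TSV path.
#' @param mA,mB the monomers the configurations refer to.
#' @export
read_dataset <- function(path, mA, mB) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  configs <- lapply(seq_len(nrow(df)), function(i)
    dimer_config(mA, mB, quat = as.numeric(df[i, c("qw", "qx", "qy", "qz")]),
                 trans = as.numeric(df[i, c("tx", "ty", "tz")]), check = FALSE))
  structure(list(configs = configs,
                 energies = df[, c("R", "elst", "exch", "indx", "dispx",
                                   "total", "weight")]),
            class = "cspff_dataset")
}
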