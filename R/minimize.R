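## Rigid-body + cell lattice-energy minimization on a symmetry-reduced
## parameter vector: only the crystal system's free cell parameters and
## the asymmetric-unit poses (fractional COM + quaternion, renormalized
## every evaluation) vary, so the space group is preserved exactly.

## Pack/unpack the reduced parameter vector.
pack_params <- function(s, dof = c("cell", "pos", "rot")) {
  free <- free_cell_params(s$sg$system)
  th <- c(); names_th <- c()
  if ("cell" %in% dof) {
    th <- unlist(s$lattice[free]); names_th <- free
  }
  for (i in seq_along(s$asu)) {
    e <- s$asu[[i]]
    if ("pos" %in% dof) {
      th <- c(th, e$frac); names_th <- c(names_th, paste0("f", i, c("x", "y", "z")))
    }
    if ("rot" %in% dof) {
      th <- c(th, e$quat); names_th <- c(names_th, paste0("q", i, 1:4))
    }
  }
  stats::setNames(th, names_th)
}

unpack_params <- function(th, s, dof = c("cell", "pos", "rot")) {
  free <- free_cell_params(s$sg$system)
  k <- 0
  l <- s$lattice
  if ("cell" %in% dof) {
    for (f in free) { k <- k + 1; l[[f]] <- th[[k]] }
  }
  l2 <- lattice(l$a, l$b, l$c, l$alpha, l$beta, l$gamma)
  asu <- s$asu
  for (i in seq_along(asu)) {
    if ("pos" %in% dof) { asu[[i]]$frac <- th[k + 1:3]; k <- k + 3 }
    if ("rot" %in% dof) {
      q <- th[k + 1:4]; k <- k + 4
      asu[[i]]$quat <- q / sqrt(sum(q^2))
    }
  }
  crystal(l2, s$sg, asu)
}

param_bounds <- function(s, dof) {
  free <- free_cell_params(s$sg$system)
  lo <- c(); hi <- c()
  if ("cell" %in% dof) {
    for (f in free) {
      if (f %in% c("a", "b", "c")) { lo <- c(lo, 2.2); hi <- c(hi, 40) }
      else { lo <- c(lo, 45); hi <- c(hi, 135) }
    }
  }
  for (i in seq_along(s$asu)) {
    if ("pos" %in% dof) { lo <- c(lo, rep(-2, 3)); hi <- c(hi, rep(3, 3)) }
    if ("rot" %in% dof) { lo <- c(lo, rep(-1.5, 4)); hi <- c(hi, rep(1.5, 4)) }
  }
  list(lower = lo, upper = hi)
}

#' Minimize the lattice energy of a crystal
#'
#' Bounded quasi-Newton (L-BFGS-B, numerical gradients) over the
#' symmetry-reduced degrees of freedom.  Collapse monitoring: every
#' evaluated state with an intermolecular contact below `contact_floor`
#' or a per-molecule energy below `energy_floor` is unsafe; if the
#' optimizer ends in an unsafe state the result carries `collapse_flag`
#' and returns the best safe state seen instead.
#'
#' @param ff a [forcefield()].
#' @param s a [crystal()].
#' @param dof degrees of freedom: any of `"cell"`, `"pos"`, `"rot"`.
#' @param maxit iteration cap.
#' @param gtol projected-gradient tolerance (kJ/mol per unit step of each
#'   reduced coordinate); `pgtol` of L-BFGS-B.
#' @param cutoff real-space cutoff (Angstrom).
#' @param contact_floor,energy_floor collapse thresholds (Angstrom,
#'   kJ/mol per molecule).
#' @return list (class `cspff_minresult`): `structure`, `energy`,
#'   `converged`, `n_iterations`, `collapse_flag`, `initial_energy`,
#'   `final_energy`.
#' @export
minimize_structure <- function(ff, s, dof = c("cell", "pos", "rot"),
                               maxit = 200, gtol = 1e-3, cutoff = 15,
                               factr = 1e6, contact_floor = 0.7,
                               energy_floor = -500) {
  th0 <- pack_params(s, dof)
  bounds <- param_bounds(s, dof)
  best_safe <- NULL
  evaluator <- make_lattice_evaluator(ff, s, cutoff = cutoff,
                                      contact_floor = contact_floor)
  free <- free_cell_params(s$sg$system)
  th_to_state <- function(th) {
    k <- 0
    l <- s$lattice
    if ("cell" %in% dof) for (f in free) { k <- k + 1; l[[f]] <- th[[k]] }
    poses <- lapply(s$asu, function(e) {
      p <- list(frac = e$frac, quat = e$quat)
      if ("pos" %in% dof) { p$frac <- th[k + 1:3]; k <<- k + 3 }
      if ("rot" %in% dof) {
        q <- th[k + 1:4]; k <<- k + 4
        p$quat <- q / sqrt(sum(q^2))
      }
      p
    })
    list(l = l, poses = poses)
  }
  eval_state <- function(th) {
    st <- th_to_state(th)
    det <- tryCatch(evaluator(st$l, st$poses), error = function(e) NULL)
    if (is.null(det) || !is.finite(det$energy))
      return(list(value = 1e8, safe = FALSE, st = st))
    safe <- det$min_contact >= contact_floor && det$energy >= energy_floor
    list(value = det$energy, safe = safe, det = det, st = st)
  }
  obj <- function(th) {
    st <- eval_state(th)
    if (st$safe && (is.null(best_safe) || st$value < best_safe$value)) {
      best_safe <<- list(value = st$value, th = th)
    }
    st$value
  }
  init <- eval_state(th0)
  if (is.null(init$det))
    stop("initial structure not evaluable (overlapping atoms or bad cell)")
  parscale <- rep(1, length(th0))
  parscale[grepl("^f", names(th0))] <- 0.2
  parscale[grepl("^q", names(th0))] <- 0.2
  opt <- stats::optim(th0, obj, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = list(maxit = maxit, pgtol = gtol,
                                     factr = factr, parscale = parscale,
                                     ndeps = rep(1e-5, length(th0))))
  fin <- eval_state(opt$par)
  collapse <- !fin$safe
  if (collapse && !is.null(best_safe)) {
    fin <- eval_state(best_safe$th)
  }
  fin_s <- tryCatch({
    asu <- s$asu
    for (i in seq_along(asu)) {
      asu[[i]]$frac <- fin$st$poses[[i]]$frac %% 1
      asu[[i]]$quat <- fin$st$poses[[i]]$quat
    }
    crystal(fin$st$l, s$sg, asu)
  }, error = function(e) NULL)
  structure(list(
    structure = fin_s, energy = fin$value,
    converged = opt$convergence == 0 && !collapse,
    n_iterations = opt$counts[["function"]],
    collapse_flag = collapse,
    initial_energy = init$value, final_energy = fin$value
  ), class = "cspff_minresult")
}

#' @export
print.cspff_minresult <- function(x, ...) {
  cat(sprintf(
    "<minimization: E %.4f -> %.4f kJ/mol, %s%s, %d evaluations>\n",
    x$initial_energy, x$final_energy,
    if (x$converged) "converged" else "not converged",
    if (x$collapse_flag) " [COLLAPSED]" else "", x$n_iterations))
  invisible(x)
}

#' Staged minimization: rough 12-6-1 first, then the target form
#'
#' Minimizing first with a hole-free 12-6-1 potential and only then with
#' the extended form keeps the second stage inside the physical basin,
#' avoiding the short-range artefact minima ("holes") that fitted
#' exponential-repulsion potentials can have.
#'
#' @param rough_ff 12-6-1 [forcefield()] (hole-free by construction).
#' @param target_ff the force field to minimize with finally.
#' @param s starting [crystal()].
#' @param rough_args argument overrides for the rough stage (looser
#'   tolerances by default).
#' @param ... passed to [minimize_structure()] (both stages).
#' @return the final-stage `cspff_minresult` with the extra fields
#'   `rough_result` and `hole_collapse` (collapse occurred in the target
#'   stage).
#' @export
staged_minimize <- function(rough_ff, target_ff, s,
                            rough_args = list(gtol = 0.05, factr = 1e8,
                                              maxit = 60, cutoff = 9),
                            ...) {
  args1 <- utils::modifyList(list(...), rough_args)
  r1 <- do.call(minimize_structure, c(list(rough_ff, s), args1))
  start2 <- if (is.null(r1$structure)) s else r1$structure
  if (identical(rough_ff, target_ff)) {
    r1$rough_result <- NULL
    r1$hole_collapse <- r1$collapse_flag
    return(r1)
  }
  r2 <- minimize_structure(target_ff, start2, ...)
  r2$rough_result <- r1
  r2$hole_collapse <- r2$collapse_flag
  r2
}

#' Minimize every candidate of a set (staged)
#'
#' Structures are processed independently in input order; individual
#' failures are recorded (`ok = FALSE`) without aborting the batch.
#'
#' @param rough_ff,target_ff as in [staged_minimize()].
#' @param cands candidate set.
#' @param ... passed to [minimize_structure()].
#' @param progress print a one-line progress marker every 50 structures.
#' @return list with `results` (per candidate) and an index `table`
#'   (id, initial/final energy, density, converged, collapsed, ok).
#' @export
minimize_set <- function(rough_ff, target_ff, cands, ..., progress = FALSE) {
  n <- length(cands$structures)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    results[[i]] <- tryCatch(
      staged_minimize(rough_ff, target_ff, cands$structures[[i]], ...),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "cspff_minfail"))
    if (progress && i %% 50 == 0) message("  minimized ", i, "/", n)
  }
  ok <- !vapply(results, inherits, TRUE, "cspff_minfail")
  tab <- data.frame(
    id = cands$meta$id,
    group = cands$meta$group,
    ok = ok,
    E_initial = ifelse(ok, vapply(results, function(r)
      if (inherits(r, "cspff_minfail")) NA_real_ else r$initial_energy, 0), NA),
    E_final = ifelse(ok, vapply(results, function(r)
      if (inherits(r, "cspff_minfail")) NA_real_ else r$final_energy, 0), NA),
    density = ifelse(ok, vapply(results, function(r)
      if (inherits(r, "cspff_minfail") || is.null(r$structure)) NA_real_
      else density(r$structure), 0), NA),
    converged = vapply(results, function(r)
      !inherits(r, "cspff_minfail") && isTRUE(r$converged), TRUE),
    collapsed = vapply(results, function(r)
      inherits(r, "cspff_minfail") || isTRUE(r$collapse_flag), TRUE)
  )
  list(results = results, table = tab)
}
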