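## Candidate crystal packing generation.
##
## Two generators: a deterministic orientation-grid search (coordination
## geometries x Euler-angle grid, cell contracted against a pure 1/r^12
## contact repulsion until a threshold energy is reached) and a two-step
## random generator (unrestricted cells to estimate dimensions, then
## restricted sampling with a rough 12-6-1 pre-optimization), both with
## the hard pair-energy rejection rule.

#' Generation configuration
#'
#' @param mode `"grid"` or `"random"`.
#' @param space_groups space-group symbols to search.
#' @param angle_step Euler-angle grid step in degrees (must divide 180);
#'   the grid is inclusive, so 10 degrees gives 19 values per angle.
#' @param n_geometries number of coordination geometries used by the grid
#'   generator (at most the size of the built-in library, 51).
#' @param per_geometry_keep densest candidates kept per geometry.
#' @param per_group_quota_step1 accepted structures per group in the
#'   unrestricted cell-estimation step.
#' @param per_group_quota_step2 accepted structures per group in the
#'   restricted generation step.
#' @param pair_energy_reject reject a structure if any intermolecular
#'   atom-atom 12-6-1 energy exceeds this (kJ/mol).
#' @param contraction_threshold contact-repulsion energy (arbitrary
#'   units, unit `1/r^12` prefactor) at which the grid generator stops
#'   contracting a cell direction.
#' @param seed integer seed for the random mode.
#' @export
generation_config <- function(mode = c("random", "grid"),
                              space_groups = spacegroup_names("random"),
                              angle_step = 10, n_geometries = 51,
                              per_geometry_keep = 500,
                              per_group_quota_step1 = 500,
                              per_group_quota_step2 = 5000,
                              pair_energy_reject = 2000,
                              contraction_threshold = 10,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(180 %% angle_step == 0, n_geometries >= 1,
            per_geometry_keep >= 1, per_group_quota_step1 >= 1,
            per_group_quota_step2 >= 1, pair_energy_reject > 0)
  list(mode = mode, space_groups = space_groups, angle_step = angle_step,
       n_geometries = n_geometries, per_geometry_keep = per_geometry_keep,
       per_group_quota_step1 = per_group_quota_step1,
       per_group_quota_step2 = per_group_quota_step2,
       pair_energy_reject = pair_energy_reject,
       contraction_threshold = contraction_threshold, seed = as.integer(seed))
}

#' Library of coordination geometries for the grid generator
#'
#' Each geometry pairs one of the 26 grid-search space groups with a cell
#' contraction scheme (the order in which the cell directions are pulled
#' in against the contact repulsion).  Two schemes per group, minus the
#' one duplicate for P1 (whose single molecule makes the orders
#' equivalent), give the default library of 51.
#'
#' @param n number of geometries (<= 51).
#' @return data frame with `geometry`, `group`, `scheme`.
#' @export
coordination_geometries <- function(n = 51) {
  groups <- spacegroup_names("grid")
  lib <- expand.grid(group = groups, scheme = c("abc", "cba"),
                     stringsAsFactors = FALSE)
  lib <- lib[order(lib$group, lib$scheme), ]
  lib <- lib[!(lib$group == "P1" & lib$scheme == "cba"), ]
  stopifnot(nrow(lib) == 51)
  if (n > nrow(lib)) stop("at most ", nrow(lib), " geometries available")
  data.frame(geometry = seq_len(n), group = lib$group[seq_len(n)],
             scheme = lib$scheme[seq_len(n)], row.names = NULL)
}

#' Enumerate the orientation-grid search plan
#'
#' The full combinatorial plan of the grid generator: every coordination
#' geometry crossed with the inclusive Euler-angle grid.  At the default
#' 10-degree step and 51 geometries this enumerates
#' 19^3 x 51 = 349,809 hypothetical candidates.
#'
#' @param cfg a [generation_config()].
#' @return data frame with `geometry`, `group`, `scheme`, `a1`, `a2`,
#'   `a3` (Euler angles, degrees).
#' @export
grid_plan <- function(cfg = generation_config(mode = "grid")) {
  geo <- coordination_geometries(cfg$n_geometries)
  angles <- seq(0, 180, by = cfg$angle_step)
  plan <- expand.grid(a3 = angles, a2 = angles, a1 = angles,
                      geometry = geo$geometry)
  plan <- plan[, c("geometry", "a1", "a2", "a3")]
  plan$group <- geo$group[plan$geometry]
  plan$scheme <- geo$scheme[plan$geometry]
  rownames(plan) <- NULL
  plan[, c("geometry", "group", "scheme", "a1", "a2", "a3")]
}

## Pure contact-repulsion force field (unit 1/r^12 between all atoms).
contact_ff <- function(types) {
  ut <- sort(unique(types))
  pairs <- list()
  for (i in seq_along(ut)) for (j in i:length(ut))
    pairs[[pair_key(ut[i], ut[j])]] <- pair_params(A12 = 1)
  forcefield("lj1261", pairs)
}

strip_charges <- function(m) { m$charges[] <- 0; m }

## Contract selected cell directions until the contact-repulsion energy
## first reaches `threshold`; returns the crystal or NULL if the
## contraction cannot bracket the threshold.
contract_cell <- function(mon, group, quat, scheme, threshold,
                          frac = c(0.13, 0.21, 0.34), cutoff = 9) {
  sg <- spacegroup(group)
  cff <- contact_ff(mon$types)
  mon0 <- strip_charges(mon)
  span <- max(sqrt(rowSums(mon$xyz^2)))
  L0 <- 2 * span + 8
  lens <- c(L0, L0, L0)
  beta0 <- if (sg$system == "monoclinic") 105 else 90
  make <- function(lens) {
    crystal(lattice(lens[1], lens[2], lens[3], beta = beta0),
            sg, list(list(monomer = mon0, frac = frac, quat = quat)))
  }
  erep <- function(lens) {
    s <- make(lens)
    lattice_energy_detail(cff, s, cutoff = cutoff)$energy * s$Z
  }
  order_idx <- match(strsplit(scheme, "")[[1]], c("a", "b", "c"))
  for (ax in order_idx) {
    lo <- 1.2; hi <- lens[ax]           # direction length bounds
    f_hi <- erep(lens)
    if (f_hi >= threshold) next         # already at/over threshold
    scan <- lens
    ok <- FALSE
    while (hi > lo * 1.01) {
      mid <- (hi + lo) / 2
      scan[ax] <- mid
      e <- tryCatch(erep(scan), error = function(e) Inf)
      if (e >= threshold) lo <- mid else hi <- mid
      ok <- TRUE
    }
    if (!ok) return(NULL)
    lens[ax] <- hi                       # just above the threshold crossing
  }
  s <- make(lens)
  e <- tryCatch(erep(lens), error = function(e) NA_real_)
  if (is.na(e) || !is.finite(e)) return(NULL)
  attr(s, "rough_energy") <- e
  s
}

#' Deterministic orientation-grid candidate generation
#'
#' For each coordination geometry and each Euler-angle triple of the
#' inclusive grid, a cell is built by contracting the geometry's cell
#' directions until the summed `1/r^12` contact energy reaches the
#' configured threshold.
#'
#' @param mon a [monomer()].
#' @param cfg a [generation_config()] in grid mode.
#' @param plan optionally a subset of [grid_plan()] rows to materialize
#'   (the full default plan enumerates 349,809 candidates; reduced
#'   searches pass a coarser config or an explicit subset).
#' @return a candidate set: list with `structures` and `meta` (data frame
#'   of provenance, rough energies and densities).
#' @export
grid_generate <- function(mon, cfg = generation_config(mode = "grid"),
                          plan = NULL) {
  if (is.null(plan)) plan <- grid_plan(cfg)
  structures <- vector("list", nrow(plan))
  keep <- logical(nrow(plan))
  rough <- dens <- rep(NA_real_, nrow(plan))
  for (i in seq_len(nrow(plan))) {
    q <- euler_to_quat(plan$a1[i], plan$a2[i], plan$a3[i])
    s <- tryCatch(
      contract_cell(mon, plan$group[i], q, plan$scheme[i],
                    cfg$contraction_threshold),
      error = function(e) NULL)
    if (is.null(s)) next
    mc <- tryCatch(min_contact(s), error = function(e) 0)
    if (mc <= 0.3) next
    structures[[i]] <- s
    keep[i] <- TRUE
    rough[i] <- attr(s, "rough_energy")
    dens[i] <- density(s)
  }
  meta <- cbind(id = seq_len(nrow(plan)), plan,
                rough_energy = rough, density = dens)[keep, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(structures = structures[keep], meta = meta),
            class = "cspff_candidates")
}

#' @export
print.cspff_candidates <- function(x, ...) {
  cat(sprintf("<candidate set: %d structures, %d group(s)>\n",
              length(x$structures),
              length(unique(x$meta$group))))
  invisible(x)
}

#' Keep the densest candidates per coordination geometry
#'
#' @param cands candidate set from [grid_generate()].
#' @param per_geometry_keep quota per geometry; geometries with fewer
#'   candidates keep all of them.
#' @return reduced candidate set; ties in density break by rough energy,
#'   then id.
#' @export
select_densest <- function(cands, per_geometry_keep = 500) {
  meta <- cands$meta
  keep_idx <- integer(0)
  for (g in unique(meta$geometry)) {
    rows <- which(meta$geometry == g)
    o <- rows[order(-meta$density[rows], meta$rough_energy[rows],
                    meta$id[rows])]
    keep_idx <- c(keep_idx, o[seq_len(min(per_geometry_keep, length(o)))])
  }
  keep_idx <- sort(keep_idx)
  structure(list(structures = cands$structures[keep_idx],
                 meta = {m <- meta[keep_idx, , drop = FALSE]; rownames(m) <- NULL; m}),
            class = "cspff_candidates")
}

## Draw one random crystal in `group`; NULL when construction fails.
random_crystal <- function(mon, sg, len_range = NULL, est = NULL) {
  span <- max(sqrt(rowSums(mon$xyz^2))) + 1.7
  Vmol <- 4 / 3 * pi * span^3 * 0.55      # effective molecular volume
  Z <- sg$order
  if (is.null(est)) {
    phi <- stats::runif(1, 0.35, 0.8)
    Vt <- Z * Vmol / phi
    r <- stats::runif(3, 0.6, 1.7)
    lens <- r / prod(r)^(1 / 3) * Vt^(1 / 3)
  } else {
    lens <- vapply(1:3, function(i)
      stats::runif(1, est$len_lo[i] * 0.8, est$len_hi[i] * 1.2), 0)
  }
  ang <- c(90, 90, 90)
  if (sg$system == "monoclinic") ang[2] <- stats::runif(1, 90, 130)
  if (sg$system == "triclinic") ang <- stats::runif(3, 70, 110)
  l <- tryCatch(lattice(lens[1], lens[2], lens[3], ang[1], ang[2], ang[3]),
                error = function(e) NULL)
  if (is.null(l)) return(NULL)
  q <- as.vector(random_quaternions(1))
  f <- stats::runif(3)
  tryCatch(crystal(l, sg, list(list(monomer = mon, frac = f, quat = q))),
           error = function(e) NULL)
}

#' Random generation, step 1: unrestricted sampling to estimate cells
#'
#' Accepts `quota` random structures in the group (rejecting any whose
#' worst intermolecular atom-atom 12-6-1 energy exceeds the threshold)
#' and summarizes the accepted cell dimensions as robust 5th-95th
#' percentile ranges.
#'
#' @param mon a [monomer()] (carrying charges for the rough Coulomb term).
#' @param group space-group symbol.
#' @param ff_rough a 12-6-1 [forcefield()] used for the rejection test.
#' @param cfg a [generation_config()].
#' @return list with `len_lo`, `len_hi` (Angstrom, per axis), the
#'   acceptance `rate`, and `n_accepted`.
#' @export
random_generate_step1 <- function(mon, group, ff_rough,
                                  cfg = generation_config()) {
  sg <- spacegroup(group)
  set.seed(cfg$seed + 1000L * match(group, cfg$space_groups, nomatch = 0L))
  quota <- cfg$per_group_quota_step1
  acc <- matrix(NA_real_, quota, 3)
  n_acc <- 0L; attempts <- 0L
  max_attempts <- max(5000L, as.integer(quota / 1e-4))
  while (n_acc < quota) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("step-1 acceptance rate below 1e-4 in %s (%d/%d accepted)",
                   group, n_acc, attempts))
    s <- random_crystal(mon, sg)
    if (is.null(s)) next
    det <- tryCatch(lattice_energy_detail(ff_rough, s, cutoff = 10),
                    error = function(e) NULL)
    if (is.null(det) || !is.finite(det$max_pair_energy) ||
        det$max_pair_energy > cfg$pair_energy_reject) next
    n_acc <- n_acc + 1L
    acc[n_acc, ] <- c(s$lattice$a, s$lattice$b, s$lattice$c)
  }
  list(len_lo = apply(acc, 2, stats::quantile, 0.05),
       len_hi = apply(acc, 2, stats::quantile, 0.95),
       rate = n_acc / attempts, n_accepted = n_acc)
}

#' Random generation, step 2: restricted sampling plus rough optimization
#'
#' Cells are drawn within the step-1 percentile ranges (plus/minus 20%),
#' the pair-energy rejection applied, and each accepted structure given a
#' short loose-tolerance lattice-energy minimization with the rough
#' 12-6-1 force field.
#'
#' @inheritParams random_generate_step1
#' @param est cell estimate from [random_generate_step1()].
#' @param quota accepted structures wanted (defaults to the config's
#'   step-2 quota).
#' @return candidate set (structures plus provenance/energy/density
#'   meta table).
#' @export
random_generate_step2 <- function(mon, group, ff_rough, est,
                                  cfg = generation_config(), quota = NULL) {
  sg <- spacegroup(group)
  if (is.null(quota)) quota <- cfg$per_group_quota_step2
  set.seed(cfg$seed + 2000L * match(group, cfg$space_groups, nomatch = 0L) + 1L)
  structures <- vector("list", quota)
  meta <- data.frame(id = seq_len(quota), group = group,
                     seed = cfg$seed, rough_energy = NA_real_,
                     density = NA_real_)
  n_acc <- 0L; attempts <- 0L
  max_attempts <- max(5000L, as.integer(quota / 1e-4))
  while (n_acc < quota) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("step-2 acceptance rate below 1e-4 in %s (%d/%d accepted)",
                   group, n_acc, attempts))
    s <- random_crystal(mon, sg, est = est)
    if (is.null(s)) next
    det <- tryCatch(lattice_energy_detail(ff_rough, s, cutoff = 10),
                    error = function(e) NULL)
    if (is.null(det) || !is.finite(det$max_pair_energy) ||
        det$max_pair_energy > cfg$pair_energy_reject) next
    res <- tryCatch(
      minimize_structure(ff_rough, s, maxit = 25, gtol = 1,
                         cutoff = 10),
      error = function(e) NULL)
    if (is.null(res) || res$collapse_flag) next
    n_acc <- n_acc + 1L
    structures[[n_acc]] <- res$structure
    meta$rough_energy[n_acc] <- res$energy
    meta$density[n_acc] <- density(res$structure)
  }
  structure(list(structures = structures[seq_len(n_acc)],
                 meta = meta[seq_len(n_acc), , drop = FALSE]),
            class = "cspff_candidates")
}

#' Two-step random generation across a set of space groups
#'
#' @inheritParams random_generate_step1
#' @param quota2 per-group step-2 quota override.
#' @return combined candidate set.
#' @export
random_generate <- function(mon, ff_rough, cfg = generation_config(),
                            quota2 = NULL) {
  sets <- lapply(cfg$space_groups, function(g) {
    est <- random_generate_step1(mon, g, ff_rough, cfg)
    random_generate_step2(mon, g, ff_rough, est, cfg, quota = quota2)
  })
  structures <- do.call(c, lapply(sets, `[[`, "structures"))
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  meta$id <- seq_len(nrow(meta))
  structure(list(structures = structures, meta = meta),
            class = "cspff_candidates")
}
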