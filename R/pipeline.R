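## End-to-end orchestration: reference data (oracle or external table)
## -> force-field fit -> candidate generation -> staged minimization ->
## clustering/ranking -> landscape, with on-disk outputs and a
## reproducibility manifest.

#' Run configuration
#'
#' Declarative settings for a full prediction run.  Any field can be
#' overridden; the defaults describe a reduced desk-scale search.
#'
#' @param monomer a [monomer()], fixture name, or path to an XYZ file.
#' @param truth_ff a [forcefield()] or path for the synthetic oracle's
#'   hidden potential; ignored when `dataset_path` is given.
#' @param dataset_path optional path to an external reference dataset
#'   (table written by [write_dataset()]); replaces the oracle.
#' @param form functional form to fit (`"extended"`, `"exp61"`,
#'   `"lj1261"`).
#' @param n_configs oracle dataset size.
#' @param noise_sigma oracle component noise (kJ/mol).
#' @param space_groups groups searched.
#' @param quota2 accepted candidates per group (step 2).
#' @param quota1 cell-estimation sample per group (step 1).
#' @param fine_top after clustering the rough-optimized candidates, how
#'   many lowest-energy representatives receive the tight staged
#'   minimization.
#' @param cutoff real-space cutoff (Angstrom) for minimizations.
#' @param maxit_rough,maxit_fine iteration caps of the two minimization
#'   stages.
#' @param top_k polymorphs reported / refined.
#' @param reference optional reference [crystal()] or CIF path scored
#'   against the ranking.
#' @param altcsp run the refinement loop after ranking.
#' @param out_dir output directory (`NULL` for no files).
#' @param seed master seed; every stochastic stage derives from it.
#' @export
run_config <- function(monomer = "diatomic", truth_ff = NULL,
                       dataset_path = NULL, form = "extended",
                       n_configs = 700, noise_sigma = 0,
                       space_groups = c("P1", "P-1", "P21", "P21/c"),
                       quota2 = 50, quota1 = 60, fine_top = 40, cutoff = 12,
                       maxit_rough = 80, maxit_fine = 120, top_k = 20,
                       reference = NULL, altcsp = FALSE, out_dir = NULL,
                       seed = 1L) {
  as.list(environment())
}

#' Read a run configuration from a YAML file
#' @param path YAML file with fields of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y[intersect(names(y), names(formals(run_config)))]
  cfg <- do.call(run_config, y)
  cfg
}

resolve_monomer <- function(m) {
  if (inherits(m, "cspff_monomer")) return(m)
  if (is.character(m) && file.exists(m)) return(read_xyz(m))
  if (is.character(m)) return(fixture_monomers(m))
  stop("cannot interpret 'monomer' configuration entry")
}

resolve_ff <- function(f, mon) {
  if (is.null(f)) return(fixture_truth_ff(mon$name))
  if (inherits(f, "cspff_forcefield")) return(f)
  if (is.character(f) && file.exists(f)) return(read_forcefield(f))
  stop("cannot interpret force-field configuration entry")
}

#' Run the full crystal structure prediction pipeline
#'
#' Stages: reference data (synthetic oracle or external table) ->
#' component-wise force-field fit (plus a rough 12-6-1 fit to the same
#' data for the staged minimizations) -> two-step random candidate
#' generation -> staged lattice-energy minimization of every candidate
#' -> duplicate clustering -> energy ranking -> landscape table, with
#' optional overlap scoring against a reference crystal and optional
#' iterative refinement.
#'
#' @param cfg a [run_config()].
#' @param progress emit per-stage messages.
#' @return list (class `cspff_run`): `fit`, `fit_rough`, `candidates`,
#'   `minimized`, `pset`, `landscape`, `overlap` (if a reference was
#'   given), `altcsp` (if enabled), `dataset`, `manifest`.
#' @export
run_csp <- function(cfg = run_config(), progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  t_all <- Sys.time()
  mon <- resolve_monomer(cfg$monomer)
  stage_times <- c()
  tick <- function(name, t0) {
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  ## Stage: reference data
  t0 <- Sys.time()
  if (!is.null(cfg$dataset_path)) {
    ds <- read_dataset(cfg$dataset_path, mon, mon)
    gt <- NULL
  } else {
    truth <- resolve_ff(cfg$truth_ff, mon)
    gt <- ground_truth(truth, noise_sigma = cfg$noise_sigma,
                       seed = cfg$seed + 17L)
    confs <- sample_dimer_configurations(mon, mon, cfg$n_configs,
                                         seed = cfg$seed + 1L)
    ds <- evaluate_reference(gt, confs)
  }
  tick("reference_data", t0)
  say("reference data: %d configurations", nrow(ds$energies))

  ## Stage: fits
  t0 <- Sys.time()
  fit <- fit_forcefield(ds, form = cfg$form,
                        config = fit_config(seed = cfg$seed + 2L),
                        hole_check = TRUE)
  fit_rough <- fit_forcefield(ds, form = "lj1261",
                              config = fit_config(seed = cfg$seed + 3L))
  mon_q <- apply_charges(mon, fit$charges)
  tick("fit", t0)
  say("fit (%s): RMSE over negative energies %.4f kJ/mol",
      cfg$form, fit$report$rmse_negative)

  ## Stage: generation
  t0 <- Sys.time()
  gcfg <- generation_config(mode = "random", space_groups = cfg$space_groups,
                            per_group_quota_step1 = cfg$quota1,
                            per_group_quota_step2 = cfg$quota2,
                            seed = cfg$seed + 4L)
  cands <- random_generate(mon_q, fit_rough$forcefield, gcfg)
  tick("generation", t0)
  say("generation: %d candidates in %d group(s)",
      length(cands$structures), length(cfg$space_groups))

  ## Stage: reduce the pool on the rough energies (the generation step
  ## already pre-optimized every candidate with the 12-6-1 field), then
  ## tight staged minimization of the reduced set
  t0 <- Sys.time()
  rough_set <- polymorph_set(cands$structures, cands$meta$rough_energy,
                             meta = cands$meta)
  rough_set <- rank_polymorphs(cluster_structures(rough_set))
  keep_ids <- utils::head(rough_set$representatives, cfg$fine_top)
  keep_idx <- match(keep_ids, rough_set$table$id)
  reduced <- structure(list(structures = rough_set$structures[keep_idx],
                            meta = cands$meta[keep_idx, , drop = FALSE]),
                       class = "cspff_candidates")
  say("reduction: %d candidates -> %d distinct -> %d for fine minimization",
      length(cands$structures), nrow(landscape_table(rough_set)),
      length(keep_idx))
  mins <- minimize_set(fit_rough$forcefield, fit$forcefield, reduced,
                       maxit = cfg$maxit_fine, cutoff = cfg$cutoff,
                       progress = progress)
  ok <- mins$table$ok & !mins$table$collapsed &
    is.finite(mins$table$E_final)
  structures <- lapply(mins$results[ok], `[[`, "structure")
  energies <- mins$table$E_final[ok]
  tick("minimization", t0)
  say("minimization: %d/%d structures survived",
      sum(ok), length(keep_idx))

  ## Stage: clustering + ranking
  t0 <- Sys.time()
  pset <- polymorph_set(structures, energies,
                        meta = mins$table[ok, , drop = FALSE])
  pset <- rank_polymorphs(cluster_structures(pset))
  land <- landscape_table(pset)
  tick("ranking", t0)
  say("ranking: %d distinct polymorphs, best E = %.4f kJ/mol",
      nrow(land), land$energy[1])

  ## Optional: overlap vs reference
  overlap <- NULL
  reference <- cfg$reference
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_cif(reference)
    overlap <- reference_rank(pset, reference, top_k = cfg$top_k)
  }

  ## Optional: refinement loop
  alt <- NULL
  if (isTRUE(cfg$altcsp) && !is.null(gt)) {
    t0 <- Sys.time()
    alt <- alt_csp_loop(fit, ds, gt, pset, fit_rough$forcefield,
                        top_k = cfg$top_k,
                        minimize_args = list(maxit = cfg$maxit_fine,
                                             cutoff = cfg$cutoff))
    pset <- alt$pset
    land <- landscape_table(pset)
    tick("refinement", t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cspff")),
    r_version = R.version.string,
    seed = cfg$seed,
    monomer = mon$name,
    form = cfg$form,
    space_groups = cfg$space_groups,
    quotas = c(step1 = cfg$quota1, step2 = cfg$quota2),
    n_configs = nrow(ds$energies),
    stage_seconds = as.list(stage_times),
    counts = list(generated = length(cands$structures),
                  minimized = sum(ok),
                  clusters = nrow(land))
  )
  out <- structure(list(fit = fit, fit_rough = fit_rough,
                        candidates = cands, minimized = mins, pset = pset,
                        landscape = land, overlap = overlap, altcsp = alt,
                        dataset = ds, manifest = manifest),
                   class = "cspff_run")
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir, top_k = cfg$top_k)
  say("total %.1f s", as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  out
}

#' @export
print.cspff_run <- function(x, ...) {
  cat(sprintf("<prediction run: %d candidates -> %d polymorphs>\n",
              x$manifest$counts$generated, x$manifest$counts$clusters))
  print(utils::head(x$landscape, 10))
  invisible(x)
}

## Rank and overlap of a reference structure within a ranked set.
reference_rank <- function(pset, reference, top_k = 20, threshold = 0.8) {
  idx <- match(utils::head(pset$representatives, top_k), pset$table$id)
  best <- NULL
  for (i in idx) {
    ov <- tryCatch(rmsd_n(pset$structures[[i]], reference,
                          threshold = threshold),
                   error = function(e) NULL)
    if (is.null(ov)) next
    if (is.null(best) || ov$rmsd < best$overlap$rmsd)
      best <- list(rank = pset$table$rank[i], overlap = ov, id = pset$table$id[i])
  }
  best
}

#' Write run outputs to a directory
#'
#' Top-ranked structures as CIFs, the landscape and minimization index
#' tables as CSV, the fitted force field in its table format, the fit
#' report and the manifest as JSON.
#'
#' @param run a `cspff_run`.
#' @param dir output directory (created if needed).
#' @param top_k how many ranked structures to write as CIFs.
#' @export
write_run <- function(run, dir, top_k = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$landscape, file.path(dir, "landscape.csv"),
                   row.names = FALSE)
  utils::write.csv(run$minimized$table, file.path(dir, "minimized_index.csv"),
                   row.names = FALSE)
  write_forcefield(run$fit$forcefield, file.path(dir, "forcefield.txt"))
  rep <- run$fit$report
  rep$hole_report <- NULL
  jsonlite::write_json(rep, file.path(dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cif_dir <- file.path(dir, "polymorphs")
  dir.create(cif_dir, showWarnings = FALSE)
  idx <- match(utils::head(run$pset$representatives, top_k),
               run$pset$table$id)
  for (k in seq_along(idx)) {
    write_cif(run$pset$structures[[idx[k]]],
              file.path(cif_dir, sprintf("rank%03d.cif", k)),
              data_name = sprintf("rank%03d", k))
  }
  invisible(dir)
}

#' Compare the extended and exp-6-1 forms on one system
#'
#' Runs the identical prediction twice -- same oracle data, same
#' generated candidates -- minimizing once with a fitted extended-form
#' field and once with a fitted exp-6-1 field, and reports each form's
#' negative-energy fit RMSE plus the rank at which the reference
#' structure is recovered.
#'
#' @param cfg a [run_config()] (its `form` is ignored); must carry a
#'   `reference` structure or CIF path.
#' @return data frame with one row per form: `form`, `rmse_negative`,
#'   `reference_rank`, `reference_rmsd`.
#' @export
compare_forms <- function(cfg = run_config()) {
  if (is.null(cfg$reference))
    stop("compare_forms needs a reference structure in the configuration")
  rows <- lapply(c("extended", "exp61"), function(fm) {
    cfg$form <- fm
    run <- run_csp(cfg, progress = FALSE)
    data.frame(form = fm,
               rmse_negative = run$fit$report$rmse_negative,
               reference_rank = if (is.null(run$overlap)) NA_integer_
                                else run$overlap$rank,
               reference_rmsd = if (is.null(run$overlap)) NA_real_
                                else run$overlap$overlap$rmsd)
  })
  do.call(rbind, rows)
}
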