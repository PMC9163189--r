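# Planted-truth prediction experiment shared by the acceptance checks:
# one candidate pool, minimized once under the hidden truth potential
# (defining the planted reference crystal) and once under the fitted
# potential.  Built lazily and cached for the session.

planted_experiment <- function() {
  shared_fixture("planted", function() {
    mon <- fixture_monomers("triatomic")
    truth <- fixture_truth_ff("triatomic")
    ds <- shared_dataset()
    fit <- shared_fit("extended")
    flj <- shared_fit("lj1261")
    monq <- cspff:::apply_charges(mon, fit$charges)
    gcfg <- generation_config(space_groups = c("P1", "P-1", "P21", "P21/c"),
                              per_group_quota_step1 = 40,
                              per_group_quota_step2 = 25, seed = 31)
    cands <- random_generate(monq, flj$forcefield, gcfg)
    rough <- rank_polymorphs(cluster_structures(
      polymorph_set(cands$structures, cands$meta$rough_energy)))
    keep <- match(utils::head(rough$representatives, 24), rough$table$id)
    reduced <- structure(list(structures = rough$structures[keep],
                              meta = cands$meta[keep, , drop = FALSE]),
                         class = "cspff_candidates")
    margs <- list(maxit = 80, cutoff = 10, factr = 1e7)
    rank_pass <- function(target_ff) {
      m <- do.call(minimize_set,
                   c(list(flj$forcefield, target_ff, reduced), margs))
      ok <- m$table$ok & !m$table$collapsed & is.finite(m$table$E_final)
      rank_polymorphs(cluster_structures(polymorph_set(
        lapply(m$results[ok], `[[`, "structure"), m$table$E_final[ok])))
    }
    psT <- rank_pass(truth)
    ref <- psT$structures[[match(psT$representatives[1], psT$table$id)]]
    psF <- rank_pass(fit$forcefield)
    list(mon = mon, truth = truth, ds = ds, fit = fit, flj = flj,
         reduced = reduced, margs = margs, psT = psT, ref = ref, psF = psF)
  })
}
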