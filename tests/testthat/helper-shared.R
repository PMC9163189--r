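# Lazily built shared fixtures, cached for the session so several test
# files can reuse the same oracle dataset and fits.

.shared <- new.env(parent = emptyenv())

shared_fixture <- function(name, builder) {
  if (is.null(.shared[[name]])) .shared[[name]] <- builder()
  .shared[[name]]
}

shared_dataset <- function() {
  shared_fixture("dataset", function() {
    mon <- fixture_monomers("triatomic")
    gt <- ground_truth(fixture_truth_ff("triatomic"), noise_sigma = 0, seed = 18L)
    cfgs <- sample_dimer_configurations(mon, mon, 700, seed = 18L)
    evaluate_reference(gt, cfgs)
  })
}

shared_fit <- function(form = "extended") {
  shared_fixture(paste0("fit_", form), function()
    fit_forcefield(shared_dataset(), form = form))
}
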