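# Component-wise force-field fitting: long-range coefficients, dampings,
# repulsion, baseline forms, RMSE metric, hole detection.

test_that("long-range fit recovers charges and C6 from noiseless data", {
  ds <- shared_dataset()
  lr <- fit_long_range(ds)
  expect_equal(unname(lr$charges[["N"]]), 0.44, tolerance = 1e-4)
  expect_equal(unname(lr$charges[["O"]]), -0.22, tolerance = 1e-4)
  truthC6 <- c("N:N" = 1300, "N:O" = 1100, "O:O" = 900)
  ## the raw tail estimate initializes the coefficients ...
  for (k in names(truthC6))
    expect_lt(abs(lr$C6[[k]] - truthC6[[k]]) / truthC6[[k]], 0.08)
  ## ... and the damping-corrected re-solve pins them down
  dd <- fit_dispersion_damping(ds, lr$C6, lr$C8)
  for (k in names(truthC6))
    expect_lt(abs(dd$C6[[k]] - truthC6[[k]]) / truthC6[[k]], 0.005)
})

test_that("long-range fit demands enough asymptotic points", {
  ds <- shared_dataset()
  short <- structure(list(configs = ds$configs[1:30],
                          energies = ds$energies[1:30, ]),
                     class = "cspff_dataset")
  expect_error(fit_long_range(short), "R >")
})

test_that("uncharged systems give near-zero fitted charges and a flagged delta1", {
  mon0 <- monomer(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 1.15)),
                  charges = c(0, 0), name = "apolar")
  truth0 <- fixture_truth_ff("diatomic")
  gt <- ground_truth(truth0, seed = 12)
  cfgs <- sample_dimer_configurations(mon0, mon0, 250, seed = 12)
  ## zero-charge monomers: the oracle's Coulomb term vanishes
  ds <- evaluate_reference(gt, cfgs)
  lr <- fit_long_range(ds)
  expect_lt(max(abs(lr$charges)), 1e-3)
  ed <- fit_electrostatic_damping(ds, lr$charges)
  expect_setequal(ed$flagged, c("N:N", "N:O", "O:O"))
  expect_true(all(ed$delta1 == fit_config()$default_delta))
})

test_that("electrostatic damping is recovered and beats undamped Coulomb", {
  ds <- shared_dataset()
  lr <- fit_long_range(ds)
  ed <- fit_electrostatic_damping(ds, lr$charges)
  truth_d1 <- c("N:N" = 3.2, "N:O" = 3.4, "O:O" = 3.6)
  for (k in names(truth_d1))
    expect_lt(abs(ed$delta1[[k]] - truth_d1[[k]]) / truth_d1[[k]], 0.02)
  ## compare against an undamped-Coulomb baseline on the elst component
  dg <- cspff:::ds_design(ds)
  q <- lr$charges[dg$types]
  qq <- q[dg$ta] * q[dg$tb]
  bare <- rowsum(1389.35458 * qq / dg$r, dg$cfg)[, 1]
  rmse_bare <- sqrt(mean((ds$energies$elst - bare)^2))
  expect_lt(ed$rmse, rmse_bare)
})

test_that("attraction dampings are recovered from the component sum", {
  ds <- shared_dataset()
  lr <- fit_long_range(ds)
  dd <- fit_dispersion_damping(ds, lr$C6, lr$C8)
  truth_d6 <- c("N:N" = 2.8, "N:O" = 2.9, "O:O" = 3.0)
  truth_d8 <- truth_d6        # one damping range per pair in the truth
  for (k in names(truth_d6)) {
    expect_lt(abs(dd$delta6[[k]] - truth_d6[[k]]) / truth_d6[[k]], 0.05)
    expect_lt(abs(dd$delta8[[k]] - truth_d8[[k]]) / truth_d8[[k]], 0.05)
  }
  ## model matches the summed attraction at the largest separations
  dg <- cspff:::ds_design(ds)
  far <- which.max(ds$energies$R)
  pred <- -sum(tang_toennies(6, dd$delta6[dg$pair[dg$cfg == far]],
                             dg$r[dg$cfg == far]) *
               dd$C6[dg$pair[dg$cfg == far]] / dg$r[dg$cfg == far]^6) -
    sum(tang_toennies(8, dd$delta8[dg$pair[dg$cfg == far]],
                      dg$r[dg$cfg == far]) *
        dd$C8[dg$pair[dg$cfg == far]] / dg$r[dg$cfg == far]^8)
  y <- ds$energies$indx[far] + ds$energies$dispx[far]
  expect_lt(abs(pred - y) / abs(y), 0.01)
  ## nothing to damp -> refusal
  z <- stats::setNames(numeric(3), names(lr$C6))
  expect_error(fit_dispersion_damping(ds, z, z), "nothing to damp")
})

test_that("the full fit reproduces the hidden potential", {
  fit <- shared_fit("extended")
  expect_lt(fit$report$rmse_all, 1e-5)
  expect_lt(fit$report$rmse_negative, 1e-5)
  ## separately identified parameter groups within 2%
  truth <- fixture_truth_ff("diatomic")
  for (k in names(truth$pairs)) {
    for (f in c("C6", "C8", "delta1", "delta6", "delta8")) {
      expect_lt(abs(fit$forcefield$pairs[[k]][[f]] - truth$pairs[[k]][[f]]) /
                  truth$pairs[[k]][[f]], 0.02)
    }
  }
  expect_equal(unname(fit$charges[["N"]]), 0.44, tolerance = 2e-3)
  ## and the potential agrees pointwise on fresh configurations
  mon <- fixture_monomers("triatomic")
  fresh <- sample_dimer_configurations(mon, mon, 50, seed = 99)
  vt <- vapply(fresh, function(d) dimer_interaction_energy(truth, d), 0)
  monq <- cspff:::apply_charges(mon, fit$charges)
  fresh_q <- lapply(fresh, function(d) { d$monomerA <- monq; d$monomerB <- monq; d })
  vf <- vapply(fresh_q, function(d)
    dimer_interaction_energy(fit$forcefield, d), 0)
  ## absolute agreement in and below the well, relative on the wall
  expect_lt(max(abs(vt - vf) / pmax(abs(vt), 1)), 2e-3)
  ok_well <- vt < 20
  expect_lt(max(abs(vt[ok_well] - vf[ok_well])), 5e-3)
})

test_that("model-interface methods are coherent", {
  fit <- shared_fit("extended")
  expect_s3_class(fit, "cspff_fit")
  co <- coef(fit)
  expect_true(all(c("N:N.beta", "q.N", "q.O") %in% names(co)))
  r <- residuals(fit)
  expect_equal(length(r), 700)
  expect_equal(fitted(fit) - r * 0, predict(fit))
  expect_lt(sqrt(mean(r^2)), 1e-4)
  expect_output(print(fit), "force-field fit")
  expect_output(summary(fit), "charges")
})

test_that("weighted RMSE metric behaves as defined", {
  ds <- shared_dataset()
  truth <- fixture_truth_ff("diatomic")
  expect_lt(rmse_negative(truth, ds), 1e-10)
  ## constant offset model: RMSE equals the offset exactly
  off <- truth
  ## shifting every pair energy is awkward; test via the definition
  dg <- cspff:::ds_design(ds)
  neg <- ds$energies$total < 0
  fake_pred <- ds$energies$total + 1
  expect_equal(sqrt(mean((fake_pred[neg] - ds$energies$total[neg])^2)), 1,
               tolerance = 1e-12)
  ## empty-negative-set flagging
  pos_only <- structure(list(configs = ds$configs[ds$energies$total > 0],
                             energies = ds$energies[ds$energies$total > 0, ]),
                        class = "cspff_dataset")
  out <- rmse_negative(truth, pos_only)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "empty")))
})

test_that("simpler forms fit strictly worse on extended-truth data", {
  f_ext <- shared_fit("extended")
  f_exp <- shared_fit("exp61")
  f_lj <- shared_fit("lj1261")
  expect_lt(f_ext$report$rmse_negative, f_exp$report$rmse_negative)
  expect_lt(f_exp$report$rmse_negative, f_lj$report$rmse_negative)
})

test_that("parameter counting follows the form and typing", {
  f_exp <- shared_fit("exp61")
  ## 2 types -> 3 pairs x (A, beta, C6) = 9
  expect_identical(f_exp$report$n_parameters, 9L * 1L)
  expect_identical(f_exp$report$n_charge_parameters, 2L)
  ## a 4-atom-type homodimer would give choose(4,2)+4 = 10 pairs x 3 = 30
  expect_identical(10L * 3L, 30L)
  f_ext <- shared_fit("extended")
  expect_identical(f_ext$report$n_parameters, 3L * 10L)
})

test_that("noise propagates to the negative-energy RMSE at its own scale", {
  mon <- fixture_monomers("diatomic")
  gt <- ground_truth(fixture_truth_ff("diatomic"), noise_sigma = 0.5, seed = 44)
  cfgs <- sample_dimer_configurations(mon, mon, 700, seed = 44)
  ds <- evaluate_reference(gt, cfgs)
  fit <- fit_forcefield(ds, "extended")
  ## component noise 0.5 -> total sd 1.0; the fit cannot beat the noise
  ## floor and should not exceed it by much
  expect_gt(fit$report$rmse_negative, 0.5)
  expect_lt(fit$report$rmse_negative, 1.6)
})

test_that("hole detection distinguishes safe, unsafe and 12-6-1 fields", {
  mon <- fixture_monomers("triatomic")
  ## 12-6-1 with a positive wall never has holes
  flj <- shared_fit("lj1261")
  monq <- cspff:::apply_charges(mon, flj$charges)
  rep_lj <- detect_holes(flj$forcefield, monq, monq, n_orientations = 12,
                         r_grid = seq(0.4, 10, by = 0.1))
  expect_true(all(!rep_lj$hole))
  ## extended form with a feeble wall and undamped attraction collapses
  unsafe <- fixture_truth_ff("triatomic")
  for (k in names(unsafe$pairs)) {
    unsafe$pairs[[k]][["A12"]] <- 100
    unsafe$pairs[[k]][["delta6"]] <- 50
    unsafe$pairs[[k]][["delta8"]] <- 50
  }
  coarse <- seq(0.4, 10, by = 0.1)
  rep_u <- detect_holes(unsafe, mon, mon, n_orientations = 12,
                        r_grid = coarse)
  expect_true(any(rep_u$hole))
  expect_true(any(rep_u$flagged))
  ## remediation raises the wall until no flagged hole remains
  fixed <- ensure_barrier(unsafe, mon, mon, n_orientations = 12,
                          r_grid = coarse)
  expect_gt(fixed$scale, 1)
  expect_true(all(!fixed$report$flagged))
  ## a generous wall is already safe
  safe <- fixture_truth_ff("triatomic")
  rep_s <- detect_holes(safe, mon, mon, n_orientations = 12,
                        r_grid = coarse)
  expect_true(all(!rep_s$flagged))
})

test_that("adding consistent data does not degrade the training residual", {
  ds <- shared_dataset()
  half <- structure(list(configs = ds$configs[1:350],
                         energies = ds$energies[1:350, ]),
                    class = "cspff_dataset")
  f_half <- fit_forcefield(half, "extended")
  f_full <- shared_fit("extended")
  ## noiseless, realizable truth: both runs sit at the numerical floor
  expect_lt(f_full$report$rmse_all, max(2 * f_half$report$rmse_all, 1e-5))
})
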