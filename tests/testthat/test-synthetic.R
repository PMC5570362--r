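# Synthetic-data generators: determinism, preset anchoring and zero-noise
# round trips with the corresponding fitters.

test_that("presets encode the control vs low-Cu contrasts", {
  ctl <- scenario_preset("TO03_control")
  low <- scenario_preset("TO03_lowCu")
  expect_equal(ctl$FvFm, 0.6)
  expect_equal(low$FvFm, 0.3)
  expect_equal(low$sigma_dark / ctl$sigma_dark, 1.3)
  expect_equal(low$NPQ_NSV / ctl$NPQ_NSV, 4)
  expect_equal(low$plastocyanin_ratio, 0.227)
  expect_equal(low$ferredoxin_ratio, 43.79)
  # TO05 changes only its growth rate under low Cu
  t5c <- scenario_preset("TO05_control")
  t5l <- scenario_preset("TO05_lowCu")
  expect_equal(t5l$sigma_dark, t5c$sigma_dark)
  expect_equal(t5l$FvFm, t5c$FvFm)
  expect_lt(t5l$mu, t5c$mu)
})

test_that("generators are bit-identical for the same seed", {
  a <- gen_st_transient("TO03_control", noise_sd = 2, seed = 99)
  b <- gen_st_transient("TO03_control", noise_sd = 2, seed = 99)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(
    gen_st_transient("TO03_control", noise_sd = 2, seed = 100)$fluorescence,
    a$fluorescence))
  p1 <- gen_pe_dataset("TO03_lowCu", "ETR", noise_cv = 0.05, seed = 7)
  p2 <- gen_pe_dataset("TO03_lowCu", "ETR", noise_cv = 0.05, seed = 7)
  expect_identical(p1$rate, p2$rate)
  g1 <- gen_growth_curve("TO05_lowCu", noise_cv = 0.05, seed = 3)
  g2 <- gen_growth_curve("TO05_lowCu", noise_cv = 0.05, seed = 3)
  expect_identical(g1$signal, g2$signal)
  t1 <- gen_proteomics_table(n_proteins = 10, seed = 5)
  t2 <- gen_proteomics_table(n_proteins = 10, seed = 5)
  expect_identical(t1$intensity_medium, t2$intensity_medium)
})

test_that("zero-noise ST transients round-trip through the fitter", {
  for (name in c("TO03_control", "TO03_lowCu")) {
    for (state in c("dark_regulated", "light_regulated")) {
      tr <- gen_st_transient(name, state, noise_sd = 0)
      truth <- attr(tr, "truth")
      fit <- fit_st_transient(tr)
      expect_equal(fit$F0, truth$F0, tolerance = 1e-6)
      expect_equal(fit$Fmax, truth$Fmax, tolerance = 1e-6)
      expect_equal(fit$sigma_PSII, truth$sigma, tolerance = 1e-6)
    }
  }
  # dark fit of the control preset reproduces Fv/Fm = 0.6
  fit <- fit_st_transient(gen_st_transient("TO03_control", noise_sd = 0))
  expect_equal(fvfm(fit$F0, fit$Fmax), 0.6, tolerance = 1e-6)
})

test_that("zero-noise PE data round-trip and photoinhibition is flagged", {
  pe <- gen_pe_dataset("TO03_control", "C14", noise_cv = 0)
  truth <- attr(pe, "truth")
  fit <- fit_pe(pe)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$Pmax, truth$Pmax, tolerance = 1e-6)
  inh <- gen_pe_dataset("TO03_control", "ETR", noise_cv = 0,
                        photoinhibition = TRUE)
  fit2 <- fit_pe(inh, exclude_photoinhibition = TRUE)
  expect_setequal(fit2$excluded_points, attr(inh, "truth")$photoinhibited)
  expect_equal(fit2$alpha, attr(inh, "truth")$alpha, tolerance = 1e-4)
})

test_that("zero-noise growth curves recover preset growth rates exactly", {
  g <- gen_growth_curve("TO03_control", noise_cv = 0)
  expect_equal(fit_growth_rate(g$day, g$signal)$mu, 1.05, tolerance = 1e-10)
  g5 <- gen_growth_curve("TO05_lowCu", noise_cv = 0)
  expect_equal(fit_growth_rate(g5$day, g5$signal)$mu, 0.82,
               tolerance = 1e-10)
})

test_that("proteomics generator produces recoverable spikes and valid schema", {
  spikes <- data.frame(protein_id = c("up4", "down4", "aon44", "mild"),
                       true_ratio = c(4, 0.25, 44, 1.5),
                       replicates_observed = c(3, 3, 1, 3))
  tab <- gen_proteomics_table(n_proteins = 20, spikes = spikes,
                              missing_rate = 0, seed = 31)
  expect_true(all(c("protein_id", "peptide_id", "replicate",
                    "intensity_light", "intensity_medium",
                    "intensity_heavy") %in% names(tab)))
  calls <- de_call_table(aggregate_protein_ratios(tab))
  expect_equal(calls$call[calls$protein_id == "up4"], "up")
  expect_equal(calls$call[calls$protein_id == "down4"], "down")
  aon <- calls[calls$protein_id == "aon44", ]
  expect_equal(aon$call, "up")
  expect_true(aon$all_or_nothing)
  expect_equal(aon$n_observed, 1)      # single-replicate pattern
  expect_equal(calls$call[calls$protein_id == "mild"], "ns")
})

test_that("generator argument validation", {
  expect_error(gen_st_transient("TO03_control", noise_sd = -1), ">= 0")
  expect_error(gen_pe_dataset("TO03_control", E = numeric(0)), "non-empty")
  expect_error(gen_proteomics_table(missing_rate = 1), "\\[0, 1\\)")
  expect_error(gen_growth_curve(0.5, days = 0:1), "3")
  expect_error(gen_physio_table(n_rep = 1), ">= 2")
})

test_that("scenario analysis assembles consistent derived quantities", {
  an <- run_scenario_analysis("TO03_control", seed = 2, st_noise_sd = 0,
                              pe_noise_cv = 0, growth_noise_cv = 0)
  expect_equal(an$params$FvFm, 0.6, tolerance = 1e-6)
  expect_equal(an$params$NPQ_NSV, 2 / 3, tolerance = 1e-6)
  expect_equal(an$mu, 1.05, tolerance = 1e-8)
  expect_equal(an$pe$Ek[an$pe$rate_type == "ETR"], 140, tolerance = 1e-4)
  # conversion factor equals the ratio of the curves at growth irradiance
  expect_equal(an$conversion_factor,
               an$etr_at_growth / (an$cassim_at_growth * 893.5 / 12 / 3600),
               tolerance = 1e-12)
})
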