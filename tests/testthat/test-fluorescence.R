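# Fluorescence yields, derived parameters and single-turnover fitting.

test_that("Fv/Fm follows (Fm-Fo)/Fm and rejects invalid yields", {
  expect_equal(fvfm(200, 500), 0.6)
  expect_equal(fvfm(350, 500), 0.3)
  expect_equal(fvfm(300, 300), 0)
  expect_error(fvfm(0, 500), "positive")
  expect_error(fvfm(200, -1), "positive")
  expect_error(fvfm(600, 500), "exceed")
})

test_that("Fo' formula gives Fo/(Fv/Fm + Fo/Fm') and collapses to Fo at Fm' = Fm", {
  expect_equal(fo_prime(200, 0.6, 400), 200 / (0.6 + 0.5))
  expect_equal(fo_prime(100, 0.5, 200), 100)
  # unquenched case: Fm' = Fm makes Fo' = Fo, for random valid yields
  set.seed(11)
  for (i in 1:50) {
    Fm <- runif(1, 100, 1000)
    Fo <- Fm * runif(1, 0.1, 0.9)
    expect_equal(fo_prime(Fo, fvfm(Fo, Fm), Fm), Fo, tolerance = 1e-12)
  }
  expect_error(fo_prime(200, 1.2, 400), "\\(0, 1\\)")
  expect_error(fo_prime(-5, 0.5, 400), "positive")
})

test_that("light-regulated parameters match their definitions and boundaries", {
  lp <- light_params(150, 250, 350)
  expect_equal(lp$FqFv_prime, 0.5)
  expect_equal(lp$FvFm_prime, 200 / 350)
  expect_equal(lp$FqFm_prime, 100 / 350)
  expect_equal(lp$NPQ_NSV, 0.75)
  # all centres open / all closed
  expect_equal(light_params(150, 150, 350)$FqFv_prime, 1)
  expect_equal(light_params(150, 350, 350)$FqFv_prime, 0)
  expect_equal(light_params(150, 350, 350)$FqFm_prime, 0)
  expect_error(light_params(350, 250, 350), "Fm'")
  expect_error(light_params(150, 400, 350), "exceed")
})

test_that("noisy F' below Fo' is clamped with a warning, not an error", {
  expect_warning(lp <- light_params(150, 140, 350), "clamp")
  expect_equal(lp$FqFv_prime, 1)
  expect_lte(lp$FqFm_prime, lp$FvFm_prime)
})

test_that("product identity and NPQ two-form equality hold on random yields", {
  set.seed(7)
  y <- random_yields(1000)
  lp <- light_params(y$Fo_prime, y$F_prime, y$Fm_prime)
  expect_equal(lp$FqFm_prime, lp$FqFv_prime * lp$FvFm_prime,
               tolerance = 1e-12)
  Fv_prime <- y$Fm_prime - y$Fo_prime
  expect_equal(y$Fm_prime / Fv_prime - 1, lp$NPQ_NSV, tolerance = 1e-12)
})

test_that("ST fit recovers noiseless forward-model parameters to 1e-6", {
  # generate with the independent deSolve oracle, not the package model
  time_us <- seq_len(128) * 4
  flux <- rep(3e-5, 128)
  fl <- ode_st_oracle(time_us, flux, F0 = 100, Fmax = 300, sigma = 500)
  tr <- st_transient(time_us, flux, fl)
  fit <- fit_st_transient(tr)
  expect_equal(fit$F0, 100, tolerance = 1e-6)
  expect_equal(fit$Fmax, 300, tolerance = 1e-6)
  expect_equal(fit$sigma_PSII, 500, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-5)
})

test_that("package closure model agrees with the ODE oracle, including connectivity", {
  time_us <- seq_len(64) * 8
  set.seed(3)
  flux <- runif(64, 1e-5, 4e-5)  # non-constant flashlet flux
  for (p in c(0, 0.35)) {
    ours <- cuphyto:::st_model(time_us, flux, 100, 300, 500, p = p)
    oracle <- ode_st_oracle(time_us, flux, 100, 300, 500, p = p)
    expect_equal(ours, unname(oracle), tolerance = 1e-7)
  }
})

test_that("ST fit is scale-equivariant in the fluorescence trace", {
  tr <- gen_st_transient("TO03_control", noise_sd = 1.5, seed = 21)
  fit1 <- fit_st_transient(tr)
  k <- 3.7
  tr2 <- st_transient(tr$time_us, tr$flux, tr$fluorescence * k)
  fit2 <- fit_st_transient(tr2)
  expect_equal(fit2$F0, k * fit1$F0, tolerance = 1e-6)
  expect_equal(fit2$Fmax, k * fit1$Fmax, tolerance = 1e-6)
  expect_equal(fit2$sigma_PSII, fit1$sigma_PSII, tolerance = 1e-6)
})

test_that("degenerate transients are rejected with informative errors", {
  time_us <- seq_len(16) * 4
  expect_error(
    fit_st_transient(st_transient(time_us, rep(0, 16),
                                  rep(100, 16))),
    "no information")
  expect_error(st_transient(1:5, rep(1e-5, 5), rep(100, 5)), ">= 8")
  expect_error(st_transient(rev(time_us), rep(1e-5, 16), rep(100, 16)),
               "increasing")
  expect_error(st_transient(time_us, rep(1e-5, 16), rep(-1, 16)),
               "non-negative")
})

test_that("chlf_params composes the dark and light parameters consistently", {
  row <- chlf_params(Fo = 200, Fm = 500, F_prime = 290, Fm_prime = 500,
                     background_E = 155)
  expect_equal(row$FvFm, 0.6)
  expect_equal(row$Foprime, 200)       # Fm' = Fm, so Fo' = Fo
  expect_equal(row$FqFv_prime, 0.7)
  expect_equal(row$NPQ_NSV, 200 / 300)
})

test_that("ST transient CSV round-trips including metadata", {
  tr <- gen_st_transient("TO03_lowCu", light_state = "light_regulated",
                         noise_sd = 1, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_st_transient(tr, f)
  back <- read_st_transient(f)
  expect_equal(back$fluorescence, tr$fluorescence, tolerance = 1e-12)
  expect_equal(back$light_state, "light_regulated")
  expect_equal(back$background_E, 155)
})
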