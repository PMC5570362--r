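# Factorial cell-means model and simple-main-effect contrasts.

test_that("identical cells give zero effects and p = 1", {
  d <- gen_physio_table("x", baseline = 5, sd = 0, seed = 1)
  d$value <- 5
  fit <- fit_factorial(d)
  expect_equal(fit$mse, 0)
  sme <- simple_main_effect(fit, vary = "cu_level",
                            fixed = c(strain = "TO03", fe_level = "high"))
  expect_equal(sme$estimate, 0)
  expect_equal(sme$F, 0)
  expect_equal(sme$p_value, 1)
})

test_that("contrast estimate equals the difference of the two cell means", {
  d <- gen_physio_table("x", baseline = 10, cu_effect = 2, sd = 0.5,
                        seed = 2)
  fit <- fit_factorial(d)
  sme <- simple_main_effect(fit, vary = "cu_level",
                            fixed = c(strain = "TO03", fe_level = "high"))
  cells <- fit$cells
  m_high <- cells$mean[cells$strain == "TO03" & cells$fe_level == "high" &
                         cells$cu_level == "high"]
  m_low <- cells$mean[cells$strain == "TO03" & cells$fe_level == "high" &
                        cells$cu_level == "low"]
  expect_equal(sme$estimate, m_low - m_high, tolerance = 1e-12)
})

test_that("pooled-error contrast agrees with the emmeans oracle", {
  d <- gen_physio_table("x", baseline = 3, cu_effect = 1.2,
                        strain_cu_effect = -0.8, sd = 0.6, seed = 7)
  fit <- fit_factorial(d)
  em <- emmeans::emmeans(fit$model, ~ cu_level | strain * fe_level)
  emc <- as.data.frame(emmeans::contrast(em, "revpairwise"))
  for (s in c("TO03", "TO05")) {
    sme <- simple_main_effect(fit, vary = "cu_level",
                              fixed = c(strain = s, fe_level = "high"))
    ref <- emc[emc$strain == s & emc$fe_level == "high", ]
    expect_equal(sme$estimate, ref$estimate, tolerance = 1e-10)
    expect_equal(sme$F, ref$t.ratio^2, tolerance = 1e-10)
    expect_equal(sme$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(sme$df2, ref$df)
  }
})

test_that("injected Cu effect is recovered within its standard error", {
  delta <- 0.15; sd <- 0.05; n_rep <- 3
  ests <- vapply(1:100, function(s) {
    d <- gen_physio_table("FvFm", baseline = 0.6, cu_effect = -delta,
                          n_rep = n_rep, sd = sd, seed = s)
    simple_main_effect(fit_factorial(d), vary = "cu_level",
                       fixed = c(strain = "TO03",
                                 fe_level = "high"))$estimate
  }, numeric(1))
  se <- sd * sqrt(2 / n_rep)
  expect_lt(abs(mean(ests) + delta), 3 * se / sqrt(100))
})

test_that("p-values do not depend on factor label order", {
  d <- gen_physio_table("x", baseline = 1, cu_effect = 0.4, sd = 0.3,
                        seed = 11)
  fit1 <- fit_factorial(d)
  d2 <- d
  d2$strain <- factor(d2$strain, levels = c("TO05", "TO03"))
  d2$cu_level <- factor(d2$cu_level, levels = c("low", "high"))
  fit2 <- fit_factorial(d2)
  s1 <- simple_main_effect(fit1, "cu_level",
                           c(strain = "TO03", fe_level = "high"))
  s2 <- simple_main_effect(fit2, "cu_level",
                           c(strain = "TO03", fe_level = "high"))
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
  expect_equal(abs(s1$estimate), abs(s2$estimate), tolerance = 1e-12)
})

test_that("missing design cells raise explicit errors", {
  d <- gen_physio_table("x", seed = 3)
  d <- d[!(d$strain == "TO03" & d$cu_level == "low"), ]
  fit <- fit_factorial(d)
  expect_error(
    simple_main_effect(fit, "cu_level",
                       c(strain = "TO03", fe_level = "high")),
    "missing design cell")
  d2 <- gen_physio_table("x", seed = 4)[1, ]
  expect_error(fit_factorial(rbind(d2, d2[0, ])), ">= 2 replicates")
})

test_that("Welch contrasts fall back to per-cell variances", {
  d <- gen_physio_table("x", baseline = 2, cu_effect = 1, sd = 0.4,
                        seed = 5)
  fit <- fit_factorial(d)
  pooled <- simple_main_effect(fit, "cu_level",
                               c(strain = "TO03", fe_level = "high"))
  welch <- simple_main_effect(fit, "cu_level",
                              c(strain = "TO03", fe_level = "high"),
                              error = "welch")
  expect_equal(pooled$estimate, welch$estimate)
  expect_lt(welch$df2, pooled$df2)   # Satterthwaite df is smaller
})
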