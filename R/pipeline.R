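# End-to-end scenario analysis: from simulated raw records through fits to
# the derived photophysiological parameters, growth rate and DE calls.

#' Analyse one scenario from simulated raw records
#'
#' Runs the full measurement chain for one scenario preset: simulates and
#' fits the dark- and light-regulated single-turnover transients (yielding
#' Fo, Fm, Fv/Fm, sigma_PSII, F', Fm', sigma_PSII' and, via the Fo'
#' formula, the light-regulated quenching parameters at growth irradiance),
#' simulates and fits the ETR and 14C PE curves, evaluates both fitted
#' curves at growth irradiance to form the electron:carbon conversion
#' factor, and fits the growth rate from a simulated growth series.
#'
#' @param preset A [scenario_preset] or its name.
#' @param seed Integer seed for all simulated records.
#' @param st_noise_sd ST transient noise (instrument units).
#' @param pe_noise_cv PE rate noise (coefficient of variation).
#' @param growth_noise_cv Growth signal noise.
#' @return List of class `scenario_analysis` with elements `preset_name`,
#'   `yields` (the five fitted/derived yields), `params` (Fv/Fm, Fq'/Fv',
#'   Fv'/Fm', Fq'/Fm', NPQ_NSV), `sigma_dark`, `sigma_prime`, `pe`
#'   (fitted alpha/Pmax/Ek per rate type), `etr_at_growth`,
#'   `cassim_at_growth`, `conversion_factor`, `mu`.
#' @export
#' @examples
#' run_scenario_analysis("TO03_control", seed = 1)$params$FvFm
run_scenario_analysis <- function(preset, seed = 1, st_noise_sd = 2,
                                  pe_noise_cv = 0.03,
                                  growth_noise_cv = 0.02) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  dark <- fit_st_transient(gen_st_transient(
    preset, "dark_regulated", noise_sd = st_noise_sd, seed = seed))
  light <- fit_st_transient(gen_st_transient(
    preset, "light_regulated", noise_sd = st_noise_sd, seed = seed + 1L))
  pars <- chlf_params(Fo = dark$F0, Fm = dark$Fmax,
                      F_prime = light$F0, Fm_prime = light$Fmax,
                      background_E = GROWTH_IRRADIANCE)

  pe_etr <- fit_pe(gen_pe_dataset(preset, "ETR", noise_cv = pe_noise_cv,
                                  seed = seed + 2L))
  pe_c14 <- fit_pe(gen_pe_dataset(preset, "C14", noise_cv = pe_noise_cv,
                                  seed = seed + 3L))
  etr_growth <- predict(pe_etr, GROWTH_IRRADIANCE)
  cas_growth <- predict(pe_c14, GROWTH_IRRADIANCE)
  cf <- conversion_factor(etr_growth, cas_growth)

  growth <- fit_growth_rate(
    gen_growth_curve(preset, noise_cv = growth_noise_cv, seed = seed + 4L)$day,
    gen_growth_curve(preset, noise_cv = growth_noise_cv, seed = seed + 4L)$signal)

  structure(
    list(preset_name = preset$name,
         yields = data.frame(Fo = dark$F0, Fm = dark$Fmax,
                             Fprime = light$F0, Fmprime = light$Fmax,
                             Foprime = pars$Foprime),
         params = pars[c("FvFm", "FqFv_prime", "FvFm_prime", "FqFm_prime",
                         "NPQ_NSV")],
         sigma_dark = dark$sigma_PSII, sigma_prime = light$sigma_PSII,
         pe = data.frame(rate_type = c("ETR", "C14"),
                         alpha = c(pe_etr$alpha, pe_c14$alpha),
                         Pmax = c(pe_etr$Pmax, pe_c14$Pmax),
                         Ek = c(pe_etr$Ek, pe_c14$Ek)),
         etr_at_growth = etr_growth, cassim_at_growth = cas_growth,
         conversion_factor = cf, mu = growth$mu),
    class = "scenario_analysis")
}

#' @export
print.scenario_analysis <- function(x, ...) {
  cat("Scenario analysis:", x$preset_name, "\n")
  cat("  Fv/Fm =", signif(x$params$FvFm, 3),
      " sigma_PSII =", signif(x$sigma_dark, 4), "A2",
      " NPQ_NSV =", signif(x$params$NPQ_NSV, 3), "\n")
  cat("  Ek(ETR) =", signif(x$pe$Ek[x$pe$rate_type == "ETR"], 4),
      " Ek(14C) =", signif(x$pe$Ek[x$pe$rate_type == "C14"], 4),
      " conversion factor =", signif(x$conversion_factor, 4), "\n")
  cat("  mu =", signif(x$mu, 3), "d-1\n")
  invisible(x)
}

#' Control vs low-Cu scenario contrast
#'
#' Runs [run_scenario_analysis()] on a control and a treatment preset and
#' summarises the contrasts the copper-limitation experiments report:
#' Fv/Fm under each condition, the low-Cu/control ratios of sigma_PSII,
#' NPQ_NSV and the conversion factor, the relative growth (mu as percent
#' of the control mu), and the DE calls for the marker proteins from a
#' simulated triplex proteome of the treatment condition.
#'
#' @param control,treatment Preset names (default TO03 control vs low Cu).
#' @param seed Integer seed.
#' @param n_proteins Background proteins in the simulated proteome.
#' @param ... Passed to [run_scenario_analysis()].
#' @return List of class `scenario_contrast`: `control`, `treatment`
#'   (the two analyses), `summary` (one-row data.frame of the contrasts)
#'   and `de` (marker-protein DE calls).
#' @export
run_scenario_contrast <- function(control = "TO03_control",
                                  treatment = "TO03_lowCu", seed = 1,
                                  n_proteins = 100, ...) {
  ctl <- run_scenario_analysis(control, seed = seed, ...)
  trt <- run_scenario_analysis(treatment, seed = seed + 100L, ...)
  prot <- gen_proteomics_table(
    n_proteins = n_proteins,
    spikes = default_spikes(scenario_preset(treatment)),
    seed = seed + 200L)
  de <- de_call_table(aggregate_protein_ratios(prot))
  markers <- de[de$protein_id %in% c("petE_plastocyanin", "petF_ferredoxin",
                                     "petH_FNR"), ]
  summary <- data.frame(
    FvFm_control = ctl$params$FvFm,
    FvFm_treatment = trt$params$FvFm,
    sigma_ratio = trt$sigma_dark / ctl$sigma_dark,
    npq_ratio = trt$params$NPQ_NSV / ctl$params$NPQ_NSV,
    conversion_factor_ratio = trt$conversion_factor / ctl$conversion_factor,
    mu_control = ctl$mu, mu_treatment = trt$mu,
    relative_growth_pct = relative_growth(trt$mu, ctl$mu))
  structure(list(control = ctl, treatment = trt, summary = summary,
                 de = markers, de_full = de),
            class = "scenario_contrast")
}

#' @export
print.scenario_contrast <- function(x, ...) {
  s <- x$summary
  cat("Contrast", x$control$preset_name, "vs", x$treatment$preset_name, "\n")
  cat(sprintf("  Fv/Fm %.2f -> %.2f | sigma x%.2f | NPQ x%.2f | CF x%.2f\n",
              s$FvFm_control, s$FvFm_treatment, s$sigma_ratio, s$npq_ratio,
              s$conversion_factor_ratio))
  cat(sprintf("  mu %.2f -> %.2f d-1 (%.0f%% of control)\n",
              s$mu_control, s$mu_treatment, s$relative_growth_pct))
  if (nrow(x$de)) {
    cat("  marker proteins:\n")
    for (i in seq_len(nrow(x$de)))
      cat(sprintf("    %-18s %-4s signed FC %.2f%s\n", x$de$protein_id[i],
                  x$de$call[i], x$de$signed_fold_change[i],
                  if (x$de$all_or_nothing[i]) " (all-or-nothing)" else ""))
  }
  invisible(x)
}
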