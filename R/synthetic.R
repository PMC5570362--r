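# Seeded synthetic-data generators for every input the analysis consumes,
# with scenario presets anchored to the control vs low-Cu contrasts of the
# two strains. Zero-noise output from each generator is an exact round-trip
# partner of the corresponding fitter.

# Scenario constants. One row per strain x Cu condition. Anchors:
#   FvFm            0.6 control -> 0.3 low Cu (TO03 only)
#   sigma_PSII      +30% under low Cu in TO03
#   NPQ_NSV         x4 under low Cu in TO03 (2/3 -> 8/3, via Fv'/Fm' 0.6 -> 3/11)
#   FqFv_prime      0.7 -> 0.6 under low Cu in TO03
#   mu              1.05/0.51 (TO03), 1.26/0.82 (TO05)
#   ETR PE          Ek 140 -> 105, alpha +18%
#   14C PE          conversion factor x2 at E = 155, Ek(14C) -33%
#   protein ratios  plastocyanin 0.227 (= -4.41 signed), ferredoxin 43.79,
#                   FNR 2.47 under low Cu in TO03
# TO05 changes only growth under low Cu; its photophysiology and proteome
# stay at control values.
.presets <- list(
  TO03_control = list(
    name = "TO03_control", strain = "TO03", cu = "high",
    Fm_dark = 500, FvFm = 0.6, sigma_dark = 500, sigma_prime = 450,
    FqFv_prime = 0.7, FvFm_prime = 0.6, mu = 1.05,
    pe_alpha_etr = 2.0, pe_Pmax_etr = 280,
    pe_alpha_c14 = 0.0087, pe_Pmax_c14 = 2.0,
    plastocyanin_ratio = 1, ferredoxin_ratio = 1, fnr_ratio = 1),
  TO03_lowCu = list(
    name = "TO03_lowCu", strain = "TO03", cu = "low",
    Fm_dark = 500, FvFm = 0.3, sigma_dark = 650, sigma_prime = 585,
    FqFv_prime = 0.6, FvFm_prime = 3 / 11, mu = 0.51,
    pe_alpha_etr = 2.36, pe_Pmax_etr = 247.8,
    pe_alpha_c14 = 0.00522, pe_Pmax_c14 = 0.8,
    plastocyanin_ratio = 0.227, ferredoxin_ratio = 43.79, fnr_ratio = 2.47),
  TO05_control = list(
    name = "TO05_control", strain = "TO05", cu = "high",
    Fm_dark = 500, FvFm = 0.6, sigma_dark = 500, sigma_prime = 450,
    FqFv_prime = 0.7, FvFm_prime = 0.6, mu = 1.26,
    pe_alpha_etr = 2.0, pe_Pmax_etr = 280,
    pe_alpha_c14 = 0.0087, pe_Pmax_c14 = 2.0,
    plastocyanin_ratio = 1, ferredoxin_ratio = 1, fnr_ratio = 1),
  TO05_lowCu = list(
    name = "TO05_lowCu", strain = "TO05", cu = "low",
    Fm_dark = 500, FvFm = 0.6, sigma_dark = 500, sigma_prime = 450,
    FqFv_prime = 0.7, FvFm_prime = 0.6, mu = 0.82,
    pe_alpha_etr = 2.0, pe_Pmax_etr = 280,
    pe_alpha_c14 = 0.0087, pe_Pmax_c14 = 2.0,
    plastocyanin_ratio = 1, ferredoxin_ratio = 1, fnr_ratio = 1))

#' Scenario preset for the synthetic generators
#'
#' Returns the parameter set describing one strain x Cu condition: the
#' dark and light-regulated fluorescence state (Fm, Fv/Fm, sigma_PSII,
#' sigma_PSII', Fq'/Fv', Fv'/Fm' at growth irradiance), the growth rate,
#' the Jassby-Platt parameters for ETR and 14C PE curves, and the true
#' low-Cu/control protein ratios for the marker proteins (plastocyanin,
#' ferredoxin, FNR). Derived yields (Fo, Fm', F', Fo', NPQ_NSV) are
#' computed from those and attached.
#'
#' @param name One of `"TO03_control"`, `"TO03_lowCu"`, `"TO05_control"`,
#'   `"TO05_lowCu"`.
#' @return A list of class `scenario_preset`.
#' @export
#' @examples
#' scenario_preset("TO03_lowCu")$sigma_dark
scenario_preset <- function(name = c("TO03_control", "TO03_lowCu",
                                     "TO05_control", "TO05_lowCu")) {
  name <- match.arg(name)
  p <- .presets[[name]]
  p$Fo <- p$Fm_dark * (1 - p$FvFm)
  # Fm' consistent with the target Fv'/Fm' given that Fo' follows the
  # dark-yield formula: Fm' = Fo * Fv'/Fm' / ((1 - Fv'/Fm') * Fv/Fm)
  p$Fm_prime <- p$Fo * p$FvFm_prime / ((1 - p$FvFm_prime) * p$FvFm)
  p$Fo_prime <- fo_prime(p$Fo, p$FvFm, p$Fm_prime)
  p$F_prime <- p$Fm_prime - p$FqFv_prime * (p$Fm_prime - p$Fo_prime)
  p$NPQ_NSV <- p$Fo_prime / (p$Fm_prime - p$Fo_prime)
  class(p) <- "scenario_preset"
  p
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario", x$name, "- Fv/Fm", x$FvFm, "| sigma", x$sigma_dark,
      "A2 | NPQ_NSV", signif(x$NPQ_NSV, 4), "| mu", x$mu, "d-1\n")
  invisible(x)
}

#' Simulate a single-turnover fluorescence transient
#'
#' Forward-integrates the cumulative single-hit closure model at the
#' preset's yields and cross-section under a constant flashlet flux, and
#' adds Gaussian noise. Dark-regulated transients run from Fo to Fm with
#' sigma_PSII; light-regulated transients (at growth irradiance) from F'
#' to Fm' with sigma_PSII'. The true generating parameters are attached as
#' `attr(x, "truth")` for recovery tests.
#'
#' @param preset A [scenario_preset] (or its name).
#' @param light_state `"dark_regulated"` or `"light_regulated"`.
#' @param noise_sd Gaussian noise sd in instrument units, >= 0.
#' @param seed Integer seed; same seed, same trace.
#' @param n_flashlets Number of samples (default 128).
#' @param dt_us Flashlet spacing, us (default 4).
#' @param flux Constant excitation flux, quanta A^-2 us^-1.
#' @param connectivity_p Joliot connectivity of the generator, default 0.
#' @return An [st_transient] with a `truth` attribute.
#' @export
gen_st_transient <- function(preset, light_state = "dark_regulated",
                             noise_sd = 0, seed = 1, n_flashlets = 128,
                             dt_us = 4, flux = 3e-5, connectivity_p = 0) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dark <- light_state == "dark_regulated"
  F0 <- if (dark) preset$Fo else preset$F_prime
  Fmax <- if (dark) preset$Fm_dark else preset$Fm_prime
  sigma <- if (dark) preset$sigma_dark else preset$sigma_prime
  time_us <- seq_len(n_flashlets) * dt_us
  flux_v <- rep(flux, n_flashlets)
  fl <- st_model(time_us, flux_v, F0, Fmax, sigma, p = connectivity_p)
  if (noise_sd > 0) {
    set.seed(seed)
    fl <- pmax(fl + stats::rnorm(n_flashlets, 0, noise_sd), 0)
  }
  out <- st_transient(time_us, flux_v, fl, light_state = light_state,
                      background_E = if (dark) 0 else GROWTH_IRRADIANCE)
  attr(out, "truth") <- list(F0 = F0, Fmax = Fmax, sigma = sigma,
                             p = connectivity_p)
  out
}

# Default 11-level irradiance grid of the photosynthetron (2-700).
pe_default_grid <- function() c(2, 10, 25, 50, 80, 120, 180, 260, 380, 520, 700)

#' Simulate a photosynthesis-irradiance dataset
#'
#' Jassby-Platt rates at the preset's (alpha, Pmax) for the chosen rate
#' type, with multiplicative lognormal noise and an optional photoinhibited
#' tail: points above `1.5 * Ek` are depressed by the factor
#' `photoinhibition_factor`.
#'
#' @param preset A [scenario_preset] (or its name).
#' @param rate_type `"ETR"` or `"C14"`.
#' @param E Irradiance grid; default 11 levels spanning 2-700.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param photoinhibition Depress the high-light tail.
#' @param photoinhibition_factor Multiplier applied above 1.5 * Ek.
#' @param n_rep Number of replicate curves (stacked in one table).
#' @return A data.frame (`replicate_id, rate_type, E, rate`) with a
#'   `truth` attribute carrying the generating alpha/Pmax/Ek.
#' @export
gen_pe_dataset <- function(preset, rate_type = c("ETR", "C14"),
                           E = pe_default_grid(), noise_cv = 0, seed = 1,
                           photoinhibition = FALSE,
                           photoinhibition_factor = 0.6, n_rep = 1) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  rate_type <- match.arg(rate_type)
  if (!length(E)) stop("irradiance grid must be non-empty")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  alpha <- if (rate_type == "ETR") preset$pe_alpha_etr else preset$pe_alpha_c14
  Pmax <- if (rate_type == "ETR") preset$pe_Pmax_etr else preset$pe_Pmax_c14
  Ek <- Pmax / alpha
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    rate <- jassby_platt(E, alpha, Pmax)
    inhibited <- photoinhibition & E > 1.5 * Ek
    rate[inhibited] <- rate[inhibited] * photoinhibition_factor
    if (noise_cv > 0) rate <- rate * exp(stats::rnorm(length(E), 0, noise_cv))
    data.frame(replicate_id = r, rate_type = rate_type, E = E, rate = rate)
  }))
  attr(out, "truth") <- list(alpha = alpha, Pmax = Pmax, Ek = Ek,
                             photoinhibited = which(E > 1.5 * Ek &
                                                      photoinhibition))
  out
}

#' Default spike table for the proteomics generator
#'
#' The marker proteins of the low-Cu response with their true
#' treatment/control ratios: plastocyanin strongly down (0.227, i.e. -4.41
#' signed), ferredoxin extremely up (43.79, an all-or-nothing-scale
#' response), FNR moderately up (2.47).
#'
#' @param preset Optional [scenario_preset] whose marker ratios to use
#'   (default: the TO03 low-Cu values).
#' @return data.frame `protein_id, true_ratio, replicates_observed`.
#' @export
default_spikes <- function(preset = scenario_preset("TO03_lowCu")) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  data.frame(
    protein_id = c("petE_plastocyanin", "petF_ferredoxin", "petH_FNR"),
    true_ratio = c(preset$plastocyanin_ratio, preset$ferredoxin_ratio,
                   preset$fnr_ratio),
    replicates_observed = 3L)
}

#' Simulate a triplex peptide intensity table
#'
#' Lognormal base intensities per peptide; the control channel carries the
#' base intensity and the treatment channel the base times the protein's
#' true ratio, each with lognormal measurement noise of `noise_sd_log2 /
#' sqrt(2)` per channel (so the peptide ratio has log2-noise
#' `noise_sd_log2`). Channels are dropped independently at `missing_rate`.
#' Spiked proteins with `replicates_observed < 3` have their treatment
#' channel removed in the remaining replicates (the all-or-nothing
#' single-replicate pattern). Background proteins have true ratio 1.
#'
#' @param n_proteins Number of background proteins.
#' @param spikes Spike table (`protein_id, true_ratio,
#'   replicates_observed`); [default_spikes()] by default, `NULL` for none.
#' @param peptides_per_protein Peptides per protein (default 3).
#' @param noise_sd_log2 sd of the peptide log2 ratio noise (default 0.3).
#' @param missing_rate Per-channel dropout probability in `[0, 1)`.
#' @param n_replicates Biological replicates (default 3).
#' @param seed Integer seed.
#' @return data.frame in the [aggregate_protein_ratios()] input schema,
#'   with a `truth` attribute mapping protein to true ratio.
#' @export
gen_proteomics_table <- function(n_proteins = 100, spikes = default_spikes(),
                                 peptides_per_protein = 3,
                                 noise_sd_log2 = 0.3, missing_rate = 0.05,
                                 n_replicates = 3, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(spikes) && any(spikes$true_ratio <= 0))
    stop("true ratios must be positive")
  set.seed(seed)
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  ratios <- rep(1, n_proteins)
  reps_obs <- rep(3L, n_proteins)
  if (!is.null(spikes) && nrow(spikes)) {
    ids <- c(as.character(spikes$protein_id), ids)
    ratios <- c(spikes$true_ratio, ratios)
    ro <- if ("replicates_observed" %in% names(spikes))
      spikes$replicates_observed else rep(3L, nrow(spikes))
    reps_obs <- c(as.integer(ro), reps_obs)
  }
  grid <- expand.grid(pep = seq_len(peptides_per_protein),
                      replicate = seq_len(n_replicates),
                      prot = seq_along(ids))
  m <- nrow(grid)
  base <- stats::rlnorm(m, meanlog = log(1e6), sdlog = 1)
  ch_sd <- noise_sd_log2 / sqrt(2)
  ctl <- base * 2^stats::rnorm(m, 0, ch_sd)
  trt <- base * ratios[grid$prot] * 2^stats::rnorm(m, 0, ch_sd)
  hvy <- base * 2^stats::rnorm(m, 0, ch_sd)
  if (missing_rate > 0) {
    ctl[stats::runif(m) < missing_rate] <- NA
    trt[stats::runif(m) < missing_rate] <- NA
    hvy[stats::runif(m) < missing_rate] <- NA
  }
  # single-replicate spike pattern: treatment channel absent outside the
  # first replicates_observed replicates
  drop <- grid$replicate > reps_obs[grid$prot]
  trt[drop] <- NA
  out <- data.frame(
    protein_id = ids[grid$prot],
    peptide_id = sprintf("%s_pep%02d", ids[grid$prot], grid$pep),
    replicate = grid$replicate,
    intensity_light = ctl, intensity_medium = trt, intensity_heavy = hvy)
  attr(out, "truth") <- data.frame(protein_id = ids, true_ratio = ratios)
  out
}

#' Simulate an exponential growth series
#'
#' `signal = 100 * exp(mu * day)` with multiplicative lognormal noise.
#'
#' @param preset A [scenario_preset], its name, or a bare growth rate
#'   (d^-1).
#' @param days Sampling days (default daily over 0-5), >= 3 points.
#' @param noise_cv Coefficient of variation of the noise.
#' @param seed Integer seed.
#' @return data.frame `day, signal` with a `truth` attribute (`mu`).
#' @export
gen_growth_curve <- function(preset, days = 0:5, noise_cv = 0, seed = 1) {
  mu <- if (is.numeric(preset)) preset else {
    if (is.character(preset)) preset <- scenario_preset(preset)
    preset$mu
  }
  if (length(days) < 3) stop("need at least 3 sampling days")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  signal <- 100 * exp(mu * days)
  if (noise_cv > 0) {
    set.seed(seed)
    signal <- signal * exp(stats::rnorm(length(days), 0, noise_cv))
  }
  out <- data.frame(day = days, signal = signal)
  attr(out, "truth") <- list(mu = mu)
  out
}

#' Simulate a balanced 2x2x2 physiology table
#'
#' One measured parameter over the full Strain x Fe x Cu design with
#' additive effects and Gaussian replicate noise, for calibrating and
#' testing the factorial contrasts.
#'
#' @param parameter Parameter name tag.
#' @param baseline Cell mean of (TO03, high Fe, high Cu).
#' @param strain_effect Added for TO05.
#' @param fe_effect Added at low Fe.
#' @param cu_effect Added at low Cu.
#' @param strain_cu_effect Added for (TO05, low Cu) — a Strain x Cu
#'   interaction.
#' @param n_rep Replicates per cell.
#' @param sd Replicate noise sd.
#' @param seed Integer seed.
#' @return data.frame `strain, fe_level, cu_level, replicate, parameter,
#'   value`.
#' @export
gen_physio_table <- function(parameter = "FvFm", baseline = 0.6,
                             strain_effect = 0, fe_effect = 0,
                             cu_effect = 0, strain_cu_effect = 0,
                             n_rep = 3, sd = 0.02, seed = 1) {
  if (n_rep < 2) stop("need >= 2 replicates per cell")
  set.seed(seed)
  design <- expand.grid(strain = c("TO03", "TO05"),
                        fe_level = c("high", "low"),
                        cu_level = c("high", "low"),
                        replicate = seq_len(n_rep),
                        stringsAsFactors = FALSE)
  mean_v <- baseline +
    strain_effect * (design$strain == "TO05") +
    fe_effect * (design$fe_level == "low") +
    cu_effect * (design$cu_level == "low") +
    strain_cu_effect * (design$strain == "TO05" & design$cu_level == "low")
  design$parameter <- parameter
  design$value <- mean_v + stats::rnorm(nrow(design), 0, sd)
  design[c("strain", "fe_level", "cu_level", "replicate", "parameter",
           "value")]
}
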