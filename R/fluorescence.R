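# Single-turnover FRRf analysis: induction-curve fitting for Fo/Fm/sigma_PSII
# and the chlorophyll-fluorescence parameters derived from the five yields.

#' Construct a single-turnover fluorescence transient
#'
#' A single-turnover (ST) flash record: a sequence of flashlets delivering a
#' known excitation photon flux while fluorescence is sampled. Under the
#' cumulative single-hit closure model, PSII reaction centres close at a rate
#' set by the product of the functional absorption cross-section and the
#' instantaneous flux, driving fluorescence from its minimum (all centres
#' open) to its maximum (all closed) within a single photochemical turnover.
#'
#' @param time_us Sample times in microseconds, strictly increasing,
#'   `time_us[1] >= 0`.
#' @param flux Excitation photon flux at each sample
#'   (quanta A^-2 us^-1), non-negative. Flux is treated as piecewise
#'   constant over the interval ending at each sample.
#' @param fluorescence Fluorescence yield in instrument units, non-negative.
#' @param light_state `"dark_regulated"` or `"light_regulated"`.
#' @param background_E Background (actinic) irradiance in
#'   umol quanta m^-2 s^-1; 0 for the dark-regulated state.
#' @return An object of class `st_transient`.
#' @export
st_transient <- function(time_us, flux, fluorescence,
                         light_state = c("dark_regulated", "light_regulated"),
                         background_E = 0) {
  light_state <- match.arg(light_state)
  n <- length(time_us)
  if (n < 8L || length(flux) != n || length(fluorescence) != n)
    stop("time, flux and fluorescence must have equal length >= 8")
  if (any(!is.finite(time_us)) || time_us[1] < 0 || any(diff(time_us) <= 0))
    stop("time must be finite, non-negative and strictly increasing")
  if (any(!is.finite(flux)) || any(flux < 0))
    stop("flux must be finite and non-negative")
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0))
    stop("fluorescence must be finite and non-negative")
  if (light_state == "dark_regulated" && background_E != 0)
    stop("dark-regulated transients must have background_E = 0")
  structure(
    list(time_us = as.numeric(time_us), flux = as.numeric(flux),
         fluorescence = as.numeric(fluorescence),
         light_state = light_state, background_E = background_E),
    class = "st_transient")
}

#' @export
print.st_transient <- function(x, ...) {
  cat("Single-turnover transient (", x$light_state, ")\n", sep = "")
  cat("  n =", length(x$time_us), "flashlets over",
      round(max(x$time_us)), "us; background E =", x$background_E,
      "umol quanta m-2 s-1\n")
  invisible(x)
}

# Cumulative photon dose (quanta A^-2) at each sample, treating flux as the
# constant rate over the interval ending at that sample. Dose at the first
# sample is flux[1] * time[1] (zero when the record starts at t = 0).
st_dose <- function(time_us, flux) {
  dt <- diff(c(0, time_us))
  cumsum(flux * dt)
}

# Fraction of closed RCII as a function of cumulative dose for cross-section
# sigma and Joliot connectivity p. With p = 0 the single-hit model has the
# closed form C = 1 - exp(-sigma * dose); with p > 0 the separable ODE
# dC/dtau = sigma i (1 - C)/(1 - p C) integrates implicitly to
# p*C - (1 - p)*log(1 - C) = sigma * dose, solved per point by root finding.
st_closure <- function(dose, sigma, p = 0) {
  if (p == 0) return(1 - exp(-sigma * dose))
  vapply(dose, function(d) {
    if (d <= 0) return(0)
    f <- function(C) p * C - (1 - p) * log1p(-C) - sigma * d
    stats::uniroot(f, lower = 0, upper = 1 - 1e-15, tol = 1e-14)$root
  }, numeric(1))
}

# Forward model of the ST fluorescence induction.
st_model <- function(time_us, flux, F0, Fmax, sigma, p = 0) {
  F0 + (Fmax - F0) * st_closure(st_dose(time_us, flux), sigma, p)
}

#' Fit a single-turnover transient for Fo/F', Fm/Fm' and sigma_PSII
#'
#' Fits the cumulative single-hit closure model
#' `F(t) = F0 + (Fmax - F0) * C(t)` with `dC/dtau = sigma * i(tau) * (1 - C)`
#' (optionally scaled by the Joliot connectivity term `(1 - C)/(1 - p*C)`)
#' to a flash record by bounded nonlinear least squares. In the
#' dark-regulated state `F0` and `Fmax` estimate Fo and Fm and `sigma` the
#' dark functional absorption cross-section sigma_PSII; in a light-regulated
#' state they estimate F', Fm' and sigma_PSII'.
#'
#' Initialisation is deterministic: `F0` from the minimum of the trace,
#' `Fmax` from its maximum, and sigma from the dose at half-rise via
#' `sigma ~ log(2) / dose_half`.
#'
#' @param x An [st_transient].
#' @param fit_connectivity Also fit the connectivity parameter `p` in
#'   `[0, 1)`; default `FALSE` (p fixed at `p`).
#' @param p Connectivity value used when `fit_connectivity = FALSE`.
#' @param max_iter Iteration cap for the Levenberg-Marquardt optimiser.
#' @return A list of class `st_fit` with elements `F0`, `Fmax`, `sigma_PSII`
#'   (A^2 RCII^-1), `connectivity_p`, `residual_rms`, `light_state`,
#'   `background_E` and `fitted`.
#' @export
#' @examples
#' tr <- gen_st_transient(scenario_preset("TO03_control"), noise_sd = 0, seed = 1)
#' fit_st_transient(tr)
fit_st_transient <- function(x, fit_connectivity = FALSE, p = 0,
                             max_iter = 200) {
  stopifnot(inherits(x, "st_transient"))
  if (all(x$flux == 0))
    stop("no information: excitation flux is zero everywhere")
  dose <- st_dose(x$time_us, x$flux)
  tr <- x$fluorescence
  F0_init <- min(tr)
  Fmax_init <- max(tr)
  if (Fmax_init <= F0_init)
    stop("no information: flat fluorescence trace")
  # dose at half-rise -> single-hit initial guess for sigma
  half <- F0_init + 0.5 * (Fmax_init - F0_init)
  ih <- which(tr >= half)[1]
  dose_half <- max(dose[ih], dose[dose > 0][1])
  sigma_init <- log(2) / dose_half

  dat <- data.frame(dose = dose, fl = tr)
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter)
  fit <- if (fit_connectivity) {
    minpack.lm::nlsLM(
      fl ~ F0 + (Fmax - F0) * st_closure(dose, sigma, p),
      data = dat,
      start = list(F0 = F0_init, Fmax = Fmax_init, sigma = sigma_init,
                   p = max(p, 0.05)),
      lower = c(0, 0, 1e-8, 0), upper = c(Inf, Inf, Inf, 0.999),
      control = ctrl)
  } else {
    force(p)
    minpack.lm::nlsLM(
      fl ~ F0 + (Fmax - F0) * st_closure(dose, sigma, p),
      data = dat,
      start = list(F0 = F0_init, Fmax = Fmax_init, sigma = sigma_init),
      lower = c(0, 0, 1e-8), upper = c(Inf, Inf, Inf),
      control = ctrl)
  }
  cf <- stats::coef(fit)
  if (!fit$convInfo$isConv)
    stop("single-turnover fit did not converge; last iterate: ",
         paste(names(cf), signif(cf, 6), sep = "=", collapse = ", "))
  res <- stats::residuals(fit)
  structure(
    list(F0 = unname(cf["F0"]), Fmax = unname(cf["Fmax"]),
         sigma_PSII = unname(cf["sigma"]),
         connectivity_p = if (fit_connectivity) unname(cf["p"]) else p,
         residual_rms = sqrt(mean(res^2)),
         light_state = x$light_state, background_E = x$background_E,
         fitted = stats::fitted(fit)),
    class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  cat("ST fit (", x$light_state, "): F0 = ", signif(x$F0, 5),
      ", Fmax = ", signif(x$Fmax, 5),
      ", sigma_PSII = ", signif(x$sigma_PSII, 5), " A2 RCII-1",
      ", rms = ", signif(x$residual_rms, 3), "\n", sep = "")
  invisible(x)
}

#' Maximum quantum yield of PSII photochemistry, Fv/Fm
#'
#' `Fv/Fm = (Fm - Fo) / Fm`, computed from the dark-regulated minimum and
#' maximum fluorescence yields.
#'
#' @param Fo,Fm Dark-regulated minimum and maximum fluorescence yields
#'   (instrument units), `0 < Fo <= Fm`.
#' @return Fv/Fm in `[0, 1)`.
#' @export
#' @examples
#' fvfm(200, 500) # 0.6
fvfm <- function(Fo, Fm) {
  if (any(!is.finite(Fo)) || any(!is.finite(Fm)) || any(Fo <= 0) || any(Fm <= 0))
    stop("Fo and Fm must be finite and positive")
  if (any(Fo > Fm))
    stop("Fo must not exceed Fm (got Fo = ", Fo[Fo > Fm][1],
         ", Fm = ", Fm[Fo > Fm][1], ")")
  (Fm - Fo) / Fm
}

#' Light-regulated minimum fluorescence yield Fo'
#'
#' Fo' is not measured directly; it is computed from the dark-regulated Fo,
#' the dark Fv/Fm and the light-regulated maximum Fm' as
#' `Fo' = Fo / (Fv/Fm + Fo/Fm')`. When Fm' equals the dark Fm the formula
#' collapses to Fo.
#'
#' @param Fo Dark-regulated minimum fluorescence yield, > 0.
#' @param FvFm Dark-regulated Fv/Fm, in (0, 1).
#' @param Fm_prime Light-regulated maximum fluorescence yield, > 0.
#' @return Fo' in instrument units.
#' @export
#' @examples
#' fo_prime(200, 0.6, 400) # 181.82
fo_prime <- function(Fo, FvFm, Fm_prime) {
  if (any(!is.finite(Fo)) || any(Fo <= 0)) stop("Fo must be positive")
  if (any(!is.finite(FvFm)) || any(FvFm <= 0) || any(FvFm >= 1))
    stop("FvFm must lie in (0, 1)")
  if (any(!is.finite(Fm_prime)) || any(Fm_prime <= 0))
    stop("Fm_prime must be positive")
  denom <- FvFm + Fo / Fm_prime
  if (any(denom == 0)) stop("zero denominator in Fo' formula")
  Fo / denom
}

#' Light-regulated chlorophyll-fluorescence parameters
#'
#' From the three light-regulated yields computes:
#' * `FqFv_prime` — photochemical quenching `Fq'/Fv' = (Fm'-F')/(Fm'-Fo')`,
#'   the fraction of functional RCII in the open state;
#' * `FvFm_prime` — `Fv'/Fm' = (Fm'-Fo')/Fm'`, the efficiency of excitation
#'   capture by open RCII;
#' * `FqFm_prime` — `Fq'/Fm' = (Fm'-F')/Fm'`, the operating quantum
#'   efficiency of PSII (Phi_PSII'), identically the product of the first two;
#' * `NPQ_NSV` — normalised Stern-Volmer non-photochemical quenching,
#'   `(Fm'/Fv') - 1 = Fo'/Fv'`.
#'
#' Noise can push F' slightly below Fo'; with `clamp = TRUE` (default) the
#' quenching ratios are clamped to `[0, 1]` with a warning instead of failing.
#'
#' @param Fo_prime,F_prime,Fm_prime Light-regulated yields, with
#'   `Fm' > Fo' > 0` and (up to noise) `Fo' <= F' <= Fm'`.
#' @param clamp Clamp out-of-range ratios caused by noisy yields.
#' @return A one-row data.frame with columns `FqFv_prime`, `FvFm_prime`,
#'   `FqFm_prime`, `NPQ_NSV`.
#' @export
#' @examples
#' light_params(150, 250, 350)
light_params <- function(Fo_prime, F_prime, Fm_prime, clamp = TRUE) {
  if (any(!is.finite(c(Fo_prime, F_prime, Fm_prime))))
    stop("yields must be finite")
  if (any(Fo_prime <= 0)) stop("Fo' must be positive")
  if (any(Fm_prime <= Fo_prime))
    stop("Fm' must exceed Fo' (Fv' would be non-positive)")
  if (any(F_prime > Fm_prime))
    stop("F' must not exceed Fm'")
  Fv_prime <- Fm_prime - Fo_prime
  fqfv <- (Fm_prime - F_prime) / Fv_prime
  if (any(fqfv > 1)) {
    if (!clamp) stop("F' below Fo': Fq'/Fv' > 1")
    warning("F' below Fo' (noisy step); clamping Fq'/Fv' to 1")
    fqfv <- pmin(fqfv, 1)
  }
  data.frame(
    FqFv_prime = fqfv,
    FvFm_prime = Fv_prime / Fm_prime,
    FqFm_prime = pmin((Fm_prime - F_prime) / Fm_prime, Fv_prime / Fm_prime),
    NPQ_NSV = Fo_prime / Fv_prime)
}

#' All chlorophyll-fluorescence parameters from the five yields
#'
#' Convenience wrapper: derives Fo' from (Fo, Fv/Fm, Fm'), then the dark and
#' light-regulated parameters in one tidy row.
#'
#' @param Fo,Fm Dark-regulated yields.
#' @param F_prime,Fm_prime Light-regulated yields.
#' @param background_E Background irradiance of the light step.
#' @inheritParams light_params
#' @return One-row data.frame: `background_E, Fo, Fm, Fprime, Fmprime,
#'   Foprime, FvFm, FqFv_prime, FvFm_prime, FqFm_prime, NPQ_NSV`.
#' @export
chlf_params <- function(Fo, Fm, F_prime, Fm_prime, background_E = NA,
                        clamp = TRUE) {
  fv <- fvfm(Fo, Fm)
  fop <- fo_prime(Fo, fv, Fm_prime)
  lp <- light_params(fop, F_prime, Fm_prime, clamp = clamp)
  cbind(data.frame(background_E = background_E, Fo = Fo, Fm = Fm,
                   Fprime = F_prime, Fmprime = Fm_prime, Foprime = fop,
                   FvFm = fv),
        lp)
}

#' Read a single-turnover transient from CSV
#'
#' Expects columns `time_us, flux_quanta_per_A2_us, fluorescence` with
#' optional `#`-prefixed metadata header lines (`# light_state=dark`,
#' `# background_E=155`).
#'
#' @param file Path to the CSV file.
#' @return An [st_transient].
#' @export
read_st_transient <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(light_state = "dark", background_E = 0)
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  state <- if (startsWith(as.character(meta$light_state), "dark"))
    "dark_regulated" else "light_regulated"
  st_transient(df$time_us, df$flux_quanta_per_A2_us, df$fluorescence,
               light_state = state,
               background_E = as.numeric(meta$background_E))
}

#' Write a single-turnover transient to CSV
#'
#' Inverse of [read_st_transient()].
#'
#' @param x An [st_transient].
#' @param file Output path.
#' @export
write_st_transient <- function(x, file) {
  stopifnot(inherits(x, "st_transient"))
  state <- if (x$light_state == "dark_regulated") "dark" else "light"
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# light_state=", state),
               paste0("# background_E=", x$background_E)), con)
  utils::write.csv(
    data.frame(time_us = x$time_us,
               flux_quanta_per_A2_us = x$flux,
               fluorescence = x$fluorescence),
    con, row.names = FALSE, quote = FALSE)
}
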