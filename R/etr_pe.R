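# ETR_RCII, Jassby-Platt PE-curve fitting with photoinhibition exclusion,
# 14C assimilation rates and the electron:carbon conversion factor.

#' Electron transport rate per PSII reaction centre
#'
#' `ETR_RCII = E * sigma_PSII' * Fq'/Fv' * 6.022e-3`, in
#' mol e- mol RCII^-1 s^-1: irradiance times the light-regulated functional
#' absorption cross-section times the fraction of open reaction centres,
#' with the unit constant collapsing umol quanta -> quanta, A^2 -> m^2 and
#' RC -> mol RC (see [etr_unit_constant()]).
#'
#' @param E Irradiance, umol quanta m^-2 s^-1, >= 0.
#' @param sigma_prime Light-regulated sigma_PSII', A^2 RCII^-1, >= 0.
#' @param fqfv_prime Fq'/Fv', in `[0, 1]`.
#' @return ETR_RCII, mol e- mol RCII^-1 s^-1. Linear in each argument.
#' @export
#' @examples
#' etr_rcii(155, 500, 0.6) # 280.02
etr_rcii <- function(E, sigma_prime, fqfv_prime) {
  if (any(!is.finite(c(E, sigma_prime, fqfv_prime))) ||
      any(E < 0) || any(sigma_prime < 0) || any(fqfv_prime < 0))
    stop("all inputs must be finite and non-negative")
  if (any(fqfv_prime > 1)) stop("Fq'/Fv' cannot exceed 1")
  E * sigma_prime * fqfv_prime * etr_unit_constant()
}

#' Jassby-Platt saturating photosynthesis-irradiance model
#'
#' `P(E) = Pmax * tanh(alpha * E / Pmax)`: linear with slope alpha at
#' sub-saturating light, saturating at Pmax, with light-saturation parameter
#' `Ek = Pmax / alpha`.
#'
#' @param E Irradiance, umol quanta m^-2 s^-1.
#' @param alpha Initial slope (rate units per umol quanta m^-2 s^-1), > 0.
#' @param Pmax Light-saturated maximum rate, > 0.
#' @return Modelled rate at each `E`.
#' @export
jassby_platt <- function(E, alpha, Pmax) {
  Pmax * tanh(alpha * E / Pmax)
}

#' Construct a PE curve
#'
#' @param E Irradiances (umol quanta m^-2 s^-1), >= 0, at least 5 points.
#' @param rate Measured rate at each irradiance: ETR_RCII
#'   (mol e- mol RCII^-1 s^-1) or 14C assimilation (g C g Chla^-1 h^-1).
#' @param rate_type `"ETR"` or `"C14"`.
#' @param replicate_id Identifier for the biological replicate.
#' @return A data.frame of class `pe_curve`.
#' @export
pe_curve <- function(E, rate, rate_type = c("ETR", "C14"), replicate_id = 1L) {
  rate_type <- match.arg(rate_type)
  if (length(E) != length(rate) || length(E) < 5L)
    stop("a PE curve needs >= 5 paired (E, rate) observations")
  if (any(!is.finite(E)) || any(E < 0)) stop("E must be finite and >= 0")
  if (any(!is.finite(rate))) stop("rates must be finite")
  structure(
    data.frame(replicate_id = replicate_id, rate_type = rate_type,
               E = as.numeric(E), rate = as.numeric(rate)),
    class = c("pe_curve", "data.frame"))
}

#' Fit the Jassby-Platt model to a PE curve
#'
#' Bounded nonlinear least squares of `P(E) = Pmax * tanh(alpha*E/Pmax)`,
#' initialised from the OLS slope over the lowest irradiances (alpha) and
#' the maximum observed rate (Pmax). Optionally excludes photoinhibited
#' points before the final fit: photoinhibition depresses the
#' highest-irradiance tail, so candidate exclusions are suffixes of the
#' irradiance-sorted points. Scanning from the longest feasible suffix
#' down, a suffix is excluded when, against the fit to the remaining
#' points, every suffix point lies above the saturation irradiance Ek and
#' falls below the fitted curve by more than twice the residual RMS. Clean
#' data exclude nothing (the rule is idempotent).
#'
#' @param curve A [pe_curve] or data.frame with columns `E` and `rate`.
#' @param exclude_photoinhibition Apply the iterative high-light exclusion
#'   rule before the final fit.
#' @param min_points Minimum usable points after exclusion (default 4).
#' @return List of class `pe_fit`: `alpha`, `Pmax`, `Ek` (= Pmax/alpha),
#'   `excluded_points` (integer indices into the input), `residual_rms`,
#'   `n_used`, plus the data actually fitted.
#' @export
#' @examples
#' E <- c(5, 10, 25, 50, 100, 200, 400, 700)
#' fit_pe(pe_curve(E, jassby_platt(E, 0.5, 100)))
fit_pe <- function(curve, exclude_photoinhibition = FALSE, min_points = 4L) {
  if (!all(c("E", "rate") %in% names(curve)))
    stop("curve must have columns E and rate")
  E <- curve$E
  rate <- curve$rate
  if (length(E) < 5L) stop("a PE curve needs >= 5 points")
  keep <- seq_along(E)
  excluded <- integer(0)
  if (exclude_photoinhibition) {
    ord <- order(E)                       # candidate suffixes in E order
    n <- length(E)
    for (j in seq(n - 3L, 0L)) {
      if (j == 0L) break
      suffix <- ord[(n - j + 1L):n]
      rest <- ord[1L:(n - j)]
      cur <- tryCatch(pe_nls(E[rest], rate[rest]), error = function(e) NULL)
      if (is.null(cur)) next
      pred <- jassby_platt(E[suffix], cur$alpha, cur$Pmax)
      resid <- rate[suffix] - pred
      qualifies <- all(E[suffix] > cur$Ek) &&
        all(resid < -2 * max(cur$rms, 0))
      if (qualifies) {
        if (n - j < min_points)
          stop("insufficient data: fewer than ", min_points,
               " points would remain after photoinhibition exclusion")
        excluded <- suffix
        keep <- rest
        break
      }
    }
  }
  final <- pe_nls(E[keep], rate[keep])
  structure(
    list(alpha = final$alpha, Pmax = final$Pmax, Ek = final$Ek,
         excluded_points = sort(excluded),
         residual_rms = final$rms, n_used = length(keep),
         E = E[keep], rate = rate[keep],
         rate_type = if ("rate_type" %in% names(curve))
           as.character(curve$rate_type[1]) else NA_character_),
    class = "pe_fit")
}

# Core tanh least squares with deterministic initialisation.
pe_nls <- function(E, rate) {
  ord <- order(E)
  nlow <- max(3L, ceiling(length(E) / 3))
  low <- ord[seq_len(nlow)]
  alpha0 <- tryCatch(
    sum(E[low] * rate[low]) / sum(E[low]^2),
    error = function(e) NA_real_)
  Pmax0 <- max(rate)
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- Pmax0 / max(E)
  if (Pmax0 <= 0) stop("rates must include positive values")
  dat <- data.frame(E = E, rate = rate)
  fit <- minpack.lm::nlsLM(
    rate ~ Pmax * tanh(alpha * E / Pmax), data = dat,
    start = list(alpha = alpha0, Pmax = Pmax0),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv)
    stop("PE fit did not converge; last iterate: ",
         paste(names(stats::coef(fit)), signif(stats::coef(fit), 6),
               sep = "=", collapse = ", "))
  cf <- stats::coef(fit)
  list(alpha = unname(cf["alpha"]), Pmax = unname(cf["Pmax"]),
       Ek = unname(cf["Pmax"] / cf["alpha"]),
       rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' @export
print.pe_fit <- function(x, ...) {
  cat("Jassby-Platt fit",
      if (!is.na(x$rate_type)) paste0(" (", x$rate_type, ")"), ":\n", sep = "")
  cat("  alpha =", signif(x$alpha, 5), " Pmax =", signif(x$Pmax, 5),
      " Ek =", signif(x$Ek, 5), "\n")
  if (length(x$excluded_points))
    cat("  excluded (photoinhibited):", x$excluded_points, "\n")
  invisible(x)
}

#' @export
predict.pe_fit <- function(object, E, ...) {
  jassby_platt(E, object$alpha, object$Pmax)
}

#' 14C carbon-assimilation rate from scintillation counts
#'
#' Standard 14C uptake computation: the assimilated fraction of the added
#' label times the dissolved inorganic carbon pool, with the conventional
#' 1.05 isotope-discrimination factor, normalised to Chla and incubation
#' time: `rate = (dpm_sample/dpm_total) * DIC * 12 * 1.05 / (Chla * t)`.
#'
#' @param dpm_sample Acidified sample counts (dpm), `0 <= dpm_sample`.
#' @param dpm_total Total added activity (dpm), `> dpm_sample`.
#' @param dic Dissolved inorganic carbon, mol C L^-1.
#' @param duration_h Incubation length, hours.
#' @param chla Chla concentration, g L^-1.
#' @return Rate in g C g Chla^-1 h^-1.
#' @export
#' @examples
#' c14_assim_rate(100, 10000, 2e-3, 1, 1e-6) # 252
c14_assim_rate <- function(dpm_sample, dpm_total, dic, duration_h, chla) {
  if (any(dpm_sample < 0) || any(dpm_total <= dpm_sample))
    stop("need 0 <= dpm_sample < dpm_total")
  if (any(dic <= 0) || any(duration_h <= 0) || any(chla <= 0))
    stop("dic, duration and chla must be positive")
  (dpm_sample / dpm_total) * dic * C_MOLAR_MASS * C14_DISCRIMINATION /
    (chla * duration_h)
}

# g C g Chla^-1 h^-1  ->  mol C mol Chla^-1 s^-1
cassim_to_molar <- function(rate_gC_gChla_h) {
  rate_gC_gChla_h * CHLA_MOLAR_MASS / C_MOLAR_MASS / 3600
}

#' Electron:carbon conversion factor
#'
#' Ratio of ETR_RCII (mol e- mol RCII^-1 s^-1) to Chla-normalised
#' C assimilation at the same irradiance. The 14C rate, measured in
#' g C g Chla^-1 h^-1, is first brought to mol C mol Chla^-1 s^-1 using the
#' molar masses of Chla (893.5 g mol^-1) and carbon (12 g mol^-1). The
#' resulting factor conflates the electron requirement per carbon fixed
#' (Phi_e:C) and the Chla associated with each RCII (1/n_PSII); the two are
#' not separable from these data.
#'
#' @param etr_at_E ETR_RCII at the reference irradiance,
#'   mol e- mol RCII^-1 s^-1, > 0.
#' @param cassim_at_E C-assimilation rate at the same irradiance, > 0, in
#'   the units named by `cassim_units`.
#' @param cassim_units `"gC_gChla_h"` (default; converted internally) or
#'   `"molC_molChla_s"` (used as is).
#' @return The conversion factor,
#'   (mol e- mol RCII^-1 s^-1) / (mol C mol Chla^-1 s^-1).
#' @export
conversion_factor <- function(etr_at_E, cassim_at_E,
                              cassim_units = c("gC_gChla_h",
                                               "molC_molChla_s")) {
  cassim_units <- match.arg(cassim_units)
  if (any(etr_at_E <= 0) || any(cassim_at_E <= 0))
    stop("rates must be positive")
  cas <- if (cassim_units == "gC_gChla_h")
    cassim_to_molar(cassim_at_E) else cassim_at_E
  etr_at_E / cas
}

#' Read a PE table from CSV
#'
#' Schema: `replicate_id, rate_type, E_umol_quanta_m2_s, rate` (an optional
#' `rate_units` column is carried through untouched).
#'
#' @param file CSV path.
#' @return data.frame with columns `replicate_id, rate_type, E, rate`.
#' @export
read_pe_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("replicate_id", "rate_type", "E_umol_quanta_m2_s", "rate")
  if (!all(need %in% names(df)))
    stop("PE CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(replicate_id = df$replicate_id,
                    rate_type = df$rate_type,
                    E = df$E_umol_quanta_m2_s, rate = df$rate)
  out
}

#' Fit every replicate PE curve in a table and average the parameters
#'
#' Fits each `(replicate_id, rate_type)` group separately, then averages
#' alpha and Pmax across replicates of the same rate type (duplicate curves
#' per biological replicate are fitted individually, not pooled); `Ek` of
#' the average is recomputed as `mean(Pmax)/mean(alpha)`.
#'
#' @param pe data.frame with columns `replicate_id, rate_type, E, rate`.
#' @inheritParams fit_pe
#' @return List with `fits` (per-replicate report data.frame) and `mean`
#'   (per rate type: alpha, Pmax, Ek).
#' @export
fit_pe_table <- function(pe, exclude_photoinhibition = FALSE) {
  groups <- split(pe, list(pe$rate_type, pe$replicate_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    f <- fit_pe(g, exclude_photoinhibition = exclude_photoinhibition)
    data.frame(replicate_id = g$replicate_id[1],
               rate_type = as.character(g$rate_type[1]),
               alpha = f$alpha, Pmax = f$Pmax, Ek = f$Ek,
               n_excluded = length(f$excluded_points),
               residual_rms = f$residual_rms)
  })
  fits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mean_tab <- do.call(rbind, lapply(split(fits, fits$rate_type), function(g) {
    data.frame(rate_type = g$rate_type[1], alpha = mean(g$alpha),
               Pmax = mean(g$Pmax), Ek = mean(g$Pmax) / mean(g$alpha),
               n_rep = nrow(g))
  }))
  rownames(mean_tab) <- NULL
  list(fits = fits, mean = mean_tab)
}
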