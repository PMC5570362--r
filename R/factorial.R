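# 2x2x2 factorial linear model (Strain x Fe x Cu) and post-hoc
# simple-main-effect contrasts against the pooled full-model error.

#' Fit the factorial cell-means model for one physiological parameter
#'
#' Fits the full-factorial linear model of a measured parameter on the
#' three design factors strain, Fe level and Cu level (all two-level).
#' The full parameterisation is equivalent to a cell-means model, so it
#' provides the cell means, the pooled within-cell variance (the model MSE)
#' and the residual degrees of freedom that the simple-main-effect
#' contrasts need.
#'
#' @param data data.frame with columns `strain`, `fe_level`, `cu_level`,
#'   `value`, and optionally `parameter` (filtered by `parameter` if given).
#' @param parameter Optional parameter name to subset on.
#' @return List of class `factorial_fit`: `model` (the `lm`), `cells`
#'   (per-cell n, mean, variance), `mse`, `df_residual`, `data`.
#' @export
#' @examples
#' d <- gen_physio_table("FvFm", seed = 1)
#' fit_factorial(d)
fit_factorial <- function(data, parameter = NULL) {
  if (!is.null(parameter)) {
    if (!"parameter" %in% names(data)) stop("no parameter column to filter")
    data <- data[data$parameter == parameter, , drop = FALSE]
    if (!nrow(data)) stop("no rows for parameter ", parameter)
  }
  need <- c("strain", "fe_level", "cu_level", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(data$value))) stop("values must be finite")
  data$strain <- factor(data$strain)
  data$fe_level <- factor(data$fe_level)
  data$cu_level <- factor(data$cu_level)
  cells <- stats::aggregate(value ~ strain + fe_level + cu_level, data = data,
                            FUN = function(v) c(n = length(v), mean = mean(v),
                                                var = stats::var(v)))
  cells <- do.call(data.frame, cells)
  names(cells) <- c("strain", "fe_level", "cu_level", "n", "mean", "var")
  if (any(cells$n < 2))
    stop("every non-empty design cell needs >= 2 replicates")
  model <- stats::lm(value ~ strain * fe_level * cu_level, data = data)
  df_res <- model$df.residual
  mse <- sum(stats::residuals(model)^2) / df_res
  structure(list(model = model, cells = cells, mse = mse,
                 df_residual = df_res, data = data),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("Factorial cell-means fit:", nrow(x$cells), "cells,",
      nrow(x$data), "observations; pooled MSE =", signif(x$mse, 5),
      "on", x$df_residual, "df\n")
  invisible(x)
}

#' Simple-main-effect contrast at fixed factor levels
#'
#' Tests the effect of one factor while the other factors are held at fixed
#' levels — e.g. the low-Cu response within strain TO03 at high Fe compares
#' the (TO03, high Fe, high Cu) and (TO03, high Fe, low Cu) cell means. The
#' difference is tested with an F statistic using the factorial model's
#' pooled error variance and residual degrees of freedom (the Welch
#' alternative uses the two cells' own variances with Satterthwaite df).
#'
#' @param fit A [fit_factorial()] result.
#' @param vary Factor to contrast: `"strain"`, `"fe_level"` or `"cu_level"`.
#' @param fixed Named character vector fixing the other two factors, e.g.
#'   `c(strain = "TO03", fe_level = "high")`.
#' @param error `"pooled"` (default) or `"welch"`.
#' @return One-row data.frame of class `contrast_result`: `vary`, `fixed`,
#'   `level_1`, `level_2`, `estimate` (mean at `level_2` minus mean at
#'   `level_1`, levels in factor order), `F`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' d <- gen_physio_table("FvFm", seed = 1)
#' simple_main_effect(fit_factorial(d), vary = "cu_level",
#'                    fixed = c(strain = "TO03", fe_level = "high"))
simple_main_effect <- function(fit, vary,
                               fixed, error = c("pooled", "welch")) {
  stopifnot(inherits(fit, "factorial_fit"))
  error <- match.arg(error)
  factors <- c("strain", "fe_level", "cu_level")
  if (!vary %in% factors) stop("vary must be one of: ",
                               paste(factors, collapse = ", "))
  others <- setdiff(factors, vary)
  if (!all(others %in% names(fixed)))
    stop("fixed must name levels for: ", paste(others, collapse = ", "))
  cells <- fit$cells
  sel <- rep(TRUE, nrow(cells))
  for (f in others) sel <- sel & cells[[f]] == fixed[[f]]
  sub <- cells[sel, , drop = FALSE]
  lv <- levels(fit$data[[vary]])
  if (length(lv) != 2) stop("factor ", vary, " must have exactly two levels")
  c1 <- sub[sub[[vary]] == lv[1], , drop = FALSE]
  c2 <- sub[sub[[vary]] == lv[2], , drop = FALSE]
  if (nrow(c1) != 1 || nrow(c2) != 1)
    stop("missing design cell for ", vary, " contrast at ",
         paste(names(fixed), fixed, sep = "=", collapse = ", "))
  est <- c2$mean - c1$mean
  if (error == "pooled") {
    se2 <- fit$mse * (1 / c1$n + 1 / c2$n)
    df2 <- fit$df_residual
  } else {
    se2 <- c1$var / c1$n + c2$var / c2$n
    df2 <- se2^2 / ((c1$var / c1$n)^2 / (c1$n - 1) +
                    (c2$var / c2$n)^2 / (c2$n - 1))
  }
  Fstat <- if (se2 == 0) {
    if (est == 0) 0 else Inf
  } else est^2 / se2
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(
    data.frame(vary = vary,
               fixed = paste(names(fixed), fixed, sep = "=", collapse = ","),
               level_1 = lv[1], level_2 = lv[2],
               estimate = est, F = Fstat, df1 = 1, df2 = df2, p_value = p),
    class = c("contrast_result", "data.frame"))
}

#' Read a tidy physiology table from CSV
#'
#' Schema: `strain, fe_level, cu_level, replicate, parameter, value`.
#'
#' @param file CSV path.
#' @return data.frame in the [fit_factorial()] input schema.
#' @export
read_physio_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("strain", "fe_level", "cu_level", "replicate", "parameter",
            "value")
  if (!all(need %in% names(df)))
    stop("physiology CSV must have columns: ", paste(need, collapse = ", "))
  df
}
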