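#' Forecast accuracy metrics: RMSE, GCV, MAPE and relative error
#'
#' \deqn{RMSE = \sqrt{\sum e_i^2 / N_v}, \quad
#'       GCV = RMSE / (1 - K/N_v)^2, \quad
#'       MAPE = 100 \sum |e_i / x_i| / N_v}
#' with \eqn{e_i = x_i - \hat x_i}; `re_series` holds the per-point
#' relative errors \eqn{e_i / x_i} and `re_sum` their sum. GCV inflates
#' the RMSE by a penalty on the regressor width K relative to the test
#' size, and tends to the RMSE as \eqn{N_v \to \infty}.
#'
#' @param observed,predicted test targets and one-step-ahead forecasts
#'   (equal length, at least 2 points).
#' @param K regressor width used by the model, `K < length(observed)`.
#' @return object of class `metrics_report`: list with `rmse`, `gcv`,
#'   `mape_percent`, `re_series`, `re_sum`, `Nv`, `K`.
#' @export
forecast_metrics <- function(observed, predicted, K) {
  x <- validate_series(observed, min_len = 2L, arg = "observed")
  xhat <- validate_series(predicted, min_len = 2L, arg = "predicted")
  if (length(x) != length(xhat)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  K <- validate_count(K, min = 1L)
  Nv <- length(x)
  if (Nv <= K) {
    stop(sprintf("GCV undefined: Nv = %d <= K = %d", Nv, K), call. = FALSE)
  }
  if (any(x == 0)) {
    stop("MAPE/RE undefined: observed value(s) equal zero at index ",
         paste(which(x == 0), collapse = ", "), call. = FALSE)
  }
  e <- x - xhat
  rmse <- sqrt(sum(e^2) / Nv)
  re <- e / x
  structure(
    list(rmse = rmse,
         gcv = rmse / (1 - K / Nv)^2,
         mape_percent = 100 * sum(abs(re)) / Nv,
         re_series = re,
         re_sum = sum(re),
         Nv = Nv, K = K),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RMSE %.6g | GCV %.6g | MAPE %.4g%% (Nv = %d, K = %d)\n",
              x$rmse, x$gcv, x$mape_percent, x$Nv, x$K))
  invisible(x)
}

#' Share of test points with relative error inside a band
#'
#' Inclusive comparison: a point with \eqn{|e_i / x_i|} exactly equal to
#' the band edge counts as inside.
#'
#' @param metrics a `metrics_report`.
#' @param band half-width of the relative-error band (e.g. 0.015 for
#'   plus or minus 1.5 percent).
#' @return fraction in \[0, 1\].
#' @export
re_band_fraction <- function(metrics, band) {
  stopifnot(inherits(metrics, "metrics_report"), band > 0)
  mean(abs(metrics$re_series) <= band)
}

#' Residual autocorrelations with 95% whiteness bounds
#'
#' Sample autocorrelations (mean-centred, normalised by the lag-0
#' variance with the biased divide-by-N estimator) for lags 1..max_lag,
#' with the usual white-noise confidence limit \eqn{\pm 1.96/\sqrt N}.
#' `white` is `TRUE` when every reported lag falls inside the limit —
#' the residuals show no serial correlation at the 5% level.
#'
#' @param residuals numeric residual series.
#' @param max_lag highest lag to report, `< length(residuals)`.
#' @return object of class `acf_report`: `lags`, `coefficients`,
#'   `conf_limit`, `white`, `N`.
#' @export
acf_with_bounds <- function(residuals, max_lag = 20) {
  r <- validate_series(residuals, min_len = 3L, arg = "residuals")
  max_lag <- validate_count(max_lag, min = 1L)
  N <- length(r)
  if (max_lag >= N) {
    stop(sprintf("max_lag = %d must be < N = %d", max_lag, N), call. = FALSE)
  }
  if (stats::var(r) == 0) {
    stop("zero-variance residuals: ACF undefined", call. = FALSE)
  }
  rho <- as.numeric(stats::acf(r, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  lim <- 1.96 / sqrt(N)
  structure(
    list(lags = seq_len(max_lag), coefficients = rho, conf_limit = lim,
         white = all(abs(rho) < lim), N = N),
    class = "acf_report"
  )
}

#' @export
print.acf_report <- function(x, ...) {
  cat(sprintf("residual ACF (N = %d, limit +/- %.4f): %s\n", x$N,
              x$conf_limit,
              if (x$white) "white (no serial correlation)" else
                paste("lags outside limit:",
                      paste(x$lags[abs(x$coefficients) >= x$conf_limit],
                            collapse = ", "))))
  invisible(x)
}

#' Pitman's pairwise test of forecast-error variances
#'
#' Tests whether two competing forecasters have equal error variance by
#' correlating the pointwise sum and difference of their one-step-ahead
#' errors: with \eqn{\Upsilon = e_1 + e_2} and \eqn{\Psi = e_1 - e_2},
#' \eqn{cov(\Upsilon, \Psi) = var(e_1) - var(e_2)}, so a correlation
#' significantly different from zero signals unequal accuracy. The 5%
#' critical value is \eqn{1.96/\sqrt{N_v}}; a negative significant
#' correlation means model 1 has the smaller error variance.
#'
#' @param e1,e2 forecast-error vectors of equal length `Nv >= 3`.
#' @return object of class `pitman_comparison`: `corr`, `threshold`,
#'   `significant`, `winner` (`"model1"`, `"model2"` or `NA`), `Nv`,
#'   `degenerate` (`TRUE` when either combination has zero variance, in
#'   which case `corr` is `NA` and the test is flagged, not an error).
#' @export
pitman_test <- function(e1, e2) {
  e1 <- validate_series(e1, min_len = 3L, arg = "e1")
  e2 <- validate_series(e2, min_len = 3L, arg = "e2")
  if (length(e1) != length(e2)) {
    stop("error vectors must have equal length", call. = FALSE)
  }
  Nv <- length(e1)
  up <- e1 + e2
  ps <- e1 - e2
  threshold <- 1.96 / sqrt(Nv)
  if (stats::sd(up) == 0 || stats::sd(ps) == 0) {
    return(structure(
      list(corr = NA_real_, threshold = threshold, significant = FALSE,
           winner = NA_character_, Nv = Nv, degenerate = TRUE),
      class = "pitman_comparison"
    ))
  }
  corr <- stats::cor(up, ps)
  significant <- abs(corr) > threshold
  winner <- if (!significant) NA_character_ else
    if (corr < 0) "model1" else "model2"
  structure(
    list(corr = corr, threshold = threshold, significant = significant,
         winner = winner, Nv = Nv, degenerate = FALSE),
    class = "pitman_comparison"
  )
}

#' @export
print.pitman_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("Pitman test: degenerate (zero variance in sum or difference)\n")
  } else {
    cat(sprintf("Pitman corr = %.4f, critical %.4f (Nv = %d): %s\n",
                x$corr, x$threshold, x$Nv,
                if (!x$significant) "no significant difference" else
                  sprintf("%s more accurate", x$winner)))
  }
  invisible(x)
}
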