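#' Generate a synthetic weekly injury-count-like series
#'
#' Stands in for undeposited surveillance data: a strictly positive
#' series with a slowly varying trend, annual-type periodic structure
#' and irregular high-frequency fluctuation,
#' \deqn{x_t = base + trend\_amp \cdot g(t/n) +
#'       seas\_amp \cdot \sin(2\pi t / seas\_period) + \epsilon_t,}
#' where g is the smoothstep ramp \eqn{u^2 (3 - 2u)} and
#' \eqn{\epsilon_t \sim N(0, noise\_sd^2)} (or, with `noise =
#' "poisson"`, `x_t` is Poisson with the deterministic part as mean).
#' The configuration is validated so the deterministic floor minus a
#' 5-sigma noise margin stays positive; values are never clipped.
#'
#' @param n series length (default 531, ten years of weekly records).
#' @param base mean level of the counts.
#' @param trend_amp amplitude of the slow monotone trend.
#' @param seas_period seasonal period in sampling intervals (default 52
#'   weeks).
#' @param seas_amp seasonal amplitude.
#' @param noise_sd standard deviation of the Gaussian fluctuation.
#' @param seed RNG seed or `NULL`.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @return numeric series of length n with attribute `deterministic`
#'   holding the noise-free curve.
#' @export
generate_accident_series <- function(n = 531, base = 50, trend_amp = 15,
                                     seas_period = 52, seas_amp = 8,
                                     noise_sd = 4, seed = NULL,
                                     noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  n <- validate_count(n, min = 3L)
  seas_period <- validate_count(seas_period, min = 2L)
  if (trend_amp < 0 || seas_amp < 0 || noise_sd < 0) {
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)
  }
  floor_det <- base - seas_amp   # g ramp is non-negative
  margin <- if (noise == "gaussian") 5 * noise_sd else 0
  if (floor_det - margin <= 0) {
    stop(sprintf(paste0("configuration implies non-positive values: ",
                        "base - seas_amp - 5*noise_sd = %.3f <= 0"),
                 floor_det - margin), call. = FALSE)
  }
  t <- seq_len(n)
  u <- t / n
  det <- base + trend_amp * u^2 * (3 - 2 * u) +
    seas_amp * sin(2 * pi * t / seas_period)
  if (!is.null(seed)) set.seed(seed)
  x <- switch(noise,
              gaussian = det + stats::rnorm(n, 0, noise_sd),
              poisson = as.numeric(stats::rpois(n, det)))
  attr(x, "deterministic") <- det
  x
}

#' Generate a seeded ARMA series
#'
#' Standard ARMA(p, q) recursion
#' \eqn{x_t = \sum_i \alpha_i x_{t-i} + \epsilon_t + \sum_j \beta_j
#' \epsilon_{t-j}} with Gaussian innovations, run past a burn-in so the
#' returned segment is (approximately) stationary. Used as the
#' parameter-recovery oracle for the conditional-sum-of-squares fitter.
#'
#' @param alpha AR coefficients (may be empty); the AR polynomial must
#'   have all roots outside the unit circle.
#' @param beta MA coefficients (may be empty).
#' @param n length of the returned series.
#' @param noise_sd innovation standard deviation.
#' @param burn_in discarded initial observations (default 100).
#' @param seed RNG seed or `NULL`.
#' @return numeric series of length n.
#' @export
generate_arma_series <- function(alpha = numeric(0), beta = numeric(0),
                                 n = 1000, noise_sd = 1, burn_in = 100,
                                 seed = NULL) {
  n <- validate_count(n, min = 1L)
  burn_in <- validate_count(burn_in, min = 0L)
  if (length(alpha)) {
    roots <- polyroot(c(1, -alpha))
    if (any(Mod(roots) <= 1 + 1e-10)) {
      stop("non-stationary AR coefficients (root inside the unit circle)",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  total <- n + burn_in
  eps <- stats::rnorm(total, 0, noise_sd)
  # MA part first (finite filter), then AR recursion
  ma <- eps
  for (j in seq_along(beta)) {
    ma <- ma + beta[j] * c(rep(0, j), utils::head(eps, total - j))
  }
  x <- if (length(alpha)) {
    as.numeric(stats::filter(ma, alpha, method = "recursive"))
  } else {
    ma
  }
  utils::tail(x, n)
}
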