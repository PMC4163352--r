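#' Iterated first differences
#'
#' Applies the first-difference operator d times; the result has length
#' `length(x) - d`. `d = 0` returns the input unchanged.
#'
#' @param x numeric series.
#' @param d non-negative integer differencing order, `d < length(x)`.
#' @return numeric vector of length `length(x) - d`.
#' @export
difference <- function(x, d) {
  x <- validate_series(x, min_len = 1L)
  d <- validate_count(d, min = 0L)
  if (d >= length(x)) {
    stop(sprintf("differencing order d = %d >= series length %d", d,
                 length(x)), call. = FALSE)
  }
  for (i in seq_len(d)) x <- diff(x)
  x
}

# conditional-sum-of-squares residual recursion:
# e_t = r_t - sum_i beta_i e_{t-i}, e pre-history zero.
# stats::filter(recursive) computes y_t = x_t + sum f_i y_{t-i}, so f = -beta.
css_residuals <- function(r, beta) {
  if (length(beta) == 0L) return(r)
  as.numeric(stats::filter(r, -beta, method = "recursive"))
}

#' Fit a linear forecaster with moving-average error terms
#'
#' Fits \eqn{\hat x_t = \sum_i \alpha_i z_i(t) + \sum_i \beta_i e_{t-i}}
#' where z(t) is the lagged (smoothed) regressor row for target t. This
#' is a regression with MA(Q) errors, not a standard ARIMA: the
#' autoregressive structure lives in the regressor matrix, which the
#' caller builds from the smoothed series. Estimation is by conditional
#' sum of squares (errors before the sample start are taken as zero):
#' alpha is initialised by ordinary least squares, beta at zero, then
#' both are minimised jointly by BFGS. With `Q = 0` the fit reduces
#' exactly to OLS.
#'
#' @param train a `regressor_set` of training rows.
#' @param Q moving-average order (number of lagged error terms),
#'   non-negative; default 0.
#' @param reltol,maxit optimiser tolerance and iteration cap (defaults
#'   1e-8 and 500); the fit is deterministic for identical input.
#' @return object of class `linear_ma_fit`: `alpha` (length K), `beta`
#'   (length Q), `residuals` (one per training row), `css` (criterion
#'   value), `K`, `Q`, `convergence` (optim code).
#' @export
fit_linear_ma <- function(train, Q = 0, reltol = 1e-8, maxit = 500) {
  stopifnot(inherits(train, "regressor_set"))
  Q <- validate_count(Q, min = 0L)
  X <- train$X
  y <- train$y
  K <- ncol(X)
  m <- nrow(X)
  if (m < K + Q + 5L) {
    stop(sprintf("too few rows (%d) for K = %d regressors + Q = %d MA terms",
                 m, K, Q), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < K) {
    warning("rank-deficient regressor matrix; using pseudo-inverse solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    alpha0 <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    alpha0 <- as.numeric(alpha0)
  } else {
    alpha0 <- qr.coef(qrX, y)
  }
  if (Q == 0L) {
    res <- y - as.numeric(X %*% alpha0)
    fit <- list(alpha = as.numeric(alpha0), beta = numeric(0),
                residuals = res, css = sum(res^2), K = K, Q = 0L,
                convergence = 0L)
    class(fit) <- "linear_ma_fit"
    return(fit)
  }
  obj <- function(par) {
    a <- par[seq_len(K)]
    b <- par[K + seq_len(Q)]
    e <- css_residuals(y - as.numeric(X %*% a), b)
    s <- sum(e^2)
    if (!is.finite(s)) s <- .Machine$double.xmax
    s
  }
  opt <- stats::optim(c(alpha0, rep(0, Q)), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (!is.finite(opt$value)) {
    stop("CSS optimisation diverged (non-finite criterion); counts: ",
         paste(opt$counts, collapse = "/"), call. = FALSE)
  }
  if (opt$convergence != 0L) {
    warning(sprintf("CSS optimiser did not fully converge (code %d, %s evals)",
                    opt$convergence, paste(opt$counts, collapse = "/")))
  }
  alpha <- opt$par[seq_len(K)]
  beta <- opt$par[K + seq_len(Q)]
  res <- css_residuals(y - as.numeric(X %*% alpha), beta)
  fit <- list(alpha = alpha, beta = beta, residuals = res, css = opt$value,
              K = K, Q = Q, convergence = opt$convergence)
  class(fit) <- "linear_ma_fit"
  fit
}

#' @export
print.linear_ma_fit <- function(x, ...) {
  cat(sprintf("linear + MA(%d) errors fit: K = %d regressors, CSS = %.6g\n",
              x$Q, x$K, x$css))
  invisible(x)
}

#' One-step-ahead forecasts with teacher-forced error recursion
#'
#' For each test row in chronological order, the prediction is
#' \eqn{\hat x_t = z(t)'\alpha + \sum_i \beta_i e_{t-i}}. The error
#' history is seeded with the tail of the training residuals and, as
#' forecasting proceeds, extended with the observed test errors
#' \eqn{e_t = x_t - \hat x_t} (teacher forcing): every forecast uses
#' only information available before its target period.
#'
#' @param fit a `linear_ma_fit`.
#' @param test a `regressor_set` with the same regressor width K.
#' @param init_errors optional numeric error history to seed the MA
#'   recursion (newest last); defaults to the training residuals. Use
#'   `numeric(0)` to start from a zero history (e.g. to reproduce the
#'   in-sample residuals on the training rows).
#' @return list with `predicted`, `observed`, `errors` (one per test
#'   row), `Nv` (row count) and `K`.
#' @export
forecast_one_step <- function(fit, test, init_errors = NULL) {
  stopifnot(inherits(fit, "linear_ma_fit"), inherits(test, "regressor_set"))
  if (ncol(test$X) != fit$K) {
    stop(sprintf("regressor width mismatch: fit K = %d, test K = %d",
                 fit$K, ncol(test$X)), call. = FALSE)
  }
  Q <- fit$Q
  if (is.null(init_errors)) init_errors <- fit$residuals
  ehist <- c(rep(0, Q), init_errors)  # zero-padded pre-history
  base <- as.numeric(test$X %*% fit$alpha)
  m <- nrow(test$X)
  pred <- numeric(m)
  err <- numeric(m)
  for (t in seq_len(m)) {
    ma <- if (Q > 0L) sum(fit$beta * rev(tail(ehist, Q))) else 0
    pred[t] <- base[t] + ma
    err[t] <- test$y[t] - pred[t]
    ehist <- c(ehist, err[t])
  }
  list(predicted = pred, observed = test$y, errors = err, Nv = m, K = fit$K)
}
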