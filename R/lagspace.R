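#' Min-max scaling to [0, 1]
#'
#' Affine map `(x - min) / (max - min)` with extremes taken from `x`
#' itself or supplied via `params` (e.g. training-portion extremes
#' applied to a full series). Values outside the parameter range are NOT
#' clipped, so test-segment values may fall outside [0, 1].
#'
#' @param x numeric series.
#' @param params optional list with `min` and `max` (as returned in the
#'   `params` element); when `NULL` they are computed from `x`.
#' @return list with `values` (scaled series) and `params`.
#' @seealso [unscale_minmax()]
#' @export
scale_minmax <- function(x, params = NULL) {
  x <- validate_series(x, min_len = 2L)
  if (is.null(params)) {
    params <- list(min = min(x), max = max(x))
  }
  if (!is.finite(params$min) || !is.finite(params$max) ||
      params$max <= params$min) {
    stop("cannot min-max scale: max <= min (constant series?)", call. = FALSE)
  }
  list(values = (x - params$min) / (params$max - params$min), params = params)
}

#' Invert min-max scaling
#'
#' @param x scaled numeric series.
#' @param params list with `min` and `max` used for the forward map.
#' @return numeric series on the original scale.
#' @export
unscale_minmax <- function(x, params) {
  x * (params$max - params$min) + params$min
}

new_regressor_set <- function(X, y, t_index, K) {
  structure(
    list(X = X, y = as.numeric(y), t_index = as.integer(t_index),
         K = as.integer(K)),
    class = "regressor_set"
  )
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("regressor set: %d rows, K = %d lagged inputs (targets t = %d..%d)\n",
              nrow(x$X), x$K, min(x$t_index), max(x$t_index)))
  invisible(x)
}

#' Lagged regressors from a moving-average-smoothed series
#'
#' For each target period t = K+1..n, the regressor row holds the K most
#' recent smoothed values, newest first:
#' `z(t) = (s[t-1], s[t-2], ..., s[t-K])`; the target is the original
#' (unsmoothed) observation `x[t]`. No row contains any value from its
#' own target period or later.
#'
#' @param smoothed smoothed series (same length as `x`).
#' @param x original series supplying the targets.
#' @param K number of lags, `1 <= K < length(x)`.
#' @return a `regressor_set`: list with `X` (rows-by-K matrix), `y`
#'   (targets), `t_index` (target periods), `K`.
#' @export
build_regressors_ma <- function(smoothed, x, K) {
  s <- validate_series(smoothed, min_len = 2L, arg = "smoothed")
  x <- validate_series(x, min_len = 2L)
  if (length(s) != length(x)) {
    stop("smoothed and original series must have equal length", call. = FALSE)
  }
  K <- validate_count(K, min = 1L)
  n <- length(x)
  if (K >= n) {
    stop(sprintf("insufficient history: K = %d >= n = %d", K, n),
         call. = FALSE)
  }
  # embed() row for target t is (s[t], s[t-1], ..., s[t-K]); drop column 1
  X <- stats::embed(s, K + 1L)[, -1L, drop = FALSE]
  new_regressor_set(X, x[(K + 1L):n], (K + 1L):n, K)
}

#' Lagged regressors from the HSVD components
#'
#' In the default mode (`"both"`, the literal two-component reading) the
#' row for target t stacks P lags of the low-frequency component and P
#' lags of the high-frequency component, giving K = 2P inputs:
#' `z(t) = (C_L[t-1..t-P], C_H[t-1..t-P])`. The alternative mode
#' `"shared"` uses P lags of the reconstructed series `C_L + C_H`
#' (K = P inputs), matching descriptions of the HSVD network as having
#' the same input width as the moving-average one.
#'
#' @param low,high HSVD components, same length as `x`.
#' @param x original series supplying the targets.
#' @param P lags per component.
#' @param mode `"both"` (K = 2P, default) or `"shared"` (K = P).
#' @return a `regressor_set` (see [build_regressors_ma()]).
#' @export
build_regressors_hsvd <- function(low, high, x, P, mode = c("both", "shared")) {
  mode <- match.arg(mode)
  low <- validate_series(low, min_len = 2L, arg = "low")
  high <- validate_series(high, min_len = 2L, arg = "high")
  x <- validate_series(x, min_len = 2L)
  if (length(low) != length(x) || length(high) != length(x)) {
    stop("components and series must have equal length", call. = FALSE)
  }
  P <- validate_count(P, min = 1L)
  n <- length(x)
  if (P >= n) {
    stop(sprintf("insufficient history: P = %d >= n = %d", P, n),
         call. = FALSE)
  }
  if (mode == "shared") {
    return(build_regressors_ma(low + high, x, P))
  }
  XL <- stats::embed(low, P + 1L)[, -1L, drop = FALSE]
  XH <- stats::embed(high, P + 1L)[, -1L, drop = FALSE]
  new_regressor_set(cbind(XL, XH), x[(P + 1L):n], (P + 1L):n, 2L * P)
}

#' Chronological train/test split of a regressor set
#'
#' The first `floor(train_fraction * rows)` rows (earliest targets) form
#' the training set; the remainder the test set. No shuffling, no RNG.
#'
#' @param rs a `regressor_set`.
#' @param train_fraction fraction in (0, 1); default 0.85.
#' @return list with `train` and `test` regressor sets.
#' @export
split_train_test <- function(rs, train_fraction = 0.85) {
  stopifnot(inherits(rs, "regressor_set"))
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  m <- nrow(rs$X)
  if (m < 2L) stop("need at least 2 regressor rows to split", call. = FALSE)
  n_train <- floor(train_fraction * m)
  if (n_train < 1L || n_train >= m) {
    stop(sprintf("split leaves an empty partition (%d rows, fraction %.3f)",
                 m, train_fraction), call. = FALSE)
  }
  tr <- seq_len(n_train)
  list(
    train = new_regressor_set(rs$X[tr, , drop = FALSE], rs$y[tr],
                              rs$t_index[tr], rs$K),
    test = new_regressor_set(rs$X[-tr, , drop = FALSE], rs$y[-tr],
                             rs$t_index[-tr], rs$K)
  )
}
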