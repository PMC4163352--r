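#' 3-point moving average smoothing
#'
#' Centred mean of each interior point and its two neighbours,
#' \eqn{\tilde s_k = (x_{k-1} + x_k + x_{k+1})/3} for \eqn{k = 2..n-1}.
#' The endpoints are copied unchanged from the source series, so the
#' smoothed series has the same length and the same first and last values
#' as the input. Constant and affine-in-time series are fixed points of
#' this filter.
#'
#' @param x numeric series of length at least 3.
#' @return numeric vector of the same length as `x`.
#' @examples
#' moving_average_3(c(1, 4, 1, 4, 1)) # 1 2 3 2 1
#' @export
moving_average_3 <- function(x) {
  x <- validate_series(x, min_len = 3L)
  n <- length(x)
  s <- x
  s[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  s
}

#' Hankel (trajectory) matrix of a series
#'
#' Embeds the series into the M x L matrix with entry (i, j) equal to
#' `x[i + j - 1]`, L = n - M + 1, so every antidiagonal is constant and
#' the last entry is `x[n]`. M is both the row count and the number of
#' components a subsequent SVD can extract.
#'
#' @param x numeric series.
#' @param M number of rows, `1 <= M < length(x)`.
#' @return an M x L numeric matrix.
#' @examples
#' build_hankel(1:5, 2)
#' @export
build_hankel <- function(x, M) {
  x <- validate_series(x, min_len = 2L)
  M <- validate_count(M, min = 1L)
  n <- length(x)
  if (M >= n) {
    stop(sprintf("M must satisfy 1 <= M < n; got M = %d, n = %d", M, n),
         call. = FALSE)
  }
  L <- n - M + 1L
  idx <- outer(seq_len(M), seq_len(L), `+`) - 1L
  matrix(x[idx], nrow = M, ncol = L)
}

#' Energy share of each singular value
#'
#' \eqn{E_i = s_i^2 / \sum_j s_j^2}. The energies sum to one and measure
#' each component's share of the series' variance structure.
#'
#' @param singular_values non-negative numeric vector, not all zero.
#' @return numeric vector of the same length summing to 1.
#' @export
component_energy <- function(singular_values) {
  s <- validate_series(singular_values, min_len = 1L, arg = "singular_values")
  if (any(s < 0)) stop("singular values must be non-negative", call. = FALSE)
  total <- sum(s^2)
  if (total <= 0) {
    stop("all singular values are zero: component energy undefined",
         call. = FALSE)
  }
  s^2 / total
}

#' HSVD decomposition of a series into low- and high-frequency components
#'
#' Embeds the series in its Hankel trajectory matrix H (M rows), takes
#' the SVD H = U S V', forms one rank-one matrix per singular value,
#' \eqn{A_i = s_i u_i v_i'}, and reassembles each component series
#' \eqn{C_i} of length n from the first row of \eqn{A_i} followed by rows
#' 2..M of its last column. Because \eqn{\sum_i A_i = H} exactly and the
#' extraction is linear, the components reconstruct the series:
#' \eqn{\sum_i C_i = x}. The first component is the low-frequency part
#' \eqn{C_L} (long-term trend); the remaining components are summed into
#' the high-frequency part \eqn{C_H}.
#'
#' Sign convention: each left singular vector is flipped so its
#' largest-magnitude entry is positive (the rank-one products \eqn{A_i},
#' and hence the components, are invariant to this; it only stabilises
#' intermediate comparisons).
#'
#' @param x numeric series.
#' @param M number of components, `2 <= M < length(x)` (default 2, which
#'   retains one trend component and one fluctuation component).
#' @param keep_matrices if `TRUE`, the rank-one matrices `A_i` are
#'   returned (for diagnostics/oracle tests).
#' @return an object of class `hsvd_result`: list with `components`
#'   (M x n matrix, row i = \eqn{C_i}), `singular_values` (non-increasing),
#'   `energies` (sum to 1; all `NA` with `degenerate = TRUE` for the
#'   all-zero series), `low` (\eqn{C_L = C_1}), `high`
#'   (\eqn{C_H = \sum_{i \ge 2} C_i}), `M`, `n`, and optionally
#'   `matrices`.
#' @examples
#' h <- hsvd_decompose(c(3, 5, 4, 6, 5, 7, 6, 8), M = 2)
#' max(abs(h$low + h$high - c(3, 5, 4, 6, 5, 7, 6, 8)))
#' @export
hsvd_decompose <- function(x, M = 2, keep_matrices = FALSE) {
  x <- validate_series(x, min_len = 3L)
  M <- validate_count(M, min = 2L)
  n <- length(x)
  if (M >= n) {
    stop(sprintf("M must satisfy 2 <= M < n; got M = %d, n = %d", M, n),
         call. = FALSE)
  }
  H <- build_hankel(x, M)
  L <- ncol(H)
  dec <- svd(H, nu = M, nv = M)
  d <- dec$d[seq_len(M)]
  U <- dec$u
  V <- dec$v
  # fix sign: largest-|.| entry of each u_i positive
  for (i in seq_len(M)) {
    j <- which.max(abs(U[, i]))
    if (U[j, i] < 0) {
      U[, i] <- -U[, i]
      V[, i] <- -V[, i]
    }
  }
  comps <- matrix(0, nrow = M, ncol = n)
  mats <- if (keep_matrices) vector("list", M) else NULL
  for (i in seq_len(M)) {
    Ai <- d[i] * tcrossprod(U[, i], V[, i])
    comps[i, ] <- c(Ai[1L, ], Ai[2:M, L])
    if (keep_matrices) mats[[i]] <- Ai
  }
  degenerate <- sum(d^2) <= 0
  energies <- if (degenerate) rep(NA_real_, M) else component_energy(d)
  res <- list(
    components = comps,
    singular_values = d,
    energies = energies,
    low = comps[1L, ],
    high = if (M == 2L) comps[2L, ] else colSums(comps[2:M, , drop = FALSE]),
    M = M,
    n = n,
    degenerate = degenerate
  )
  if (keep_matrices) res$matrices <- mats
  class(res) <- "hsvd_result"
  res
}

#' @export
print.hsvd_result <- function(x, ...) {
  cat(sprintf("HSVD decomposition: n = %d, M = %d\n", x$n, x$M))
  cat("singular values:", format(x$singular_values, digits = 5), "\n")
  if (x$degenerate) {
    cat("energies: undefined (all-zero series)\n")
  } else {
    cat("energies:       ", format(x$energies, digits = 4), "\n")
  }
  invisible(x)
}
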