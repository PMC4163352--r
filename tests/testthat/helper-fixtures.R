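# shared fixtures built in code

# bare regressor set from a design matrix and targets (targets indexed
# so that every regressor notionally predates its target)
make_rs <- function(X, y) {
  X <- as.matrix(X)
  hankelcast:::new_regressor_set(X, y, seq_len(nrow(X)) + ncol(X), ncol(X))
}

# noiseless target linear in two inputs; representable by a small
# sigmoid network near the origin
linear_target_rs <- function(n = 200, seed = 99) {
  set.seed(seed)
  Z <- matrix(runif(n * 2), ncol = 2)
  make_rs(Z, 0.3 * Z[, 1] + 0.5 * Z[, 2])
}

# regression design with an MA(2) error process: the model class of
# fit_linear_ma with Q = 2
ma2_error_rs <- function(n = 400, seed = 1) {
  set.seed(seed)
  z <- runif(n)
  e <- rnorm(n, 0, 0.3)
  u <- e + 0.7 * c(0, head(e, -1)) + 0.5 * c(0, 0, head(e, -2))
  make_rs(matrix(z, ncol = 1), 0.8 * z + u)
}

random_ann <- function(K, Q, seed) {
  set.seed(seed)
  ann_weights(matrix(runif(K * Q, -1, 1), nrow = Q), runif(Q, -1, 1))
}

# central finite-difference gradient of the batch SSE (independent oracle)
fd_gradient <- function(weights, batch, h = 1e-6) {
  par <- c(as.numeric(weights$w), weights$v)
  K <- weights$K
  Q <- weights$Q
  sse_at <- function(p) {
    w <- ann_weights(matrix(p[seq_len(K * Q)], nrow = Q), p[K * Q + seq_len(Q)])
    sum((batch$y - ann_forward(w, batch$X))^2)
  }
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (sse_at(up) - sse_at(dn)) / (2 * h)
  }, numeric(1))
}
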