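#' Autoregressive network weights ANN(K, Q, 1)
#'
#' Single hidden layer, sigmoid hidden units, linear output, no bias
#' terms: the total parameter count is D = K*Q + Q, matching the swarm
#' dimension used by the PSO trainer.
#'
#' @param w hidden-layer weight matrix, Q rows (hidden units) by K
#'   columns (inputs).
#' @param v output weight vector of length Q.
#' @return object of class `ann_weights`.
#' @export
ann_weights <- function(w, v) {
  w <- as.matrix(w)
  v <- as.numeric(v)
  if (!all(is.finite(w)) || !all(is.finite(v))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (nrow(w) != length(v)) {
    stop(sprintf("dimension mismatch: w has %d rows but v has length %d",
                 nrow(w), length(v)), call. = FALSE)
  }
  structure(list(w = w, v = v, K = ncol(w), Q = nrow(w)),
            class = "ann_weights")
}

#' @export
print.ann_weights <- function(x, ...) {
  cat(sprintf("ANN(%d, %d, 1): %d parameters\n", x$K, x$Q,
              x$K * x$Q + x$Q))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# (weights <-> flat parameter vector) used by both trainers
weights_to_par <- function(weights) c(as.numeric(weights$w), weights$v)
par_to_weights <- function(par, K, Q) {
  ann_weights(matrix(par[seq_len(K * Q)], nrow = Q, ncol = K),
              par[K * Q + seq_len(Q)])
}

#' Network forward pass
#'
#' \eqn{h_j = f(\sum_i w_{ji} z_i)}, output \eqn{\sum_j v_j h_j} with the
#' logistic sigmoid \eqn{f(x) = 1/(1 + e^{-x})}. `z` may be a single lag
#' vector (length K) or a matrix with one lag vector per row.
#'
#' @param weights an `ann_weights` object.
#' @param z lag vector of length K, or an n x K matrix.
#' @return a single predicted value, or a vector of n predictions.
#' @export
ann_forward <- function(weights, z) {
  stopifnot(inherits(weights, "ann_weights"))
  if (is.matrix(z)) {
    if (ncol(z) != weights$K) {
      stop(sprintf("input width %d != K = %d", ncol(z), weights$K),
           call. = FALSE)
    }
    H <- sigmoid(z %*% t(weights$w))   # n x Q
    return(as.numeric(H %*% weights$v))
  }
  if (length(z) != weights$K) {
    stop(sprintf("input length %d != K = %d", length(z), weights$K),
         call. = FALSE)
  }
  h <- sigmoid(as.numeric(weights$w %*% z))
  sum(weights$v * h)
}

#' Analytic gradient of the sum-of-squared-error
#'
#' Exact gradient of \eqn{E = \sum_t (x_t - \hat x_t)^2} with respect to
#' every weight, for a batch of regressor rows. Used by the RPROP
#' trainer and checked against central finite differences in the tests.
#'
#' @param weights an `ann_weights` object.
#' @param batch a `regressor_set` with `K` matching the network.
#' @return list with `grad_w` (Q x K), `grad_v` (length Q) and `sse`.
#' @export
ann_gradients <- function(weights, batch) {
  stopifnot(inherits(weights, "ann_weights"), inherits(batch, "regressor_set"))
  Z <- batch$X
  if (nrow(Z) == 0L) stop("empty batch", call. = FALSE)
  if (ncol(Z) != weights$K) {
    stop(sprintf("batch width %d != K = %d", ncol(Z), weights$K),
         call. = FALSE)
  }
  H <- sigmoid(Z %*% t(weights$w))          # n x Q
  e <- batch$y - as.numeric(H %*% weights$v)
  grad_v <- -2 * as.numeric(crossprod(H, e))
  # dE/dw_ji = -2 sum_t e_t v_j h_tj (1 - h_tj) z_ti
  D <- (e %o% weights$v) * H * (1 - H)      # n x Q
  grad_w <- -2 * crossprod(D, Z)            # Q x K
  list(grad_w = grad_w, grad_v = grad_v, sse = sum(e^2))
}

ann_rmse <- function(weights, batch) {
  e <- batch$y - ann_forward(weights, batch$X)
  sqrt(mean(e^2))
}

#' PSO trainer configuration
#'
#' Defaults: swarm size 30, learning factors c1 = c2 = 2, inertia
#' decreasing linearly from 0.9 to 0.4, 2500 iterations, positions
#' initialised uniformly in \[-init_range, init_range\] (default 1) with
#' reflection at those bounds, velocities in \[-0.5, 0.5\].
#'
#' @param np swarm size (>= 2).
#' @param c1,c2 cognitive and social learning factors.
#' @param imax,imin inertia bounds, `imax > imin > 0`.
#' @param itermax iteration count.
#' @param init_range symmetric position bound.
#' @param seed RNG seed (integer) or `NULL`.
#' @return list of class `pso_config`.
#' @export
pso_config <- function(np = 30, c1 = 2, c2 = 2, imax = 0.9, imin = 0.4,
                       itermax = 2500, init_range = 1, seed = NULL) {
  np <- validate_count(np, min = 2L)
  itermax <- validate_count(itermax, min = 1L)
  if (!(imax > imin && imin > 0)) {
    stop("inertia bounds must satisfy imax > imin > 0", call. = FALSE)
  }
  structure(list(np = np, c1 = c1, c2 = c2, imax = imax, imin = imin,
                 itermax = itermax, init_range = init_range, seed = seed),
            class = "pso_config")
}

#' Linearly decreasing inertia weight
#'
#' \eqn{I_l = I_{max} - (I_{max} - I_{min})\, l / iter_{max}}: equal to
#' `imax` at iteration 0 and `imin` at the final iteration.
#'
#' @param l iteration index, `0 <= l <= itermax`.
#' @param cfg a `pso_config`.
#' @return the inertia weight at iteration l.
#' @export
inertia_weight <- function(l, cfg) {
  stopifnot(inherits(cfg, "pso_config"), l >= 0, l <= cfg$itermax)
  cfg$imax - (cfg$imax - cfg$imin) * l / cfg$itermax
}

#' Train the network by particle swarm optimisation
#'
#' Each particle is a flattened weight vector in D = K*Q + Q dimensions;
#' fitness is the training RMSE. Velocity update (canonical form):
#' \deqn{V \gets I_l V + c_1 r_1 (p_{best} - X) + c_2 r_2 (g_{best} - X)}
#' with per-dimension uniform r in \[0, 1\] and linearly decreasing
#' inertia; positions leaving \[-init_range, init_range\] are reflected
#' and their velocity component negated. Fully reproducible given the
#' seed; the returned trace (global-best RMSE per iteration, element 1 =
#' initial swarm) is non-increasing by construction.
#'
#' @param train a `regressor_set`.
#' @param K,Q input width and hidden-unit count.
#' @param cfg a `pso_config`.
#' @return list with `weights` (global-best `ann_weights`), `trace`
#'   (length itermax + 1) and `rmse` (final global best).
#' @export
train_pso <- function(train, K, Q, cfg = pso_config()) {
  stopifnot(inherits(train, "regressor_set"), inherits(cfg, "pso_config"))
  K <- validate_count(K, min = 1L)
  Q <- validate_count(Q, min = 1L)
  if (ncol(train$X) != K) {
    stop(sprintf("regressor width %d != K = %d", ncol(train$X), K),
         call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  D <- K * Q + Q
  b <- cfg$init_range
  X <- matrix(runif(cfg$np * D, -b, b), nrow = cfg$np)
  V <- matrix(runif(cfg$np * D, -0.5, 0.5), nrow = cfg$np)
  fitness <- function(p) ann_rmse(par_to_weights(p, K, Q), train)
  fit <- apply(X, 1L, fitness)
  if (any(!is.finite(fit))) stop("non-finite fitness at initialisation",
                                 call. = FALSE)
  pbest <- X
  pfit <- fit
  g <- which.min(pfit)
  gbest <- pbest[g, ]
  gfit <- pfit[g]
  trace <- numeric(cfg$itermax + 1L)
  trace[1L] <- gfit
  for (l in seq_len(cfg$itermax)) {
    I <- inertia_weight(l, cfg)
    r1 <- matrix(runif(cfg$np * D), nrow = cfg$np)
    r2 <- matrix(runif(cfg$np * D), nrow = cfg$np)
    V <- I * V + cfg$c1 * r1 * (pbest - X) +
      cfg$c2 * r2 * (matrix(gbest, cfg$np, D, byrow = TRUE) - X)
    X <- X + V
    # reflect at the position bounds, flipping the velocity component
    over <- X > b
    X[over] <- 2 * b - X[over]
    V[over] <- -V[over]
    under <- X < -b
    X[under] <- -2 * b - X[under]
    V[under] <- -V[under]
    fit <- apply(X, 1L, fitness)
    if (any(!is.finite(fit))) {
      stop(sprintf("non-finite fitness at iteration %d", l), call. = FALSE)
    }
    improved <- fit < pfit
    pbest[improved, ] <- X[improved, , drop = FALSE]
    pfit[improved] <- fit[improved]
    g <- which.min(pfit)
    if (pfit[g] < gfit) {
      gfit <- pfit[g]
      gbest <- pbest[g, ]
    }
    trace[l + 1L] <- gfit
  }
  list(weights = par_to_weights(gbest, K, Q), trace = trace, rmse = gfit)
}

#' RPROP trainer configuration
#'
#' Standard published defaults: step increase 1.2, decrease 0.5, initial
#' step 0.1, step bounds \[1e-6, 50\], 100 epochs.
#'
#' @param eta_plus,eta_minus step adaptation factors,
#'   `0 < eta_minus < 1 < eta_plus`.
#' @param delta0,delta_min,delta_max initial and bounding step sizes.
#' @param epochs number of batch epochs.
#' @param seed RNG seed for the uniform \[-0.5, 0.5\] weight
#'   initialisation, or `NULL`.
#' @return list of class `rprop_config`.
#' @export
rprop_config <- function(eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                         delta_min = 1e-6, delta_max = 50, epochs = 100,
                         seed = NULL) {
  if (!(eta_minus > 0 && eta_minus < 1 && eta_plus > 1)) {
    stop("need 0 < eta_minus < 1 < eta_plus", call. = FALSE)
  }
  if (!(delta_min > 0 && delta_min <= delta0 && delta0 <= delta_max)) {
    stop("step bounds must satisfy 0 < delta_min <= delta0 <= delta_max",
         call. = FALSE)
  }
  epochs <- validate_count(epochs, min = 1L)
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max,
                 epochs = epochs, seed = seed),
            class = "rprop_config")
}

#' One RPROP adaptation step (generic, per-parameter)
#'
#' Sign-based update: where the gradient keeps its sign across
#' consecutive steps the step size grows by `eta_plus`; where it flips,
#' the step shrinks by `eta_minus` and the stored gradient is zeroed so
#' no adaptation happens in the succeeding step. Steps are clipped to
#' \[delta_min, delta_max\] and each parameter moves opposite its
#' gradient sign.
#'
#' @param par current parameter vector.
#' @param grad gradient at `par`.
#' @param state list with `delta` and `prev_grad` (as returned), or
#'   `NULL` to initialise with `delta0` steps.
#' @param cfg an `rprop_config`.
#' @return list with updated `par` and `state`.
#' @export
rprop_step <- function(par, grad, state, cfg) {
  stopifnot(inherits(cfg, "rprop_config"))
  if (is.null(state)) {
    state <- list(delta = rep(cfg$delta0, length(par)),
                  prev_grad = rep(0, length(par)))
  }
  sgn <- sign(grad * state$prev_grad)
  delta <- state$delta
  up <- sgn > 0
  dn <- sgn < 0
  delta[up] <- pmin(delta[up] * cfg$eta_plus, cfg$delta_max)
  delta[dn] <- pmax(delta[dn] * cfg$eta_minus, cfg$delta_min)
  g <- grad
  g[dn] <- 0
  par <- par - sign(g) * delta
  list(par = par, state = list(delta = delta, prev_grad = g))
}

#' Train the network by resilient backpropagation
#'
#' Batch RPROP on the exact analytic gradient of the training
#' sum-of-squared-error; weights are initialised uniformly in
#' \[-0.5, 0.5\] from the seed. Deterministic given the seed.
#'
#' @param train a `regressor_set`.
#' @param K,Q input width and hidden-unit count.
#' @param cfg an `rprop_config`.
#' @return list with `weights` (`ann_weights` after the last epoch),
#'   `trace` (training RMSE per epoch, element 1 = initial weights) and
#'   `rmse` (best RMSE seen; the returned weights are those achieving it).
#' @export
train_rprop <- function(train, K, Q, cfg = rprop_config()) {
  stopifnot(inherits(train, "regressor_set"), inherits(cfg, "rprop_config"))
  K <- validate_count(K, min = 1L)
  Q <- validate_count(Q, min = 1L)
  if (ncol(train$X) != K) {
    stop(sprintf("regressor width %d != K = %d", ncol(train$X), K),
         call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  D <- K * Q + Q
  par <- runif(D, -0.5, 0.5)
  state <- NULL
  trace <- numeric(cfg$epochs + 1L)
  trace[1L] <- ann_rmse(par_to_weights(par, K, Q), train)
  best_par <- par
  best_rmse <- trace[1L]
  for (ep in seq_len(cfg$epochs)) {
    w <- par_to_weights(par, K, Q)
    gr <- ann_gradients(w, train)
    grad <- c(as.numeric(gr$grad_w), gr$grad_v)
    if (any(!is.finite(grad))) {
      stop(sprintf("non-finite gradient at epoch %d (rmse trace: %s)",
                   ep, paste(format(utils::head(trace, ep), digits = 4),
                             collapse = ", ")), call. = FALSE)
    }
    st <- rprop_step(par, grad, state, cfg)
    par <- st$par
    state <- st$state
    trace[ep + 1L] <- ann_rmse(par_to_weights(par, K, Q), train)
    if (trace[ep + 1L] < best_rmse) {
      best_rmse <- trace[ep + 1L]
      best_par <- par
    }
  }
  list(weights = par_to_weights(best_par, K, Q), trace = trace,
       rmse = best_rmse)
}
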