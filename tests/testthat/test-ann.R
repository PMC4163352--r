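test_that("forward pass matches closed-form sigmoid evaluation", {
  # all-zero weights: hidden activations 0.5, zero output weights -> 0
  w0 <- ann_weights(matrix(0, 3, 2), rep(0, 3))
  expect_equal(ann_forward(w0, c(1, -1)), 0)
  # K = 1, Q = 1: f(ln 3) = 1/(1 + 1/3) = 0.75, output 2 * 0.75 = 1.5
  w1 <- ann_weights(matrix(log(3), 1, 1), 2)
  expect_equal(ann_forward(w1, 1), 1.5, tolerance = 1e-12)
  # linearity in v for fixed w and z
  set.seed(1)
  w <- matrix(rnorm(6), 2, 3)
  z <- rnorm(3)
  v1 <- rnorm(2); v2 <- rnorm(2)
  expect_equal(ann_forward(ann_weights(w, v1 + v2), z),
               ann_forward(ann_weights(w, v1), z) +
                 ann_forward(ann_weights(w, v2), z),
               tolerance = 1e-12)
  # batch form agrees with per-row evaluation
  Z <- matrix(rnorm(12), ncol = 3)
  net <- ann_weights(w, v1)
  expect_equal(ann_forward(net, Z),
               apply(Z, 1, function(r) ann_forward(net, r)))
  expect_error(ann_forward(net, c(1, 2)), "input length")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    K <- sample(1:5, 1); Q <- sample(1:5, 1)
    net <- random_ann(K, Q, seed)
    batch <- make_rs(matrix(runif(20 * K, -1, 1), ncol = K), rnorm(20))
    g <- ann_gradients(net, batch)
    ana <- c(as.numeric(g$grad_w), g$grad_v)
    num <- fd_gradient(net, batch)
    expect_lt(max(abs(ana - num)) / max(1, max(abs(num))), 1e-5)
  }
})

test_that("gradient has the hand-derived form and vanishes at zero residual", {
  set.seed(7)
  net <- random_ann(2, 3, 7)
  Z <- matrix(runif(30 * 2), ncol = 2)
  # targets equal to the network output: zero residual, zero gradient
  rs0 <- make_rs(Z, ann_forward(net, Z))
  g0 <- ann_gradients(net, rs0)
  expect_lt(max(abs(c(g0$grad_w, g0$grad_v))), 1e-10)
  # dE/dv_j = -2 sum_t e_t h_j(t)
  rs <- make_rs(Z, rnorm(30))
  H <- 1 / (1 + exp(-(Z %*% t(net$w))))
  e <- rs$y - as.numeric(H %*% net$v)
  expect_equal(ann_gradients(net, rs)$grad_v,
               as.numeric(-2 * crossprod(H, e)), tolerance = 1e-10)
  expect_error(ann_gradients(net, make_rs(Z[0, , drop = FALSE], numeric(0))),
               "empty")
})

test_that("inertia weight decreases linearly between its bounds", {
  cfg <- pso_config(itermax = 100, imax = 0.9, imin = 0.4)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(100, cfg), 0.4)
  expect_equal(inertia_weight(50, cfg), (0.9 + 0.4) / 2)
})

test_that("one PSO iteration matches a hand-unrolled update", {
  rs <- linear_target_rs(n = 40, seed = 3)
  cfg <- pso_config(np = 2, itermax = 1, seed = 1234)
  out <- train_pso(rs, 2, 2, cfg)

  # independently replay the seeded draws and the update rule
  D <- 2 * 2 + 2
  b <- cfg$init_range
  set.seed(1234)
  X <- matrix(runif(2 * D, -b, b), nrow = 2)
  V <- matrix(runif(2 * D, -0.5, 0.5), nrow = 2)
  rmse_of <- function(p) {
    net <- ann_weights(matrix(p[1:4], nrow = 2), p[5:6])
    sqrt(mean((rs$y - ann_forward(net, rs$X))^2))
  }
  fit <- apply(X, 1, rmse_of)
  pbest <- X; pfit <- fit
  gbest <- X[which.min(fit), ]
  r1 <- matrix(runif(2 * D), nrow = 2)
  r2 <- matrix(runif(2 * D), nrow = 2)
  I <- cfg$imin   # l = itermax = 1
  V <- I * V + cfg$c1 * r1 * (pbest - X) +
    cfg$c2 * r2 * (matrix(gbest, 2, D, byrow = TRUE) - X)
  X <- X + V
  over <- X > b; X[over] <- 2 * b - X[over]
  under <- X < -b; X[under] <- -2 * b - X[under]
  fit <- apply(X, 1, rmse_of)
  better <- fit < pfit
  pbest[better, ] <- X[better, , drop = FALSE]
  pfit[better] <- fit[better]
  expected_best <- pbest[which.min(pfit), ]

  expect_equal(c(as.numeric(out$weights$w), out$weights$v), expected_best,
               tolerance = 1e-12)
  expect_equal(out$rmse, min(pfit), tolerance = 1e-12)
})

test_that("PSO global-best trace is non-increasing and seed-deterministic", {
  rs <- linear_target_rs(n = 80, seed = 4)
  cfg <- pso_config(np = 10, itermax = 60, seed = 77)
  a <- train_pso(rs, 2, 3, cfg)
  b <- train_pso(rs, 2, 3, cfg)
  expect_true(all(diff(a$trace) <= 0))
  expect_identical(a$trace, b$trace)
  expect_identical(a$weights$w, b$weights$w)
  c2 <- train_pso(rs, 2, 3, pso_config(np = 10, itermax = 60, seed = 78))
  expect_false(identical(a$weights$w, c2$weights$w))
})

test_that("RPROP step rule follows the sign-change adaptation exactly", {
  cfg <- rprop_config(delta0 = 0.1, epochs = 10)
  # zero gradient: parameters unchanged
  st <- rprop_step(c(1, 2), c(0, 0), NULL, cfg)
  expect_equal(st$par, c(1, 2))
  # two consecutive same-sign gradients grow the step by exactly eta_plus
  st1 <- rprop_step(0, 1, NULL, cfg)        # first step: delta0
  expect_equal(st1$par, -0.1)
  st2 <- rprop_step(st1$par, 1, st1$state, cfg)
  expect_equal(st2$state$delta, 0.1 * 1.2)
  expect_equal(st2$par, st1$par - 0.1 * 1.2)
  # sign change shrinks the step and suppresses the next adaptation
  st3 <- rprop_step(st2$par, -1, st2$state, cfg)
  expect_equal(st3$state$delta, 0.1 * 1.2 * 0.5)
  expect_equal(st3$state$prev_grad, 0)      # zeroed: no adaptation next
  st4 <- rprop_step(st3$par, -1, st3$state, cfg)
  expect_equal(st4$state$delta, st3$state$delta)  # unchanged sign product = 0
})

test_that("RPROP minimises a 1-D quadratic to 1e-3 within 60 epochs", {
  cfg <- rprop_config(delta0 = 0.1)
  w <- 0; state <- NULL
  for (ep in 1:60) {
    st <- rprop_step(w, 2 * (w - 3), state, cfg)
    w <- st$par; state <- st$state
  }
  expect_lt(abs(w - 3), 1e-3)
})

test_that("RPROP training is seed-deterministic with bounded steps", {
  rs <- linear_target_rs(n = 80, seed = 9)
  cfg <- rprop_config(epochs = 40, seed = 13)
  a <- train_rprop(rs, 2, 3, cfg)
  b <- train_rprop(rs, 2, 3, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$weights$v, b$weights$v)
  # step bounds hold along an explicit rprop_step trajectory
  set.seed(1)
  par <- runif(5); state <- NULL
  for (i in 1:50) {
    st <- rprop_step(par, rnorm(5), state, rprop_config(delta_max = 0.5))
    par <- st$par; state <- st$state
    expect_true(all(state$delta >= 1e-6 & state$delta <= 0.5))
  }
})

test_that("trainer configs validate their invariants", {
  expect_error(pso_config(np = 1), "integer >= 2")
  expect_error(pso_config(imax = 0.3, imin = 0.4), "imax > imin")
  expect_error(rprop_config(eta_plus = 0.9), "eta_minus")
  expect_error(rprop_config(delta0 = 100, delta_max = 50), "bounds")
})
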