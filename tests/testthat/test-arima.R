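test_that("iterated differencing matches hand evaluation", {
  expect_equal(difference(rep(4, 4), 1), rep(0, 3))
  expect_equal(difference(c(1, 3, 6, 10), 1), c(2, 3, 4))
  expect_equal(difference(c(1, 3, 6, 10), 2), c(1, 1))
  expect_identical(difference(c(2, 7, 1), 0), c(2, 7, 1))
  expect_error(difference(1:3, 3), "length")
})

test_that("Q = 0 fit is exact least squares on noiseless linear targets", {
  set.seed(21)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  alpha_true <- c(0.7, -1.2, 0.4)
  rs <- make_rs(X, as.numeric(X %*% alpha_true))
  fit <- fit_linear_ma(rs, Q = 0)
  expect_lt(max(abs(fit$alpha - alpha_true)), 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # independent normal-equations oracle
  set.seed(22)
  y <- as.numeric(X %*% alpha_true) + rnorm(60, 0, 0.2)
  rs2 <- make_rs(X, y)
  fit2 <- fit_linear_ma(rs2, Q = 0)
  expect_lt(max(abs(fit2$alpha - solve(crossprod(X), crossprod(X, y)))),
            1e-8)
  # degenerate: all-zero targets give all-zero coefficients
  fit0 <- fit_linear_ma(make_rs(X, rep(0, 60)), Q = 0)
  expect_equal(fit0$alpha, rep(0, 3), tolerance = 1e-10)
})

test_that("rank-deficient regressors fall back to the pseudo-inverse", {
  set.seed(4)
  Z <- matrix(rnorm(40), ncol = 1)
  X <- cbind(Z, 2 * Z)           # exactly collinear
  rs <- make_rs(X, as.numeric(Z) * 3)
  expect_warning(fit <- fit_linear_ma(rs, Q = 0), "rank-deficient")
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("CSS fit recovers regression + MA error coefficients", {
  rs <- ma2_error_rs(n = 1500, seed = 10)
  fit <- fit_linear_ma(rs, Q = 2)
  expect_lt(abs(fit$alpha - 0.8), 0.05)
  expect_lt(abs(fit$beta[1] - 0.7), 0.08)
  expect_lt(abs(fit$beta[2] - 0.5), 0.08)
})

test_that("one-step forecasts follow the teacher-forced recursion", {
  # persistence: alpha = 1, Q = 0 predicts the previous (lag-1) value
  fitP <- structure(list(alpha = 1, beta = numeric(0),
                         residuals = numeric(0), css = 0, K = 1L, Q = 0L,
                         convergence = 0L), class = "linear_ma_fit")
  te <- make_rs(matrix(c(5, 6, 7), ncol = 1), c(6, 7, 8))
  fc <- forecast_one_step(fitP, te)
  expect_equal(fc$predicted, c(5, 6, 7))
  # all-zero coefficients predict zero
  fit0 <- structure(list(alpha = c(0, 0), beta = 0, residuals = c(0.1, -0.2),
                         css = 0, K = 2L, Q = 1L, convergence = 0L),
                    class = "linear_ma_fit")
  te0 <- make_rs(matrix(rnorm(6), ncol = 2), rnorm(3))
  expect_equal(forecast_one_step(fit0, te0)$predicted, rep(0, 3))
  # Q = 1 tiny case: hand-unrolled recursion as oracle
  alpha <- 0.5; beta <- 0.4
  fit1 <- structure(list(alpha = alpha, beta = beta, residuals = c(0.2),
                         css = 0, K = 1L, Q = 1L, convergence = 0L),
                    class = "linear_ma_fit")
  z <- c(1, 2, 3); y <- c(1.0, 1.5, 2.1)
  te1 <- make_rs(matrix(z, ncol = 1), y)
  fc1 <- forecast_one_step(fit1, te1)
  e_hist <- 0.2
  expected <- numeric(3)
  for (t in 1:3) {
    expected[t] <- alpha * z[t] + beta * e_hist
    e_hist <- y[t] - expected[t]
  }
  expect_equal(fc1$predicted, expected, tolerance = 1e-12)
})

test_that("forecasting the training rows reproduces the in-sample residuals", {
  rs <- ma2_error_rs(n = 300, seed = 5)
  fit <- fit_linear_ma(rs, Q = 2)
  fc <- forecast_one_step(fit, rs, init_errors = numeric(0))
  expect_lt(max(abs(fc$errors - fit$residuals)), 1e-10)
})

test_that("forecast order matters only when MA terms are present", {
  rs <- ma2_error_rs(n = 300, seed = 6)
  sp <- split_train_test(rs, 0.85)
  perm <- rev(seq_along(sp$test$y))
  permuted <- hankelcast:::new_regressor_set(
    sp$test$X[perm, , drop = FALSE], sp$test$y[perm],
    sp$test$t_index[perm], sp$test$K)
  fit0 <- fit_linear_ma(sp$train, Q = 0)
  f_a <- forecast_one_step(fit0, sp$test)$predicted
  f_b <- forecast_one_step(fit0, permuted)$predicted
  expect_equal(f_a, f_b[perm], tolerance = 1e-12)
  fit2 <- fit_linear_ma(sp$train, Q = 2)
  g_a <- forecast_one_step(fit2, sp$test)$predicted
  g_b <- forecast_one_step(fit2, permuted)$predicted
  expect_false(isTRUE(all.equal(g_a, g_b[perm])))
})

test_that("fit and forecast validate dimensions", {
  rs <- ma2_error_rs(n = 50, seed = 2)
  fit <- fit_linear_ma(rs, Q = 1)
  wide <- make_rs(matrix(rnorm(20), ncol = 2), rnorm(10))
  expect_error(forecast_one_step(fit, wide), "width mismatch")
  expect_error(fit_linear_ma(make_rs(matrix(1:6, ncol = 1), rnorm(6)), Q = 2),
               "too few rows")
})
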