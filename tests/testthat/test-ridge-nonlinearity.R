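test_that("ridge at vanishing penalty recovers a noiseless linear map", {
  set.seed(31)
  n <- 500; p <- 15   # 5 channels x 3 lags
  X <- matrix(rnorm(n * p), n, p)
  k <- rnorm(p)
  y <- 2.5 + drop(X %*% k)
  plan <- make_segments(n, 10)
  fit <- fit_linear_ridge(X, y, plan, lambda_grid = c(1e-10, 1e-8))
  expect_lt(max(abs(fit$weights - k)) / max(abs(k)), 1e-6)
  expect_equal(fit$a0, 2.5, tolerance = 1e-6)

  # oracle: closed-form least squares on the training bins
  tr <- plan$train_bins
  ols <- lm.fit(cbind(1, X[tr, ]), y[tr])$coefficients
  expect_equal(unname(fit$weights), unname(ols[-1]), tolerance = 1e-6)
})

test_that("weights shrink monotonically with the penalty", {
  set.seed(32)
  X <- matrix(rnorm(300 * 10), 300, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(300)
  plan <- make_segments(300, 10)
  norms <- vapply(c(1e-2, 1, 100, 1e4), function(l)
    sqrt(sum(fit_linear_ridge(X, y, plan, lambda_grid = l)$weights^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("independent targets select a large penalty", {
  set.seed(33)
  X <- matrix(rnorm(400 * 20), 400, 20)
  y <- rnorm(400)
  fit <- fit_linear_ridge(X, y, make_segments(400, 10))
  expect_gte(fit$lambda, 1)
})

test_that("duplicated channels leave predictions unchanged", {
  set.seed(34)
  X <- matrix(rnorm(300 * 8), 300, 8)
  y <- drop(X %*% rnorm(8)) + 0.3 * rnorm(300)
  plan <- make_segments(300, 10)
  # duplicating every channel halves the effective penalty on their sum,
  # so the duplicate fit at 2*lambda matches the single fit at lambda
  f1 <- fit_linear_ridge(X, y, plan, lambda_grid = 1)
  f2 <- fit_linear_ridge(cbind(X, X), y, plan, lambda_grid = 2)
  p1 <- f1$a0 + drop(X %*% f1$weights)
  p2 <- f2$a0 + drop(cbind(X, X) %*% f2$weights)
  expect_equal(p1, p2, tolerance = 1e-8)
  # weight mass splits evenly across the duplicates
  expect_equal(f2$weights[1:8] + f2$weights[9:16], f1$weights,
               tolerance = 1e-8)
  expect_equal(f2$weights[1:8], f2$weights[9:16], tolerance = 1e-8)
})

test_that("logistic output fit recovers identity, step, and known curves", {
  z <- seq(-3, 3, length.out = 400)

  ident <- fit_output_nonlinearity(z, z)
  expect_lt(mean((predict(ident, z) - z)^2), 1e-4)

  step_y <- ifelse(z > 0.5, 2, 0)
  st <- fit_output_nonlinearity(z, step_y)
  expect_lt(abs(st$c - 0.5), 0.15)
  expect_lt(abs(st$d), 0.05)

  truth <- 1 + 3 / (1 + exp(-(z - 0.4) / 0.3))
  cv <- fit_output_nonlinearity(z, truth)
  expect_lt(max(abs(predict(cv, z) - truth)) / 3, 0.01)
})

test_that("logistic fit never ends above the best affine map's error", {
  set.seed(35)
  for (i in 1:5) {
    z <- rnorm(200)
    y <- 0.5 * z + rnorm(200)
    nl <- fit_output_nonlinearity(z, y)
    affine_mse <- mean(lm(y ~ z)$residuals^2)
    # the affine-equivalent logistic is a large-d linearization, so allow
    # its tiny curvature error
    expect_lte(nl$train_mse, affine_mse * (1 + 1e-4) + 1e-10)
  }
  # constant z degenerates gracefully
  flat <- fit_output_nonlinearity(rep(1, 50), rnorm(50))
  expect_true(is.finite(flat$train_mse))
})
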