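#' Fit the logistic output nonlinearity
#'
#' The linear stage output `z` is mapped to the final predicted rate through
#' a four-parameter logistic
#' \deqn{\hat y = a + b / (1 + \exp(-(z - c)/d))}
#' fitted by gradient descent on mean-square error against the training
#' PSTH. Initialization: `a = min(y)`, `b = range(y)`, `c = median(z)`,
#' `d = sd(z)/4`; the step size adapts (halving on any MSE increase) and
#' iteration stops when the relative MSE change drops below `tol`. If the
#' descent fails to reach the MSE of the best affine map of `z`, an
#' affine-equivalent parameterization (large `d`, so the curve is locally
#' linear over the range of `z`) is returned instead and flagged.
#'
#' @param z Numeric linear predictions on training bins.
#' @param y Numeric training PSTH.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative-MSE early-stopping tolerance (default 1e-8).
#' @return A `logistic_nl` object: parameters `a`, `b`, `c`, `d`,
#'   `train_mse`, and `fallback` (TRUE when the affine parameterization was
#'   used).
#' @export
fit_output_nonlinearity <- function(z, y, max_iter = 1000, tol = 1e-8) {
  stopifnot(length(z) == length(y))
  sz <- sd(z)
  if (!is.finite(sz) || sz == 0) {
    # constant linear output: predict the mean through a flat curve
    return(new_logistic_nl(a = mean(y), b = 0, c = 0, d = 1,
                           train_mse = var_pop0(y), fallback = TRUE))
  }
  # optimize on standardized z for conditioning, then map c and d back
  mz <- mean(z)
  zs <- (z - mz) / sz
  th <- c(a = min(y), b = diff(range(y)), c = median(zs), d = 1 / 4)
  if (th["b"] == 0) {
    return(new_logistic_nl(a = mean(y), b = 0, c = 0, d = 1,
                           train_mse = 0, fallback = FALSE))
  }
  mse_of <- function(th) mean((logistic4(zs, th) - y)^2)
  cur <- mse_of(th)
  lr <- 0.05
  for (it in seq_len(max_iter)) {
    g <- logistic4_grad(zs, y, th)
    # scale step by parameter magnitudes so a/b and c/d move comparably
    step <- lr * g / max(sqrt(sum(g^2)), 1e-12) *
      max(abs(th["b"]), sd(y), 1e-8)
    cand <- th - step
    cand["d"] <- sign(cand["d"]) * max(abs(cand["d"]), 1e-4)
    new <- mse_of(cand)
    if (new <= cur) {
      improved <- (cur - new) / max(cur, 1e-300)
      th <- cand; cur <- new
      lr <- lr * 1.1
      if (improved < tol) break
    } else {
      lr <- lr / 2
      if (lr < 1e-12) break
    }
  }
  # guard: never worse than the best affine map of z
  af <- affine_logistic(zs, y)
  fallback <- af$mse < cur - 1e-12
  if (fallback) { th <- af$theta; cur <- af$mse }
  new_logistic_nl(a = unname(th["a"]), b = unname(th["b"]),
                  c = unname(mz + sz * th["c"]), d = unname(sz * th["d"]),
                  train_mse = cur, fallback = fallback)
}

new_logistic_nl <- function(a, b, c, d, train_mse, fallback) {
  structure(list(a = a, b = b, c = c, d = d, train_mse = train_mse,
                 fallback = fallback),
            class = "logistic_nl")
}

logistic4 <- function(z, th) {
  th[["a"]] + th[["b"]] / (1 + exp(-(z - th[["c"]]) / th[["d"]]))
}

logistic4_grad <- function(z, y, th) {
  s <- 1 / (1 + exp(-(z - th[["c"]]) / th[["d"]]))
  r <- th[["a"]] + th[["b"]] * s - y
  ss <- s * (1 - s)
  c(a = 2 * mean(r),
    b = 2 * mean(r * s),
    c = 2 * mean(r * th[["b"]] * ss * (-1 / th[["d"]])),
    d = 2 * mean(r * th[["b"]] * ss * (-(z - th[["c"]]) / th[["d"]]^2)))
}

# Affine-equivalent logistic: with d much larger than the spread of z the
# logistic is linear over the data range with slope b/(4d).
affine_logistic <- function(zs, y) {
  fit <- lm(y ~ zs)
  alpha <- coef(fit)[[1]]; beta <- coef(fit)[[2]]
  d <- 500 * max(sd(zs), 1)
  b <- beta * 4 * d
  cc <- mean(zs)
  a <- alpha + beta * cc - b / 2
  theta <- c(a = a, b = b, c = cc, d = d)
  list(theta = theta, mse = mean((logistic4(zs, theta) - y)^2))
}

#' Evaluate a fitted logistic nonlinearity
#'
#' @param object A `logistic_nl` from [fit_output_nonlinearity()].
#' @param z Numeric vector of linear-stage outputs.
#' @param ... Unused.
#' @return Predicted rates.
#' @export
predict.logistic_nl <- function(object, z, ...) {
  object$a + object$b / (1 + exp(-(z - object$c) / object$d))
}
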