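# Closed-form SVD ridge path. One decomposition serves every lambda on the
# grid and, because many units are fitted on the same stimulus or
# source-population design, the decomposition is cached in a ridge_design so
# it is shared across units.

default_lambda_grid <- function() 10^seq(-4, 4, length.out = 17)

#' Precompute a shared ridge design
#'
#' Centers and decomposes the training design once so that the full ridge
#' regularization path, for any number of target units, costs only
#' matrix-vector products. Two decompositions are held: the training bins
#' minus the validation slice (used to select lambda) and the full training
#' set (used for the final fit at the selected lambda).
#'
#' @param X n x p design matrix (flattened lag tensor).
#' @param plan A [make_segments()] plan aligned with the rows of `X`.
#' @return A `ridge_design` object.
#' @export
ridge_design <- function(X, plan) {
  X <- as.matrix(X)
  sel_idx <- setdiff(plan$train_bins, plan$validation_bins)
  structure(
    list(sel = svd_part(X, sel_idx),
         full = svd_part(X, plan$train_bins),
         val_idx = plan$validation_bins,
         X_val = X[plan$validation_bins, , drop = FALSE],
         plan = plan),
    class = "ridge_design")
}

svd_part <- function(X, idx) {
  Xs <- X[idx, , drop = FALSE]
  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2L, mu)
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  list(idx = idx, mu = mu, u = sv$u, d = sv$d, v = sv$v)
}

ridge_coef <- function(part, y, lambda) {
  yc <- y[part$idx] - mean(y[part$idx])
  uty <- crossprod(part$u, yc)
  w <- part$v %*% (uty * part$d / (part$d^2 + lambda))
  a0 <- mean(y[part$idx]) - sum(part$mu * w)
  list(weights = drop(w), a0 = a0)
}

#' Fit the ridge-regularized linear stage
#'
#' Minimizes mean-square error between the linear output `z = a0 + X w` and
#' the target PSTH subject to an L2 penalty `lambda ||w||^2`. The penalty
#' strength is chosen on the plan's validation slice (a held-out subset of
#' the training bins, disjoint from the test segment); the final weights are
#' refitted on all training bins at the selected lambda.
#'
#' @param X n x p design matrix, or a precomputed [ridge_design()].
#' @param y Numeric target vector over all n bins (only training bins are
#'   used).
#' @param plan A [make_segments()] plan (ignored when `X` is a
#'   `ridge_design`).
#' @param lambda_grid Penalty grid; default logarithmic, 1e-4 to 1e4, 17
#'   points.
#' @return A `linear_stage` object: `weights`, `a0`, `lambda`,
#'   `validation_mse` (one value per grid point).
#' @export
fit_linear_ridge <- function(X, y, plan = NULL,
                             lambda_grid = default_lambda_grid()) {
  des <- if (inherits(X, "ridge_design")) X else {
    if (is.null(plan)) abort("plan is required when X is a matrix")
    ridge_design(X, plan)
  }
  y_val <- y[des$plan$validation_bins]
  val_mse <- vapply(lambda_grid, function(l) {
    fit <- ridge_coef(des$sel, y, l)
    mean((fit$a0 + drop(des$X_val %*% fit$weights) - y_val)^2)
  }, numeric(1))
  best <- which.min(val_mse)
  fit <- ridge_coef(des$full, y, lambda_grid[best])
  structure(
    list(weights = fit$weights, a0 = fit$a0, lambda = lambda_grid[best],
         lambda_grid = lambda_grid, validation_mse = val_mse),
    class = "linear_stage")
}

predict_linear <- function(stage, X) drop(stage$a0 + X %*% stage$weights)
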