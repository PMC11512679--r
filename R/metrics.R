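#' Signal power, noise power, noise ratio and CC_max for one unit
#'
#' Decomposes a unit's response variance across repeated presentations of a
#' frozen stimulus into a stimulus-locked (signal) part and a trial-varying
#' (noise) part. With `N` trials, PSTH variance `Var(ybar)` and mean
#' within-trial variance `Vbar`:
#' \deqn{SP = (N Var(\bar y) - \bar V) / (N - 1), \quad NP = \bar V - SP}
#' so that `SP + NP/N = Var(ybar)` exactly. The noise ratio is `NR = NP/SP`
#' and the ceiling correlation achievable by any deterministic model of the
#' PSTH is `CC_max = sqrt(SP / Var(ybar))` (clipped to [0, 1]).
#'
#' @param counts Trials x bins spike-count matrix (>= 2 trials).
#' @return One-row tibble: `signal_power`, `noise_power`, `noise_ratio`,
#'   `cc_max`, `n_trials`, `reliable` (FALSE when the signal-power estimate
#'   is non-positive, in which case `NR = Inf` and `CC_max = 0`).
#' @examples
#' y <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0))
#' signal_noise_power(y)$noise_ratio  # 0
#' @export
signal_noise_power <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) abort("need at least 2 trials")
  unit_reliability(counts)
}

unit_reliability <- function(counts) {
  n <- nrow(counts)
  ybar <- colMeans(counts)
  vp <- var_pop0(ybar)
  vbar <- mean(apply(counts, 1L, var_pop0))
  sp <- (n * vp - vbar) / (n - 1)
  np <- vbar - sp
  if (sp > 0) {
    nr <- np / sp
    cc_max <- if (vp > 0) min(1, sqrt(max(sp, 0) / vp)) else 0
    reliable <- TRUE
  } else {
    nr <- Inf
    cc_max <- 0
    reliable <- FALSE
  }
  tibble(signal_power = sp, noise_power = np, noise_ratio = nr,
         cc_max = cc_max, n_trials = n, reliable = reliable)
}

# n-denominator variance; keeps the SP + NP/N = Var(PSTH) identity exact and
# is the natural plug-in estimator for power quantities.
var_pop0 <- function(x) mean((x - mean(x))^2)

#' Normalized correlation coefficient of a prediction
#'
#' CC_norm is the Pearson correlation between a model prediction and the
#' test-set PSTH, divided by the ceiling correlation CC_max estimated from
#' trial-to-trial variability of the same trials, so that values near 1 mean
#' the model captures all of the predictable (stimulus-locked) response.
#'
#' @param prediction Numeric vector of predicted rates on the test bins.
#' @param counts_test Trials x test-bins count matrix from the same condition
#'   as the prediction (reliability is always estimated per condition).
#' @param cc_max_floor Units with `CC_max` below this floor get `cc_norm =
#'   NA` and `reliable = FALSE`; they are excluded from population medians
#'   to avoid division blow-ups. Default 0.05.
#' @return One-row tibble: `cc_abs`, `cc_max`, `cc_norm`, `reliable`.
#'   Constant predictions give `cc_abs = 0` by convention.
#' @export
cc_norm <- function(prediction, counts_test, cc_max_floor = 0.05) {
  counts_test <- as.matrix(counts_test)
  rel <- unit_reliability(counts_test)
  cc_abs <- pearson_or_zero(prediction, colMeans(counts_test))
  ok <- rel$reliable && rel$cc_max >= cc_max_floor
  tibble(cc_abs = cc_abs, cc_max = rel$cc_max,
         cc_norm = if (ok) cc_abs / rel$cc_max else NA_real_,
         reliable = ok)
}
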