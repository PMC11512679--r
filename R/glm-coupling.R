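# Single-trial Poisson GLM with stimulus, spike-history and between-neuron
# coupling terms. Filters live on a 5 ms lag grid and are parameterized by
# a small temporal basis: one-hot deltas at the shortest latencies followed
# by logarithmically spaced raised cosines.

#' Build a temporal basis of deltas and raised cosines
#'
#' The first functions are delta (one-hot) functions at the given latencies;
#' the remaining functions are raised cosines
#' `B_j(tau) = 0.5 (1 + cos(pi * clip((log(tau + 1) - phi_j)/w, -1, 1)))`
#' with log-spaced peak latencies ending at `last_peak_ms` and shared width
#' `w` equal to the peak spacing, so adjacent functions cross at half
#' height. All support lies within `span_ms`. The standard recipes are
#' (12, 250, c(5, 10), 150) for coupling filters and (7, 100, c(5, 10), 50)
#' for spike-history filters.
#'
#' @param n_functions Total number of basis functions (>= number of deltas).
#' @param span_ms Filter support in ms.
#' @param first_deltas_ms Latencies of the delta functions.
#' @param last_peak_ms Peak latency of the longest raised cosine.
#' @param bin_ms Lag-grid resolution (default 5 ms).
#' @return A `temporal_basis`: `matrix` (lags x functions, nonnegative),
#'   `lags_ms`, `kind`, `peak_latencies_ms`, `span_ms`, `bin_ms`.
#' @export
build_basis <- function(n_functions, span_ms, first_deltas_ms = c(5, 10),
                        last_peak_ms, bin_ms = 5) {
  n_deltas <- length(first_deltas_ms)
  if (n_functions < n_deltas) abort("n_functions < number of deltas")
  if (last_peak_ms >= span_ms) abort("last_peak_ms must be below span_ms")
  lags <- seq(bin_ms, span_ms, by = bin_ms)
  B <- matrix(0, length(lags), n_functions)
  for (i in seq_len(n_deltas)) B[match(first_deltas_ms[i], lags), i] <- 1
  n_rc <- n_functions - n_deltas
  peaks <- first_deltas_ms
  if (n_rc > 0L) {
    first_peak <- max(first_deltas_ms) + bin_ms
    if (last_peak_ms < first_peak)
      abort("infeasible raised-cosine spacing: last peak before first peak")
    phi <- seq(log(first_peak + 1), log(last_peak_ms + 1),
               length.out = n_rc)
    w <- if (n_rc > 1L) diff(phi)[1] else log(last_peak_ms + 1) - log(max(first_deltas_ms) + 1)
    if (exp(phi[n_rc] + w) - 1 > span_ms)
      abort("infeasible spacing: longest raised cosine exceeds span_ms")
    for (j in seq_len(n_rc)) {
      u <- (log(lags + 1) - phi[j]) / w
      B[, n_deltas + j] <- 0.5 * (1 + cos(pi * pmin(pmax(u, -1), 1)))
      B[abs(u) >= 1, n_deltas + j] <- 0
    }
    peaks <- c(peaks, exp(phi) - 1)
  }
  structure(
    list(matrix = B, lags_ms = lags,
         kind = c(rep("delta", n_deltas), rep("raised_cosine", n_rc)),
         peak_latencies_ms = peaks, span_ms = span_ms, bin_ms = bin_ms),
    class = "temporal_basis")
}

#' Standard coupling and spike-history basis recipes
#'
#' @param bin_ms Lag resolution (default 5 ms).
#' @return A `temporal_basis`: 12 functions over 250 ms (coupling) or 7
#'   functions over 100 ms (history), deltas at 5 and 10 ms, last raised
#'   cosine peaking at 150 / 50 ms.
#' @export
coupling_basis <- function(bin_ms = 5) build_basis(12L, 250, c(5, 10), 150, bin_ms)

#' @rdname coupling_basis
#' @export
history_basis <- function(bin_ms = 5) build_basis(7L, 100, c(5, 10), 50, bin_ms)

#' Reconstruct a time-domain filter from basis coefficients
#'
#' @param coefficients One coefficient per basis function.
#' @param basis A [build_basis()] object.
#' @return Numeric filter over the basis lag grid.
#' @export
reconstruct_filter <- function(coefficients, basis) {
  drop(basis$matrix %*% coefficients)
}

#' Project a time-domain filter onto a basis (least squares)
#'
#' Projection after reconstruction returns the original coefficients
#' exactly (the basis has full column rank).
#'
#' @param filter Numeric filter over the basis lag grid.
#' @param basis A [build_basis()] object.
#' @return Coefficient vector.
#' @export
project_filter <- function(filter, basis) {
  drop(solve(crossprod(basis$matrix), crossprod(basis$matrix, filter)))
}

# causal convolution of one spike train with every basis function:
# out[t, j] = sum_l B[l, j] * spk[t - l]; lag-0 terms never enter.
basis_convolve <- function(spk, basis) {
  L <- nrow(basis$matrix)
  n <- length(spk)
  x <- c(rep(0, L), spk)   # zero history before the trial start
  out <- matrix(0, n, ncol(basis$matrix))
  for (j in seq_len(ncol(basis$matrix))) {
    v <- stats::filter(x, c(0, basis$matrix[, j]), method = "convolution",
                       sides = 1)
    out[, j] <- v[(L + 1L):(L + n)]
  }
  out
}

#' Build the design for the single-trial Poisson GLM
#'
#' Rows are 5 ms bins of concatenated single trials. Blocks: (i) stimulus —
#' the sound-level history of the most recent 125 ms (25 lags at 5 ms),
#' either per frequency channel (`"frequency"`) or summed over frequency
#' (`"summed"`); (ii) coupling — for each simultaneously recorded partner
#' unit, its spikes convolved with the 12-function/250 ms basis; (iii)
#' history — the unit's own spikes convolved with the 7-function/100 ms
#' basis. All regressors are strictly causal in spikes (lags start at one
#' bin), so permuting future partner spikes cannot change any entry.
#'
#' @param recording A 5 ms `sim_recording` (e.g. from
#'   [simulate_coupled_population()]).
#' @param target_id Unit to model.
#' @param cochleagram The stimulus cochleagram (25 ms chords; levels are
#'   upsampled to the 5 ms grid). `NULL` drops the stimulus block.
#' @param stimulus_block `"frequency"`, `"summed"`, or `"none"`.
#' @param partners Partner unit ids (default: all other units in the
#'   target's penetration).
#' @param basis_c,basis_h Coupling and history bases.
#' @param stimulus_lags Number of 5 ms stimulus lags (default 25 = 125 ms).
#' @return A `glm_design`: `X`, `y`, `trial`, `blocks` (column indices per
#'   block), bases and ids.
#' @export
make_glm_design <- function(recording, target_id, cochleagram = NULL,
                            stimulus_block = c("frequency", "summed", "none"),
                            partners = NULL,
                            basis_c = coupling_basis(),
                            basis_h = history_basis(),
                            stimulus_lags = 25L) {
  stimulus_block <- match.arg(stimulus_block)
  units <- recording$units
  if (!target_id %in% units$unit_id) abort("unknown target unit")
  if (is.null(partners)) {
    pen <- units$penetration[units$unit_id == target_id]
    partners <- setdiff(units$unit_id[units$penetration == pen], target_id)
  }
  cm <- recording$counts[[target_id]]
  n_trials <- nrow(cm); nb <- ncol(cm)
  y <- as.vector(t(cm))                      # trials concatenated
  trial <- rep(seq_len(n_trials), each = nb)

  blocks <- list(); Xparts <- list()
  if (stimulus_block != "none" && !is.null(cochleagram)) {
    up <- cochleagram$levels[rep(seq_len(nrow(cochleagram$levels)),
                                 each = as.integer(cochleagram$bin_duration_ms / 5)),
                             , drop = FALSE]
    up <- up - mean(up)
    if (stimulus_block == "summed") up <- matrix(rowMeans(up), ncol = 1)
    Xs1 <- flatten_design(tensorize(up, (-(stimulus_lags - 1L)):0L))
    Xparts$stimulus <- Xs1[rep(seq_len(nb), n_trials), , drop = FALSE]
  }
  for (p in partners) {
    pc <- recording$counts[[p]]
    Xparts[[paste0("coupling:", p)]] <-
      do.call(rbind, lapply(seq_len(n_trials), function(d)
        basis_convolve(pc[d, ], basis_c)))
  }
  Xparts$history <- do.call(rbind, lapply(seq_len(n_trials), function(d)
    basis_convolve(cm[d, ], basis_h)))

  X <- do.call(cbind, Xparts)
  at <- 0L
  for (nm in names(Xparts)) {
    blocks[[nm]] <- at + seq_len(ncol(Xparts[[nm]]))
    at <- at + ncol(Xparts[[nm]])
  }
  structure(
    list(X = X, y = y, trial = trial, blocks = blocks,
         target_id = target_id, partners = partners,
         basis_c = basis_c, basis_h = basis_h,
         n_trials = n_trials, n_bins = nb,
         stimulus_block = stimulus_block),
    class = "glm_design")
}

#' Fit the penalized Poisson GLM
#'
#' Elastic-net-penalized Poisson regression (glmnet; ridge, `alpha = 0`, by
#' default). Trained on `n_train` concatenated single trials; the penalty
#' strength is chosen by Poisson deviance on the last training trial, then
#' the model is refitted on all training trials at that penalty. The
#' remaining trials are the held-out test set.
#'
#' @param design A [make_glm_design()].
#' @param include_coupling Keep (TRUE) or drop (FALSE) the coupling blocks;
#'   nothing else changes.
#' @param alpha Elastic-net mixing (0 = ridge).
#' @param n_train Number of training trials (default 5).
#' @param nlambda Length of the automatic penalty path.
#' @return A `poisson_glm_fit`: `intercept`, `coefficients` (named by
#'   design column), `lambda`, `blocks`, `include_coupling`, trial split.
#' @export
fit_poisson_glm <- function(design, include_coupling = TRUE, alpha = 0,
                            n_train = 5L, nlambda = 20L) {
  if (design$n_trials <= n_train)
    abort("need at least one held-out trial beyond n_train")
  keep <- glm_keep_cols(design, include_coupling)
  val_trial <- n_train
  sel_rows <- design$trial < val_trial
  val_rows <- design$trial == val_trial
  train_rows <- design$trial <= n_train
  X <- design$X[, keep, drop = FALSE]
  f1 <- glmnet::glmnet(X[sel_rows, , drop = FALSE], design$y[sel_rows],
                       family = "poisson", alpha = alpha, nlambda = nlambda,
                       standardize = TRUE)
  mu_val <- predict(f1, X[val_rows, , drop = FALSE], type = "response")
  yv <- design$y[val_rows]
  # mean Poisson deviance per lambda on the validation trial
  dev <- colMeans(2 * (ifelse(yv > 0, yv * log(yv / mu_val), 0) -
                         (yv - mu_val)))
  lam <- f1$lambda[which.min(dev)]
  f2 <- glmnet::glmnet(X[train_rows, , drop = FALSE], design$y[train_rows],
                       family = "poisson", alpha = alpha,
                       lambda = f1$lambda, standardize = TRUE)
  beta <- drop(coef(f2, s = lam))
  co <- setNames(numeric(length(keep)), colnames(design$X)[keep] %||%
                   as.character(keep))
  co[] <- beta[-1]
  structure(
    list(intercept = beta[1], coefficients = co, kept_cols = keep,
         lambda = lam, alpha = alpha, blocks = design$blocks,
         include_coupling = include_coupling, n_train = n_train,
         target_id = design$target_id, partners = design$partners,
         basis_c = design$basis_c, basis_h = design$basis_h),
    class = "poisson_glm_fit")
}

glm_keep_cols <- function(design, include_coupling) {
  nm <- names(design$blocks)
  use <- if (include_coupling) nm else nm[!startsWith(nm, "coupling:")]
  sort(unlist(design$blocks[use], use.names = FALSE))
}

#' Predicted rate of a fitted Poisson GLM
#'
#' @param object A `poisson_glm_fit`.
#' @param design The matching `glm_design`.
#' @param rows Row subset (default all).
#' @param ... Unused.
#' @return Predicted spikes per bin, `exp(eta)`, strictly positive.
#' @export
predict.poisson_glm_fit <- function(object, design, rows = NULL, ...) {
  rows <- rows %||% seq_len(nrow(design$X))
  eta <- object$intercept +
    drop(design$X[rows, object$kept_cols, drop = FALSE] %*% object$coefficients)
  exp(eta)
}

#' Single-trial test performance of a Poisson GLM
#'
#' Pearson correlation between the predicted rate and the observed 5 ms
#' spike counts over the held-out test trials (constant predictions give 0
#' by convention).
#'
#' @param fit A `poisson_glm_fit`.
#' @param design The matching `glm_design`.
#' @param test_trials Trial indices to test on (default: all trials after
#'   the training split).
#' @return Pearson r.
#' @export
evaluate_single_trial <- function(fit, design, test_trials = NULL) {
  test_trials <- test_trials %||%
    setdiff(unique(design$trial), seq_len(fit$n_train))
  rows <- which(design$trial %in% test_trials)
  pearson_or_zero(predict(fit, design, rows), design$y[rows])
}

#' Reconstructed coupling and history filters of a fit
#'
#' Each filter is the basis expansion of its fitted coefficients: a
#' time-domain filter on the 5 ms lag grid relating the target's firing to
#' a partner's (or its own) recent spiking.
#'
#' @param fit A `poisson_glm_fit` with coupling included.
#' @return Tibble: `target`, `source` (`"self"` for the history filter),
#'   `lag_ms`, `value`.
#' @export
coupling_filters <- function(fit) {
  rows <- list()
  for (nm in names(fit$blocks)) {
    if (startsWith(nm, "coupling:")) {
      cf <- filter_from_block(fit, nm, fit$basis_c)
      rows[[nm]] <- tibble(target = fit$target_id,
                           source = sub("^coupling:", "", nm),
                           lag_ms = fit$basis_c$lags_ms, value = cf)
    }
  }
  hf <- filter_from_block(fit, "history", fit$basis_h)
  rows$history <- tibble(target = fit$target_id, source = "self",
                         lag_ms = fit$basis_h$lags_ms, value = hf)
  bind_rows(rows)
}

filter_from_block <- function(fit, block, basis) {
  cols <- fit$blocks[[block]]
  idx <- match(cols, fit$kept_cols)
  if (anyNA(idx)) return(rep(0, length(basis$lags_ms)))
  reconstruct_filter(unname(fit$coefficients[idx]), basis)
}

#' Fast/slow excitatory/inhibitory decomposition of a filter
#'
#' Integrates the positive (excitatory) and negative (inhibitory) parts of
#' a time-domain filter over fast (< 10 ms) and slow (>= 10 ms) lags.
#'
#' @param filter Numeric filter values.
#' @param lags_ms Lag of each value in ms.
#' @return One-row tibble: `fast_excitatory`, `slow_excitatory`,
#'   `fast_inhibitory`, `slow_inhibitory` (inhibitory masses are reported
#'   as positive magnitudes).
#' @export
filter_components <- function(filter, lags_ms) {
  fast <- lags_ms < 10
  tibble(fast_excitatory = sum(pmax(filter[fast], 0)),
         slow_excitatory = sum(pmax(filter[!fast], 0)),
         fast_inhibitory = sum(pmax(-filter[fast], 0)),
         slow_inhibitory = sum(pmax(-filter[!fast], 0)))
}

#' Fit coupled and stimulus-only GLMs for every unit of a recording
#'
#' @param recording A 5 ms `sim_recording`.
#' @param cochleagram Stimulus cochleagram (or `NULL`).
#' @param stimulus_block Stimulus block variant (see [make_glm_design()]).
#' @param alpha,n_train,nlambda Passed to [fit_poisson_glm()].
#' @return List: `results` tibble (`unit_id`, `r_coupled`,
#'   `r_stimulus_only`, `coupling_contribution`), `filters` tibble from
#'   [coupling_filters()] of each coupled fit, `fits` (named list).
#' @export
fit_population_glms <- function(recording, cochleagram = NULL,
                                stimulus_block = "frequency", alpha = 0,
                                n_train = 5L, nlambda = 20L) {
  ids <- recording$units$unit_id
  rows <- list(); filt <- list(); fits <- list()
  for (id in ids) {
    des <- make_glm_design(recording, id, cochleagram, stimulus_block)
    fc <- fit_poisson_glm(des, include_coupling = TRUE, alpha = alpha,
                          n_train = n_train, nlambda = nlambda)
    f0 <- fit_poisson_glm(des, include_coupling = FALSE, alpha = alpha,
                          n_train = n_train, nlambda = nlambda)
    rc <- evaluate_single_trial(fc, des)
    r0 <- evaluate_single_trial(f0, des)
    rows[[id]] <- tibble(unit_id = id, r_coupled = rc, r_stimulus_only = r0,
                         coupling_contribution = rc - r0)
    filt[[id]] <- coupling_filters(fc)
    fits[[id]] <- fc
  }
  list(results = bind_rows(rows), filters = bind_rows(filt), fits = fits)
}

#' Compare coupling between conditions (e.g. cortex active vs silenced)
#'
#' @param glms_active,glms_silenced Outputs of [fit_population_glms()] on
#'   matched units under the two conditions (unmatched units are dropped).
#' @param refit_jitter Optional null scale for the filter-change metric
#'   (e.g. from split-seed refits); reported alongside, not subtracted.
#' @return List of tibbles: `contribution` (per unit and condition),
#'   `filter_change` (per coupled pair: `1 - r` between condition filters),
#'   `components` (fast/slow excitatory/inhibitory masses per pair and
#'   condition).
#' @export
coupling_analyses <- function(glms_active, glms_silenced,
                              refit_jitter = NA_real_) {
  shared <- intersect(glms_active$results$unit_id,
                      glms_silenced$results$unit_id)
  contribution <- bind_rows(
    mutate(filter(glms_active$results, .data$unit_id %in% shared),
           condition = "active"),
    mutate(filter(glms_silenced$results, .data$unit_id %in% shared),
           condition = "silenced"))
  fa <- filter(glms_active$filters, .data$source != "self",
               .data$target %in% shared)
  fs <- filter(glms_silenced$filters, .data$source != "self",
               .data$target %in% shared)
  pairs <- left_join(fa, fs, by = c("target", "source", "lag_ms"),
                     suffix = c("_active", "_silenced"))
  filter_change <- pairs %>%
    group_by(.data$target, .data$source) %>%
    summarise(change = 1 - pearson_or_zero(.data$value_active,
                                           .data$value_silenced),
              .groups = "drop") %>%
    mutate(refit_jitter = refit_jitter)
  comp <- function(ftab, cond) {
    ftab %>%
      group_by(.data$target, .data$source) %>%
      summarise(filter_components(.data$value, .data$lag_ms),
                .groups = "drop") %>%
      mutate(condition = cond)
  }
  list(contribution = contribution,
       filter_change = filter_change,
       components = bind_rows(comp(fa, "active"), comp(fs, "silenced")))
}
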