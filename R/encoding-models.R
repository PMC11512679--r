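# Linear-nonlinear encoding models. All variants share one pipeline:
# lagged design -> ridge linear stage (lambda on the validation slice) ->
# logistic output nonlinearity, trained strictly on the plan's training
# bins and evaluated by CC_norm on the held-out test segment.

strf_lag_offsets <- function(n_history = 13L) (-(n_history - 1L)):0L
pcm_lag_offsets <- function(history = 8L, future = 5L) seq.int(-history, future)

fit_ln_core <- function(design, Xf, y, plan, kind, dims, lag_offsets,
                        channel_ids, lambda_grid = default_lambda_grid()) {
  lin <- fit_linear_ridge(design, y, lambda_grid = lambda_grid)
  z <- predict_linear(lin, Xf)
  nl <- fit_output_nonlinearity(z[plan$train_bins], y[plan$train_bins])
  structure(
    list(linear = lin, nonlinearity = nl, kind = kind, dims = dims,
         lag_offsets = lag_offsets, channel_ids = channel_ids,
         plan = plan,
         training_record = list(lambda = lin$lambda,
                                lambda_grid = lin$lambda_grid,
                                validation_mse = lin$validation_mse,
                                nl_fallback = nl$fallback)),
    class = "ln_model")
}

#' Predict from a fitted linear-nonlinear model
#'
#' @param object An `ln_model`.
#' @param newdata A time x channel x lag tensor from [tensorize()] (or its
#'   flattened matrix) matching the model's design.
#' @param ... Unused.
#' @return Predicted rate per time bin.
#' @export
predict.ln_model <- function(object, newdata, ...) {
  X <- if (length(dim(newdata)) == 3L) flatten_design(newdata) else newdata
  predict(object$nonlinearity, predict_linear(object$linear, X))
}

#' @export
print.ln_model <- function(x, ...) {
  cat(sprintf("<ln_model:%s> %d channels x %d lags, lambda=%g%s\n",
              x$kind, x$dims[1], x$dims[2], x$linear$lambda,
              if (x$nonlinearity$fallback) " (affine output)" else ""))
  invisible(x)
}

#' Kernel of a fitted linear-nonlinear model
#'
#' @param model An `ln_model`.
#' @return Channel x lag weight matrix (frequencies x history for STRFs,
#'   source units x lags for PCMs).
#' @export
ln_kernel <- function(model) {
  k <- matrix(model$linear$weights, model$dims[1], model$dims[2])
  rownames(k) <- model$channel_ids
  colnames(k) <- paste0("lag", model$lag_offsets)
  k
}

evaluate_ln <- function(model, Xf, counts, plan, cc_max_floor = 0.05) {
  pred <- predict(model, Xf[plan$test_bins, , drop = FALSE])
  cc_norm(pred, counts[, plan$test_bins, drop = FALSE],
          cc_max_floor = cc_max_floor)
}

stimulus_design <- function(cochleagram, plan, n_history = 13L) {
  boundaries <- sort(unique(c(cochleagram$trial_boundaries, plan$boundaries)))
  X <- tensorize(cochleagram$levels - mean(cochleagram$levels),
                 strf_lag_offsets(n_history), boundaries)
  flatten_design(X)
}

population_design <- function(source_psths, plan, history = 8L, future = 5L,
                              trial_boundaries = 1L) {
  boundaries <- sort(unique(c(trial_boundaries, plan$boundaries)))
  X <- tensorize(source_psths, pcm_lag_offsets(history, future), boundaries)
  flatten_design(X)
}

#' Fit a linear-nonlinear STRF model for one unit
#'
#' The linear stage is a spectrotemporal kernel over the cochleagram's most
#' recent `n_history` (default 13) chords, ridge-fitted to the training-set
#' PSTH; a logistic output nonlinearity is then fitted to the linear output.
#'
#' @param cochleagram A [generate_drc()] cochleagram.
#' @param counts Trials x bins spike-count matrix for the unit.
#' @param plan A [make_segments()] plan over the stimulus bins.
#' @param n_history Number of stimulus history steps.
#' @param lambda_grid Ridge penalty grid.
#' @return An `ln_model` with an `$evaluation` tibble (`cc_abs`, `cc_max`,
#'   `cc_norm`, `reliable`) from the held-out test segment.
#' @export
fit_strf <- function(cochleagram, counts, plan, n_history = 13L,
                     lambda_grid = default_lambda_grid()) {
  Xf <- stimulus_design(cochleagram, plan, n_history)
  des <- ridge_design(Xf, plan)
  y <- psth(counts)
  m <- fit_ln_core(des, Xf, y, plan, "STRF",
                   c(ncol(cochleagram$levels), n_history),
                   strf_lag_offsets(n_history),
                   cochleagram$frequencies)
  m$evaluation <- evaluate_ln(m, Xf, counts, plan)
  m
}

#' Fit a population communication model (PCM) for one unit
#'
#' Identical in form and optimization to the STRF model but the inputs are
#' lagged trial-averaged responses (PSTHs) of a source population: 8
#' history steps, the same bin, and 5 future steps (future lags compensate
#' latency differences between areas). Source units must not include the
#' target and, by the simultaneity rule, must come from other penetrations.
#'
#' @param source_psths Bins x source-units matrix of PSTHs (column names =
#'   source unit ids).
#' @param counts Trials x bins counts of the target unit.
#' @param plan A [make_segments()] plan.
#' @param history,future Numbers of past and future lag steps.
#' @param trial_boundaries First-bin indices of stimulus trials.
#' @param target_id Optional target unit id, checked against the sources.
#' @param lambda_grid Ridge penalty grid.
#' @return An `ln_model` with `$evaluation` as in [fit_strf()].
#' @export
fit_pcm <- function(source_psths, counts, plan, history = 8L, future = 5L,
                    trial_boundaries = 1L, target_id = NULL,
                    lambda_grid = default_lambda_grid()) {
  source_psths <- as.matrix(source_psths)
  if (ncol(source_psths) == 0L) abort("source population is empty")
  if (!is.null(target_id) && target_id %in% colnames(source_psths))
    abort("target unit must not be part of the source population")
  Xf <- population_design(source_psths, plan, history, future,
                          trial_boundaries)
  des <- ridge_design(Xf, plan)
  m <- fit_ln_core(des, Xf, psth(counts), plan, "PCM",
                   c(ncol(source_psths), history + future + 1L),
                   pcm_lag_offsets(history, future),
                   colnames(source_psths) %||% seq_len(ncol(source_psths)))
  m$evaluation <- evaluate_ln(m, Xf, counts, plan)
  m
}

#' Fit STRF models for every unit of a recording
#'
#' All units share one design decomposition, so the per-unit cost is small.
#'
#' @param cochleagram Stimulus cochleagram.
#' @param recording A `sim_recording` (or named list of count matrices).
#' @param plan A [make_segments()] plan.
#' @param n_history Stimulus history steps.
#' @param lambda_grid Ridge penalty grid.
#' @param keep_models Keep the fitted `ln_model`s (default TRUE).
#' @return List: `results` tibble (unit_id, model, cc_abs, cc_max, cc_norm,
#'   reliable, lambda) and `models` (named list or NULL).
#' @export
fit_strf_population <- function(cochleagram, recording, plan,
                                n_history = 13L,
                                lambda_grid = default_lambda_grid(),
                                keep_models = TRUE) {
  counts <- recording_counts(recording)
  Xf <- stimulus_design(cochleagram, plan, n_history)
  des <- ridge_design(Xf, plan)
  fit_many(des, Xf, counts, plan, "STRF",
           c(ncol(cochleagram$levels), n_history),
           strf_lag_offsets(n_history), cochleagram$frequencies,
           lambda_grid, keep_models)
}

fit_many <- function(des, Xf, counts, plan, kind, dims, lag_offsets,
                     channel_ids, lambda_grid, keep_models) {
  models <- if (keep_models) vector("list", length(counts))
  rows <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    m <- fit_ln_core(des, Xf, psth(counts[[i]]), plan, kind, dims,
                     lag_offsets, channel_ids, lambda_grid)
    ev <- evaluate_ln(m, Xf, counts[[i]], plan)
    rows[[i]] <- mutate(ev, unit_id = names(counts)[i], model = kind,
                        lambda = m$linear$lambda, .before = 1L)
    if (keep_models) models[[i]] <- m
  }
  if (keep_models) names(models) <- names(counts)
  list(results = bind_rows(rows), models = models)
}

#' Fit PCMs for every unit of a target recording
#'
#' Source PSTHs are taken from one or more source recordings; units sharing
#' a penetration with the target (and the target itself) are excluded from
#' its source population, mirroring the restriction to non-simultaneously
#' recorded sources.
#'
#' @param target_recording `sim_recording` of target units.
#' @param source_recordings A `sim_recording` or list of them (their PSTHs
#'   are pooled; e.g. IC + MGB sources for A1 targets).
#' @param plan A [make_segments()] plan.
#' @param history,future Lag steps (defaults 8 and 5).
#' @param model_label Label in the results (default "PCM").
#' @param lambda_grid Ridge penalty grid.
#' @param keep_models Keep fitted models (default FALSE: population runs).
#' @return As [fit_strf_population()].
#' @export
fit_pcm_population <- function(target_recording, source_recordings, plan,
                               history = 8L, future = 5L,
                               model_label = "PCM",
                               lambda_grid = default_lambda_grid(),
                               keep_models = FALSE) {
  if (inherits(source_recordings, "sim_recording"))
    source_recordings <- list(source_recordings)
  src_psth <- do.call(cbind, lapply(source_recordings, psth_matrix))
  src_units <- bind_rows(lapply(source_recordings, function(r)
    select(r$units, "unit_id", "penetration")))
  tb <- source_recordings[[1]]$trial_boundaries
  tgt_units <- target_recording$units
  counts <- target_recording$counts
  # one shared design per distinct source set (cross-area PCMs share one)
  rows <- list(); models <- list()
  pens <- unique(tgt_units$penetration)
  src_sets <- lapply(pens, function(pen) {
    in_pen <- tgt_units$unit_id[tgt_units$penetration == pen]
    src_units$unit_id[src_units$penetration != pen &
                        !(src_units$unit_id %in% in_pen)]
  })
  names(src_sets) <- pens
  for (key in unique(vapply(src_sets, paste, character(1), collapse = ","))) {
    use_pens <- pens[vapply(src_sets, paste, character(1),
                            collapse = ",") == key]
    keep_src <- src_sets[[use_pens[1]]]
    if (length(keep_src) == 0L) abort("source population is empty")
    in_pens <- tgt_units$unit_id[tgt_units$penetration %in% use_pens]
    Xf <- population_design(src_psth[, keep_src, drop = FALSE], plan,
                            history, future, tb)
    des <- ridge_design(Xf, plan)
    out <- fit_many(des, Xf, counts[in_pens], plan, model_label,
                    c(length(keep_src), history + future + 1L),
                    pcm_lag_offsets(history, future), keep_src,
                    lambda_grid, keep_models)
    rows[[key]] <- out$results
    if (keep_models) models <- c(models, out$models)
  }
  list(results = bind_rows(rows),
       models = if (keep_models) models else NULL)
}

#' Fit a network receptive field (NRF) model for one unit
#'
#' A single-hidden-layer network with logistic activations (hidden and
#' output), trained by gradient-based minimization of mean-square error on
#' the same lagged stimulus design as the STRF. The hidden-layer size is a
#' hyperparameter chosen on the validation slice.
#'
#' @param cochleagram Stimulus cochleagram.
#' @param counts Trials x bins counts.
#' @param plan A [make_segments()] plan.
#' @param hidden_sizes Candidate hidden-unit counts (default 2, 4, 8, 16).
#' @param decay_grid Candidate weight-decay (L2) strengths, selected on the
#'   validation slice together with the hidden size.
#' @param n_history Stimulus history steps.
#' @param seed Seed for weight initialization (fit is deterministic given
#'   data and seed).
#' @param maxit Optimizer iteration cap per candidate.
#' @return An `nrf_model` with `$evaluation` as in [fit_strf()] and
#'   `$hidden_size`, the selected size.
#' @export
fit_nrf <- function(cochleagram, counts, plan,
                    hidden_sizes = c(2L, 4L, 8L, 16L),
                    decay_grid = c(0.05, 0.5, 2), n_history = 13L,
                    seed = 1L, maxit = 500L) {
  Xf <- stimulus_design(cochleagram, plan, n_history)
  y <- psth(counts)
  sel_idx <- setdiff(plan$train_bins, plan$validation_bins)
  mu <- colMeans(Xf[sel_idx, , drop = FALSE])
  sg <- pmax(apply(Xf[sel_idx, , drop = FALSE], 2, sd), 1e-8)
  Xs <- sweep(sweep(Xf, 2L, mu), 2L, sg, "/")
  ylo <- min(y[sel_idx]); yhi <- max(y[sel_idx])
  yr <- max(yhi - ylo, 1e-8)
  ys <- (y - ylo) / yr
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  grid <- expand.grid(size = hidden_sizes, decay = decay_grid)
  fits <- lapply(seq_len(nrow(grid)), function(k) {
    h <- grid$size[k]
    decay <- grid$decay[k]
    net <- NULL
    for (attempt in 1:3) {
      set.seed(split_seed(seed, 500L + 10L * k + attempt))
      net <- tryCatch(
        nnet::nnet(Xs[sel_idx, , drop = FALSE], ys[sel_idx], size = h,
                   linout = FALSE, entropy = FALSE, decay = decay,
                   maxit = maxit, MaxNWts = 100000L, trace = FALSE),
        error = function(e) NULL)
      if (!is.null(net) && all(is.finite(net$wts))) break
      decay <- decay * 100   # retry with stronger damping
    }
    if (is.null(net)) return(NULL)
    val_pred <- drop(predict(net, Xs[plan$validation_bins, , drop = FALSE]))
    list(net = net, size = h, decay = decay,
         val_mse = mean((val_pred - ys[plan$validation_bins])^2))
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) abort("all network fits diverged")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "val_mse"))]]
  pred_all <- ylo + yr * drop(predict(best$net, Xs))
  m <- structure(
    list(net = best$net, hidden_size = best$size, scale = list(
      mu = mu, sg = sg, ylo = ylo, yr = yr), plan = plan,
      kind = "NRF", decay = best$decay,
      training_record = list(hidden_sizes = hidden_sizes,
                             decay_grid = decay_grid,
                             val_mse = vapply(fits, `[[`, numeric(1), "val_mse"),
                             seed = seed)),
    class = "nrf_model")
  m$evaluation <- cc_norm(pred_all[plan$test_bins],
                          counts[, plan$test_bins, drop = FALSE])
  m
}

#' @export
predict.nrf_model <- function(object, newdata, ...) {
  X <- if (length(dim(newdata)) == 3L) flatten_design(newdata) else newdata
  Xs <- sweep(sweep(X, 2L, object$scale$mu), 2L, object$scale$sg, "/")
  object$scale$ylo + object$scale$yr * drop(predict(object$net, Xs))
}

#' Fit two-stage (STRF -> PCM) models for a target recording
#'
#' Stage 1 fits an LN STRF model to every IC unit and replaces the recorded
#' IC PSTHs with the modeled responses IC'; stage 2 fits a PCM from IC' to
#' each target unit. The composite is a spectrogram-to-response network
#' whose hidden units are constrained to model real midbrain units; its
#' performance relative to plain STRFs and to PCMs on recorded responses
#' measures how much of the population-model advantage STRFs can explain.
#'
#' @param cochleagram Stimulus cochleagram.
#' @param ic_recording `sim_recording` of the IC source population.
#' @param target_recording `sim_recording` of the target units.
#' @param plan A [make_segments()] plan.
#' @param stage1 `"strf"` (default) or `"pcm"`: how the stage-1 models of
#'   the IC units are built (the PCM variant models each IC unit from the
#'   other IC penetrations).
#' @param history,future Stage-2 PCM lags.
#' @param lambda_grid Ridge penalty grid.
#' @param stage1_psths Optional precomputed bins x IC-units matrix of
#'   stage-1 predicted responses (overrides `stage1`).
#' @return List: `results` tibble (model = "TwoStage"), `stage1_psths`.
#' @export
fit_two_stage <- function(cochleagram, ic_recording, target_recording, plan,
                          stage1 = c("strf", "pcm"), history = 8L,
                          future = 5L, lambda_grid = default_lambda_grid(),
                          stage1_psths = NULL) {
  stage1 <- match.arg(stage1)
  if (is.null(stage1_psths)) {
    if (stage1 == "strf") {
      s1 <- fit_strf_population(cochleagram, ic_recording, plan,
                                lambda_grid = lambda_grid,
                                keep_models = TRUE)
      Xf <- stimulus_design(cochleagram, plan)
      stage1_psths <- vapply(s1$models, function(m) predict(m, Xf),
                             numeric(plan$n_bins))
    } else {
      s1 <- fit_pcm_population(ic_recording, ic_recording, plan, history,
                               future, lambda_grid = lambda_grid,
                               keep_models = TRUE)
      src_psth <- psth_matrix(ic_recording)
      stage1_psths <- vapply(names(s1$models), function(id) {
        m <- s1$models[[id]]
        Xf <- population_design(src_psth[, m$channel_ids, drop = FALSE],
                                plan, history, future,
                                ic_recording$trial_boundaries)
        predict(m, Xf)
      }, numeric(plan$n_bins))
    }
    colnames(stage1_psths) <- ic_recording$units$unit_id
  }
  # stage-2 PCM on the modeled responses; model outputs carry no
  # simultaneity, so no penetration exclusion applies
  Xf2 <- population_design(stage1_psths, plan, history, future,
                           ic_recording$trial_boundaries)
  des2 <- ridge_design(Xf2, plan)
  out <- fit_many(des2, Xf2, target_recording$counts, plan, "TwoStage",
                  c(ncol(stage1_psths), history + future + 1L),
                  pcm_lag_offsets(history, future), colnames(stage1_psths),
                  lambda_grid, keep_models = FALSE)
  list(results = out$results, stage1_psths = stage1_psths)
}

#' Tuning summaries of a fitted STRF
#'
#' The frequency tuning curve is the sum of the kernel's positive
#' coefficients over time lags. Tuning width is the number of curve values
#' above 0.25 x maximum; best frequency is the peak of the curve after 10x
#' cubic-spline interpolation along log-frequency (ties broken toward the
#' lower frequency); overlap with a source population is the summed dot
#' product of tuning curves.
#'
#' @param strf An `ln_model` of kind STRF, or a frequency x lag kernel
#'   matrix.
#' @param frequencies Grid frequencies (Hz); required when `strf` is a bare
#'   matrix.
#' @param source_curves Optional matrix (frequencies x source units) of
#'   source tuning curves for the overlap summary.
#' @return One-row tibble: `best_frequency` (Hz, `NA` if the kernel has no
#'   positive part), `tuning_width` (grid steps), `overlap` (`NA` without
#'   sources).
#' @export
strf_summaries <- function(strf, frequencies = NULL, source_curves = NULL) {
  k <- if (inherits(strf, "ln_model")) ln_kernel(strf) else as.matrix(strf)
  if (is.null(frequencies)) frequencies <- as.numeric(rownames(k))
  if (any(is.na(frequencies))) abort("frequencies are required")
  tc <- tuning_curve(k)
  if (max(tc) <= 0) {
    return(tibble(best_frequency = NA_real_, tuning_width = 0L,
                  overlap = overlap_sum(tc, source_curves)))
  }
  width <- sum(tc > 0.25 * max(tc))
  sp <- spline(log2(frequencies), tc, n = 10L * length(tc))
  # refine the peak on the 10x spline grid locally around the raw argmax;
  # which.max on the raw curve takes the first (lowest) frequency on ties
  i0 <- which.max(tc)
  step <- if (length(frequencies) > 1)
    diff(log2(frequencies))[max(i0 - 1L, 1L)] else 1
  near <- abs(sp$x - log2(frequencies[i0])) <= step
  bf <- 2^sp$x[near][which.max(sp$y[near])]
  tibble(best_frequency = bf, tuning_width = width,
         overlap = overlap_sum(tc, source_curves))
}

tuning_curve <- function(k) rowSums(pmax(k, 0))

overlap_sum <- function(tc, source_curves) {
  if (is.null(source_curves)) return(NA_real_)
  sum(crossprod(source_curves, tc))
}
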