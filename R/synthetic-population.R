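# Ground-truth generator of hierarchical spiking populations. Three areas
# are emulated: an IC-like stage whose rates are a rectified linear function
# of the cochleagram (an LN ground truth), and MGB-like / A1-like stages
# whose rates are rectified lagged linear combinations of the rates of the
# area below. Rates (not spikes) feed downstream, so within-penetration
# noise correlations arise only through shared stimulus drive unless
# explicit spike coupling is simulated (see simulate_coupled_population).

#' Make IC-like model units
#'
#' Each unit gets a gammatone-like spectrotemporal kernel: localized Gaussian
#' frequency tuning whose best frequencies tile the grid, multiplied by a
#' biphasic (excitation then rebound suppression) temporal profile, plus a
#' threshold-linear output nonlinearity.
#'
#' @param n Number of units.
#' @param grid A [build_frequency_grid()].
#' @param n_lags Kernel length in 25 ms history steps (default 13).
#' @param units_per_penetration Units per simulated electrode penetration.
#' @param threshold_q Rectifier threshold as a quantile of each unit's
#'   linear drive; a vector is sampled from per unit. The default (0.3-0.55
#'   per unit) gives substantial but not extreme rectification, so IC-like
#'   units are LN in ground truth yet imperfectly captured by an LN fit
#'   with a smooth output curve, as real midbrain units are.
#' @param target_rate Mean firing rate in spikes per bin (default 0.8, i.e.
#'   32 spikes/s at 25 ms bins).
#' @param seed Integer seed.
#' @return Unit manifest tibble with list-column `kernel`.
#' @export
make_ic_units <- function(n, grid = build_frequency_grid(1000, 64000, 4),
                          n_lags = 13L, units_per_penetration = 15L,
                          threshold_q = NULL, target_rate = 0.8, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 101L))
  thr <- if (is.null(threshold_q)) runif(n, 0.3, 0.55) else
    rep_len(threshold_q, n)
  nf <- length(grid$frequencies)
  bf <- runif(n, 1, nf)                     # best frequencies tile the grid
  bw <- runif(n, 1.2, 2.5)                  # tuning bandwidth (grid steps)
  lat <- sample.int(2L, n, replace = TRUE)  # temporal peak at lag 1-2
  kernels <- lapply(seq_len(n), function(i) {
    fr <- exp(-0.5 * ((seq_len(nf) - bf[i]) / bw[i])^2)
    h <- seq_len(n_lags) - 1L
    tp <- exp(-h / 1.5) * (h >= lat[i] - 1L) -
      0.45 * exp(-(h - lat[i] - 2)^2 / 2)
    k <- outer(fr, tp)
    k / sqrt(sum(k^2))
  })
  tibble(
    unit_id = sprintf("IC%03d", seq_len(n)),
    area = "IC",
    penetration = paste0("ICp", (seq_len(n) - 1L) %/% units_per_penetration + 1L),
    latency_bins = 1L,
    nl = "rectifier",
    threshold_q = thr,
    target_rate = target_rate,
    baseline = 0.05,
    kernel = kernels)
}

#' Make downstream (MGB- or A1-like) model units
#'
#' Each unit pools a random sparse subset of source-area units with positive
#' weights, applies an area latency, and passes the pooled drive through a
#' threshold-linear (rectifying) or identity nonlinearity. Rectification
#' with a threshold well above zero makes the composite map non-invertible,
#' which is what degrades linear (STRF) predictability downstream.
#'
#' @param n Number of units.
#' @param source_ids Character vector of source-area unit ids.
#' @param area `"MGB"` or `"A1"`.
#' @param n_sources Number of source units pooled per unit (default 4).
#' @param latency_bins Added response latency in bins (defaults: MGB 2,
#'   A1 3 at 25 ms bins — latency grows along the pathway).
#' @param threshold_q Rectifier threshold quantile of the pooled drive
#'   (defaults: MGB 0.5, A1 0.65).
#' @param nl `"rectifier"` or `"identity"`.
#' @param units_per_penetration Units per simulated penetration.
#' @param target_rate Mean rate, spikes per bin.
#' @param seed Integer seed.
#' @return Unit manifest tibble with list-column `mix` (named source
#'   weights).
#' @export
make_downstream_units <- function(n, source_ids, area = c("MGB", "A1"),
                                  n_sources = 3L,
                                  latency_bins = if (area == "MGB") 2L else 3L,
                                  threshold_q = if (area == "MGB") 0.65 else 0.75,
                                  nl = "rectifier",
                                  units_per_penetration = 10L,
                                  target_rate = if (area == "MGB") 0.6 else 0.45,
                                  seed = 1L) {
  area <- match.arg(area)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, if (area == "MGB") 202L else 303L))
  n_sources <- min(n_sources, length(source_ids))
  mixes <- lapply(seq_len(n), function(i) {
    src <- sample(source_ids, n_sources)
    w <- runif(n_sources, 0.3, 1)
    setNames(w / sum(w), src)
  })
  tibble(
    unit_id = sprintf("%s%03d", area, seq_len(n)),
    area = area,
    penetration = paste0(area, "p", (seq_len(n) - 1L) %/% units_per_penetration + 1L),
    latency_bins = as.integer(latency_bins),
    nl = nl,
    threshold_q = threshold_q,
    target_rate = target_rate,
    baseline = 0.04,
    mix = mixes)
}

# shift a per-bin series later in time by `by` bins, zero-filling after each
# boundary so responses never precede their stimulus within a trial
shift_series <- function(x, by, boundaries) {
  if (by == 0L) return(x)
  n <- length(x)
  seg <- segment_ids(n, boundaries)
  out <- numeric(n)
  idx <- seq_len(n) - by
  ok <- idx >= 1L & idx <= n
  ok[ok] <- seg[idx[ok]] == seg[ok]
  out[ok] <- x[idx[ok]]
  out
}

rectify_rate <- function(drive, nl, threshold_q, target_rate, baseline) {
  if (nl == "identity") {
    g <- drive - min(drive)
    sc <- mean(g)
    rate <- baseline + if (sc > 0) (target_rate - baseline) * g / sc else 0
  } else {
    th <- quantile(drive, threshold_q, names = FALSE)
    g <- pmax(drive - th, 0)
    sc <- mean(g)
    rate <- baseline + if (sc > 0) (target_rate - baseline) * g / sc else 0
  }
  pmax(rate, 0)
}

new_sim_recording <- function(counts, rates, units, bin_duration_ms,
                              trial_boundaries, condition = "active") {
  structure(
    list(counts = counts, rates = rates, units = units,
         bin_duration_ms = bin_duration_ms,
         trial_boundaries = trial_boundaries, condition = condition),
    class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("<sim_recording> %d units (%s), %d trials x %d bins, condition=%s\n",
              nrow(x$units), paste(unique(x$units$area), collapse = "/"),
              nrow(x$counts[[1]]), ncol(x$counts[[1]]), x$condition))
  invisible(x)
}

#' Simulate IC-like responses to a DRC
#'
#' Each unit's rate is `nonlinearity(a0 + sum_fh X_tfh k_fh)` over the
#' (mean-centered) cochleagram history tensor, delayed by the unit latency;
#' spikes are Poisson, independent across trials around that rate (frozen
#' stimulus, so the rate is identical on every trial).
#'
#' @param cochleagram A [generate_drc()] cochleagram.
#' @param units Manifest from [make_ic_units()].
#' @param n_trials Number of frozen-stimulus repeats.
#' @param seed Integer seed.
#' @return A `sim_recording`: per-unit trial x bin counts, ground-truth rate
#'   matrix (bins x units), unit manifest, trial boundaries.
#' @export
simulate_ic <- function(cochleagram, units, n_trials, seed = 1L) {
  nf <- ncol(cochleagram$levels)
  n_lags <- ncol(units$kernel[[1]])
  if (nrow(units$kernel[[1]]) != nf)
    abort("IC kernels are not defined on the cochleagram's frequency grid")
  X <- tensorize(cochleagram$levels - mean(cochleagram$levels),
                 (-(n_lags - 1L)):0L, cochleagram$trial_boundaries)
  Xf <- flatten_design(X)
  nb <- nrow(Xf)
  rates <- matrix(0, nb, nrow(units), dimnames = list(NULL, units$unit_id))
  for (i in seq_len(nrow(units))) {
    # unit kernels store history step h = 0..n_lags-1 in columns; the
    # design's lag offsets run ascending (-h ... 0), so flip
    k <- units$kernel[[i]][, n_lags:1, drop = FALSE]
    drive <- drop(Xf %*% as.vector(k))
    drive <- shift_series(drive, units$latency_bins[i],
                          cochleagram$trial_boundaries)
    rates[, i] <- rectify_rate(drive, units$nl[i], units$threshold_q[i],
                               units$target_rate[i], units$baseline[i])
  }
  draw_poisson_recording(rates, units, n_trials,
                         cochleagram$bin_duration_ms,
                         cochleagram$trial_boundaries, seed)
}

#' Simulate a downstream area from source ground-truth rates
#'
#' Each unit's rate is a static nonlinearity of a latency-delayed linear
#' combination of source-unit ground-truth rates, optionally gain-scaled by
#' a silencing condition; spikes are Poisson per trial.
#'
#' @param source A `sim_recording` for the source area.
#' @param units Manifest from [make_downstream_units()]; every id in each
#'   unit's `mix` must exist in the source recording.
#' @param n_trials Number of trials.
#' @param silencing A [silencing_condition()] or `NULL` (active).
#' @param seed Integer seed.
#' @return A `sim_recording`.
#' @export
simulate_downstream <- function(source, units, n_trials, silencing = NULL,
                                seed = 1L) {
  cond <- silencing %||% silencing_condition(active = TRUE)
  missing_src <- setdiff(unique(unlist(lapply(units$mix, names))),
                         colnames(source$rates))
  if (length(missing_src))
    abort(paste("mix references unknown source units:",
                paste(missing_src, collapse = ", ")))
  nb <- nrow(source$rates)
  rates <- matrix(0, nb, nrow(units), dimnames = list(NULL, units$unit_id))
  for (i in seq_len(nrow(units))) {
    mix <- units$mix[[i]]
    drive <- drop(source$rates[, names(mix), drop = FALSE] %*% mix)
    # source rates already carry the source area's latency; add the rest
    extra_lat <- max(0L, units$latency_bins[i] - source$units$latency_bins[1])
    drive <- shift_series(drive, extra_lat, source$trial_boundaries)
    gain <- if (units$area[i] == "MGB") cond$mgb_gain_factor else 1
    rates[, i] <- gain * rectify_rate(drive, units$nl[i], units$threshold_q[i],
                                      units$target_rate[i], units$baseline[i])
  }
  rec <- draw_poisson_recording(rates, units, n_trials,
                                source$bin_duration_ms,
                                source$trial_boundaries, seed,
                                trial_jitter_sd = cond$trial_jitter_sd)
  rec$condition <- if (cond$active) "active" else "silenced"
  rec
}

draw_poisson_recording <- function(rates, units, n_trials, bin_ms,
                                   trial_boundaries, seed,
                                   trial_jitter_sd = 0) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 404L))
  nb <- nrow(rates)
  counts <- lapply(seq_len(ncol(rates)), function(i) {
    jit <- if (trial_jitter_sd > 0)
      exp(rnorm(n_trials, -trial_jitter_sd^2 / 2, trial_jitter_sd))
    else rep(1, n_trials)
    matrix(rpois(n_trials * nb, rep(jit, each = nb) * rates[, i]),
           nrow = n_trials, ncol = nb, byrow = TRUE)
  })
  names(counts) <- colnames(rates)
  new_sim_recording(counts, rates, units, bin_ms, trial_boundaries)
}

#' Effective spectrotemporal kernel of a simulated LN unit
#'
#' A unit with response latency `latency_bins` acts on the stimulus through
#' its kernel delayed by that latency; this returns the ground-truth kernel
#' on the history axis a fitted STRF estimates (column `h` = response to the
#' stimulus `h` bins back, `h = 0 .. n_history-1`), for direct comparison
#' with `ln_kernel(fit)[, n_history:1]`.
#'
#' @param kernel Frequency x history ground-truth kernel (history step 0
#'   first).
#' @param latency_bins Unit latency in bins.
#' @param n_history History length of the fitted model (default 13).
#' @return Frequency x `n_history` matrix.
#' @export
effective_strf_kernel <- function(kernel, latency_bins, n_history = 13L) {
  out <- matrix(0, nrow(kernel), n_history)
  src <- seq_len(min(ncol(kernel), n_history - latency_bins))
  out[, src + latency_bins] <- kernel[, src]
  out
}

#' Cortical-silencing condition
#'
#' Emulates transient optogenetic suppression of cortex as seen from
#' downstream-targeted subcortical stations: thalamic gain drops (default
#' 30% rate decrease), within-penetration spike coupling weakens, and
#' cortex-driven trial-to-trial gain jitter disappears — while the linear
#' spectrotemporal tuning of the subcortical units is untouched.
#'
#' @param active `TRUE` for the control condition (all factors identity).
#' @param mgb_gain_factor Multiplicative rate gain on MGB-like units.
#' @param coupling_scale Multiplicative scale on ground-truth coupling
#'   filters in the coupled simulator.
#' @param trial_jitter_sd SD of per-trial lognormal gain jitter.
#' @return A `silencing_condition` list.
#' @export
silencing_condition <- function(active = TRUE,
                                mgb_gain_factor = if (active) 1 else 0.7,
                                coupling_scale = if (active) 1 else 0.5,
                                trial_jitter_sd = 0) {
  if (active && (mgb_gain_factor != 1 || coupling_scale != 1))
    abort("active condition must leave all factors at identity")
  structure(list(active = active, mgb_gain_factor = mgb_gain_factor,
                 coupling_scale = coupling_scale,
                 trial_jitter_sd = trial_jitter_sd),
            class = "silencing_condition")
}

#' Simulate the default three-area hierarchy scenario
#'
#' The workhorse scenario: an IC population with LN (rectified-linear)
#' ground truth, an MGB population pooling IC rates through a rectifier, and
#' an A1 population pooling MGB rates through a stronger rectifier. Latency
#' increases along the pathway (1, 2, 3 bins). All randomness derives from
#' `seed`.
#'
#' @param seed Master seed.
#' @param n_ic,n_mgb,n_a1 Population sizes (defaults 60/30/30).
#' @param n_chords Number of DRC chords (default 6000).
#' @param n_trials Frozen-stimulus repeats (default 10).
#' @param contrast Stimulus contrast condition.
#' @param silencing Optional [silencing_condition()] applied to MGB and A1.
#' @param session Integer session index offsetting only the spike-draw
#'   random streams: the same `seed` with different `session`s yields the
#'   same stimulus, units and ground-truth rates but independent
#'   trial-to-trial noise, emulating separate blocks of trials (e.g. the
#'   cortex-active and cortex-silenced halves of a silencing experiment).
#' @return List with `stimulus` (cochleagram) and `sim_recording`s `ic`,
#'   `mgb`, `a1`, plus the combined unit manifest `units`.
#' @export
simulate_hierarchy <- function(seed = 1L, n_ic = 60L, n_mgb = 30L,
                               n_a1 = 30L, n_chords = 6000L, n_trials = 10L,
                               contrast = "low", silencing = NULL,
                               session = 0L) {
  n_trial_chunks <- max(1L, n_chords %/% 200L)
  while (n_chords %% n_trial_chunks != 0L) n_trial_chunks <- n_trial_chunks - 1L
  spec <- drc_spec(n_chords, contrast, n_trials = n_trial_chunks,
                   n_repeats = n_trials, seed = split_seed(seed, 1L))
  coch <- generate_drc(spec)
  off <- 100L * as.integer(session)
  ic_units <- make_ic_units(n_ic, seed = split_seed(seed, 2L))
  ic <- simulate_ic(coch, ic_units, n_trials,
                    seed = split_seed(seed, 3L + off))
  mgb_units <- make_downstream_units(n_mgb, ic_units$unit_id, "MGB",
                                     seed = split_seed(seed, 4L))
  mgb <- simulate_downstream(ic, mgb_units, n_trials, silencing,
                             seed = split_seed(seed, 5L + off))
  a1_units <- make_downstream_units(n_a1, mgb_units$unit_id, "A1",
                                    seed = split_seed(seed, 6L))
  a1_src <- mgb
  a1 <- simulate_downstream(a1_src, a1_units, n_trials, silencing,
                            seed = split_seed(seed, 7L + off))
  list(stimulus = coch, ic = ic, mgb = mgb, a1 = a1,
       units = bind_rows(select(ic_units, -"kernel"),
                         select(mgb_units, -"mix"),
                         select(a1_units, -"mix")))
}

#' PSTH matrix of a simulated recording
#'
#' @param recording A `sim_recording`.
#' @return Bins x units matrix of trial-averaged responses.
#' @export
psth_matrix <- function(recording) {
  vapply(recording$counts, colMeans, numeric(ncol(recording$counts[[1]])))
}

#' Write / read a simulated recording as plain text
#'
#' Per-unit spike counts go to `<path>_counts.csv` (long format: unit_id,
#' trial, bin, count — zeros omitted), ground-truth rates to
#' `<path>_rates.csv`, and the unit manifest plus dimensions to
#' `<path>_meta.json`. Kernel/mix list-columns are not serialized.
#'
#' @param recording A `sim_recording`.
#' @param path File-path stem.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the restored `sim_recording`.
#' @export
write_recording <- function(recording, path) {
  long <- bind_rows(imap(recording$counts, function(cm, id) {
    nz <- which(cm > 0, arr.ind = TRUE)
    tibble(unit_id = id, trial = nz[, 1], bin = nz[, 2],
           count = cm[nz])
  }))
  write.csv(long, paste0(path, "_counts.csv"), row.names = FALSE)
  write.csv(as.data.frame(recording$rates), paste0(path, "_rates.csv"),
            row.names = FALSE)
  units <- recording$units
  units <- units[, !vapply(units, is.list, logical(1))]
  jsonlite::write_json(
    list(units = units,
         n_trials = nrow(recording$counts[[1]]),
         n_bins = ncol(recording$counts[[1]]),
         bin_duration_ms = recording$bin_duration_ms,
         trial_boundaries = recording$trial_boundaries,
         condition = recording$condition),
    paste0(path, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_meta.json"),
                              simplifyVector = TRUE)
  long <- read.csv(paste0(path, "_counts.csv"))
  rates <- as.matrix(read.csv(paste0(path, "_rates.csv"), check.names = FALSE))
  units <- as_tibble(meta$units)
  counts <- lapply(units$unit_id, function(id) {
    cm <- matrix(0L, meta$n_trials, meta$n_bins)
    rows <- long[long$unit_id == id, ]
    cm[cbind(rows$trial, rows$bin)] <- rows$count
    cm
  })
  names(counts) <- units$unit_id
  new_sim_recording(counts, rates, units, meta$bin_duration_ms,
                    as.integer(meta$trial_boundaries), meta$condition)
}
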