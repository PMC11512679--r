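# Discrete-time conditional-intensity simulation of a coupled population at
# 5 ms bins: the generative twin of the Poisson coupling GLM, used for
# parameter-recovery experiments.

#' Simulate a population with ground-truth spike coupling
#'
#' Spikes are drawn sequentially bin by bin from
#' `n_i(t) ~ Poisson(exp(s_i(t) + sum_j (F_ij * n_j)(t) + (h_i * n_i)(t)))`
#' where `s_i` is the per-unit stimulus drive (log-rate), `F_ij` are
#' coupling filters from unit `j` to unit `i` and `h_i` is the unit's own
#' spike-history filter; all filters act on lags of at least one bin (lag 0
#' excluded), so units are conditionally independent given the past. The
#' log rate is clamped at `log(max_rate)`; if the realized mean rate
#' exceeds `explode_limit` the simulation aborts with a diagnostic (a
#' positive-feedback loop has run away).
#'
#' @param stimulus_drive Bins x units matrix of log-rate drives for one
#'   sweep of the stimulus (repeated on every trial).
#' @param coupling_filters Array `[target, source, lag]` on the 5 ms lag
#'   grid; the diagonal must be zero (self terms go in
#'   `history_filters`).
#' @param history_filters Units x lag matrix of spike-history filters.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param bin_ms Bin width (default 5).
#' @param max_rate Per-bin rate clamp (spikes/bin, default 3).
#' @param explode_limit Mean-rate abort threshold (spikes/bin, default 2).
#' @return A `sim_recording` (units named `U01`, ... in one penetration)
#'   with `$coupling` holding the ground-truth filters.
#' @export
simulate_coupled_population <- function(stimulus_drive, coupling_filters,
                                        history_filters, n_trials, seed = 1L,
                                        bin_ms = 5, max_rate = 3,
                                        explode_limit = 2) {
  S <- as.matrix(stimulus_drive)
  nb <- nrow(S); U <- ncol(S)
  stopifnot(dim(coupling_filters)[1] == U, dim(coupling_filters)[2] == U,
            nrow(history_filters) == U)
  L <- dim(coupling_filters)[3]
  Lh <- ncol(history_filters)
  if (any(abs(vapply(seq_len(U), function(i) sum(abs(coupling_filters[i, i, ])),
                     numeric(1))) > 0))
    abort("coupling_filters diagonal must be zero; use history_filters")
  # [target, source*lag] layout matching as.vector of an L x U spike block
  Fmat <- matrix(0, U, U * L)
  for (j in seq_len(U)) for (l in seq_len(L))
    Fmat[, (j - 1L) * L + l] <- coupling_filters[, j, l]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 606L))
  log_max <- log(max_rate)
  counts <- array(0L, dim = c(n_trials, nb, U))
  for (d in seq_len(n_trials)) {
    n <- matrix(0L, nb, U)
    recent <- matrix(0L, L, U)   # row l = spikes at t - l
    for (t in seq_len(nb)) {
      cc <- drop(Fmat %*% as.vector(recent))
      hh <- colSums(t(history_filters) * recent[seq_len(Lh), , drop = FALSE])
      lam <- exp(pmin(S[t, ] + cc + hh, log_max))
      n[t, ] <- rpois(U, lam)
      recent <- rbind(n[t, ], recent[-L, , drop = FALSE])
    }
    if (mean(n) > explode_limit)
      abort(sprintf(
        "unstable coupled simulation: mean rate %.2f spikes/bin exceeds %g",
        mean(n), explode_limit))
    counts[d, , ] <- n
  }
  ids <- sprintf("U%02d", seq_len(U))
  units <- tibble(unit_id = ids, area = "IC", penetration = "p1",
                  latency_bins = 0L)
  count_list <- lapply(seq_len(U), function(i) counts[, , i, drop = FALSE][, , 1])
  names(count_list) <- ids
  rec <- new_sim_recording(count_list, rates = NULL, units = units,
                           bin_duration_ms = bin_ms, trial_boundaries = 1L)
  rec$coupling <- list(filters = coupling_filters,
                       history = history_filters,
                       stimulus_drive = S,
                       lags_ms = bin_ms * seq_len(L),
                       history_lags_ms = bin_ms * seq_len(Lh))
  rec
}

#' Default coupled-population scenario
#'
#' A single simulated penetration of `n_units` units driven by a DRC: each
#' unit's stimulus drive is a temporally filtered version of the
#' frequency-averaged sound level, and a random subset of directed pairs
#' carries ground-truth coupling filters built on the standard 12-function
#' basis (fast excitatory lobe at 5-10 ms plus a weak slow inhibitory
#' tail). All units have a refractory-style negative history filter.
#'
#' @param seed Master seed.
#' @param n_units Population size (default 5).
#' @param n_chords Number of DRC chords (default 6000).
#' @param n_trials Number of trials (default 7: 5 train + 2 test).
#' @param coupling_scale Scale on all coupling filters (a silenced cortex
#'   is emulated with values < 1; 0 removes coupling).
#' @param p_connect Probability that a directed pair is coupled.
#' @param base_rate Baseline rate, spikes per 5 ms bin.
#' @param contrast Stimulus contrast condition.
#' @return List: `recording` (5 ms `sim_recording`), `stimulus`
#'   (cochleagram), `coupling` (ground-truth filter array), `coupled_pairs`
#'   tibble.
#' @export
coupled_scenario <- function(seed = 1L, n_units = 5L, n_chords = 6000L,
                             n_trials = 7L, coupling_scale = 1,
                             p_connect = 0.4, base_rate = 0.12,
                             contrast = "low") {
  spec <- drc_spec(n_chords, contrast, seed = split_seed(seed, 1L))
  coch <- generate_drc(spec)
  up_factor <- as.integer(spec$chord_duration_ms / 5)
  lt <- rowMeans(coch$levels) - mean(coch$levels)
  lt5 <- rep(lt, each = up_factor)
  nb <- length(lt5)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 2L))
  # per-unit temporal filter of the summed level history (25 lags of 5 ms)
  S <- matrix(0, nb, n_units)
  for (i in seq_len(n_units)) {
    lagk <- runif(1, 1.5, 4)
    h <- 0:24
    w <- exp(-(h - lagk)^2 / 4) - 0.4 * exp(-(h - lagk - 5)^2 / 8)
    w <- w / sum(abs(w))
    drive <- stats::filter(c(rep(0, 25), lt5), c(0, w), sides = 1)[26:(25 + nb)]
    S[, i] <- log(base_rate) + 0.10 * runif(1, 0.7, 1.3) * drive
  }
  bc <- coupling_basis()
  L <- length(bc$lags_ms)
  Fk <- array(0, dim = c(n_units, n_units, L))
  pairs <- list()
  for (i in seq_len(n_units)) for (j in seq_len(n_units)) {
    if (i == j) next
    if (runif(1) < p_connect) {
      co <- numeric(12)
      co[1:2] <- c(runif(1, 0.5, 0.9), runif(1, 0.2, 0.5))     # fast excitation
      co[5:7] <- -runif(3, 0.02, 0.08)                          # slow inhibition
      Fk[i, j, ] <- coupling_scale * reconstruct_filter(co, bc)
      pairs[[length(pairs) + 1L]] <- tibble(target = i, source = j)
    }
  }
  bh <- history_basis()
  H <- matrix(0, n_units, length(bh$lags_ms))
  for (i in seq_len(n_units)) {
    hco <- c(-1.2, -0.6, -runif(5, 0.02, 0.1))
    H[i, ] <- reconstruct_filter(hco, bh)
  }
  rec <- simulate_coupled_population(S, Fk, H, n_trials,
                                     seed = split_seed(seed, 3L))
  list(recording = rec, stimulus = coch, coupling = Fk, history = H,
       coupled_pairs = bind_rows(pairs))
}
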