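#' Bin spike times into a trial x bin count matrix
#'
#' @param spikes List with one numeric vector of spike times (ms, relative to
#'   trial onset) per trial.
#' @param trial_duration_ms Duration of each trial in ms; must be a multiple
#'   of `bin_duration_ms`.
#' @param bin_duration_ms Bin width in ms (25 for the trial-averaged models,
#'   5 for the single-trial GLM).
#' @return Integer matrix, trials x bins. Spikes outside `[0,
#'   trial_duration_ms)` are dropped; their count is reported via a warning
#'   and stored in the `"n_dropped"` attribute.
#' @examples
#' bin_spikes(list(c(1, 26, 27)), 50, 25)  # counts 1 and 2
#' @export
bin_spikes <- function(spikes, trial_duration_ms, bin_duration_ms) {
  if (trial_duration_ms %% bin_duration_ms != 0)
    abort("bin_duration_ms must divide trial_duration_ms")
  n_bins <- as.integer(trial_duration_ms / bin_duration_ms)
  dropped <- 0L
  counts <- t(vapply(spikes, function(st) {
    ok <- st >= 0 & st < trial_duration_ms
    dropped <<- dropped + sum(!ok)
    tabulate(floor(st[ok] / bin_duration_ms) + 1L, nbins = n_bins)
  }, integer(n_bins)))
  if (dropped > 0L)
    warn(sprintf("%d spikes outside trial bounds were dropped", dropped))
  attr(counts, "n_dropped") <- dropped
  attr(counts, "bin_duration_ms") <- bin_duration_ms
  counts
}

#' Rebin a count matrix to a coarser resolution
#'
#' Sums groups of adjacent bins; rebinning 5 ms counts by a factor of 5
#' reproduces 25 ms counts exactly.
#'
#' @param counts Trials x bins matrix.
#' @param factor Integer number of bins to merge; must divide `ncol(counts)`.
#' @return Trials x (bins / factor) matrix.
#' @export
rebin_counts <- function(counts, factor) {
  factor <- as.integer(factor)
  if (ncol(counts) %% factor != 0) abort("factor must divide the bin count")
  grp <- rep(seq_len(ncol(counts) %/% factor), each = factor)
  out <- t(rowsum(t(counts), grp))
  dimnames(out) <- NULL
  out
}

#' Peristimulus time histogram
#'
#' @param counts Trials x bins spike-count matrix.
#' @return Numeric vector of per-bin mean counts (column means).
#' @export
psth <- function(counts) colMeans(counts)

#' Lagged (tensorized) design from a time x channel matrix
#'
#' Builds the time x channel x lag tensor used by the linear stages: entry
#' `[t, c, j]` equals `source[t + lag_offsets[j], c]`. Negative offsets are
#' past samples. Samples are zero where `t + offset` falls outside the series
#' or crosses a boundary in `boundaries` (trial joins and cross-validation
#' segment joins), so no information leaks across those joins through the
#' lags.
#'
#' @param source Time x channel numeric matrix (a cochleagram's levels, or a
#'   matrix of source-unit PSTHs).
#' @param lag_offsets Sorted integer offsets; STRFs use `0:-12` (13 history
#'   steps), population communication models use `-8:5` (8 history + same
#'   bin + 5 future steps).
#' @param boundaries Integer vector of first-bin indices of contiguous
#'   segments (default: one segment).
#' @return 3-d array time x channel x lag with attributes `lag_offsets` and
#'   `channel_ids`.
#' @export
tensorize <- function(source, lag_offsets, boundaries = 1L) {
  source <- as.matrix(source)
  lag_offsets <- as.integer(lag_offsets)
  if (is.unsorted(lag_offsets)) abort("lag_offsets must be sorted")
  n <- nrow(source); nc <- ncol(source)
  seg <- segment_ids(n, boundaries)
  out <- array(0, dim = c(n, nc, length(lag_offsets)))
  t_all <- seq_len(n)
  for (j in seq_along(lag_offsets)) {
    src_t <- t_all + lag_offsets[j]
    ok <- src_t >= 1L & src_t <= n
    ok[ok] <- seg[src_t[ok]] == seg[ok]
    out[ok, , j] <- source[src_t[ok], , drop = FALSE]
  }
  attr(out, "lag_offsets") <- lag_offsets
  attr(out, "channel_ids") <- colnames(source) %||% seq_len(nc)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

segment_ids <- function(n, boundaries) {
  boundaries <- sort(unique(as.integer(boundaries)))
  if (length(boundaries) == 0L || boundaries[1] != 1L)
    boundaries <- c(1L, boundaries)
  findInterval(seq_len(n), boundaries)
}

# Flatten a time x channel x lag tensor to a time x (channel*lag) matrix,
# channel index varying fastest (column block per lag).
flatten_design <- function(tensor) {
  d <- dim(tensor)
  out <- tensor
  dim(out) <- c(d[1], d[2] * d[3])
  attr(out, "design_dims") <- d[2:3]
  attr(out, "lag_offsets") <- attr(tensor, "lag_offsets")
  out
}

#' Select units by response reliability (noise ratio)
#'
#' Units whose trial-to-trial variability dwarfs their stimulus-locked signal
#' are excluded from trial-averaged model fitting using the noise ratio
#' NR = noise power / signal power; the standard inclusion rule is NR < 200.
#'
#' @param recording A `sim_recording` (see [simulate_ic()]) or a named list
#'   of trial x bin count matrices.
#' @param threshold Inclusion threshold on NR (default 200). `Inf` keeps all
#'   units with a defined NR.
#' @return Tibble with one row per unit: `unit_id`, `noise_ratio`,
#'   `included`, `reason` (`NA` when included).
#' @export
noise_ratio_filter <- function(recording, threshold = 200) {
  counts <- recording_counts(recording)
  rows <- imap(counts, function(cm, id) {
    if (is.null(dim(cm)) || nrow(cm) < 2L) {
      return(tibble(unit_id = id, noise_ratio = NA_real_, included = FALSE,
                    reason = "fewer than 2 trials: noise ratio undefined"))
    }
    rel <- unit_reliability(cm)
    inc <- is.finite(rel$noise_ratio) && rel$noise_ratio < threshold
    tibble(unit_id = id, noise_ratio = rel$noise_ratio, included = inc,
           reason = if (inc) NA_character_ else
             sprintf("noise ratio %.3g >= %.3g", rel$noise_ratio, threshold))
  })
  bind_rows(rows)
}

recording_counts <- function(recording) {
  if (inherits(recording, "sim_recording")) recording$counts
  else if (is.list(recording)) {
    if (is.null(names(recording)))
      names(recording) <- sprintf("u%03d", seq_along(recording))
    recording
  } else abort("expected a sim_recording or a list of count matrices")
}
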