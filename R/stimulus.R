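#' Logarithmic tone-frequency grid
#'
#' Builds the grid of tone frequencies used by dynamic random chord (DRC)
#' stimuli: frequencies logarithmically spaced between `fmin` and `fmax`,
#' endpoints inclusive, with `steps_per_octave` tones per octave. The
#' standard stimulus uses 25 frequencies from 1 to 64 kHz at quarter-octave
#' spacing.
#'
#' @param fmin,fmax Lowest and highest tone frequency in Hz. The octave span
#'   `log2(fmax/fmin)` times `steps_per_octave` must be an integer (within
#'   1e-6), so both endpoints sit on the grid.
#' @param steps_per_octave Number of grid steps per octave (integer >= 1).
#' @return A `frequency_grid` object: list with `frequencies` (Hz, strictly
#'   increasing), `fmin`, `fmax`, `steps_per_octave`.
#' @examples
#' g <- build_frequency_grid(1000, 64000, 4)
#' length(g$frequencies)  # 25
#' @export
build_frequency_grid <- function(fmin, fmax, steps_per_octave) {
  if (!(fmin > 0) || fmax < fmin) abort("need fmax >= fmin > 0")
  steps_per_octave <- as.integer(steps_per_octave)
  if (steps_per_octave < 1) abort("steps_per_octave must be >= 1")
  span <- log2(fmax / fmin) * steps_per_octave
  if (abs(span - round(span)) > 1e-6) {
    abort(sprintf(
      "octave span of [%g, %g] Hz is not an integer number of 1/%d-octave steps",
      fmin, fmax, steps_per_octave))
  }
  n_steps <- as.integer(round(span))
  freqs <- fmin * 2^(seqic(0L, n_steps) / steps_per_octave)
  freqs[length(freqs)] <- fmax
  structure(
    list(frequencies = freqs, fmin = fmin, fmax = fmax,
         steps_per_octave = steps_per_octave),
    class = "frequency_grid")
}

# integer sequence that is empty-safe for n_steps = 0
seqic <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

contrast_level_bounds <- function(contrast) {
  switch(contrast,
    low = c(30, 50),
    high = c(20, 60),
    abort("contrast must be 'low' or 'high'"))
}

#' Specify a dynamic random chord stimulus
#'
#' A DRC is a sequence of 25 ms chords; in each chord every grid frequency is
#' present at an independently drawn sound level. Low contrast draws levels
#' uniformly from 30-50 dB SPL, high contrast from 20-60 dB SPL; the mean is
#' 40 dB SPL in both conditions.
#'
#' @param n_chords Total number of chords (time bins).
#' @param contrast `"low"` or `"high"`.
#' @param chord_duration_ms Chord duration in ms (default 25).
#' @param n_trials Number of contiguous trials the chord sequence is split
#'   into; `n_chords` must be divisible by `n_trials`.
#' @param n_repeats Number of frozen repeats of the full sequence presented
#'   to obtain trial-to-trial variability (used by the simulators).
#' @param seed Integer RNG seed for the level draws.
#' @return A `drc_spec` object.
#' @export
drc_spec <- function(n_chords, contrast = c("low", "high"),
                     chord_duration_ms = 25, n_trials = 1L,
                     n_repeats = 1L, seed = 1L) {
  contrast <- match.arg(contrast)
  n_chords <- as.integer(n_chords)
  n_trials <- as.integer(n_trials)
  if (n_chords < 1L) abort("n_chords must be positive")
  if (n_chords %% n_trials != 0L)
    abort("n_chords must be a multiple of n_trials")
  structure(
    list(n_chords = n_chords, contrast = contrast,
         level_bounds = contrast_level_bounds(contrast),
         chord_duration_ms = chord_duration_ms,
         n_trials = n_trials, chords_per_trial = n_chords %/% n_trials,
         n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
    class = "drc_spec")
}

#' Dataset-style DRC presets
#'
#' `drc_dataset_h()`: 6,400 chords in 40 s trials, 8 frozen repeats.
#' `drc_dataset_o()`: 6,000 chords in 5 s trials, 10 frozen repeats (the
#' configuration used with cortical silencing).
#'
#' @param contrast `"low"` or `"high"`.
#' @param seed Integer RNG seed.
#' @return A `drc_spec`.
#' @export
drc_dataset_h <- function(contrast = "low", seed = 1L) {
  drc_spec(6400L, contrast, n_trials = 4L, n_repeats = 8L, seed = seed)
}

#' @rdname drc_dataset_h
#' @export
drc_dataset_o <- function(contrast = "low", seed = 1L) {
  drc_spec(6000L, contrast, n_trials = 30L, n_repeats = 10L, seed = seed)
}

#' Generate a DRC cochleagram
#'
#' Draws the chord-by-frequency matrix of tone levels (dB SPL), i.i.d.
#' uniform within the contrast's level bounds. This matrix is the stimulus
#' representation consumed by all encoding models (a log-spectrogram /
#' cochleagram); no audio waveform is synthesized.
#'
#' @param spec A [drc_spec()].
#' @param grid A [build_frequency_grid()]; defaults to the standard 25
#'   quarter-octave frequencies from 1 to 64 kHz.
#' @return A `cochleagram` object: `levels` (n_chords x n_frequencies matrix,
#'   dB SPL), `frequencies`, `bin_duration_ms`, `trial_boundaries` (first bin
#'   of each trial), and the generating `spec`.
#' @examples
#' coch <- generate_drc(drc_spec(100, "low", seed = 7))
#' range(coch$levels)  # within [30, 50]
#' @export
generate_drc <- function(spec, grid = build_frequency_grid(1000, 64000, 4)) {
  stopifnot(inherits(spec, "drc_spec"), inherits(grid, "frequency_grid"))
  nf <- length(grid$frequencies)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lv <- matrix(runif(spec$n_chords * nf, spec$level_bounds[1], spec$level_bounds[2]),
               nrow = spec$n_chords, ncol = nf)
  colnames(lv) <- sprintf("f%02d", seq_len(nf))
  structure(
    list(levels = lv,
         frequencies = grid$frequencies,
         bin_duration_ms = spec$chord_duration_ms,
         trial_boundaries = seq.int(1L, spec$n_chords, by = spec$chords_per_trial),
         spec = spec),
    class = "cochleagram")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram> %d chords x %d frequencies, %g ms bins, %s contrast\n",
              nrow(x$levels), ncol(x$levels), x$bin_duration_ms,
              x$spec$contrast))
  invisible(x)
}

#' Write / read a cochleagram as plain text
#'
#' The levels matrix is stored as CSV and the metadata (frequencies, bin
#' duration, trial boundaries, generating spec) as a JSON sidecar with
#' extension `.json` appended to `path`.
#'
#' @param x A `cochleagram`.
#' @param path CSV file path.
#' @return `write_cochleagram` returns `path` invisibly; `read_cochleagram`
#'   returns the restored `cochleagram`.
#' @export
write_cochleagram <- function(x, path) {
  stopifnot(inherits(x, "cochleagram"))
  write.csv(as.data.frame(x$levels), path, row.names = FALSE)
  meta <- list(frequencies = x$frequencies,
               bin_duration_ms = x$bin_duration_ms,
               trial_boundaries = x$trial_boundaries,
               spec = unclass(x$spec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cochleagram
#' @export
read_cochleagram <- function(path) {
  lv <- as.matrix(read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- meta$spec
  spec$contrast <- as.character(spec$contrast)
  class(spec) <- "drc_spec"
  structure(
    list(levels = lv, frequencies = meta$frequencies,
         bin_duration_ms = meta$bin_duration_ms,
         trial_boundaries = as.integer(meta$trial_boundaries),
         spec = spec),
    class = "cochleagram")
}
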