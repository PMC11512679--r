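#' Contiguous train / validation / test segmentation of the stimulus
#'
#' The stimulus timeline is divided into `n_segments` equally sized
#' contiguous segments (any remainder bins go to the final segment). Models
#' are trained on all segments except the test segment; the penalty /
#' hyperparameter is selected on a contiguous validation slice consisting of
#' the last `validation_fraction` of the training bins. Lag tensorization is
#' zero-padded at every segment boundary so train and test never share
#' samples through the lags.
#'
#' @param n_bins Total number of time bins.
#' @param n_segments Number of segments (16 for the main analyses, 15 for
#'   the silencing analyses).
#' @param test_index Which segment is held out (default: the last).
#' @param validation_fraction Fraction of training bins used for
#'   hyperparameter selection (default 0.2).
#' @return A `segmentation_plan`: `segment_starts`, `segment_of` (segment id
#'   per bin), `test_bins`, `train_bins`, `validation_bins`, `boundaries`.
#' @examples
#' p <- make_segments(160, 16)
#' lengths(split(seq_len(160), p$segment_of))  # all 10
#' @export
make_segments <- function(n_bins, n_segments = 16L, test_index = n_segments,
                          validation_fraction = 0.2) {
  n_bins <- as.integer(n_bins); n_segments <- as.integer(n_segments)
  if (n_segments > n_bins) abort("more segments than bins")
  if (test_index < 1L || test_index > n_segments) abort("bad test_index")
  base <- n_bins %/% n_segments
  starts <- 1L + base * (seq_len(n_segments) - 1L)
  segment_of <- pmin(findInterval(seq_len(n_bins), starts), n_segments)
  test_bins <- which(segment_of == test_index)
  train_bins <- which(segment_of != test_index)
  n_val <- max(1L, as.integer(floor(validation_fraction * length(train_bins))))
  validation_bins <- tail(train_bins, n_val)
  structure(
    list(n_bins = n_bins, n_segments = n_segments, test_index = test_index,
         segment_starts = starts, segment_of = segment_of,
         test_bins = test_bins, train_bins = train_bins,
         validation_bins = validation_bins,
         boundaries = starts),
    class = "segmentation_plan")
}

#' Compare two sets of per-unit model performances
#'
#' Applies the package's standard nonparametric machinery: Wilcoxon
#' signed-rank for paired arms (zero differences dropped; if all
#' differences are zero, p = 1 by convention) or Mann-Whitney U for
#' independent arms, plus bootstrap 95% confidence intervals (percentile,
#' resampling with replacement) for the median of each arm and for the
#' median paired difference.
#'
#' @param a,b Numeric vectors of per-unit scores (aligned unit-for-unit when
#'   `paired = TRUE`). `NA`s are removed (pairwise when paired).
#' @param paired Paired Wilcoxon (TRUE) or independent Mann-Whitney (FALSE).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: `n`, `median_a`, `median_b`, `median_diff` (a -
#'   b; paired median of differences, otherwise difference of medians),
#'   `ci_lo`, `ci_hi` (CI of `median_diff`), `p_value`, `test`,
#'   `reliable_p` (FALSE when n < 5).
#' @export
compare_models <- function(a, b, paired = TRUE, n_boot = 10000L, seed = 1L) {
  if (paired) {
    if (length(a) != length(b)) abort("paired arms must have equal length")
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    d <- a - b
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(d[d != 0], exact = FALSE)$p.value)
    test <- "wilcoxon_signed_rank"
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (length(a) && length(b))
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value) else NA_real_
    test <- "mann_whitney_u"
  }
  n <- if (paired) length(a) else min(length(a), length(b))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 17L))
  boots <- boot_medians(a, b, paired, n_boot)
  tibble(n = n,
         median_a = median(a), median_b = median(b),
         median_diff = if (paired) median(a - b) else median(a) - median(b),
         ci_lo = boots[1], ci_hi = boots[2],
         p_value = p, test = test, reliable_p = n >= 5L)
}

boot_medians <- function(a, b, paired, n_boot) {
  if (paired) {
    d <- a - b
    m <- vapply(seq_len(n_boot), function(i)
      median(d[sample.int(length(d), replace = TRUE)]), numeric(1))
  } else {
    m <- vapply(seq_len(n_boot), function(i)
      median(a[sample.int(length(a), replace = TRUE)]) -
        median(b[sample.int(length(b), replace = TRUE)]), numeric(1))
  }
  unname(quantile(m, c(0.025, 0.975), type = 7))
}

#' Bootstrap confidence interval for a median
#'
#' Percentile bootstrap CI (default 95%) of the median of `x`, resampling
#' with replacement.
#'
#' @param x Numeric vector (`NA`s dropped).
#' @param n_boot Number of resamples.
#' @param conf Confidence level.
#' @param seed Seed for resampling.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  x <- x[is.finite(x)]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 29L))
  m <- vapply(seq_len(n_boot), function(i)
    median(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  al <- (1 - conf) / 2
  stats::setNames(unname(quantile(m, c(al, 1 - al), type = 7)), c("lo", "hi"))
}
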