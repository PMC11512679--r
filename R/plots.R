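#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_hline
#'   geom_point geom_abline scale_fill_gradient2 scale_x_log10 facet_wrap
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a cochleagram
#'
#' @param object A `cochleagram`.
#' @param max_bins Plot at most this many leading chords.
#' @param ... Unused.
#' @return A ggplot: time x frequency heatmap of tone levels (dB SPL).
#' @export
autoplot.cochleagram <- function(object, max_bins = 200L, ...) {
  nb <- min(nrow(object$levels), max_bins)
  df <- tibble(
    time_s = rep(seq_len(nb) * object$bin_duration_ms / 1000,
                 times = ncol(object$levels)),
    frequency_khz = rep(object$frequencies / 1000, each = nb),
    level = as.vector(object$levels[seq_len(nb), ]))
  ggplot(df, aes(.data$time_s, .data$frequency_khz, fill = .data$level)) +
    geom_tile() +
    scale_x_log10() +
    labs(x = "time (s)", y = "frequency (kHz)", fill = "dB SPL") +
    theme_minimal()
}

#' Plot a fitted linear-nonlinear kernel
#'
#' STRFs are drawn as frequency x history heatmaps; PCM weights as source
#' unit x lag heatmaps.
#'
#' @param object An `ln_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ln_model <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = unique(df$channel))
  ggplot(df, aes(.data$lag, .data$channel, fill = .data$estimate)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "lag (bins)",
         y = if (object$kind == "STRF") "frequency channel" else "source unit",
         fill = "weight",
         title = sprintf("%s kernel", object$kind)) +
    theme_minimal()
}

#' Plot reconstructed coupling / history filters
#'
#' @param filters Tibble from [coupling_filters()].
#' @return A ggplot: one panel per source unit, filter value against lag.
#' @export
plot_coupling_filters <- function(filters) {
  ggplot(filters, aes(.data$lag_ms, .data$value)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    facet_wrap(~source, scales = "free_y") +
    labs(x = "lag (ms)", y = "filter weight") +
    theme_minimal()
}

#' Paired per-unit model comparison scatter
#'
#' One point per unit, model A performance against model B, with the unity
#' line; the standard way to display a paired CC_norm comparison.
#'
#' @param results Results tibble (as from [run_experiment()]).
#' @param model_a,model_b Model labels in `results$model`.
#' @param metric Column to compare (default `"cc_norm"`).
#' @return A ggplot.
#' @export
plot_model_comparison <- function(results, model_a, model_b,
                                  metric = "cc_norm") {
  a <- filter(results, .data$model == model_a)
  b <- filter(results, .data$model == model_b)
  df <- left_join(select(a, "unit_id", a_val = !!metric),
                  select(b, "unit_id", b_val = !!metric), by = "unit_id")
  ggplot(df, aes(.data$b_val, .data$a_val)) +
    geom_abline(linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.6) +
    labs(x = model_b, y = model_a) +
    theme_minimal()
}
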