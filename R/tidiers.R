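#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted linear-nonlinear model
#'
#' @param x An `ln_model`.
#' @param ... Unused.
#' @return Tibble with one row per (channel, lag) weight: `channel`, `lag`,
#'   `estimate`.
#' @export
tidy.ln_model <- function(x, ...) {
  k <- ln_kernel(x)
  tibble(channel = rep(rownames(k), times = ncol(k)),
         lag = rep(x$lag_offsets, each = nrow(k)),
         estimate = as.vector(k))
}

#' One-row summary of a fitted linear-nonlinear model
#'
#' @param x An `ln_model`.
#' @param ... Unused.
#' @return Tibble: model kind, ridge penalty, output-nonlinearity
#'   parameters, and held-out performance when the model was evaluated.
#' @export
glance.ln_model <- function(x, ...) {
  ev <- x$evaluation %||% tibble(cc_abs = NA_real_, cc_max = NA_real_,
                                 cc_norm = NA_real_, reliable = NA)
  tibble(kind = x$kind, n_channels = x$dims[1], n_lags = x$dims[2],
         lambda = x$linear$lambda,
         nl_a = x$nonlinearity$a, nl_b = x$nonlinearity$b,
         nl_c = x$nonlinearity$c, nl_d = x$nonlinearity$d,
         nl_fallback = x$nonlinearity$fallback,
         cc_abs = ev$cc_abs, cc_max = ev$cc_max, cc_norm = ev$cc_norm)
}

#' Tidy a fitted Poisson coupling GLM
#'
#' @param x A `poisson_glm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `block` (stimulus,
#'   coupling:<unit>, history), `index` within the block, `estimate`.
#' @export
tidy.poisson_glm_fit <- function(x, ...) {
  rows <- lapply(names(x$blocks), function(nm) {
    idx <- match(x$blocks[[nm]], x$kept_cols)
    if (anyNA(idx)) return(NULL)
    tibble(block = nm, index = seq_along(idx),
           estimate = unname(x$coefficients[idx]))
  })
  bind_rows(rows)
}

#' One-row summary of a fitted Poisson coupling GLM
#'
#' @param x A `poisson_glm_fit`.
#' @param ... Unused.
#' @return Tibble: target unit, number of partners, penalty, intercept.
#' @export
glance.poisson_glm_fit <- function(x, ...) {
  tibble(target = x$target_id, n_partners = length(x$partners),
         include_coupling = x$include_coupling,
         lambda = x$lambda, alpha = x$alpha, intercept = x$intercept)
}
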