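# End-to-end experiment orchestration: simulate -> select units -> fit the
# requested models -> evaluate on the held-out segment -> compare -> report.

#' Evaluate STRF models for each area of a simulated hierarchy
#'
#' @param sim Output of [simulate_hierarchy()].
#' @param plan A [make_segments()] plan.
#' @param areas Areas to fit (default all three).
#' @param nr_threshold Noise-ratio inclusion threshold.
#' @return Tibble with one row per included unit: `unit_id`, `area`,
#'   `model`, `cc_abs`, `cc_max`, `cc_norm`, `reliable`, `lambda`.
#' @export
eval_strf_models <- function(sim, plan, areas = c("ic", "mgb", "a1"),
                             nr_threshold = 200) {
  bind_rows(lapply(areas, function(a) {
    rec <- sim[[a]]
    keep <- filter(noise_ratio_filter(rec, nr_threshold), .data$included)
    rec <- subset_recording(rec, keep$unit_id)
    out <- fit_strf_population(sim$stimulus, rec, plan, keep_models = FALSE)
    mutate(out$results, area = toupper(a), .after = "unit_id")
  }))
}

#' Evaluate PCM models between areas of a simulated hierarchy
#'
#' @param sim Output of [simulate_hierarchy()].
#' @param plan A [make_segments()] plan.
#' @param source_areas Source areas, e.g. `"ic"` or `c("ic", "mgb")`.
#' @param target_area Target area.
#' @param model_label Label for the results (default built from the areas).
#' @param nr_threshold Noise-ratio inclusion threshold.
#' @return Tibble as [eval_strf_models()].
#' @export
eval_pcm_models <- function(sim, plan, source_areas, target_area,
                            model_label = NULL, nr_threshold = 200) {
  model_label <- model_label %||%
    sprintf("PCM(%s->%s)", paste(toupper(source_areas), collapse = "+"),
            toupper(target_area))
  tgt <- sim[[target_area]]
  keep <- filter(noise_ratio_filter(tgt, nr_threshold), .data$included)
  tgt <- subset_recording(tgt, keep$unit_id)
  out <- fit_pcm_population(tgt, lapply(source_areas, function(a) sim[[a]]),
                            plan, model_label = model_label)
  mutate(out$results, area = toupper(target_area), .after = "unit_id")
}

subset_recording <- function(rec, unit_ids) {
  rec$counts <- rec$counts[unit_ids]
  rec$units <- filter(rec$units, .data$unit_id %in% unit_ids)
  if (!is.null(rec$rates)) rec$rates <- rec$rates[, unit_ids, drop = FALSE]
  rec
}

hierarchy_orderings <- function(results, n_boot = 2000L, seed = 1L) {
  sc <- function(model, area = NULL) {
    r <- filter(results, .data$model == !!model, .data$reliable)
    if (!is.null(area)) r <- filter(r, .data$area == !!area)
    setNames(r$cc_norm, r$unit_id)
  }
  paired_on <- function(a, b) {
    ids <- intersect(names(a), names(b))
    compare_models(a[ids], b[ids], paired = TRUE, n_boot = n_boot,
                   seed = seed)
  }
  checks <- list(
    strf_ic_gt_mgb = compare_models(sc("STRF", "IC"), sc("STRF", "MGB"),
                                    paired = FALSE, n_boot = n_boot,
                                    seed = seed),
    strf_mgb_gt_a1 = compare_models(sc("STRF", "MGB"), sc("STRF", "A1"),
                                    paired = FALSE, n_boot = n_boot,
                                    seed = seed),
    pcm_ic_a1_gt_strf_a1 = paired_on(sc("PCM(IC->A1)"), sc("STRF", "A1")),
    pcm_icmgb_gt_pcm_ic = paired_on(sc("PCM(IC+MGB->A1)"), sc("PCM(IC->A1)")),
    two_stage_gt_strf_a1 = paired_on(sc("TwoStage", "A1"), sc("STRF", "A1")),
    pcm_ic_a1_gt_two_stage = paired_on(sc("PCM(IC->A1)"), sc("TwoStage", "A1")),
    strf_ic_gt_pcm_a1_ic = paired_on(sc("STRF", "IC"), sc("PCM(A1->IC)")))
  bind_rows(checks, .id = "check")
}

#' Run a reproducible scenario experiment
#'
#' Scenarios: `"hierarchy"` fits STRFs in all three areas, ascending PCMs
#' (IC to A1, IC+MGB to A1), a two-stage model for A1 and the descending
#' PCM (A1 to IC), and tests the expected performance orderings;
#' `"silencing"` compares STRF CC_norm and GLM coupling between the
#' cortex-active and cortex-silenced conditions; `"coupled"` runs the
#' spike-coupling parameter-recovery analysis.
#'
#' @param config List (or path to a JSON file) with `scenario`, `seed`, and
#'   optional overrides: `n_ic`, `n_mgb`, `n_a1`, `n_chords`, `n_trials`,
#'   `n_segments`, `n_boot`, `n_units`, `coupling_scale`,
#'   `stimulus_block`.
#' @param out_dir Optional directory: writes `results.csv` (one row per
#'   unit x model) and `summary.json` (comparisons), both deterministic
#'   given the config.
#' @return A `popcomm_report`: list with `results`, `comparisons`, extra
#'   scenario tables, and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(scenario = "hierarchy", seed = 1L, n_ic = 60L, n_mgb = 30L,
         n_a1 = 30L, n_chords = 6000L, n_trials = 10L, n_segments = 16L,
         n_boot = 2000L, n_units = 5L, coupling_scale = 0.5,
         stimulus_block = "summed", nr_threshold = 200),
    config)
  rep <- switch(cfg$scenario,
    hierarchy = run_hierarchy_experiment(cfg),
    silencing = run_silencing_experiment(cfg),
    coupled = run_coupled_experiment(cfg),
    abort(sprintf("unknown scenario '%s'", cfg$scenario)))
  rep$config <- cfg
  class(rep) <- "popcomm_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep$results, file.path(out_dir, "results.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = cfg, comparisons = rep$comparisons),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = 10)
  }
  rep
}

run_hierarchy_experiment <- function(cfg) {
  sim <- simulate_hierarchy(seed = cfg$seed, n_ic = cfg$n_ic,
                            n_mgb = cfg$n_mgb, n_a1 = cfg$n_a1,
                            n_chords = cfg$n_chords, n_trials = cfg$n_trials)
  plan <- make_segments(cfg$n_chords, cfg$n_segments)
  results <- bind_rows(
    eval_strf_models(sim, plan, nr_threshold = cfg$nr_threshold),
    eval_pcm_models(sim, plan, "ic", "a1", nr_threshold = cfg$nr_threshold),
    eval_pcm_models(sim, plan, c("ic", "mgb"), "a1",
                    nr_threshold = cfg$nr_threshold),
    eval_pcm_models(sim, plan, "a1", "ic", nr_threshold = cfg$nr_threshold),
    {
      keep <- filter(noise_ratio_filter(sim$a1, cfg$nr_threshold),
                     .data$included)
      ts <- fit_two_stage(sim$stimulus, sim$ic,
                          subset_recording(sim$a1, keep$unit_id), plan)
      mutate(ts$results, area = "A1", .after = "unit_id")
    })
  list(results = results,
       comparisons = hierarchy_orderings(results, cfg$n_boot, cfg$seed))
}

run_silencing_experiment <- function(cfg) {
  act <- simulate_hierarchy(seed = cfg$seed, n_ic = cfg$n_ic,
                            n_mgb = cfg$n_mgb, n_a1 = cfg$n_a1,
                            n_chords = cfg$n_chords, n_trials = cfg$n_trials)
  # session = 1: same stimulus, units and rates, independent trial noise
  # (the silenced block consists of different trials than the active block)
  sil <- simulate_hierarchy(seed = cfg$seed, n_ic = cfg$n_ic,
                            n_mgb = cfg$n_mgb, n_a1 = cfg$n_a1,
                            n_chords = cfg$n_chords, n_trials = cfg$n_trials,
                            silencing = silencing_condition(active = FALSE),
                            session = 1L)
  plan <- make_segments(cfg$n_chords, 15L)
  strf_act <- eval_strf_models(act, plan, c("ic", "mgb"),
                               nr_threshold = cfg$nr_threshold)
  strf_sil <- eval_strf_models(sil, plan, c("ic", "mgb"),
                               nr_threshold = cfg$nr_threshold)
  joined <- left_join(strf_act, strf_sil, by = c("unit_id", "area", "model"),
                      suffix = c("_active", "_silenced"))
  mgb <- filter(joined, .data$area == "MGB",
                .data$reliable_active, .data$reliable_silenced)
  strf_cmp <- compare_models(mgb$cc_norm_active, mgb$cc_norm_silenced,
                             paired = TRUE, n_boot = cfg$n_boot,
                             seed = cfg$seed)
  rate_change <- bind_rows(lapply(c("ic", "mgb"), function(a) {
    ra <- mean(vapply(act[[a]]$counts, mean, numeric(1)))
    rs <- mean(vapply(sil[[a]]$counts, mean, numeric(1)))
    tibble(area = toupper(a), rate_active = ra, rate_silenced = rs,
           pct_change = 100 * (rs - ra) / ra)
  }))
  # spike-coupling arm: same population, coupling weakened when silenced
  ca <- coupled_scenario(seed = cfg$seed, n_units = cfg$n_units,
                         n_chords = min(cfg$n_chords, 2000L),
                         coupling_scale = 1)
  cs <- coupled_scenario(seed = cfg$seed, n_units = cfg$n_units,
                         n_chords = min(cfg$n_chords, 2000L),
                         coupling_scale = cfg$coupling_scale)
  ga <- fit_population_glms(ca$recording, ca$stimulus,
                            stimulus_block = cfg$stimulus_block)
  gs <- fit_population_glms(cs$recording, cs$stimulus,
                            stimulus_block = cfg$stimulus_block)
  cpl <- coupling_analyses(ga, gs)
  ids <- ca$recording$units$unit_id
  cpl$pairs <- mutate(ca$coupled_pairs, target = ids[.data$target],
                      source = ids[.data$source])
  list(results = bind_rows(mutate(strf_act, condition = "active"),
                           mutate(strf_sil, condition = "silenced")),
       comparisons = mutate(strf_cmp, check = "strf_mgb_active_vs_silenced",
                            .before = 1L),
       rate_change = rate_change, coupling = cpl)
}

run_coupled_experiment <- function(cfg) {
  sc <- coupled_scenario(seed = cfg$seed, n_units = cfg$n_units,
                         n_chords = cfg$n_chords)
  glms <- fit_population_glms(sc$recording, sc$stimulus,
                              stimulus_block = cfg$stimulus_block)
  rec_tbl <- coupling_recovery(glms$filters, sc)
  list(results = glms$results,
       comparisons = tibble(
         check = "coupled_gt_stimulus_only",
         median_diff = median(glms$results$coupling_contribution),
         recovery_r = median(rec_tbl$r)),
       recovery = rec_tbl, filters = glms$filters)
}

#' Correlate reconstructed coupling filters with simulator ground truth
#'
#' @param filters Filter tibble from [fit_population_glms()].
#' @param scenario Output of [coupled_scenario()].
#' @return Tibble with one row per coupled ground-truth pair: `target`,
#'   `source`, `r` (Pearson correlation between fitted and true filter).
#' @export
coupling_recovery <- function(filters, scenario) {
  ids <- scenario$recording$units$unit_id
  pairs <- scenario$coupled_pairs
  bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    ti <- pairs$target[k]; si <- pairs$source[k]
    truth <- scenario$coupling[ti, si, ]
    fitted <- filter(filters, .data$target == ids[ti],
                     .data$source == ids[si])$value
    tibble(target = ids[ti], source = ids[si],
           r = pearson_or_zero(fitted, truth))
  }))
}

#' @export
print.popcomm_report <- function(x, ...) {
  cat(sprintf("<popcomm_report> scenario=%s, %d result rows\n",
              x$config$scenario, nrow(x$results)))
  print(x$comparisons)
  invisible(x)
}
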