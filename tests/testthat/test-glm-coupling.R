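test_that("standard basis recipes match their specification", {
  bc <- coupling_basis()
  expect_equal(ncol(bc$matrix), 12L)
  expect_equal(bc$kind, c(rep("delta", 2), rep("raised_cosine", 10)))
  # deltas are one-hot at 5 and 10 ms
  expect_equal(bc$matrix[, 1], as.numeric(bc$lags_ms == 5))
  expect_equal(bc$matrix[, 2], as.numeric(bc$lags_ms == 10))
  # peaks strictly increase, the last at 150 ms, support within 250 ms
  rc_peaks <- bc$peak_latencies_ms[-(1:2)]
  expect_true(all(diff(rc_peaks) > 0))
  expect_equal(max(rc_peaks), 150, tolerance = 1e-9)
  # log spacing: ratios of (peak + 1) are constant
  expect_equal(sd(diff(log(rc_peaks + 1))), 0, tolerance = 1e-9)
  expect_true(all(bc$matrix >= 0))
  expect_equal(max(bc$lags_ms), 250)

  bh <- history_basis()
  expect_equal(ncol(bh$matrix), 7L)
  expect_equal(max(bh$peak_latencies_ms), 50, tolerance = 1e-9)
  expect_equal(max(bh$lags_ms), 100)

  two <- build_basis(2L, 50, c(5, 10), 40)
  expect_equal(two$matrix[, 1], as.numeric(two$lags_ms == 5))
  expect_equal(two$matrix[, 2], as.numeric(two$lags_ms == 10))

  expect_error(build_basis(5L, 100, c(5, 10), 120), "below span")
  expect_error(build_basis(1L, 100, c(5, 10), 50), "deltas")
})

test_that("basis projection is the left inverse of reconstruction", {
  bc <- coupling_basis()
  set.seed(111)
  for (i in 1:10) {
    co <- rnorm(12)
    f <- reconstruct_filter(co, bc)
    expect_equal(project_filter(f, bc), co, tolerance = 1e-9)
  }
})

test_that("the GLM design is strictly causal in partner spikes", {
  sc <- coupled_scenario(seed = 112, n_units = 3, n_chords = 100,
                         n_trials = 3)
  rec <- sc$recording
  des1 <- make_glm_design(rec, "U01", sc$stimulus, "summed")
  # change partner spikes from bin t onward: rows before t are unchanged
  t_cut <- 300L
  rec2 <- rec
  rec2$counts$U02[, t_cut:ncol(rec2$counts$U02)] <- 0L
  des2 <- make_glm_design(rec2, "U01", sc$stimulus, "summed")
  nb <- des1$n_bins
  head_rows <- which(des1$trial == 1L)[seq_len(t_cut - 1L)]
  expect_equal(des1$X[head_rows, ], des2$X[head_rows, ])
  # and some later row does change (the spikes really entered the design)
  expect_false(isTRUE(all.equal(des1$X[des1$trial == 1L, ],
                                des2$X[des2$trial == 1L, ])))
})

test_that("an intercept-only world is fitted as its training mean rate", {
  set.seed(113)
  nb <- 2000L; n_trials <- 7L
  cm <- matrix(rpois(n_trials * nb, 0.25), n_trials, nb)
  rec <- popcomm:::new_sim_recording(
    list(U01 = cm, U02 = matrix(rpois(n_trials * nb, 0.2), n_trials, nb)),
    rates = NULL,
    units = tibble::tibble(unit_id = c("U01", "U02"), area = "IC",
                           penetration = "p1", latency_bins = 0L),
    bin_duration_ms = 5, trial_boundaries = 1L)
  des <- make_glm_design(rec, "U01", NULL, "none")
  fit <- fit_poisson_glm(des, include_coupling = TRUE)
  train_mean <- mean(des$y[des$trial <= 5L])
  expect_lt(abs(fit$intercept - log(train_mean)), 1e-2)
  expect_lt(max(abs(fit$coefficients)), 0.05)
})

test_that("single-trial evaluation uses the held-out trials with conventions", {
  sc <- coupled_scenario(seed = 114, n_units = 3, n_chords = 300,
                         n_trials = 7)
  des <- make_glm_design(sc$recording, "U02", sc$stimulus, "summed")
  fit <- fit_poisson_glm(des)
  r <- evaluate_single_trial(fit, des)
  expect_true(r >= -1 && r <= 1)
  # conventions on the correlation itself
  expect_equal(popcomm:::pearson_or_zero(rep(1, 100), rpois(100, 1)), 0)
  y <- rpois(200, 2)
  expect_equal(popcomm:::pearson_or_zero(y, y), 1)
})

test_that("coupling filters are recovered and matter only when present", {
  sc <- coupled_scenario(seed = 115, n_units = 5, n_chords = 1000,
                         n_trials = 7)
  glms <- fit_population_glms(sc$recording, sc$stimulus,
                              stimulus_block = "summed")
  rec_tbl <- coupling_recovery(glms$filters, sc)
  expect_gt(median(rec_tbl$r), 0.8)
  coupled_targets <- unique(rec_tbl$target)
  contrib <- glms$results$coupling_contribution[
    glms$results$unit_id %in% coupled_targets]
  expect_gt(median(contrib), 0)

  # no coupling in the generator: no benefit from the coupling block
  sc0 <- coupled_scenario(seed = 116, n_units = 4, n_chords = 800,
                          n_trials = 7, coupling_scale = 0)
  glms0 <- fit_population_glms(sc0$recording, sc0$stimulus,
                               stimulus_block = "summed")
  expect_lt(abs(median(glms0$results$coupling_contribution)), 0.01)
})

test_that("filter component masses split at the 10 ms boundary", {
  lags <- seq(5, 250, by = 5)
  f <- numeric(50); f[1] <- 0.7           # all mass at 5 ms, positive
  comp <- filter_components(f, lags)
  expect_equal(comp$fast_excitatory, 0.7)
  expect_equal(comp$slow_excitatory, 0)
  expect_equal(comp$fast_inhibitory, 0)

  g <- numeric(50); g[1] <- 0.4; g[5] <- -0.3   # 25 ms inhibitory lobe
  comp2 <- filter_components(g, lags)
  expect_equal(comp2$fast_excitatory, 0.4)
  expect_equal(comp2$slow_inhibitory, 0.3)
})

test_that("identical conditions show no filter change", {
  sc <- coupled_scenario(seed = 117, n_units = 3, n_chords = 400,
                         n_trials = 7)
  glms <- fit_population_glms(sc$recording, sc$stimulus,
                              stimulus_block = "summed")
  ana <- coupling_analyses(glms, glms)
  expect_true(all(abs(ana$filter_change$change) < 1e-12))
  act <- ana$contribution[ana$contribution$condition == "active", ]
  sil <- ana$contribution[ana$contribution$condition == "silenced", ]
  expect_equal(act$coupling_contribution, sil$coupling_contribution)
})
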