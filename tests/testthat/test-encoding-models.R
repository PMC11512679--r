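test_that("fitted STRF kernels track the generating kernels", {
  coch <- generate_drc(drc_spec(2000, "low", n_trials = 10, seed = 41))
  units <- make_ic_units(4, seed = 42)
  rec <- simulate_ic(coch, units, 8, seed = 43)
  plan <- make_segments(2000, 16)
  out <- fit_strf_population(coch, rec, plan)
  rs <- vapply(seq_len(4), function(i)
    kernel_recovery_r(out$models[[i]], units$kernel[[i]],
                      units$latency_bins[i]), numeric(1))
  expect_gt(median(rs), 0.9)
  expect_true(all(out$results$cc_norm > 0.5))
})

test_that("all-zero responses yield a flagged zero evaluation", {
  coch <- tiny_coch(300, seed = 44)
  plan <- make_segments(300, 10)
  m <- fit_strf(coch, matrix(0L, 4, 300), plan)
  expect_equal(m$evaluation$cc_abs, 0)
  expect_false(m$evaluation$reliable)
})

test_that("PCM finds a latency-shifted copy of a source unit", {
  set.seed(45)
  nb <- 1200L
  src <- matrix(runif(nb * 3, 0.2, 2), nb, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  target_rate <- c(rep(0.3, 2), src[1:(nb - 2), 1])  # copy of s1, lag 2
  cm <- poisson_counts(target_rate, 24, seed = 46)
  plan <- make_segments(nb, 12)
  m <- fit_pcm(src, cm, plan, target_id = "t1")
  expect_gt(m$evaluation$cc_norm, 0.9)
  k <- ln_kernel(m)
  peak <- which(abs(k) == max(abs(k)), arr.ind = TRUE)
  expect_equal(rownames(k)[peak[1]], "s1")
  expect_equal(m$lag_offsets[peak[2]], -2L)
})

test_that("PCM guards its source population", {
  src <- matrix(runif(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  cm <- poisson_counts(rep(1, 100), 4)
  plan <- make_segments(100, 5)
  expect_error(fit_pcm(src[, 0, drop = FALSE], cm, plan), "empty")
  expect_error(fit_pcm(src, cm, plan, target_id = "a"), "target unit")
})

test_that("targets independent of the sources score near zero", {
  set.seed(47)
  nb <- 600L
  src <- matrix(runif(nb * 5, 0.2, 2), nb, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  plan <- make_segments(nb, 10)
  meds <- vapply(1:20, function(i) {
    cm <- poisson_counts(runif(nb, 0.2, 2), 16, seed = 400 + i)
    fit_pcm(src, cm, plan)$evaluation$cc_norm
  }, numeric(1))
  expect_lt(abs(median(meds, na.rm = TRUE)), 0.05)
})

test_that("a rectified sum of sources is better explained by a PCM than a STRF", {
  coch <- generate_drc(drc_spec(1500, "low", n_trials = 5, seed = 48))
  ic_units <- make_ic_units(6, seed = 49)
  ic <- simulate_ic(coch, ic_units, 12, seed = 50)
  mgb_units <- make_downstream_units(4, ic_units$unit_id, "MGB", seed = 51)
  mgb <- simulate_downstream(ic, mgb_units, 12, seed = 52)
  plan <- make_segments(1500, 15)
  strf <- fit_strf_population(coch, mgb, plan, keep_models = FALSE)$results
  pcm <- fit_pcm_population(mgb, ic, plan)$results
  expect_gt(median(pcm$cc_norm - strf$cc_norm, na.rm = TRUE), 0)
})

test_that("two-stage with perfect stage-1 responses equals the direct PCM", {
  coch <- generate_drc(drc_spec(1000, "low", n_trials = 5, seed = 53))
  ic_units <- make_ic_units(5, seed = 54)
  ic <- simulate_ic(coch, ic_units, 8, seed = 55)
  mgb_units <- make_downstream_units(3, ic_units$unit_id, "MGB", seed = 56)
  mgb <- simulate_downstream(ic, mgb_units, 8, seed = 57)
  plan <- make_segments(1000, 10)

  # substitute ground-truth rates for the stage-1 predictions
  ts <- fit_two_stage(coch, ic, mgb, plan, stage1_psths = ic$rates)
  direct <- vapply(mgb_units$unit_id, function(id)
    fit_pcm(ic$rates, mgb$counts[[id]], plan,
            trial_boundaries = ic$trial_boundaries)$evaluation$cc_norm,
    numeric(1))
  expect_equal(ts$results$cc_norm, unname(direct), tolerance = 1e-8)
})

test_that("training never touches the held-out segment (leakage canary)", {
  coch <- tiny_coch(600, seed = 58)
  units <- make_ic_units(1, seed = 59)
  rec <- simulate_ic(coch, units, 6, seed = 60)
  plan <- make_segments(600, 10)
  m1 <- fit_strf(coch, rec$counts[[1]], plan)
  corrupted <- rec$counts[[1]]
  corrupted[, plan$test_bins] <- 99L
  m2 <- fit_strf(coch, corrupted, plan)
  expect_identical(m1$linear$weights, m2$linear$weights)
  expect_identical(m1$nonlinearity$a, m2$nonlinearity$a)
  expect_identical(m1$linear$lambda, m2$linear$lambda)
})

test_that("STRF summaries locate peaks, widths, and break ties downward", {
  freqs <- build_frequency_grid(1000, 64000, 4)$frequencies
  k <- matrix(0, 25, 13)
  k[7, 3] <- 1
  s <- strf_summaries(k, freqs)
  expect_equal(s$tuning_width, 1L)
  # peak location at the resolution of the 10x spline grid
  expect_lt(abs(log2(s$best_frequency) - log2(freqs[7])), 1 / 40 + 1e-9)

  # two equal peaks: the lower frequency wins
  k2 <- matrix(0, 25, 13); k2[5, 2] <- 1; k2[20, 2] <- 1
  expect_lt(abs(log2(strf_summaries(k2, freqs)$best_frequency) -
                  log2(freqs[5])), 1 / 40 + 1e-9)

  # Gaussian bump peaks at its center within one interpolated step
  bump <- exp(-0.5 * ((1:25 - 12.3) / 2)^2)
  k3 <- matrix(bump, 25, 13) * rep(exp(-(0:12)), each = 25)
  bf <- strf_summaries(k3, freqs)$best_frequency
  centre <- 1000 * 2^((12.3 - 1) / 4)
  expect_lt(abs(log2(bf) - log2(centre)), 1 / 40 + 1e-9)

  # all-nonpositive kernel: zero width, undefined best frequency
  s0 <- strf_summaries(-k, freqs)
  expect_equal(s0$tuning_width, 0L)
  expect_true(is.na(s0$best_frequency))

  # overlap is the summed dot product with source tuning curves
  src <- cbind(bump, rev(bump))
  s4 <- strf_summaries(k3, freqs, source_curves = src)
  tc <- rowSums(pmax(k3, 0))
  expect_equal(s4$overlap, sum(tc * bump) + sum(tc * rev(bump)))
})

test_that("network models match STRFs on linear units and are reproducible", {
  coch <- generate_drc(drc_spec(1500, "low", seed = 61))
  units <- make_ic_units(1, threshold_q = 0.01, seed = 62)
  rec <- simulate_ic(coch, units, 10, seed = 63)
  plan <- make_segments(1500, 16)
  nrf <- fit_nrf(coch, rec$counts[[1]], plan, hidden_sizes = c(2L, 4L),
                 seed = 64)
  strf <- fit_strf(coch, rec$counts[[1]], plan)
  expect_lt(abs(nrf$evaluation$cc_norm - strf$evaluation$cc_norm), 0.05)

  nrf2 <- fit_nrf(coch, rec$counts[[1]], plan, hidden_sizes = c(2L, 4L),
                  seed = 64)
  expect_identical(nrf$evaluation$cc_norm, nrf2$evaluation$cc_norm)
  expect_identical(nrf$net$wts, nrf2$net$wts)
})

test_that("network models beat STRFs on a gain-modulated interaction unit", {
  coch <- generate_drc(drc_spec(3000, "low", seed = 65))
  X <- coch$levels - 40
  z1 <- rowMeans(X[, 6:10]); z1 <- z1 / sd(z1)
  z2 <- rowMeans(X[, 16:20]); z2 <- z2 / sd(z2)
  r <- pmax(z1, 0) * (0.3 + 1.7 / (1 + exp(-2 * z2)))
  r <- 0.9 * r / mean(r)
  cm <- poisson_counts(r, 10, seed = 66)
  plan <- make_segments(3000, 16)
  nrf <- fit_nrf(coch, cm, plan, hidden_sizes = c(4L, 8L), seed = 67)
  strf <- fit_strf(coch, cm, plan)
  expect_gt(nrf$evaluation$cc_norm, strf$evaluation$cc_norm)
})

test_that("tidy and glance expose kernels and fit summaries", {
  coch <- tiny_coch(300, seed = 68)
  units <- make_ic_units(1, seed = 69)
  rec <- simulate_ic(coch, units, 4, seed = 70)
  m <- fit_strf(coch, rec$counts[[1]], make_segments(300, 10))
  td <- tidy(m)
  expect_equal(nrow(td), 25 * 13)
  expect_named(td, c("channel", "lag", "estimate"))
  gl <- glance(m)
  expect_equal(gl$kind, "STRF")
  expect_true(is.finite(gl$cc_norm) || is.na(gl$cc_norm))
})
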