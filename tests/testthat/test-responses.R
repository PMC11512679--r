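test_that("spike binning counts spikes in the right bins", {
  expect_equal(as.vector(bin_spikes(list(c(1, 26, 27)), 50, 25)), c(1L, 2L))
  expect_equal(as.vector(bin_spikes(list(numeric(0)), 100, 25)), rep(0L, 4))
  expect_warning(out <- bin_spikes(list(c(10, 120)), 100, 25), "dropped")
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_error(bin_spikes(list(1), 100, 30), "divide")
})

test_that("rebinning 5 ms counts by 5 reproduces 25 ms counts", {
  set.seed(11)
  spikes <- lapply(1:4, function(i) sort(runif(80, 0, 500)))
  fine <- bin_spikes(spikes, 500, 5)
  coarse <- bin_spikes(spikes, 500, 25)
  expect_equal(rebin_counts(fine, 5L), coarse, ignore_attr = TRUE)
  expect_error(rebin_counts(fine, 3L), "divide")
})

test_that("tensorization shifts, zero-pads, and round-trips", {
  # impulse at t = 10 with lag -3 appears only at t = 13
  src <- matrix(0, 20, 1); src[10, 1] <- 1
  tens <- tensorize(src, c(-3L, 0L))
  expect_equal(which(tens[, 1, 1] != 0), 13L)
  expect_equal(tens[, 1, 2], src[, 1])

  # lag {0} is the identity
  m <- matrix(rnorm(40), 20, 2)
  expect_equal(tensorize(m, 0L)[, , 1], m)

  # one-hot round trip for every lag, with zero padding outside the range
  lags <- -2:1
  tt <- tensorize(m, lags)
  for (j in seq_along(lags)) {
    expected <- matrix(0, 20, 2)
    idx <- seq_len(20) + lags[j]
    ok <- idx >= 1 & idx <= 20
    expected[ok, ] <- m[idx[ok], ]
    expect_equal(tt[, , j], expected)
  }

  # no leakage across a segment boundary at t = 11
  tb <- tensorize(m, -2L, boundaries = c(1L, 11L))
  expect_equal(tb[11, , 1], c(0, 0))
  expect_equal(tb[12, , 1], c(0, 0))
  expect_equal(tb[13, , 1], m[11, ])

  # constant input: all rows equal away from boundaries
  cm <- matrix(1, 20, 1)
  tc <- tensorize(cm, c(-2L, 0L))
  expect_true(all(tc[3:20, 1, 1] == 1))
})

test_that("noise-ratio selection keeps reliable units and logs exclusions", {
  reliable <- rbind(c(3, 0, 2, 0, 5), c(3, 0, 2, 0, 5))
  set.seed(2)
  noise <- matrix(rpois(40 * 200, 1.5), 40, 200)   # no stimulus locking
  out <- noise_ratio_filter(list(good = reliable, flat = noise),
                            threshold = 200)
  expect_true(out$included[out$unit_id == "good"])
  expect_equal(out$noise_ratio[out$unit_id == "good"], 0)
  expect_false(out$included[out$unit_id == "flat"])
  expect_match(out$reason[out$unit_id == "flat"], "noise ratio")

  single <- noise_ratio_filter(list(one = matrix(1, 1, 5)))
  expect_false(single$included)
  expect_match(single$reason, "fewer than 2 trials")

  all_in <- noise_ratio_filter(list(good = reliable, flat = noise),
                               threshold = Inf)
  expect_true(all(all_in$included))
})

test_that("PSTH converges to the generative rate as trials grow", {
  coch <- tiny_coch(300, seed = 5)
  units <- make_ic_units(2, seed = 6)
  errs <- vapply(c(4L, 16L, 64L), function(nt) {
    rec <- simulate_ic(coch, units, nt, seed = 9)
    mean(vapply(seq_len(2), function(i)
      sqrt(mean((psth(rec$counts[[i]]) - rec$rates[, i])^2)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
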