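test_that("a zero kernel gives baseline-rate Poisson counts", {
  coch <- tiny_coch(500, seed = 71)
  units <- make_ic_units(1, seed = 72)
  units$kernel[[1]][] <- 0
  units$baseline <- 0.4
  units$target_rate <- 0.4
  rec <- simulate_ic(coch, units, 20, seed = 73)
  expect_true(all(rec$rates[, 1] == 0.4))
  n <- length(rec$counts[[1]])
  expect_lt(abs(mean(rec$counts[[1]]) - 0.4), 3 * sqrt(0.4 / n))
})

test_that("simulation is deterministic in the seed", {
  coch <- tiny_coch(200, seed = 74)
  units <- make_ic_units(3, seed = 75)
  a <- simulate_ic(coch, units, 4, seed = 76)
  b <- simulate_ic(coch, units, 4, seed = 76)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, simulate_ic(coch, units, 4, 77)$counts))
})

test_that("trial-averaged PSTHs track the ground-truth rate", {
  coch <- tiny_coch(400, seed = 78)
  units <- make_ic_units(4, seed = 79)
  rec <- simulate_ic(coch, units, 64, seed = 80)
  rs <- vapply(seq_len(4), function(i)
    cor(psth(rec$counts[[i]]), rec$rates[, i]), numeric(1))
  expect_true(all(rs > 0.95))
})

test_that("identity downstream units copy the source rates", {
  coch <- tiny_coch(300, seed = 81)
  ic_units <- make_ic_units(2, seed = 82)
  ic <- simulate_ic(coch, ic_units, 4, seed = 83)
  d_units <- make_downstream_units(1, ic_units$unit_id[1], "MGB",
                                   n_sources = 1L, latency_bins = 1L,
                                   nl = "identity", seed = 84)
  d_units$mix[[1]] <- c(IC001 = 1)
  d_units$baseline <- 0
  d_units$target_rate <- mean(ic$rates[, 1])
  rec <- simulate_downstream(ic, d_units, 4, seed = 85)
  expect_equal(cor(rec$rates[, 1], ic$rates[, 1]), 1, tolerance = 1e-9)
})

test_that("rectification above the median zeroes most bins", {
  coch <- tiny_coch(400, seed = 86)
  ic_units <- make_ic_units(3, seed = 87)
  ic <- simulate_ic(coch, ic_units, 4, seed = 88)
  d_units <- make_downstream_units(2, ic_units$unit_id, "MGB",
                                   threshold_q = 0.6, seed = 89)
  d_units$baseline <- 0
  rec <- simulate_downstream(ic, d_units, 4, seed = 90)
  frac_zero <- colMeans(rec$rates == 0)
  expect_true(all(frac_zero >= 0.5))
})

test_that("downstream units reject unknown sources", {
  coch <- tiny_coch(100, seed = 91)
  ic_units <- make_ic_units(2, seed = 92)
  ic <- simulate_ic(coch, ic_units, 2, seed = 93)
  bad <- make_downstream_units(1, "ghost", "MGB", n_sources = 1L, seed = 94)
  expect_error(simulate_downstream(ic, bad, 2, seed = 95), "unknown source")
})

test_that("silencing scales MGB rates down and leaves IC untouched", {
  sim_on <- simulate_hierarchy(seed = 96, n_ic = 10, n_mgb = 6, n_a1 = 4,
                               n_chords = 400, n_trials = 4)
  sim_off <- simulate_hierarchy(seed = 96, n_ic = 10, n_mgb = 6, n_a1 = 4,
                                n_chords = 400, n_trials = 4,
                                silencing = silencing_condition(FALSE,
                                  mgb_gain_factor = 0.7))
  expect_equal(sim_off$ic$rates, sim_on$ic$rates)
  ratio <- mean(sim_off$mgb$rates) / mean(sim_on$mgb$rates)
  expect_equal(ratio, 0.7, tolerance = 1e-9)
  expect_error(silencing_condition(TRUE, mgb_gain_factor = 0.5), "identity")
})

test_that("uncoupled units show no noise correlations", {
  set.seed(97)
  U <- 4; nb <- 2500
  S <- matrix(log(0.2), nb, U)
  Fk <- array(0, dim = c(U, U, 50))
  H <- matrix(0, U, 20)
  rec <- simulate_coupled_population(S, Fk, H, n_trials = 4, seed = 98)
  resid <- vapply(rec$counts, function(cm) as.vector(t(cm)),
                  numeric(4 * nb))
  cors <- cor(resid)[upper.tri(diag(U))]
  expect_true(all(abs(cors) < 0.02))
})

test_that("positive coupling produces a cross-correlogram peak at its lag", {
  U <- 2; nb <- 6000
  S <- matrix(log(0.15), nb, U)
  Fk <- array(0, dim = c(U, U, 50))
  Fk[2, 1, 1] <- 2.5     # unit 1 excites unit 2 at a 5 ms lag
  H <- matrix(0, U, 20)
  rec <- simulate_coupled_population(S, Fk, H, n_trials = 2, seed = 99)
  x <- as.vector(t(rec$counts$U01)); y <- as.vector(t(rec$counts$U02))
  xc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 1L)   # +1 bin = +5 ms
})

test_that("runaway positive feedback aborts with a diagnostic", {
  U <- 2; nb <- 2000
  S <- matrix(log(0.3), nb, U)
  Fk <- array(0, dim = c(U, U, 50))
  Fk[2, 1, 1:3] <- 4; Fk[1, 2, 1:3] <- 4
  H <- matrix(0, U, 20)
  expect_error(simulate_coupled_population(S, Fk, H, 1, seed = 100,
                                           max_rate = 50),
               "unstable")
})

test_that("recordings round-trip through the text container", {
  coch <- tiny_coch(80, seed = 101)
  units <- make_ic_units(2, seed = 102)
  rec <- simulate_ic(coch, units, 3, seed = 103)
  path <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$counts, rec$counts, ignore_attr = TRUE)
  expect_equal(unname(back$rates), unname(rec$rates), tolerance = 1e-10)
  expect_equal(back$units$unit_id, rec$units$unit_id)
})
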