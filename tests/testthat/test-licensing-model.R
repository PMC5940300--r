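test_that("trajectory follows the pause-ramp-wait timing in closed form", {
  # rate 1, no pause: full licensing exactly at the end of minimum G1
  traj <- simulate_trajectory(licensing_params(rate = 1, n_steps = 10))
  expect_equal(traj$samples, seq(0.1, 1, by = 0.1))

  # analytic timing oracle: pause ends at step u*n, ramp ends at step
  # (u + 1/rate)*n, recording stops at max(1, u + c/rate)*n
  cases <- list(
    list(rate = 2, u = 0.25, c = 1, n = 10000L),
    list(rate = 4, u = 0.5, c = 1, n = 10000L),
    list(rate = 0.5, u = 0.25, c = 1, n = 2000L),   # slow: G1 extends
    list(rate = 2, u = 0, c = 0.3, n = 5000L)       # checkpoint loss
  )
  for (cs in cases) {
    traj <- simulate_trajectory(licensing_params(
      rate = cs$rate, unlicensed_fraction = cs$u,
      checkpoint_threshold = cs$c, n_steps = cs$n))
    t_exit <- max(1, cs$u + cs$c / cs$rate)
    expect_equal(length(traj$samples), ceiling(t_exit * cs$n - 1e-9))
    expect_equal(traj$step_duration, 1 / cs$n)
    # zero until the pause ends
    pause_steps <- floor(cs$u * cs$n)
    if (pause_steps > 0) {
      expect_true(all(traj$samples[seq_len(pause_steps)] == 0))
    }
    if (pause_steps < length(traj$samples)) {
      expect_gt(traj$samples[pause_steps + 1L], 0)
    }
    # clamped at the checkpoint from the ramp end onward
    ramp_end <- ceiling((cs$u + cs$c / cs$rate) * cs$n - 1e-9)
    expect_equal(sum(traj$samples == cs$c),
                 length(traj$samples) - ramp_end + 1L)
    expect_true(all(diff(traj$samples) >= 0))
    expect_true(all(traj$samples >= 0 & traj$samples <= cs$c))
  }

  # the case the simulator was built around: rate 2, pause 0.25 of G1
  traj <- simulate_trajectory(licensing_params(rate = 2,
                                               unlicensed_fraction = 0.25))
  expect_length(traj$samples, 10000L)
  expect_equal(traj$samples[2500], 0)
  expect_gt(traj$samples[2501], 0)
  expect_equal(traj$samples[7500], 1)
  expect_equal(sum(traj$samples == 1), 2501L)  # steps 7500..10000
})

test_that("invalid simulator parameters are rejected", {
  expect_error(licensing_params(rate = 0), "rate")
  expect_error(licensing_params(rate = -1), "rate")
  expect_error(licensing_params(n_steps = 0), "n_steps")
  expect_error(licensing_params(checkpoint_threshold = 0), "checkpoint")
  expect_error(licensing_params(background = 1), "background")
  expect_error(licensing_params(push_fraction = 1), "push_fraction")
  expect_error(licensing_params(n_bins = 1), "n_bins")
})

test_that("histogram binning matches an independent brute-force oracle", {
  traj <- simulate_trajectory(licensing_params(rate = 1, n_steps = 10000))
  h <- build_histogram(traj)
  expect_length(h$counts, 101L)
  expect_equal(h$total, 10000)
  expect_equal(h$counts, oracle_bin_counts(traj$samples, 101))
  # near-uniform occupancy at rate 1, no pause: ~100 per interior bin
  expect_true(all(abs(h$counts[2:100] - 100) <= 1))

  # a harder case exercising pause, ramp and full-licensing plateau
  traj2 <- simulate_trajectory(licensing_params(rate = 3,
                                                unlicensed_fraction = 0.4))
  expect_equal(build_histogram(traj2)$counts,
               oracle_bin_counts(traj2$samples, 101))

  # all-zero trajectory collapses into the 0% bin
  tz <- simulate_trajectory(licensing_params(rate = 1, n_steps = 50))
  tz$samples <- rep(0, 50)
  hz <- build_histogram(tz)
  expect_equal(hz$counts[1], 50)
  expect_equal(sum(hz$counts[-1]), 0)

  expect_error(build_histogram(traj, n_bins = 1), "n_bins")
})

test_that("background adjustment shifts counts up and clips at the top", {
  base <- simulate_trajectory(licensing_params(rate = 1, n_steps = 100))
  mk <- function(counts) {
    t0 <- base
    h <- build_histogram(t0)
    h$counts <- counts
    h$total <- sum(counts)
    h
  }
  # mass at 0% moves to the 5% bin under the default +5% background
  h0 <- mk(c(1000, rep(0, 100)))
  hb <- apply_background(h0, 0.05)
  expect_equal(hb$counts[6], 1000)
  expect_equal(sum(hb$counts[-6]), 0)
  expect_equal(hb$stage, "background_adjusted")
  # zero background is the identity
  expect_equal(apply_background(h0, 0)$counts, h0$counts)
  # mass already at 100% stays there (clipped)
  htop <- mk(c(rep(0, 100), 1000))
  expect_equal(apply_background(htop, 0.05)$counts[101], 1000)
  # mass within one background-width of the top accumulates at the top
  hnear <- mk(c(rep(0, 98), 10, 0, 20))
  expect_equal(apply_background(hnear, 0.05)$counts[101], 30)
  expect_error(apply_background(h0, 1), "background")
  expect_error(apply_background(apply_background(h0, 0.05), 0.05), "raw")
})

test_that("sequential push smoothing matches the closed-form cascade oracle", {
  base <- build_histogram(
    simulate_trajectory(licensing_params(rate = 1, n_steps = 100)))
  # 80% of a concentrated interior bin moves up at the forward visit:
  # delta of 1000 at bin 50 (0-based), checked bin-for-bin against the
  # independent cascade oracle
  h <- base
  h$counts <- numeric(101)
  h$counts[51] <- 1000
  h$total <- 1000
  sm <- smooth_histogram(h, 0.8)
  expect_equal(sm$counts, oracle_smooth(h$counts, 0.8), tolerance = 1e-12)
  expect_equal(sm$total, 1000)
  expect_equal(sm$stage, "smoothed")

  # randomized histograms: oracle equality and exact conservation
  withr::with_seed(7, {
    for (i in 1:5) {
      h$counts <- stats::runif(101, 0, 50)
      h$total <- sum(h$counts)
      p <- stats::runif(1, 0, 0.95)
      sm <- smooth_histogram(h, p)
      expect_equal(sm$counts, oracle_smooth(h$counts, p), tolerance = 1e-9)
      expect_equal(sm$total, h$total, tolerance = 1e-12)
    }
  })
  expect_error(smooth_histogram(base, 1), "push_fraction")
})

test_that("steady-state snapshot oracle agrees with the recorded trajectory", {
  # occupancy is inversely proportional to licensing speed: the brute-force
  # population snapshot and the single-cell trajectory histogram agree
  # within multinomial sampling error
  p <- licensing_params(rate = 2, unlicensed_fraction = 0.2)
  raw <- build_histogram(simulate_trajectory(p))
  snap <- population_snapshot_oracle(p, n_cells = 60000, seed = 5)
  n <- attr(snap, "n_in_g1")
  pexp <- raw$counts / raw$total
  dev <- abs(snap$counts - n * pexp) /
    sqrt(pmax(n * pexp * (1 - pexp), 1e-12))
  expect_lt(max(dev[pexp > 0]), 4)
  expect_equal(sum(snap$counts[pexp == 0]), 0)

  # with a very fast rate and a checkpoint, cells queue fully licensed
  fast <- population_snapshot_oracle(licensing_params(rate = 100),
                                     n_cells = 20000, seed = 6)
  expect_gt(fast$counts[101] / sum(fast$counts), 0.95)

  # doubling the rate halves the occupancy of intermediate ramp bins
  s1 <- population_snapshot_oracle(licensing_params(rate = 2),
                                   n_cells = 200000, seed = 8)
  s2 <- population_snapshot_oracle(licensing_params(rate = 4),
                                   n_cells = 200000, seed = 9)
  ramp_bins <- 31:70  # licensing 30-69%: traversed by both ramps
  occ1 <- sum(s1$counts[ramp_bins]) / sum(s1$counts)
  occ2 <- sum(s2$counts[ramp_bins]) / sum(s2$counts)
  expect_equal(occ1 / occ2, 2, tolerance = 0.05)
})

test_that("a paused unlicensed period produces a detectable discrete peak", {
  # pause + fast ramp: discrete peak of unlicensed cells
  h <- simulate_licensing_histogram(
    licensing_params(rate = 4, unlicensed_fraction = 0.5))
  pk <- detect_unlicensed_peak(h)
  expect_true(pk$present)

  # slow licensing with no pause: uniform occupancy, no discrete peak
  h0 <- simulate_licensing_histogram(licensing_params(rate = 1))
  expect_false(detect_unlicensed_peak(h0)$present)

  # peak mass approximates the fraction of G1 spent unlicensed, u / T
  for (cs in list(c(4, 0.5), c(2, 0.5), c(4, 0.25))) {
    rate <- cs[1]; u <- cs[2]
    expected <- u / max(1, u + 1 / rate)
    raw <- simulate_licensing_histogram(
      licensing_params(rate = rate, unlicensed_fraction = u),
      stage = "raw")
    expect_equal(detect_unlicensed_peak(raw)$peak_fraction, expected,
                 tolerance = 0.02)
    sm <- simulate_licensing_histogram(
      licensing_params(rate = rate, unlicensed_fraction = u))
    expect_equal(detect_unlicensed_peak(sm)$peak_fraction, expected,
                 tolerance = 0.15)
  }

  empty <- build_histogram(
    simulate_trajectory(licensing_params(rate = 1, n_steps = 10)))
  empty$counts <- numeric(101)
  empty$total <- 0
  expect_error(detect_unlicensed_peak(empty), "empty")
})

test_that("grid fitting finds its own output exactly and breaks ties low", {
  obs <- simulate_licensing_histogram(
    licensing_params(rate = 2, unlicensed_fraction = 0.3, n_steps = 2000))
  grid <- licensing_grid(rate = c(1, 2, 3),
                         unlicensed_fraction = c(0.1, 0.3, 0.5))
  fit <- fit_params(obs, grid, n_steps = 2000)
  expect_equal(fit$best_rate, 2)
  expect_equal(fit$best_unlicensed_fraction, 0.3)
  expect_equal(fit$distance, 0, tolerance = 1e-12)
  expect_error(fit_params(obs, grid[0, ]), "nonempty")

  # checkpoint-loss (Apc-like) input: best fit needs no unlicensed pause
  # and the observed histogram shows no unlicensed peak
  obs_apc <- simulate_licensing_histogram(
    licensing_params(rate = 2, checkpoint_threshold = 0.3, n_steps = 2000))
  grid3 <- licensing_grid(rate = c(1, 2), unlicensed_fraction = c(0, 0.25, 0.5),
                          checkpoint_threshold = c(0.3, 1))
  fit_apc <- fit_params(obs_apc, grid3, n_steps = 2000)
  expect_equal(fit_apc$best_unlicensed_fraction, 0)
  expect_equal(fit_apc$best_checkpoint_threshold, 0.3)
  expect_false(detect_unlicensed_peak(obs_apc)$present)
})
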