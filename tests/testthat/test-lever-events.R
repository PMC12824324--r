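# Event detection and schedule resolution.

fs <- 250

# analytic trapezoid rendered on the sampling grid, built independently of the
# package's renderer
trapezoid_trace <- function(t_end, onset, amp, rise_v, plateau, fall_v) {
  tt <- seq(0, t_end, by = 1 / fs)
  rel <- tt - onset
  y <- pmin(pmax(rel, 0) * rise_v, amp)
  past <- rel - (amp / rise_v + plateau)
  y <- ifelse(past > 0, pmax(amp - past * fall_v, 0), y)
  list(time = tt, pos = y)
}

test_that("voltage-to-position calibration is the exact linear map", {
  expect_identical(voltage_to_position(2.5), 3.5)
  expect_identical(voltage_to_position(0), 0)
  expect_equal(voltage_to_position(1.0), 1.4)
  expect_error(voltage_to_position(-0.1), "negative")
})

test_that("a flat trace yields no presses and non-uniform grids are rejected", {
  tt <- seq(0, 2, by = 1 / fs)
  expect_identical(nrow(detect_presses(tt, rep(0, length(tt)))), 0L)
  expect_error(detect_presses(c(0, 0.004, 0.01), c(0, 1, 0)), "non-uniform")
})

test_that("a single trapezoid press is segmented with the hand-computed spans", {
  tr <- trapezoid_trace(2, onset = 0.3, amp = 3.0, rise_v = 20,
                        plateau = 1.0, fall_v = 20)
  ev <- detect_presses(tr$time, tr$pos)
  expect_identical(nrow(ev), 1L)
  # hand geometry: touch up-cross at 0.3 + 0.1/20, spatial band crossings at
  # 0.3 + 2.6/20 and 0.3 + 3/20 + 1 + 0.4/20; all to within a sample or two
  expect_lt(abs(ev$onset_time - (0.3 + 0.1 / 20)), 1.5 / fs)
  expect_lt(abs(ev$spatial_start - (0.3 + 2.6 / 20)), 1.5 / fs)
  expect_lt(abs(ev$spatial_end - (0.3 + 3 / 20 + 1 + 0.4 / 20)), 1.5 / fs)
  expect_lt(abs(ev$duration_above - (1 + 0.4 / 20 + 0.4 / 20)), 2.5 / fs)
  expect_equal(ev$peak_displacement, 3.0, tolerance = 1e-6)
})

test_that("two separated presses give two ordered events; hysteresis merges chatter", {
  t1 <- trapezoid_trace(4, 0.3, 2.0, 20, 0.4, 20)
  t2 <- trapezoid_trace(4, 2.0, 2.8, 20, 0.4, 20)
  pos <- pmax(t1$pos, t2$pos)
  ev <- detect_presses(t1$time, pos)
  expect_identical(nrow(ev), 2L)
  expect_true(ev$onset_time[1] < ev$onset_time[2])
  expect_true(is.na(ev$spatial_start[1]) && !is.na(ev$spatial_start[2]))
  # a dip into the hysteresis band (between touch - hys and touch) must not
  # split the press
  tt <- seq(0, 1, by = 1 / fs)
  pos <- rep(0, length(tt))
  pos[tt >= 0.2 & tt < 0.5] <- 0.5
  pos[tt >= 0.35 & tt < 0.37] <- 0.09  # below touch, above touch - 0.02
  expect_identical(nrow(detect_presses(tt, pos)), 1L)
  pos[tt >= 0.35 & tt < 0.37] <- 0.05  # below the hysteresis band: splits
  expect_identical(nrow(detect_presses(tt, pos)), 2L)
})

test_that("bilateral pairing intersects above-spatial spans", {
  mk <- function(on, sp_start, sp_end, off) {
    data.frame(onset_time = on, offset_time = off, peak_displacement = 3,
               spatial_start = sp_start, spatial_end = sp_end,
               duration_above = sp_end - sp_start)
  }
  # identical spans: joint equals either
  a <- pair_bilateral(mk(0.9, 1.0, 3.0, 3.1), mk(0.9, 1.0, 3.0, 3.1))
  expect_equal(a$joint_onset, 1.0)
  expect_equal(a$duration_above, 2.0)
  # interval intersection
  a <- pair_bilateral(mk(0.9, 1.0, 3.0, 3.1), mk(1.1, 1.2, 2.5, 2.6))
  expect_equal(a$joint_onset, 1.2)
  expect_equal(a$joint_end, 2.5)
  expect_equal(a$duration_above, 1.3)
  # disjoint spans: no attempt
  expect_identical(nrow(pair_bilateral(mk(0.9, 1.0, 2.0, 2.1),
                                       mk(2.4, 2.5, 3.5, 3.6))), 0L)
})

test_that("fixed-interval schedule matches a brute-force gate walk", {
  # attempts every 5 s from t = 0, each holding 800 ms
  onsets <- seq(0, 120, by = 5)
  att <- data.frame(left_onset = onsets - 0.1, right_onset = onsets - 0.1,
                    joint_onset = onsets, joint_end = onsets + 0.8,
                    duration_above = 0.8)
  res <- apply_fixed_interval(att, interval_s = 30, hold_s = 0.75)
  # independent walk over the same rules
  gate <- 0
  expected <- c()
  for (o in onsets) {
    if (o >= gate) {
      expected <- c(expected, o + 0.75)
      gate <- o + 0.75 + 30
    }
  }
  expect_equal(res$trials$reward_time, expected)
  expect_true(all(diff(res$trials$reward_time) >= 30))
  # under-threshold hold while the gate is open is not rewarded
  att2 <- att
  att2$duration_above <- 0.7
  att2$joint_end <- att2$joint_onset + 0.7
  expect_null(apply_fixed_interval(att2)$trials)
})

test_that("raising the hold threshold never increases rewards", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      onsets <- sort(runif(40, 0, 400))
      holds <- runif(40, 0.2, 1.6)
      att <- data.frame(left_onset = onsets, right_onset = onsets,
                        joint_onset = onsets, joint_end = onsets + holds,
                        duration_above = holds)
      n_rewards <- vapply(seq(0.2, 1.4, by = 0.2), function(h) {
        tr <- apply_fixed_interval(att, hold_s = h)$trials
        if (is.null(tr)) 0L else nrow(tr)
      }, integer(1))
      expect_true(all(diff(n_rewards) <= 0))
    }
  })
})

test_that("block schedule alternates thresholds every 20 rewarded trials", {
  holds <- rep(1.4, 45)  # long enough for either threshold
  onsets <- cumsum(rep(3, 45))
  att <- data.frame(left_onset = onsets, right_onset = onsets,
                    joint_onset = onsets, joint_end = onsets + holds,
                    duration_above = holds)
  res <- apply_block_schedule(att)
  expect_identical(res$trials$required_interval_ms[1:20], rep(1250, 20))
  expect_identical(res$trials$required_interval_ms[21:40], rep(750, 20))
  expect_identical(res$trials$required_interval_ms[41:45], rep(1250, 5))
  # 1000 ms holds in a 1250 ms block: no rewards, attempts accumulate
  att$duration_above <- 1.0
  att$joint_end <- att$joint_onset + 1.0
  res2 <- apply_block_schedule(att)
  expect_null(res2$trials)
  expect_true(all(!res2$attempts$success))
})

test_that("noise-free sessions round-trip: rewards to one sample, counts exact", {
  cfg <- noise_free_config(n_trials = 10)
  s <- simulate_fixed_interval_session(cfg, 0, seed = 21)
  an <- analyze_lever_session(s)
  expect_identical(nrow(an$trials), nrow(s$ground_truth$trials))
  expect_lte(max(abs(an$trials$reward_time - s$reward_times)), 1 / fs)
  s2 <- simulate_two_interval_session(cfg, 0, seed = 22)
  an2 <- analyze_lever_session(s2)
  expect_identical(nrow(an2$trials), nrow(s2$ground_truth$trials))
  expect_lte(max(abs(an2$trials$reward_time - s2$reward_times)), 1 / fs)
  expect_equal(an2$trials$required_interval_ms,
               s2$ground_truth$trials$required_interval_ms)
})

test_that("reward count equals successful attempts and effort is conserved", {
  cfg <- gen_config(n_trials = 12)
  s <- simulate_two_interval_session(cfg, 0.05, seed = 23)
  an <- analyze_lever_session(s)
  expect_identical(sum(an$attempts$success), nrow(an$trials))
  # conservation: per-trial effort sums to the press time attributed to the
  # trials (bilateral mean of above-touch durations of presses whose onset
  # falls before the last reward)
  last_r <- max(an$trials$reward_time)
  keep_l <- an$presses$left$onset_time <= last_r
  keep_r <- an$presses$right$onset_time <= last_r
  tot <- 0.5 * (sum(an$presses$left$offset_time[keep_l] -
                      an$presses$left$onset_time[keep_l]) +
                  sum(an$presses$right$offset_time[keep_r] -
                        an$presses$right$onset_time[keep_r]))
  expect_equal(sum(an$trials$effort_s), tot, tolerance = 1e-6)
})
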