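# Generator contracts: determinism, scalar timing, degenerate limits, and the
# clock/motor distortion semantics.

test_that("identical config and seed reproduce sessions bit-identically", {
  cfg <- gen_config(n_trials = 5)
  a <- simulate_fixed_interval_session(cfg, 0.05, seed = 42)
  b <- simulate_fixed_interval_session(cfg, 0.05, seed = 42)
  expect_identical(a$reward_times, b$reward_times)
  expect_identical(a$left_pos, b$left_pos)
  c1 <- simulate_two_interval_session(cfg, 0.2, seed = 7)
  c2 <- simulate_two_interval_session(cfg, 0.2, seed = 7)
  expect_identical(c1$ground_truth$trials, c2$ground_truth$trials)
  t1 <- simulate_treadmill_session(cfg, 0.1, seed = 3)
  t2 <- simulate_treadmill_session(cfg, 0.1, seed = 3)
  expect_identical(t1$trials[[1]]$position_cm, t2$trials[[1]]$position_cm)
  d <- simulate_fixed_interval_session(cfg, 0.05, seed = 43)
  expect_false(identical(a$reward_times, d$reward_times))
})

test_that("unknown dose labels and nonpositive trial counts are rejected", {
  cfg <- gen_config(n_trials = 3)
  expect_error(simulate_fixed_interval_session(cfg, 0.3, 1), "unknown dose")
  expect_error(simulate_two_interval_trials(cfg, -1, 1), "unknown dose")
  bad <- cfg
  bad$n_trials <- 0L
  expect_error(simulate_fixed_interval_session(bad, 0, 1), "trial count")
})

test_that("config validation enforces the documented invariants", {
  expect_error(gen_config(weber_fraction = 0), "weber")
  expect_error(gen_config(weber_fraction = 1), "weber")
  expect_error(gen_config(clock_gain = c(1, -1, 1, 1, 1)), "> 0")
  expect_error(gen_config(dose_levels = c(0.2, 0.1)), "ascending")
  expect_error(gen_config(press_amplitude_cm = 3.8), "3.5")
})

test_that("degenerate-noise fixed-interval limit rewards the first bout after 30 s", {
  cfg <- noise_free_config(n_trials = 10)
  s <- simulate_fixed_interval_session(cfg, 0, seed = 2)
  iri <- diff(c(0, s$reward_times))
  # every reward strictly after a full 30 s gate, with only bout latency extra
  expect_true(all(iri >= 30))
  expect_lt(stats::median(iri), 34)
  # all positions physically bounded
  expect_true(all(s$left_pos >= 0 & s$left_pos <= 3.5))
  expect_true(all(s$right_pos >= 0 & s$right_pos <= 3.5))
  expect_true(all(diff(s$reward_times) > 0))
})

test_that("free-running press density peaks at the subjective target (Monte-Carlo)", {
  # clock gain 0.75: subjective 30 s is reached at 30/0.75 = 40 s objective
  cfg <- gen_config(dose_levels = 0, clock_gain = 0.75, motor_scale = 1)
  tt <- chronobeh:::sample_fi_press_times_free(cfg, 0, n_intervals = 2000,
                                               horizon_s = 60, seed = 5)
  h <- hist(tt, breaks = seq(0, 60, by = 1), plot = FALSE)
  expect_equal(h$mids[which.max(h$counts)], 40, tolerance = 0.05)
})

test_that("produced hold intervals obey the scalar (Weber) property", {
  cfg <- gen_config(n_trials = 600, reactive_fraction = 0)
  att <- simulate_two_interval_trials(cfg, 0, seed = 11)$attempts
  for (req in c(750, 1250)) {
    h <- att$hold[att$required_ms == req]
    expect_gt(length(h), 300)
    expect_equal(stats::sd(h) / mean(h), cfg$weber_fraction, tolerance = 0.08)
  }
})

test_that("two-interval block structure alternates 20-trial blocks from 1250 ms", {
  cfg <- gen_config(n_trials = 80)
  tr <- simulate_two_interval_trials(cfg, 0, seed = 3)$trials
  expect_identical(tr$required_interval_ms,
                   rep(rep(c(1250, 750), 2), each = 20))
  expect_identical(tr$block_id, rep(1:4, each = 20L))
})

test_that("control production overshoots the requirement by the planned margin", {
  cfg <- noise_free_config(n_trials = 40)
  tr <- simulate_two_interval_trials(cfg, 0, seed = 4)$trials
  expect_equal(stats::median(tr$overshoot_ms[tr$required_interval_ms == 750]),
               100, tolerance = 0.01)
  expect_equal(stats::median(tr$overshoot_ms[tr$required_interval_ms == 1250]),
               100, tolerance = 0.01)
})

test_that("production modes separate additively vs multiplicatively", {
  # motor slowing: release lag 200 ms at motor scale 0.5 adds 200 ms to both
  # intervals, so fraction increments differ by 1250/750
  cfg_m <- noise_free_config(n_trials = 40, production_mode = "motor_slowing",
                             dose_levels = c(0, 1), motor_scale = c(1, 0.5),
                             clock_gain = 1, release_lag_ms = 200)
  tr0 <- simulate_two_interval_trials(cfg_m, 0, seed = 5)$trials
  tr1 <- simulate_two_interval_trials(cfg_m, 1, seed = 6)$trials
  inc <- function(trd, trc, req) {
    stats::median(trd$overshoot_ms[trd$required_interval_ms == req]) / req -
      stats::median(trc$overshoot_ms[trc$required_interval_ms == req]) / req
  }
  ratio_m <- inc(tr1, tr0, 750) / inc(tr1, tr0, 1250)
  expect_equal(ratio_m, 1250 / 750, tolerance = 0.02)
  # timing scaling: a 20% slower production clock lengthens proportionally
  cfg_t <- noise_free_config(n_trials = 40, production_mode = "timing_scaling",
                             dose_levels = c(0, 1), motor_scale = 1,
                             clock_gain = c(1, 1 / 1.2))
  tr0 <- simulate_two_interval_trials(cfg_t, 0, seed = 7)$trials
  tr1 <- simulate_two_interval_trials(cfg_t, 1, seed = 8)$trials
  ratio_t <- inc(tr1, tr0, 750) / inc(tr1, tr0, 1250)
  expect_equal(ratio_t, 1, tolerance = 0.02)
  expect_equal(inc(tr1, tr0, 750), 0.2, tolerance = 0.01)
})

test_that("treadmill control trials last exactly the goal time, bounded in the arena", {
  cfg <- gen_config(n_trials = 6, treadmill = noise_free_treadmill())
  s <- simulate_treadmill_session(cfg, 0, seed = 9)
  for (tr in s$trials) {
    a <- align_and_duration(tr)
    expect_equal(a$duration_s, 7, tolerance = 0.02)
    expect_true(a$correct || a$duration_s > 6.98)
    expect_true(all(tr$position_cm >= 0 & tr$position_cm <= 80))
  }
})

test_that("treadmill peak speed rises with belt speed and scales with motor state", {
  cfg <- gen_config(n_trials = 1, treadmill = noise_free_treadmill())
  pk <- vapply(c(27, 30, 33), function(v) {
    s <- simulate_treadmill_session(cfg, 0, belt_speeds = v, seed = 20 + v)
    s$trials[[1]]$ground_truth$v_peak
  }, numeric(1))
  expect_true(all(diff(pk) > 0))
  cfg6 <- gen_config(n_trials = 1, dose_levels = c(0, 1), motor_scale = c(1, 0.6),
                     clock_gain = 1,
                     treadmill = noise_free_treadmill(strategy = "shortened_hold"))
  s0 <- simulate_treadmill_session(cfg6, 0, belt_speeds = 30, seed = 1)
  s6 <- simulate_treadmill_session(cfg6, 1, belt_speeds = 30, seed = 1)
  expect_equal(s6$trials[[1]]$ground_truth$v_peak /
                 s0$trials[[1]]$ground_truth$v_peak, 0.6, tolerance = 1e-9)
  # slowed animal shortens the hold but keeps the sequence near goal time
  expect_lt(s6$trials[[1]]$ground_truth$t_hold, s0$trials[[1]]$ground_truth$t_hold)
  expect_equal(align_and_duration(s6$trials[[1]])$duration_s, 7, tolerance = 0.02)
})

test_that("infeasible treadmill kinematics are signalled, not truncated", {
  cfg <- gen_config(n_trials = 2, dose_levels = c(0, 1),
                    motor_scale = c(1, 0.25), clock_gain = 1,
                    treadmill = noise_free_treadmill(strategy = "shortened_hold"))
  expect_error(simulate_treadmill_session(cfg, 1, belt_speeds = 30, seed = 1),
               "infeasible")
  expect_error(simulate_treadmill_session(cfg, 0, belt_speeds = 40, seed = 1),
               "outside the configured set")
})

test_that("generator configs round-trip through YAML", {
  cfg <- gen_config(n_trials = 17, weber_fraction = 0.12,
                    treadmill = list(goal_time_s = 6.5))
  path <- tempfile(fileext = ".yaml")
  write_gen_config(cfg, path)
  cfg2 <- read_gen_config(path)
  expect_equal(cfg2$n_trials, 17L)
  expect_equal(cfg2$weber_fraction, 0.12)
  expect_equal(cfg2$treadmill$goal_time_s, 6.5)
  expect_error(read_gen_config({
    p <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(nonsense_field = 1), p)
    p
  }), "unknown config fields")
})
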