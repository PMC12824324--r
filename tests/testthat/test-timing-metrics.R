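# Timing and kinematic metrics.

test_that("overshoot and overshoot fraction follow their definitions", {
  expect_equal(overshoot(10.9, 10.0), 900)
  expect_equal(overshoot(10.0, 10.0), 0)
  expect_error(overshoot(10, NA), "unrewarded")
  expect_equal(overshoot_fraction(150, 750), 0.2)
  expect_equal(overshoot_fraction(150, 1250), 0.12)
  expect_equal(overshoot_fraction(0, 321), 0)
  expect_error(overshoot_fraction(-1, 750), "negative")
  expect_error(overshoot_fraction(10, 0), "positive")
})

test_that("interlimb correlation matches the reference implementation", {
  x <- seq(0, 2.6, length.out = 100)
  expect_equal(interlimb_correlation(x, x), 1)
  expect_equal(interlimb_correlation(x, -x + 5), -1)
  withr::with_seed(3, {
    y <- x + rnorm(100, 0, 0.1)
    expect_equal(interlimb_correlation(x, y), stats::cor(x, y), tolerance = 1e-12)
  })
  expect_true(is.na(interlimb_correlation(rep(1, 10), x[1:10])))
  expect_error(interlimb_correlation(1:2, 1:2), "3 samples")
})

test_that("bmov is the across-trial variance of absolute onset lags", {
  expect_equal(bmov(c(0.2, 0.2, 0.2)), 0)
  expect_equal(bmov(c(0.1, 0.3)), 0.02)
  expect_error(bmov(0.1), "2 trials")
  # folded-normal identity: var(|N(0, s)|) = s^2 (1 - 2/pi)
  withr::with_seed(4, {
    s <- 0.05
    lags <- abs(rnorm(40000, 0, s))
    expect_equal(bmov(lags), s^2 * (1 - 2 / pi), tolerance = 0.03)
  })
})

test_that("movement speed is the 4 ms finite difference", {
  expect_equal(movement_speed(rep(1.3, 50))$max_speed, 0)
  ramp <- seq(0, 2.6, by = 2.6 / 50)  # 2.6 cm in 0.2 s at 250 Hz
  sp <- movement_speed(ramp)
  expect_true(all(abs(sp$speed - 13) < 1e-9))
  expect_equal(sp$max_speed, 13)
  expect_error(movement_speed(1), "2 samples")
})

test_that("trajectory variability recovers the normal-IQR identity", {
  template <- sin(seq(0, pi, length.out = 100)) * 2.6
  expect_equal(trajectory_variability(replicate(5, template, simplify = FALSE)), 0)
  withr::with_seed(5, {
    sigma <- 0.2
    traces <- replicate(400, template + rnorm(100, 0, sigma), simplify = FALSE)
    tv <- trajectory_variability(traces)
    expect_equal(tv, 2 * stats::qnorm(0.75) * sigma, tolerance = 0.05)
    shifted <- lapply(traces, function(x) x + 0.7)
    expect_equal(trajectory_variability(shifted), tv, tolerance = 1e-9)
  })
  expect_error(trajectory_variability(list(template, template)), "3 trials")
})

test_that("efficiency metrics follow the schedule walk", {
  trials <- data.frame(reward_time = seq(10, 1000, by = 10),
                       n_attempts = rep(1L, 100),
                       effort_s = rep(0.9, 100))
  em <- efficiency_metrics(trials)
  expect_equal(em$time_to_first_n_s, 1000)
  expect_equal(em$trials_per_session, 100L)
  expect_equal(em$attempts_per_reward, 1)
  # every reward preceded by one failed 500 ms attempt at a 750 ms threshold
  trials2 <- data.frame(reward_time = seq(4, 120, by = 4),
                        n_attempts = 2L, effort_s = 0.5 + 0.9)
  em2 <- efficiency_metrics(trials2, first_n = 10)
  expect_equal(em2$attempts_per_reward, 2)
  expect_equal(em2$effort_per_reward_s, 1.4)
  # empty input: all missing, no crash
  em3 <- efficiency_metrics(NULL)
  expect_true(is.na(em3$time_to_first_n_s))
  expect_identical(em3$trials_per_session, 0L)
  # short session: time to first 100 missing
  expect_true(is.na(efficiency_metrics(trials[1:50, ])$time_to_first_n_s))
})

test_that("peri-reward histogram bins, normalises and conserves counts", {
  # presses only at rewards: single occupied bin at 0
  h <- peri_reward_histogram(c(40, 80), c(40, 80))
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(h$bin_left[h$count > 0], 0)
  # conservation: sum(rate) * binwidth * n_trials = total count in window
  withr::with_seed(6, {
    presses <- sort(runif(500, 0, 200))
    rewards <- seq(30, 180, by = 30)
    h2 <- peri_reward_histogram(presses, rewards)
    in_win <- as.vector(outer(presses, rewards, "-"))
    expect_equal(sum(h2$rate) * h2$binwidth * h2$n_trials,
                 sum(in_win >= -30 & in_win < 5))
  })
  expect_error(peri_reward_histogram(1:3, numeric(0)), "at least one reward")
  h3 <- peri_reward_histogram(numeric(0), 50)
  expect_true(all(h3$count == 0))
})

test_that("uniform pressing yields a flat histogram at the Poisson rate", {
  withr::with_seed(7, {
    lambda <- 0.8
    t_end <- 4000
    presses <- sort(runif(rpois(1, lambda * t_end), 0, t_end))
    rewards <- seq(100, t_end - 100, by = 40)
    h <- peri_reward_histogram(presses, rewards)
    expect_equal(mean(h$rate), lambda, tolerance = 0.05)
    expect_lt(stats::sd(h$rate) / mean(h$rate), 0.2)
  })
})

test_that("histogram AUC integrates the pre-reward rate", {
  h <- peri_reward_histogram(numeric(0), 50)
  expect_equal(histogram_auc(h), 0)
  # flat rate r over the 30 s pre-window integrates to 30 r
  h$rate <- rep(0.4, length(h$rate))
  expect_equal(histogram_auc(h), 30 * 0.4)
})

test_that("peak interval locates the smoothed pre-reward maximum", {
  # all presses 0.5 s before reward
  h <- peri_reward_histogram(c(29.5, 59.2), c(30, 59.7))
  expect_equal(peak_interval(h), 29.5)
  # a single-bin spike still maps to its own bin after smoothing
  h2 <- peri_reward_histogram(rep(25.2, 5), 30)  # lag -4.8, bin [-5, -4)
  expect_equal(peak_interval(h2), 25.5)
  expect_error(peak_interval(peri_reward_histogram(numeric(0), 30)), "no peak")
})

test_that("trial splits partition with the documented conventions", {
  trials <- data.frame(trial_index = 1:100,
                       block_id = rep(1:5, each = 20))
  s <- split_trials(trials, "halves")
  expect_identical(nrow(s$first_half), 50L)
  expect_identical(nrow(s$second_half), 50L)
  s2 <- split_trials(data.frame(trial_index = 1:101), "halves")
  expect_identical(nrow(s2$first_half), 50L)  # odd count: second half larger
  expect_identical(nrow(s2$second_half), 51L)
  s3 <- split_trials(trials, "block_edges_10")
  expect_identical(nrow(s3$block_first), 50L)
  expect_identical(nrow(s3$block_last), 50L)
  expect_true(all(s3$block_first$trial_index %% 20 %in% c(1:10)))
  expect_error(split_trials(trials, "first_last_100"), "at least 200")
  s4 <- split_trials(trials, "first_last_100", edge_n = 40)
  expect_identical(s4$first$trial_index, 1:40)
  expect_identical(s4$last$trial_index, 61:100)
})

test_that("aggregates are medians with quartiles excluding missing values", {
  trials <- data.frame(overshoot_ms = c(100, 200, 300, NA),
                       interlimb_r = c(0.9, NA, 0.8, 0.7))
  a <- aggregate_trial_metrics(trials, c("overshoot_ms", "interlimb_r"))
  expect_equal(a$median[a$metric == "overshoot_ms"], 200)
  expect_equal(a$n[a$metric == "interlimb_r"], 3)
  expect_equal(a$median[a$metric == "interlimb_r"], 0.8)
})
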