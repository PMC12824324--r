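# Synthetic lever sessions: scalar-timing press model, trapezoidal waveforms,
# 250 Hz trace rendering.

FS_LEVER <- 250
POS_MAX <- 3.5

# --- waveform geometry -------------------------------------------------------

# A press is a trapezoid: linear rise at `rise_v`, plateau at `amp`, linear
# fall at `fall_v`, plus correlated positional jitter added at render time.
# All analytic spans below are exact for the noise-free trapezoid.

press_touch_span <- function(onset, amp, rise_v, fall_v, plateau, touch = 0.1) {
  c(onset + touch / rise_v,
    onset + amp / rise_v + plateau + (amp - touch) / fall_v)
}

press_spatial_onset <- function(onset, rise_v, spatial = 2.6) onset + spatial / rise_v

# Plateau needed so the above-spatial span lasts `h` seconds; clamped at zero
# (a press cannot be shorter than its rise/fall through the spatial band).
plateau_for_hold <- function(h, amp, rise_v, fall_v, spatial = 2.6) {
  pmax(h - (amp - spatial) * (1 / rise_v + 1 / fall_v), 0)
}

# --- hold-duration model -----------------------------------------------------

# Produced above-spatial hold for one attempt at a required interval.
# Planned holds: (required * timing distortion) + margin + additive motor
# lengthening, all scaled by multiplicative scalar-timing noise so that
# SD/mean of the produced interval equals the Weber fraction.
sample_hold <- function(n, required_s, config, dose, reactive = rep(FALSE, n)) {
  g <- clock_gain_for(config, dose)
  m <- motor_scale_for(config, dose)
  distmult <- if (config$production_mode == "timing_scaling") 1 / g else 1
  add_s <- if (config$production_mode == "motor_slowing") {
    config$release_lag_ms / 1000 * (1 / m - 1)
  } else 0
  planned <- required_s * distmult + config$planned_margin_ms / 1000 + add_s
  planned_reactive <- required_s + config$reaction_time_ms / 1000 / m + add_s
  base <- ifelse(reactive, planned_reactive, planned)
  pmax(base * (1 + config$weber_fraction * stats::rnorm(n)), 0.05)
}

# --- fixed-interval press-timing model --------------------------------------

# Checking-press rate (presses/s) at elapsed time tau since the last reward:
# baseline + Gaussian bump centred on the subjective target, with a sustained
# floor after the target has passed unrewarded.
fi_press_rate <- function(tau, t_peak, sigma, config) {
  bump <- exp(-(tau - t_peak)^2 / (2 * sigma^2))
  sustained <- ifelse(tau > t_peak, config$sustain_fraction, 0)
  config$baseline_press_rate + config$press_rate_peak * pmax(bump, sustained)
}

# Inhomogeneous-Poisson checking-press times on [t0, t1] (elapsed coordinates),
# by thinning, with a refractory dead time between presses.
sample_check_presses <- function(t0, t1, t_peak, sigma, config, dead = 0.35) {
  if (t1 <= t0) return(numeric(0))
  lam_max <- config$baseline_press_rate + config$press_rate_peak
  n <- stats::rpois(1, lam_max * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < fi_press_rate(cand, t_peak, sigma, config) / lam_max
  cand <- cand[keep]
  out <- numeric(0)
  last <- -Inf
  for (tt in cand) {
    if (tt - last >= dead) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

# Free-running sampler of checking-press times over `n_intervals` independent
# intervals with no reward truncation; used to verify the generator's own
# press-time density (e.g. its peak sits at fi_interval / clock_gain).
sample_fi_press_times_free <- function(config, dose, n_intervals, horizon_s, seed) {
  g <- clock_gain_for(config, dose)
  t_peak <- config$fi_interval_s / g
  sigma <- config$weber_fraction * t_peak
  with_seed(seed, {
    unlist(lapply(seq_len(n_intervals), function(i) {
      sample_check_presses(0, horizon_s, t_peak, sigma, config)
    }))
  })
}

# --- event assembly ----------------------------------------------------------

new_press_row <- function(lever, onset, amp, rise_v, fall_v, plateau, kind) {
  data.frame(lever = lever, onset = onset, amp = amp, rise_v = rise_v,
             fall_v = fall_v, plateau = plateau, kind = kind)
}

# Build the two-lever event rows of one full (coordinated) attempt whose joint
# above-spatial span starts at `joint_spatial_onset` and lasts `hold`.
full_attempt_events <- function(joint_spatial_onset, hold, lag, amp_l, amp_r,
                                v, spatial = 2.6) {
  span_each <- hold + abs(lag)
  pl <- plateau_for_hold(span_each, amp_l, v, v, spatial)
  pr <- plateau_for_hold(span_each, amp_r, v, v, spatial)
  # the later lever's spatial crossing defines the joint onset
  on_l <- joint_spatial_onset - spatial / v - max(0, -lag)
  on_r <- joint_spatial_onset - spatial / v - max(0, lag)
  rbind(new_press_row("left", on_l, amp_l, v, v, pl, "full"),
        new_press_row("right", on_r, amp_r, v, v, pr, "full"))
}

attempt_window <- function(ev) {
  c(min(ev$onset), max(ev$onset + ev$amp / ev$rise_v + ev$plateau + ev$amp / ev$fall_v))
}

# --- trace rendering ---------------------------------------------------------

render_lever_trace <- function(events, t_end, jitter_sd, fs = FS_LEVER) {
  n <- ceiling(t_end * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  pos <- list(left = numeric(n), right = numeric(n))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      t_rise <- e$amp / e$rise_v
      t_fall <- e$amp / e$fall_v
      t_tot <- t_rise + e$plateau + t_fall
      i0 <- max(1L, ceiling(e$onset * fs) + 1L)
      i1 <- min(n, floor((e$onset + t_tot) * fs) + 1L)
      if (i1 < i0) next
      rel <- tt[i0:i1] - e$onset
      y <- pmin(rel * e$rise_v, e$amp)
      past <- rel - (t_rise + e$plateau)
      y <- ifelse(past > 0, pmax(e$amp - past * e$fall_v, 0), y)
      pos[[e$lever]][i0:i1] <- pmax(pos[[e$lever]][i0:i1], y)
    }
  }
  left <- pmin(pmax(pos$left + smooth_noise(n, jitter_sd), 0), POS_MAX)
  right <- pmin(pmax(pos$right + smooth_noise(n, jitter_sd), 0), POS_MAX)
  data.frame(time_s = tt, left_cm = left, right_cm = right)
}

new_lever_session <- function(trace, schedule, dose, reward_times, block_labels,
                              ground_truth) {
  structure(list(
    time = trace$time_s, left_pos = trace$left_cm, right_pos = trace$right_cm,
    fs = FS_LEVER, schedule = schedule, dose = dose,
    reward_times = reward_times, block_labels = block_labels,
    ground_truth = ground_truth
  ), class = "lever_session")
}

#' @export
print.lever_session <- function(x, ...) {
  cat("<lever_session> schedule:", x$schedule, " dose:", x$dose, "mg/kg\n")
  cat("  ", length(x$time), "samples at", x$fs, "Hz (",
      format(round(max(x$time), 1)), "s ),", length(x$reward_times), "rewards\n")
  invisible(x)
}

# --- fixed-interval session --------------------------------------------------

#' Simulate a fixed-interval (peak-interval) lever session
#'
#' Generates a session of the 30 s fixed-interval schedule under a
#' scalar-timing press model. The animal's subjective time runs at
#' `clock_gain(dose)` times objective time, so its pressing (a Gaussian bump of
#' checking presses plus timed full attempts, over a low baseline) is centred
#' at objective time `fi_interval_s / clock_gain`, with scalar (Weber) spread.
#' The schedule itself is veridical: the first coordinated attempt holding both
#' levers above the spatial threshold for the required duration, starting at or
#' after 30 s of objective time since the previous reward, is rewarded and the
#' counter resets. With clock gain above 1 pressing starts early and spreads
#' across the whole interval; full attempts that meet the gate are retried
#' until one is rewarded.
#'
#' @param config a [gen_config()].
#' @param dose a dose label in `config$dose_levels`.
#' @param seed integer seed for this session.
#' @return a `lever_session`: 250 Hz two-lever trace, reward times, and a
#'   `ground_truth` list with the generating parameters, per-trial records,
#'   attempt table and press-onset times.
#' @examples
#' s <- simulate_fixed_interval_session(gen_config(n_trials = 3), dose = 0, seed = 1)
#' s$reward_times
#' @export
simulate_fixed_interval_session <- function(config, dose, seed = config$seed) {
  stopifnot(inherits(config, "gen_config"))
  i_dose <- dose_index(config, dose)
  if (config$n_trials < 1) stop("nonpositive trial count")
  g <- config$clock_gain[i_dose]
  m <- config$motor_scale[i_dose]
  t_peak <- config$fi_interval_s / g
  sigma <- config$weber_fraction * t_peak
  v <- config$lever_rise_speed_cm_s * m
  hold_req <- config$fi_hold_s

  with_seed(seed, {
    events <- list()
    rewards <- numeric(config$n_trials)
    trials <- vector("list", config$n_trials)
    attempts <- list()
    last_reward <- 0
    gate <- 0  # first gate opens at session start
    for (k in seq_len(config$n_trials)) {
      # timed full attempts, retried until the gate rewards one
      tau <- max(0.3, stats::rnorm(1, t_peak, sigma))
      n_att <- 0L
      repeat {
        n_att <- n_att + 1L
        a <- last_reward + tau
        # the schedule acts on the digitized trace: quantize the joint onset
        # to the first 250 Hz sample at or above the spatial crossing
        a_q <- ceiling(a * FS_LEVER - 1e-9) / FS_LEVER
        h <- sample_hold(1, hold_req, config, dose)
        lag <- stats::rnorm(1, 0, config$coordination_noise)
        amp <- pmin(config$press_amplitude_cm + stats::runif(2, -0.05, 0.05), POS_MAX)
        ev <- full_attempt_events(a, h, lag, amp[1], amp[2], v)
        ok <- (a_q >= gate) && (h >= hold_req)
        events[[length(events) + 1L]] <- ev
        attempts[[length(attempts) + 1L]] <- data.frame(
          trial = k, joint_spatial_onset = a, hold = h, lag = lag, success = ok)
        if (ok) {
          reward <- a_q + hold_req
          break
        }
        w <- attempt_window(ev)
        tau <- tau + (w[2] - w[1]) + 0.3 + stats::rexp(1, 1 / 1.5)
      }
      # checking presses across the interval, avoiding the full attempts
      full_w <- lapply(events[seq(length(events) - n_att + 1L, length(events))],
                       attempt_window)
      taps <- sample_check_presses(0.5, reward - last_reward, t_peak, sigma, config)
      taps <- last_reward + taps
      if (length(taps) && length(full_w)) {
        bad <- vapply(taps, function(tt) {
          any(vapply(full_w, function(w) tt > w[1] - 0.35 && tt < w[2] + 0.1, logical(1)))
        }, logical(1))
        taps <- taps[!bad]
      }
      for (tt in taps) {
        lag <- stats::rnorm(1, 0, config$coordination_noise)
        amp <- stats::runif(2, 0.6, 2.4)
        pl <- 0.12 / m
        events[[length(events) + 1L]] <-
          rbind(new_press_row("left", tt, amp[1], v, v, pl, "tap"),
                new_press_row("right", tt + lag, amp[2], v, v, pl, "tap"))
      }
      rewards[k] <- reward
      trials[[k]] <- data.frame(
        trial_index = k, required_interval_ms = hold_req * 1000,
        n_attempts = n_att, reward_time = reward,
        overshoot_ms = (attempts[[length(attempts)]]$hold - hold_req) * 1000,
        onset_lag_abs_s = abs(attempts[[length(attempts)]]$lag),
        n_taps = length(taps))
      last_reward <- reward
      gate <- reward + config$fi_interval_s
    }
    events <- do.call(rbind, events)
    events <- events[order(events$onset), ]
    trace <- render_lever_trace(events, max(rewards) + 2, config$trace_jitter_cm)
    gt <- list(
      params = list(dose = dose, clock_gain = g, motor_scale = m,
                    t_peak = t_peak, sigma = sigma, lever_speed = v,
                    planned_margin_ms = config$planned_margin_ms, seed = seed),
      trials = do.call(rbind, trials),
      attempts = do.call(rbind, attempts),
      press_onsets = list(left = sort(events$onset[events$lever == "left"]),
                          right = sort(events$onset[events$lever == "right"])),
      events = events)
    new_lever_session(trace, "fixed_interval", dose, rewards,
                      rep(NA_real_, config$n_trials), gt)
  })
}

# --- two-interval production session ----------------------------------------

#' Simulate two-interval production trials (event level)
#'
#' Trial-level core of the two-interval hold-production generator: alternating
#' 20-trial blocks (longest interval first) of bilateral holds at 1250 or
#' 750 ms. Each attempt draws a produced hold
#' `(required x timing distortion + margin + motor lengthening) x (1 + weber x Z)`;
#' draws shorter than the requirement are failed attempts that are retried,
#' so attempt counts and effort accumulate as in the real schedule. In
#' `motor_slowing` mode the dose adds an interval-independent increment
#' (release lag scaled by `1/motor_scale`); in `timing_scaling` mode the dose
#' multiplies the produced interval by `1/clock_gain`. A configurable fraction
#' of rewarded trials is reactive (release follows the reward by the reaction
#' time) rather than planned.
#'
#' @inheritParams simulate_fixed_interval_session
#' @return a list with `trials` (one row per rewarded trial: block, required
#'   interval, attempts, overshoot, onset lag, effort), `attempts` (every
#'   attempt incl. failed) and `params`.
#' @export
simulate_two_interval_trials <- function(config, dose, seed = config$seed) {
  stopifnot(inherits(config, "gen_config"))
  i_dose <- dose_index(config, dose)
  if (config$n_trials < 1) stop("nonpositive trial count")
  m <- config$motor_scale[i_dose]
  v <- config$lever_rise_speed_cm_s * m
  thr <- config$ti_thresholds_ms / 1000
  with_seed(seed, {
    n_tr <- config$n_trials
    tr_mat <- matrix(0, n_tr, 8)  # block, required, n_att, effort, reward, overshoot, lag, reactive
    att_acc <- vector("list", 4L * n_tr)
    n_att_tot <- 0L
    t_cur <- 1 + stats::rexp(1, 2)
    for (k in seq_len(n_tr)) {
      block_id <- (k - 1L) %/% config$ti_block_len + 1L
      required <- thr[(block_id - 1L) %% 2L + 1L]
      reactive <- stats::runif(1) < config$reactive_fraction
      n_att <- 0L
      effort <- 0
      repeat {
        n_att <- n_att + 1L
        h <- sample_hold(1, required, config, dose,
                         reactive = reactive && n_att == 1L)
        lag <- stats::rnorm(1, 0, config$coordination_noise)
        amp <- pmin(config$press_amplitude_cm + stats::runif(2, -0.05, 0.05), POS_MAX)
        ok <- h >= required
        # above-touch press duration of each lever (analytic, for effort)
        span_each <- h + abs(lag)
        dur_touch <- span_each + (2.6 - config$touch_threshold_cm) * 2 / v
        effort <- effort + dur_touch
        n_att_tot <- n_att_tot + 1L
        att_acc[[n_att_tot]] <- c(k, block_id, required * 1000, t_cur, h, lag,
                                  amp[1], amp[2], reactive && n_att == 1L, ok)
        if (ok) break
        t_cur <- t_cur + h + 0.3 / m + stats::rexp(1, 1 / 0.7)
      }
      # reward clock runs on the digitized trace (first sample at/above the
      # spatial crossing)
      reward <- ceiling(t_cur * FS_LEVER - 1e-9) / FS_LEVER + required
      tr_mat[k, ] <- c(block_id, required * 1000, n_att, effort, reward,
                       (h - required) * 1000, abs(lag), reactive)
      t_cur <- reward + (h - required) + 0.3 + config$iti_s + stats::rexp(1, 2)
    }
    am <- do.call(rbind, att_acc[seq_len(n_att_tot)])
    attempts <- data.frame(
      trial = as.integer(am[, 1]), block_id = as.integer(am[, 2]),
      required_ms = am[, 3], joint_spatial_onset = am[, 4], hold = am[, 5],
      lag = am[, 6], amp_l = am[, 7], amp_r = am[, 8],
      reactive = am[, 9] > 0, success = am[, 10] > 0)
    trials <- data.frame(
      trial_index = seq_len(n_tr), block_id = as.integer(tr_mat[, 1]),
      required_interval_ms = tr_mat[, 2], n_attempts = as.integer(tr_mat[, 3]),
      effort_s = tr_mat[, 4], reward_time = tr_mat[, 5],
      overshoot_ms = tr_mat[, 6], onset_lag_abs_s = tr_mat[, 7],
      max_speed_cm_s = v, reactive = tr_mat[, 8] > 0)
    list(trials = trials,
         attempts = attempts,
         params = list(dose = dose, motor_scale = m, lever_speed = v,
                       clock_gain = config$clock_gain[i_dose],
                       planned_margin_ms = config$planned_margin_ms,
                       production_mode = config$production_mode, seed = seed))
  })
}

#' Simulate a two-interval production lever session
#'
#' Wraps [simulate_two_interval_trials()] and renders the 250 Hz two-lever
#' trace (trapezoidal presses with inter-lever onset lag and correlated
#' positional jitter).
#'
#' @inheritParams simulate_fixed_interval_session
#' @return a `lever_session` with `schedule = "two_interval"`; `block_labels`
#'   holds the per-trial required interval in ms.
#' @examples
#' s <- simulate_two_interval_session(gen_config(n_trials = 4), dose = 0, seed = 1)
#' s$block_labels
#' @export
simulate_two_interval_session <- function(config, dose, seed = config$seed) {
  core <- simulate_two_interval_trials(config, dose, seed)
  att <- core$attempts
  v <- config$lever_rise_speed_cm_s * motor_scale_for(config, dose)
  ev <- do.call(rbind, lapply(seq_len(nrow(att)), function(i) {
    full_attempt_events(att$joint_spatial_onset[i], att$hold[i], att$lag[i],
                        att$amp_l[i], att$amp_r[i], v)
  }))
  ev <- ev[order(ev$onset), ]
  # rendering draws jitter: seed it from the session stream for determinism
  trace <- with_seed(derive_seed(seed, 777), {
    render_lever_trace(ev, max(core$trials$reward_time) + 2,
                       config$trace_jitter_cm)
  })
  gt <- c(core, list(
    press_onsets = list(left = sort(ev$onset[ev$lever == "left"]),
                        right = sort(ev$onset[ev$lever == "right"])),
    events = ev))
  new_lever_session(trace, "two_interval", dose, core$trials$reward_time,
                    core$trials$required_interval_ms, gt)
}
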