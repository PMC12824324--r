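# Synthetic treadmill sessions: three-phase front-back-front kinematics at 100 Hz.

FS_TREADMILL <- 100

# Kinematic plan of one trial. Position is measured from the front wall
# (0 = front, increasing rearward); the trial starts at the goal-zone boundary
# moving rearward and ends when the final run crosses back into the goal zone.
# Phases: passive transport at belt speed, position hold at the rear (trot),
# final acceleration with a triangular ground-frame speed profile peaking at
# `peak_speed_gain x belt_speed x motor_scale`. `rear_cm` is the trial's
# rear-most reach under full transport; `hold_ctrl_s` the control-like hold
# kept by the partial-transport strategy.
plan_treadmill_trial <- function(duration_s, belt_speed, v_peak, tm, strategy,
                                 rear_cm = tm$rear_position_cm,
                                 hold_ctrl_s = NULL) {
  goal <- tm$goal_zone_cm
  r_full <- rear_cm - goal
  t_tr_full <- r_full / belt_speed
  t_run_full <- 2 * r_full / v_peak
  hold_full <- duration_s - t_tr_full - t_run_full
  if (strategy %in% c("normal", "shortened_hold")) {
    if (hold_full < 0) {
      stop("infeasible kinematics: goal unreachable with a shortened hold ",
           "(belt ", belt_speed, " cm/s, peak ", round(v_peak, 1), " cm/s)")
    }
    return(list(strategy = strategy, rear = rear_cm,
                t_transport = t_tr_full, t_hold = hold_full, t_run = t_run_full,
                v_peak = v_peak))
  }
  # partial transport: keep a control-like hold, stop the transport early
  if (is.null(hold_ctrl_s)) {
    v_peak_ctrl <- tm$peak_speed_gain * belt_speed
    hold_ctrl_s <- duration_s - r_full / belt_speed - 2 * r_full / v_peak_ctrl
  }
  hold_ctrl_s <- max(hold_ctrl_s, 0.2)
  r <- (duration_s - hold_ctrl_s) / (1 / belt_speed + 2 / v_peak)
  if (r <= 2) {
    stop("infeasible kinematics: no reachable turning point ",
         "(belt ", belt_speed, " cm/s, peak ", round(v_peak, 1), " cm/s)")
  }
  r <- min(r, r_full)
  list(strategy = "partial_transport", rear = goal + r,
       t_transport = r / belt_speed, t_hold = hold_ctrl_s,
       t_run = 2 * r / v_peak, v_peak = v_peak)
}

# Noise-free position at time t (from trial start) for a planned trial.
treadmill_position <- function(t, plan, tm) {
  goal <- tm$goal_zone_cm
  t1 <- plan$t_transport
  t2 <- t1 + plan$t_hold
  t3 <- t2 + plan$t_run
  r <- plan$rear - goal
  belt <- r / t1
  half <- plan$t_run / 2
  a <- plan$v_peak / half
  run_pos <- function(u) {
    # distance covered since run start under the triangular speed profile
    d <- ifelse(u <= half, 0.5 * a * u^2,
                0.5 * a * half^2 + plan$v_peak * (u - half) - 0.5 * a * (u - half)^2)
    plan$rear - d
  }
  ifelse(t < t1, goal + belt * t,
         ifelse(t < t2, plan$rear,
                ifelse(t <= t3, run_pos(t - t2), goal - (t - t3) * plan$v_peak * 0.3)))
}

#' Simulate a treadmill session of timed front-back-front sequences
#'
#' Each trial draws a belt speed from `belt_speeds`, a timed sequence duration
#' around the 7 s goal (plus planned margin, with the configured duration CV),
#' and constructs the three-phase trajectory. When `motor_scale(dose) < 1`
#' the attainable peak speed of the final run shrinks and the generator
#' compensates to keep the duration near goal time, either by shortening the
#' rear hold or by stopping the passive transport before the rear wall
#' (strategy per `config$treadmill$strategy`; `"auto"` shortens the hold while
#' feasible). Infeasible kinematics raise an error rather than truncating.
#'
#' @inheritParams simulate_fixed_interval_session
#' @param belt_speeds belt speeds (cm/s) to draw from; defaults to the
#'   configured set. Must be a subset of it.
#' @return an object of class `treadmill_session`: a list of trials, each with
#'   `time_s`/`position_cm` at 100 Hz, `belt_speed`, `trial_start`, and ground
#'   truth (planned phases, strategy, peak speed, durations).
#' @examples
#' s <- simulate_treadmill_session(gen_config(n_trials = 3), dose = 0, seed = 1)
#' s$trials[[1]]$belt_speed
#' @export
simulate_treadmill_session <- function(config, dose,
                                       belt_speeds = config$treadmill$belt_speed_set,
                                       seed = config$seed) {
  stopifnot(inherits(config, "gen_config"))
  if (!all(belt_speeds %in% config$treadmill$belt_speed_set)) {
    stop("belt_speeds outside the configured set")
  }
  if (config$n_trials < 1) stop("nonpositive trial count")
  m <- motor_scale_for(config, dose)
  tm <- config$treadmill
  with_seed(seed, {
    trials <- vector("list", config$n_trials)
    t_session <- 0
    for (k in seq_len(config$n_trials)) {
      vb <- belt_speeds[sample.int(length(belt_speeds), 1)]
      target <- (tm$goal_time_s + tm$plan_margin_s) *
        (1 + tm$duration_cv * stats::rnorm(1))
      v_peak <- tm$peak_speed_gain * vb * m
      # trial-to-trial variation of the rear-most reach under full transport
      rear_eff <- tm$rear_position_cm - stats::runif(1, 0, 1.5)
      r_eff <- rear_eff - tm$goal_zone_cm
      hold_ctrl <- target - r_eff / vb - 2 * r_eff / (tm$peak_speed_gain * vb)
      hold_full <- target - r_eff / vb - 2 * r_eff / v_peak
      strategy <- tm$strategy
      if (strategy == "auto") {
        strategy <- if (hold_full >= 0.75 * hold_ctrl) "normal"
                    else sample(c("shortened_hold", "partial_transport"), 1)
      }
      plan <- plan_treadmill_trial(target, vb, v_peak, tm, strategy,
                                   rear_cm = rear_eff, hold_ctrl_s = hold_ctrl)
      dur <- plan$t_transport + plan$t_hold + plan$t_run
      n <- ceiling((dur + 0.5) * FS_TREADMILL) + 1L
      tt <- (seq_len(n) - 1L) / FS_TREADMILL
      pos <- treadmill_position(tt, plan, tm)
      if (tm$trot_amplitude_cm > 0 && plan$t_hold > 0.1) {
        # tapered zero-mean wobble: continuous at the phase boundaries
        t0h <- plan$t_transport
        t1h <- plan$t_transport + plan$t_hold
        in_hold <- tt >= t0h & tt <= t1h
        taper <- pmin(1, (tt[in_hold] - t0h) / 0.5, (t1h - tt[in_hold]) / 0.5)
        pos[in_hold] <- pos[in_hold] +
          tm$trot_amplitude_cm * taper * sin(2 * pi * (tt[in_hold] - t0h))
      }
      pos <- pos + smooth_noise(n, tm$jitter_cm, 5L)
      pos <- pmin(pmax(pos, 0), tm$belt_length_cm)
      trials[[k]] <- list(
        time_s = tt, position_cm = pos, belt_speed = vb,
        trial_start = t_session,
        ground_truth = list(
          strategy = plan$strategy, rear = plan$rear, v_peak = plan$v_peak,
          t_transport = plan$t_transport, t_hold = plan$t_hold,
          t_run = plan$t_run, duration = dur))
      t_session <- t_session + dur + 3  # reward + return to front
    }
    structure(list(trials = trials, dose = dose, motor_scale = m,
                   config = config, seed = seed),
              class = "treadmill_session")
  })
}

#' @export
print.treadmill_session <- function(x, ...) {
  cat("<treadmill_session> dose:", x$dose, "mg/kg,",
      length(x$trials), "trials, motor_scale", x$motor_scale, "\n")
  invisible(x)
}

#' Convert camera pixels to centimetres
#'
#' The lateral high-speed camera records at 100 frames/s with 9 pixels per cm;
#' ingest of pixel-unit trajectories goes through this exact linear map.
#'
#' @param px position in pixels.
#' @param pixels_per_cm camera calibration (pixels/cm).
#' @return position in cm.
#' @examples
#' pixels_to_cm(9)   # 1 cm
#' @export
pixels_to_cm <- function(px, pixels_per_cm = 9) {
  stopifnot(pixels_per_cm > 0)
  px / pixels_per_cm
}
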