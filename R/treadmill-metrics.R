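# Treadmill sequence scoring: alignment, phase segmentation, peak speed,
# stereotypy, compensatory strategy classification.

# Signed ground-frame velocity (cm/s, positive rearward): centered difference
# smoothed with a 50 ms boxcar.
treadmill_velocity <- function(position_cm, fs = 100) {
  n <- length(position_cm)
  if (n < 3L) stop("trace shorter than 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (position_cm[3:n] - position_cm[1:(n - 2)]) * fs / 2
  v[1] <- v[2]
  v[n] <- v[n - 1]
  box_smooth(v, max(1L, round(0.05 * fs)))
}

# First downward crossing of the goal-zone boundary (position from > goal to
# <= goal); fractional-sample interpolation.
goal_entrance_time <- function(time_s, position_cm, goal_cm = 10) {
  above <- position_cm > goal_cm
  cross <- which(above[-length(above)] & !above[-1L])
  if (!length(cross)) stop("no goal entrance within trial")
  i <- cross[1L]
  frac <- (position_cm[i] - goal_cm) / (position_cm[i] - position_cm[i + 1L])
  time_s[i] + frac * (time_s[i + 1L] - time_s[i])
}

#' Align a treadmill trial to its goal entrance and score its duration
#'
#' The entrance time is the first crossing of the goal-zone boundary (10 cm
#' from the front wall) after trial start; the trace is re-referenced so t = 0
#' at entrance, the sequence duration is entrance minus trial start, and the
#' trial is correct when the duration reaches the goal time.
#'
#' @param trial one element of a `treadmill_session` (list with `time_s`,
#'   `position_cm`, `belt_speed`, `trial_start`) or any list with those
#'   fields.
#' @param goal_cm goal-zone depth (cm).
#' @param goal_time_s required minimum duration (s).
#' @return list with `time_rel` (s, 0 at entrance), `position_cm`,
#'   `entrance_time` (s from trial start), `duration_s`, `correct`.
#' @export
align_and_duration <- function(trial, goal_cm = 10, goal_time_s = 7) {
  ent <- goal_entrance_time(trial$time_s, trial$position_cm, goal_cm)
  dur <- ent - trial$time_s[1L]  # invariant to shifts of the absolute clock
  list(time_rel = trial$time_s - ent, position_cm = trial$position_cm,
       belt_speed = trial$belt_speed, entrance_time = ent,
       duration_s = dur, correct = dur >= goal_time_s)
}

#' Segment a treadmill trial into transport, hold and acceleration phases
#'
#' Works on the smoothed ground-frame velocity (50 ms boxcar over centered
#' differences). The transport phase ends at the half-amplitude crossing of
#' the belt speed; the final acceleration starts where the velocity crosses a
#' small negative threshold, linearly extrapolated back to zero so the corner
#' of the triangular speed profile is recovered to within a sample or two;
#' the hold phase is what lies between (empty when the two boundaries meet).
#' Traces without a clean structure are scored best-effort and flagged.
#'
#' @param trial a trial list (`time_s`, `position_cm`, `belt_speed`).
#' @param goal_cm goal-zone depth (cm).
#' @param hold_tol absolute ground velocity below which the animal is
#'   considered holding (cm/s).
#' @param run_thresh velocity threshold (cm/s, magnitude) used to anchor the
#'   acceleration-onset extrapolation.
#' @return list with `transport`, `hold`, `run` spans (s from trial start;
#'   `hold` may be `NULL`), `entrance_time`, `min_rear_position` (the
#'   rear-most position reached, cm), `quality`.
#' @export
segment_phases <- function(trial, goal_cm = 10, hold_tol = 3, run_thresh = 4) {
  tt <- trial$time_s
  pos <- trial$position_cm
  fs <- 1 / grid_step(tt)
  v <- treadmill_velocity(pos, fs)
  ent <- goal_entrance_time(tt, pos, goal_cm)
  ent_i <- max(which(tt <= ent))
  quality <- "ok"

  # transport end: half-amplitude crossing of the belt speed
  vb <- trial$belt_speed
  below <- which(v[seq_len(ent_i)] <= vb / 2)
  below <- below[below > 2L]
  if (!length(below)) {
    t_transport_end <- tt[ent_i]
    quality <- "no-transport-end"
  } else {
    i <- below[1L]
    t_transport_end <- if (i > 1L && v[i - 1L] > vb / 2) {
      stats::approx(v[(i - 1L):i], tt[(i - 1L):i], xout = vb / 2)$y
    } else tt[i]
  }

  # acceleration onset: anchor at the fastest front-ward point, walk backward
  # to the -run_thresh crossing and extrapolate the speed ramp to v = 0 (so
  # noise spikes during the hold cannot trigger a false onset, and the
  # triangular profile's corner is recovered to within a sample or two)
  i_min <- which.min(v[seq_len(ent_i)])
  if (v[i_min] > -run_thresh) {
    t_run_start <- t_transport_end
    quality <- "no-run-onset"
  } else {
    j <- i_min
    while (j > 1L && v[j] < -run_thresh) j <- j - 1L
    slope_win <- j:min(j + 8L, i_min)
    slope <- if (length(slope_win) > 1L) {
      stats::coef(stats::lm(v[slope_win] ~ tt[slope_win]))[2]
    } else NA_real_
    t_run_start <- if (is.finite(slope) && slope < -1) tt[j] - v[j] / slope else tt[j]
    t_run_start <- min(max(t_run_start, t_transport_end), tt[ent_i])
  }

  hold <- if (t_run_start - t_transport_end > 1 / fs) {
    c(t_transport_end, t_run_start)
  } else NULL
  list(transport = c(tt[1L], t_transport_end),
       hold = hold,
       run = c(t_run_start, ent),
       entrance_time = ent,
       hold_duration = if (is.null(hold)) 0 else diff(hold),
       min_rear_position = max(pos[seq_len(ent_i)]),
       quality = quality)
}

#' Peak speed of the final acceleration
#'
#' Maximum ground-frame speed (|dposition/dt|, smoothed as in
#' [segment_phases()]) within the acceleration phase.
#'
#' @param trial a trial list.
#' @param phases optional precomputed [segment_phases()] result.
#' @param ... passed to [segment_phases()].
#' @return peak speed (cm/s).
#' @export
peak_speed <- function(trial, phases = NULL, ...) {
  if (is.null(phases)) phases <- segment_phases(trial, ...)
  if (is.null(phases$run)) stop("no acceleration phase found")
  tt <- trial$time_s
  fs <- 1 / grid_step(tt)
  v <- treadmill_velocity(trial$position_cm, fs)
  in_run <- tt >= phases$run[1L] & tt <= phases$run[2L]
  if (!any(in_run)) stop("no acceleration phase found")
  max(abs(v[in_run]))
}

#' Trajectory differences against the central-speed template
#'
#' Median entrance-aligned position trajectory per belt speed minus the
#' median trajectory at the reference speed, on a common time grid, summarised
#' by the mean absolute difference.
#'
#' @param trials list of treadmill trials.
#' @param reference_belt_speed template belt speed (cm/s).
#' @param window time window relative to entrance (s).
#' @param step grid step (s).
#' @param goal_cm goal-zone depth (cm).
#' @return list with `grid` (time, s), `median_by_speed` (matrix, one column
#'   per belt speed), `difference` (same minus reference column) and a
#'   `summary` data.frame (`belt_speed`, `n_trials`, `mean_abs_diff_cm`).
#' @export
trajectory_difference <- function(trials, reference_belt_speed = 30,
                                  window = c(-6.5, -0.1), step = 0.01,
                                  goal_cm = 10) {
  speeds <- vapply(trials, function(x) x$belt_speed, numeric(1))
  if (sum(speeds == reference_belt_speed) < 3L) {
    stop("need at least 3 trials at the reference belt speed")
  }
  grid <- seq(window[1], window[2], by = step)
  aligned <- lapply(trials, function(tr) {
    a <- align_and_duration(tr, goal_cm = goal_cm)
    stats::approx(a$time_rel, a$position_cm, xout = grid, rule = 1)$y
  })
  mat <- do.call(cbind, aligned)
  u_speeds <- sort(unique(speeds))
  med <- vapply(u_speeds, function(s) {
    apply(mat[, speeds == s, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  }, numeric(length(grid)))
  colnames(med) <- u_speeds
  ref <- med[, as.character(reference_belt_speed)]
  diffm <- med - ref
  list(grid = grid, median_by_speed = med, difference = diffm,
       summary = data.frame(
         belt_speed = u_speeds,
         n_trials = as.integer(table(factor(speeds, levels = u_speeds))),
         mean_abs_diff_cm = colMeans(abs(diffm), na.rm = TRUE)))
}

#' Control reference statistics for strategy classification
#'
#' Summarises control (dose 0) trials: the 5th percentiles and dispersion of
#' the hold duration and of the rear-most position reached, against which
#' compensatory strategies are scored.
#'
#' @param trials list of control treadmill trials.
#' @param ... passed to [segment_phases()].
#' @return list of reference statistics.
#' @export
control_reference <- function(trials, ...) {
  segs <- lapply(trials, segment_phases, ...)
  hold <- vapply(segs, `[[`, numeric(1), "hold_duration")
  rear <- vapply(segs, `[[`, numeric(1), "min_rear_position")
  list(hold_q05 = stats::quantile(hold, 0.05, names = FALSE),
       rear_q05 = stats::quantile(rear, 0.05, names = FALSE),
       hold_mean = mean(hold), hold_sd = max(stats::sd(hold), 1e-6),
       rear_mean = mean(rear), rear_sd = max(stats::sd(rear), 1e-6),
       n = length(trials))
}

#' Classify the compensatory strategy of a treadmill trial
#'
#' `shortened_hold` when the hold duration falls below the control 5th
#' percentile; `partial_transport` when the rear-most position reached falls
#' below the control 5th percentile; when both criteria fire, the label with
#' the larger deviation in control-referenced z-units wins; otherwise
#' `normal`.
#'
#' @param trial a trial list.
#' @param reference a [control_reference()] result.
#' @param phases optional precomputed segmentation.
#' @param ... passed to [segment_phases()].
#' @return one of `"normal"`, `"shortened_hold"`, `"partial_transport"`.
#' @export
classify_strategy <- function(trial, reference, phases = NULL, ...) {
  if (missing(reference) || is.null(reference)) stop("control reference required")
  if (is.null(phases)) phases <- segment_phases(trial, ...)
  short_hold <- phases$hold_duration < reference$hold_q05
  partial <- phases$min_rear_position < reference$rear_q05
  if (short_hold && partial) {
    z_hold <- (reference$hold_mean - phases$hold_duration) / reference$hold_sd
    z_rear <- (reference$rear_mean - phases$min_rear_position) / reference$rear_sd
    if (z_hold >= z_rear) "shortened_hold" else "partial_transport"
  } else if (short_hold) {
    "shortened_hold"
  } else if (partial) {
    "partial_transport"
  } else {
    "normal"
  }
}

#' Score every trial of a treadmill session
#'
#' Convenience wrapper: durations, correctness, phases, peak speeds, rear
#' reach and (when a control reference is given) strategy labels.
#'
#' @param session a `treadmill_session`.
#' @param reference optional [control_reference()] result.
#' @param ... passed to [segment_phases()].
#' @return a data.frame with one row per trial.
#' @export
score_treadmill_session <- function(session, reference = NULL, ...) {
  stopifnot(inherits(session, "treadmill_session"))
  rows <- lapply(seq_along(session$trials), function(k) {
    tr <- session$trials[[k]]
    al <- align_and_duration(tr, goal_time_s = session$config$treadmill$goal_time_s)
    ph <- segment_phases(tr, ...)
    data.frame(
      trial_index = k, belt_speed = tr$belt_speed,
      duration_s = al$duration_s, correct = al$correct,
      peak_speed_cm_s = peak_speed(tr, phases = ph),
      hold_duration_s = ph$hold_duration,
      min_rear_position_cm = ph$min_rear_position,
      quality = ph$quality,
      strategy = if (is.null(reference)) NA_character_
                 else classify_strategy(tr, reference, phases = ph))
  })
  do.call(rbind, rows)
}
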