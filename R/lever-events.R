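# Event detection: press segmentation, bilateral pairing, reward schedules.

#' Convert a transducer voltage to lever displacement
#'
#' The levers are read through a linear voltage transducer calibrated so that
#' 3.5 cm of displacement corresponds to 2.5 V.
#'
#' @param v voltage reading(s), in volts; must be non-negative.
#' @return displacement in cm (`v * 3.5 / 2.5`).
#' @examples
#' voltage_to_position(2.5)  # 3.5 cm
#' @export
voltage_to_position <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("negative voltage input")
  v * (3.5 / 2.5)
}

#' Detect press events on a single lever trace
#'
#' A press starts at the upward crossing of `touch_threshold` and ends at the
#' first sample back below `touch_threshold - hysteresis` (the hysteresis
#' suppresses transducer chatter at 250 samples/s). Within each press the
#' longest contiguous span at or above `spatial_threshold` is recorded; presses
#' that never reach it have an `NA` span. Event times are sample times; spans
#' are half-open `[onset, offset)`.
#'
#' @param time_s uniform sample-time grid (s).
#' @param position_cm lever displacement (cm).
#' @param touch_threshold press-detection threshold (cm); displacements above
#'   0.1 cm count as lever touches.
#' @param spatial_threshold full-press displacement criterion (cm), 2.6 cm in
#'   the trained task.
#' @param hysteresis release hysteresis below `touch_threshold` (cm).
#' @return a data.frame of press events: `onset_time`, `offset_time`,
#'   `peak_displacement`, `spatial_start`, `spatial_end`, `duration_above`.
#' @export
detect_presses <- function(time_s, position_cm, touch_threshold = 0.1,
                           spatial_threshold = 2.6, hysteresis = 0.02) {
  dt <- grid_step(time_s)
  stopifnot(length(position_cm) == length(time_s))
  above <- position_cm >= touch_threshold
  below_end <- position_cm < (touch_threshold - hysteresis)
  starts <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(starts)) {
    return(data.frame(onset_time = numeric(0), offset_time = numeric(0),
                      peak_displacement = numeric(0), spatial_start = numeric(0),
                      spatial_end = numeric(0), duration_above = numeric(0)))
  }
  end_idx <- which(below_end)
  out <- vector("list", length(starts))
  n_ev <- 0L
  cur_end <- 0L
  for (s in starts) {
    if (s <= cur_end) next  # chatter re-entry within the hysteresis band
    pos_after <- end_idx[end_idx > s]
    e <- if (length(pos_after)) pos_after[1] else length(position_cm) + 1L
    cur_end <- e
    seg <- position_cm[s:min(e - 1L, length(position_cm))]
    sp <- longest_run_at_or_above(seg, spatial_threshold)
    n_ev <- n_ev + 1L
    out[[n_ev]] <- data.frame(
      onset_time = time_s[s],
      offset_time = if (e <= length(time_s)) time_s[e] else time_s[length(time_s)] + dt,
      peak_displacement = max(seg),
      spatial_start = if (is.null(sp)) NA_real_ else time_s[s + sp[1] - 1L],
      spatial_end = if (is.null(sp)) NA_real_ else time_s[s + sp[2] - 1L] + dt,
      duration_above = if (is.null(sp)) NA_real_ else (sp[2] - sp[1] + 1L) * dt)
  }
  do.call(rbind, out[seq_len(n_ev)])
}

# Indices (start, end) of the longest contiguous run of x >= threshold.
longest_run_at_or_above <- function(x, threshold) {
  r <- rle(x >= threshold)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  best <- i[which.max(r$lengths[i])]
  c(starts[best], ends[best])
}

#' Pair left and right presses into bilateral attempts
#'
#' Attempts are formed from temporally overlapping left/right above-spatial
#' spans: the joint onset is the first instant both levers are at or above the
#' spatial threshold and `duration_above` is the length of the overlap.
#' Presses that never reach the spatial threshold, or whose spans do not
#' overlap, yield no attempt.
#'
#' @param left,right press-event data.frames from [detect_presses()],
#'   time-sorted.
#' @return a data.frame of attempts: `left_onset`, `right_onset` (press
#'   onsets), `joint_onset`, `joint_end`, `duration_above`.
#' @export
pair_bilateral <- function(left, right) {
  l <- left[!is.na(left$spatial_start), , drop = FALSE]
  r <- right[!is.na(right$spatial_start), , drop = FALSE]
  empty <- data.frame(left_onset = numeric(0), right_onset = numeric(0),
                      joint_onset = numeric(0), joint_end = numeric(0),
                      duration_above = numeric(0))
  if (!nrow(l) || !nrow(r)) return(empty)
  if (is.unsorted(l$spatial_start) || is.unsorted(r$spatial_start)) {
    stop("press events must be time-sorted")
  }
  out <- list()
  j <- 1L
  for (i in seq_len(nrow(l))) {
    while (j <= nrow(r) && r$spatial_end[j] <= l$spatial_start[i]) j <- j + 1L
    jj <- j
    while (jj <= nrow(r) && r$spatial_start[jj] < l$spatial_end[i]) {
      on <- max(l$spatial_start[i], r$spatial_start[jj])
      off <- min(l$spatial_end[i], r$spatial_end[jj])
      if (off > on) {
        out[[length(out) + 1L]] <- data.frame(
          left_onset = l$onset_time[i], right_onset = r$onset_time[jj],
          joint_onset = on, joint_end = off, duration_above = off - on)
      }
      jj <- jj + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Resolve a fixed-interval schedule over bilateral attempts
#'
#' The reward gate opens `interval_s` after the previous reward (and at
#' session start). The first attempt whose joint onset falls while the gate is
#' open and whose joint hold lasts at least `hold_s` is rewarded at
#' `joint_onset + hold_s`; the counter then resets. Attempts while the gate is
#' closed, and under-threshold holds, are logged as unrewarded.
#'
#' @param attempts attempt data.frame from [pair_bilateral()], time-sorted.
#' @param interval_s fixed interval (s).
#' @param hold_s required joint hold (s).
#' @param session_start time of the first gate opening (s).
#' @return a list with `attempts` (input plus `success`, `trial` and
#'   `reward_time` columns) and `trials` (one row per reward: `trial_index`,
#'   `required_interval_ms`, `n_attempts`, `reward_time`, `overshoot_ms`,
#'   `onset_lag_abs_s`).
#' @export
apply_fixed_interval <- function(attempts, interval_s = 30, hold_s = 0.75,
                                 session_start = 0) {
  att <- attempts[order(attempts$joint_onset), , drop = FALSE]
  att$success <- FALSE
  att$trial <- NA_integer_
  att$reward_time <- NA_real_
  gate <- session_start
  trial <- 0L
  n_att <- 0L
  trials <- list()
  for (i in seq_len(nrow(att))) {
    n_att <- n_att + 1L
    if (att$joint_onset[i] >= gate && att$duration_above[i] >= hold_s) {
      trial <- trial + 1L
      reward <- att$joint_onset[i] + hold_s
      att$success[i] <- TRUE
      att$reward_time[i] <- reward
      att$trial[i] <- trial
      trials[[trial]] <- data.frame(
        trial_index = trial, required_interval_ms = hold_s * 1000,
        n_attempts = n_att, reward_time = reward,
        overshoot_ms = (att$joint_end[i] - reward) * 1000,
        onset_lag_abs_s = abs(att$left_onset[i] - att$right_onset[i]))
      gate <- reward + interval_s
      n_att <- 0L
    }
  }
  list(attempts = att,
       trials = if (length(trials)) do.call(rbind, trials) else NULL)
}

#' Resolve the alternating-block two-interval schedule
#'
#' Trials alternate in blocks of `block_len` rewarded trials between the two
#' hold thresholds, starting with the longest. An attempt whose joint hold
#' meets the current threshold closes the trial (reward at
#' `joint_onset + threshold`); shorter attempts accumulate in `n_attempts`.
#' The threshold applies to the joint above-spatial duration, not the press
#' duration.
#'
#' @inheritParams apply_fixed_interval
#' @param block_len rewarded trials per block.
#' @param thresholds_ms the two required intervals (ms), longest first.
#' @return as [apply_fixed_interval()], with `block_id` per trial.
#' @export
apply_block_schedule <- function(attempts, block_len = 20,
                                 thresholds_ms = c(1250, 750)) {
  att <- attempts[order(attempts$joint_onset), , drop = FALSE]
  att$success <- FALSE
  att$trial <- NA_integer_
  att$reward_time <- NA_real_
  trial <- 0L
  n_att <- 0L
  trials <- list()
  for (i in seq_len(nrow(att))) {
    block_id <- trial %/% block_len + 1L
    required <- thresholds_ms[(block_id - 1L) %% 2L + 1L] / 1000
    n_att <- n_att + 1L
    if (att$duration_above[i] >= required) {
      trial <- trial + 1L
      reward <- att$joint_onset[i] + required
      att$success[i] <- TRUE
      att$reward_time[i] <- reward
      att$trial[i] <- trial
      trials[[trial]] <- data.frame(
        trial_index = trial, block_id = block_id,
        required_interval_ms = required * 1000, n_attempts = n_att,
        reward_time = reward,
        overshoot_ms = (att$joint_end[i] - reward) * 1000,
        onset_lag_abs_s = abs(att$left_onset[i] - att$right_onset[i]))
      n_att <- 0L
    }
  }
  list(attempts = att,
       trials = if (length(trials)) do.call(rbind, trials) else NULL)
}

#' Detect events and resolve trials for a lever session
#'
#' Full per-session pipeline: detect presses on both levers, pair them into
#' bilateral attempts, resolve the session's schedule, and attach trace-based
#' per-trial metrics (interlimb correlation over the successful movement,
#' maximum lever speed within the rewarded press, effort, session-time
#' fraction).
#'
#' @param session a `lever_session` (simulated or read from disk).
#' @param touch_threshold,spatial_threshold,hysteresis see [detect_presses()].
#' @return a list with `presses` (per lever), `attempts`, and `trials` (a
#'   trial-record data.frame with metric columns).
#' @export
analyze_lever_session <- function(session, touch_threshold = 0.1,
                                  spatial_threshold = 2.6, hysteresis = 0.02) {
  stopifnot(inherits(session, "lever_session"))
  lp <- detect_presses(session$time, session$left_pos, touch_threshold,
                       spatial_threshold, hysteresis)
  rp <- detect_presses(session$time, session$right_pos, touch_threshold,
                       spatial_threshold, hysteresis)
  att <- pair_bilateral(lp, rp)
  res <- if (identical(session$schedule, "fixed_interval")) {
    apply_fixed_interval(att)
  } else {
    apply_block_schedule(att)
  }
  trials <- res$trials
  if (!is.null(trials) && nrow(trials)) {
    dt <- 1 / session$fs
    succ <- res$attempts[res$attempts$success, , drop = FALSE]
    succ <- succ[order(succ$trial), , drop = FALSE]
    prev_reward <- c(0, trials$reward_time[-nrow(trials)])
    trials$interlimb_r <- NA_real_
    trials$max_speed_cm_s <- NA_real_
    trials$effort_s <- NA_real_
    for (k in seq_len(nrow(trials))) {
      i0 <- floor(succ$joint_onset[k] / dt) + 1L
      i1 <- floor(succ$reward_time[k] / dt) + 1L
      if (i1 - i0 >= 2L) {
        trials$interlimb_r[k] <- interlimb_correlation(
          session$left_pos[i0:i1], session$right_pos[i0:i1])
      }
      p0 <- floor(min(succ$left_onset[k], succ$right_onset[k]) / dt) + 1L
      p1 <- min(floor(succ$joint_end[k] / dt) + 40L, length(session$left_pos))
      sp <- movement_speed(session$left_pos[p0:p1], fs = session$fs)
      trials$max_speed_cm_s[k] <- sp$max_speed
      in_win_l <- lp$onset_time > prev_reward[k] & lp$onset_time <= trials$reward_time[k]
      in_win_r <- rp$onset_time > prev_reward[k] & rp$onset_time <= trials$reward_time[k]
      trials$effort_s[k] <- 0.5 *
        (sum(lp$offset_time[in_win_l] - lp$onset_time[in_win_l]) +
           sum(rp$offset_time[in_win_r] - rp$onset_time[in_win_r]))
    }
    trials$session_time_fraction <- trials$reward_time / max(session$time)
  }
  list(presses = list(left = lp, right = rp), attempts = res$attempts,
       trials = trials)
}
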