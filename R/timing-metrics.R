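# Per-trial and per-session timing/kinematic metrics for the lever tasks.

#' Overshoot of a rewarded hold
#'
#' Time the levers remained pressed after the reward: joint release (first
#' instant either lever drops below the spatial threshold) minus reward time.
#'
#' @param release_s joint release time(s), s.
#' @param reward_s reward time(s), s; `NA` marks an unrewarded trial.
#' @return overshoot in ms.
#' @export
overshoot <- function(release_s, reward_s) {
  if (any(is.na(reward_s))) stop("overshoot is undefined for unrewarded trials")
  (release_s - reward_s) * 1000
}

#' Overshoot fraction
#'
#' The magnitude of the overshoot relative to the required interval: an
#' overshoot of 150 ms is a fraction of 0.2 against the 750 ms interval but
#' 0.12 against the 1250 ms interval.
#'
#' @param overshoot_ms overshoot (ms), non-negative.
#' @param required_ms required hold interval (ms), positive.
#' @return the dimensionless ratio `overshoot_ms / required_ms`.
#' @examples
#' overshoot_fraction(150, 750)   # 0.2
#' overshoot_fraction(150, 1250)  # 0.12
#' @export
overshoot_fraction <- function(overshoot_ms, required_ms) {
  if (any(required_ms <= 0)) stop("required_ms must be positive")
  if (any(overshoot_ms < 0, na.rm = TRUE)) stop("negative overshoot rejected")
  overshoot_ms / required_ms
}

#' Interlimb correlation
#'
#' Pearson correlation between the left and right lever positions from the
#' beginning of the successful bilateral movement to reward delivery. A
#' zero-variance trace makes the coefficient undefined; it is reported as
#' `NA` (missing), never as 0.
#'
#' @param left,right position series restricted to the movement window
#'   (at least 3 samples).
#' @return Pearson r, or `NA` if undefined.
#' @export
interlimb_correlation <- function(left, right) {
  stopifnot(length(left) == length(right))
  if (length(left) < 3L) stop("window must contain at least 3 samples")
  if (stats::sd(left) == 0 || stats::sd(right) == 0) return(NA_real_)
  sum((left - mean(left)) * (right - mean(right))) /
    ((length(left) - 1) * stats::sd(left) * stats::sd(right))
}

#' Bilateral movement onset variability (BMOV)
#'
#' Variance across trials of the absolute difference between the two
#' forepaws' movement-onset times. Reported in s-squared; its square root is
#' the same quantity on the seconds scale.
#'
#' @param onset_lag_abs_s per-trial absolute onset lags (s), or a trial-record
#'   data.frame with an `onset_lag_abs_s` column. At least 2 trials.
#' @return sample variance (s^2).
#' @export
bmov <- function(onset_lag_abs_s) {
  if (is.data.frame(onset_lag_abs_s)) onset_lag_abs_s <- onset_lag_abs_s$onset_lag_abs_s
  if (length(onset_lag_abs_s) < 2L) stop("bmov needs at least 2 trials")
  stats::var(onset_lag_abs_s)
}

#' Instantaneous movement speed of a lever trace
#'
#' Absolute position difference in consecutive 4 ms bins, in cm/s, and its
#' maximum over the press.
#'
#' @param position_cm position series on the 250 samples/s grid.
#' @param fs sampling rate (Hz).
#' @return a list with `speed` (length `n - 1`) and `max_speed`.
#' @export
movement_speed <- function(position_cm, fs = 250) {
  if (length(position_cm) < 2L) stop("trace shorter than 2 samples")
  speed <- abs(diff(position_cm)) * fs
  list(speed = speed, max_speed = max(speed))
}

#' Across-trial trajectory variability
#'
#' Trials are aligned to the movement onset, resampled to a common length,
#' and the across-trial interquartile range of position is averaged over time
#' points. Invariant to any offset common to all trials.
#'
#' @param traces list of single-lever position vectors (one per trial),
#'   aligned to joint onset. At least 3 trials.
#' @param n_points common resampling length.
#' @return mean over time points of the across-trial IQR (cm).
#' @export
trajectory_variability <- function(traces, n_points = 100L) {
  if (length(traces) < 3L) stop("trajectory variability needs at least 3 trials")
  mat <- vapply(traces, function(x) {
    if (length(x) == n_points) return(as.numeric(x))
    stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_points))$y
  }, numeric(n_points))
  iqr_t <- apply(mat, 1L, function(row) diff(stats::quantile(row, c(0.25, 0.75), names = FALSE)))
  mean(iqr_t)
}

#' Session efficiency metrics
#'
#' Task-engagement summaries: time to the first `first_n` rewards, total
#' rewarded trials, mean accumulated press time (effort) per reward, and mean
#' attempts per reward. Analyses of the two-interval task conventionally use
#' the first 100 trials of each session, where engagement is consistent.
#'
#' @param trials trial-record data.frame (may be `NULL` or empty).
#' @param first_n number of trials defining the engagement window.
#' @return list with `time_to_first_n_s` (`NA` when fewer than `first_n`
#'   trials), `trials_per_session`, `effort_per_reward_s`,
#'   `attempts_per_reward`.
#' @export
efficiency_metrics <- function(trials, first_n = 100L) {
  if (is.null(trials) || !nrow(trials)) {
    return(list(time_to_first_n_s = NA_real_, trials_per_session = 0L,
                effort_per_reward_s = NA_real_, attempts_per_reward = NA_real_))
  }
  list(
    time_to_first_n_s = if (nrow(trials) >= first_n) trials$reward_time[first_n] else NA_real_,
    trials_per_session = nrow(trials),
    effort_per_reward_s = if ("effort_s" %in% names(trials)) mean(trials$effort_s) else NA_real_,
    attempts_per_reward = mean(trials$n_attempts))
}

#' Peri-reward press histogram
#'
#' Press onsets re-referenced to every reward and binned over the window,
#' normalised to presses per trial per bin.
#'
#' @param press_onsets press-onset times (s), any lever convention.
#' @param reward_times reward onset times (s); at least one.
#' @param window histogram window relative to reward (s).
#' @param binwidth bin width (s).
#' @return an object of class `peri_reward_histogram`: `bin_left`,
#'   `bin_right`, `bin_center`, `count`, `rate` (presses/trial/bin),
#'   `n_trials`, `binwidth`.
#' @export
peri_reward_histogram <- function(press_onsets, reward_times,
                                  window = c(-30, 5), binwidth = 1) {
  if (!length(reward_times)) stop("at least one reward is required")
  edges <- seq(window[1], window[2], by = binwidth)
  rel <- as.vector(outer(press_onsets, reward_times, "-"))
  rel <- rel[rel >= window[1] & rel < window[2]]
  counts <- if (length(rel)) {
    tabulate(findInterval(rel, edges), nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  structure(list(
    bin_left = edges[-length(edges)], bin_right = edges[-1L],
    bin_center = (edges[-length(edges)] + edges[-1L]) / 2,
    count = counts, rate = counts / (length(reward_times) * binwidth),
    n_trials = length(reward_times), binwidth = binwidth,
    smoothing = "none"), class = "peri_reward_histogram")
}

#' @export
print.peri_reward_histogram <- function(x, ...) {
  cat("<peri_reward_histogram>", length(x$count), "bins of", x$binwidth,
      "s over [", x$bin_left[1], ",", x$bin_right[length(x$bin_right)],
      "] s,", x$n_trials, "trials\n")
  invisible(x)
}

#' Area under the peri-reward rate curve
#'
#' Integral of the press-rate curve (presses/trial/bin, treated as a step
#' function over the bins) across the pre-reward window `[-30, 0]` s. Higher
#' values indicate pressing spread across the interval rather than
#' concentrated at the reward.
#'
#' @param hist a [peri_reward_histogram()].
#' @param pre_window integration window (s).
#' @return the area (presses/trial).
#' @export
histogram_auc <- function(hist, pre_window = c(-30, 0)) {
  stopifnot(inherits(hist, "peri_reward_histogram"))
  pre <- hist$bin_left >= pre_window[1] & hist$bin_right <= pre_window[2]
  sum(hist$rate[pre] * hist$binwidth)
}

#' Peak interval from a peri-reward histogram
#'
#' Locates the maximum of the 3-bin moving-average-smoothed rate curve within
#' the pre-reward window and expresses it as time since the previous reward,
#' i.e. `interval_s + t_rel` for the peak's bin centre `t_rel`. Smoothed ties
#' (a single-bin spike ties with its neighbours under the moving average) are
#' broken by the raw rate, then toward the earliest bin.
#'
#' @param hist a [peri_reward_histogram()].
#' @param interval_s the schedule's fixed interval (s).
#' @return the peak interval (s).
#' @export
peak_interval <- function(hist, interval_s = 30) {
  stopifnot(inherits(hist, "peri_reward_histogram"))
  if (all(hist$count == 0)) stop("all-zero histogram has no peak")
  sm <- box_smooth(hist$rate, 3L)
  pre <- which(hist$bin_center < 0)
  # ties on the smoothed curve (a lone spike ties with its neighbours) are
  # broken by the raw rate, then toward the earliest bin
  cand <- pre[sm[pre] >= max(sm[pre]) - 1e-12]
  i <- cand[which.max(hist$rate[cand])]
  interval_s + hist$bin_center[i]
}

#' Split trials for robustness analyses
#'
#' Disjoint labeled trial subsets used to re-check dose effects within
#' sessions: session halves (an odd trial goes to the second half), the first
#' versus last 100 trials, or the first versus last 10 trials of each block.
#'
#' @param trials trial-record data.frame.
#' @param scheme one of `"halves"`, `"first_last_100"`, `"block_edges_10"`.
#' @param block_len trials per block for `"block_edges_10"`.
#' @param edge_n trials per side for the 100-trial and block-edge schemes.
#' @return a named list of data.frames.
#' @export
split_trials <- function(trials, scheme = c("halves", "first_last_100", "block_edges_10"),
                         block_len = 20L, edge_n = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(trials)
  switch(scheme,
    halves = {
      if (n < 2L) stop("halves split needs at least 2 trials")
      h <- n %/% 2L
      list(first_half = trials[seq_len(h), , drop = FALSE],
           second_half = trials[(h + 1L):n, , drop = FALSE])
    },
    first_last_100 = {
      k <- edge_n %||% 100L
      if (n < 2L * k) stop("first/last split needs at least ", 2L * k, " trials")
      list(first = trials[seq_len(k), , drop = FALSE],
           last = trials[(n - k + 1L):n, , drop = FALSE])
    },
    block_edges_10 = {
      k <- edge_n %||% 10L
      if (!"block_id" %in% names(trials)) stop("block_edges split needs block_id")
      if (any(table(trials$block_id) < 2L * k)) {
        stop("every block needs at least ", 2L * k, " trials for the edge split")
      }
      first <- do.call(rbind, lapply(split(trials, trials$block_id),
                                     function(b) b[seq_len(k), , drop = FALSE]))
      last <- do.call(rbind, lapply(split(trials, trials$block_id),
                                    function(b) b[(nrow(b) - k + 1L):nrow(b), , drop = FALSE]))
      rownames(first) <- rownames(last) <- NULL
      list(block_first = first, block_last = last)
    })
}

#' Aggregate trial metrics as median with quartiles
#'
#' Behavioural metrics are summarised as a median with 25th/75th percentiles;
#' undefined values (e.g. correlations on zero-variance windows) are excluded,
#' never imputed.
#'
#' @param trials trial-record data.frame.
#' @param metrics metric column names to aggregate.
#' @return a tidy data.frame: `metric`, `n`, `median`, `q25`, `q75`.
#' @export
aggregate_trial_metrics <- function(trials,
                                    metrics = intersect(
                                      c("overshoot_ms", "overshoot_fraction",
                                        "interlimb_r", "onset_lag_abs_s",
                                        "max_speed_cm_s", "effort_s", "n_attempts"),
                                      names(trials))) {
  do.call(rbind, lapply(metrics, function(mname) {
    x <- trials[[mname]]
    x <- x[!is.na(x)]
    q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(metric = mname, n = length(x), median = q[2], q25 = q[1], q75 = q[3])
  }))
}
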