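# End-to-end orchestration: simulate (or ingest) -> detect -> metrics ->
# statistics -> report, plus on-disk session bundles and run manifests.

# Deterministic polynomial hash (mod 2^31 - 1) of an R object's deparsed form.
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Left-lever press onsets of a session from generator ground truth, optionally
# excluding the schedule-triggering (rewarded) press of each trial, which is
# present by construction and carries no timing information.
session_press_onsets <- function(session, exclude_rewarded = TRUE) {
  gt <- session$ground_truth
  onsets <- gt$press_onsets$left
  if (!exclude_rewarded) return(onsets)
  att <- gt$attempts[gt$attempts$success, , drop = FALSE]
  v <- gt$params$lever_speed %||% 26
  excl <- att$joint_spatial_onset - 2.6 / v - pmax(0, -att$lag)
  for (e in excl) {
    i <- which.min(abs(onsets - e))
    if (length(i) && abs(onsets[i] - e) < 0.05) onsets <- onsets[-i]
  }
  onsets
}

#' Recover the peak interval of a dose condition
#'
#' Pools press onsets and rewards across fixed-interval sessions of one
#' condition, builds the peri-reward histogram (excluding each trial's
#' schedule-triggering press), and returns its [peak_interval()].
#'
#' @param sessions list of fixed-interval `lever_session`s.
#' @param ... passed to [peri_reward_histogram()].
#' @return peak interval (s).
#' @export
recover_peak_interval <- function(sessions, ...) {
  hs <- pooled_histogram(sessions, ...)
  peak_interval(hs)
}

#' @rdname recover_peak_interval
#' @export
pooled_histogram <- function(sessions, ...) {
  onsets <- list()
  rewards <- list()
  t0 <- 0
  for (s in sessions) {
    onsets[[length(onsets) + 1L]] <- session_press_onsets(s) + t0
    rewards[[length(rewards) + 1L]] <- s$reward_times + t0
    t0 <- t0 + max(s$time) + 100
  }
  peri_reward_histogram(unlist(onsets), unlist(rewards), ...)
}

#' Classify the generative production mode from overshoot fractions
#'
#' The headline dissociation logic: a motor-slowing lengthening adds the same
#' number of milliseconds to both required intervals, so the overshoot-fraction
#' increments (dose minus control) differ between the short and long interval
#' by the interval ratio (1250/750); a timing-scaling lengthening multiplies
#' both intervals equally, so the increments match. The discriminator pools
#' the increments over all non-control doses and thresholds the
#' short-over-long ratio at the geometric midpoint of the two predictions.
#'
#' @param trials trial records with `dose`, `required_interval_ms` and
#'   `overshoot_ms` columns, covering control and at least one other dose.
#' @param control_dose the control label.
#' @return list with `ratio`, `threshold`, `mode` (`"motor_slowing"` or
#'   `"timing_scaling"`), `evidence` (log-ratio distance from the threshold)
#'   and the per-dose increment `table`.
#' @export
classify_production_mode <- function(trials, control_dose = 0) {
  stopifnot(all(c("dose", "required_interval_ms", "overshoot_ms") %in% names(trials)))
  ints <- sort(unique(trials$required_interval_ms))
  if (length(ints) != 2L) stop("need exactly two required intervals")
  frac <- trials$overshoot_ms / trials$required_interval_ms
  cell <- aggregate(frac, list(dose = trials$dose, required = trials$required_interval_ms), mean)
  ctrl <- cell[cell$dose == control_dose, ]
  if (!nrow(ctrl)) stop("no control-dose trials")
  dosed <- cell[cell$dose != control_dose, ]
  dosed$inc <- dosed$x - ctrl$x[match(dosed$required, ctrl$required)]
  inc_short <- sum(dosed$inc[dosed$required == ints[1]])
  inc_long <- sum(dosed$inc[dosed$required == ints[2]])
  expected <- ints[2] / ints[1]         # e.g. 1250/750
  threshold <- sqrt(expected)           # geometric midpoint of 1 and the ratio
  ratio <- if (inc_long > 0) inc_short / inc_long else if (inc_short > 0) Inf else NA_real_
  mode <- if (is.na(ratio)) "indeterminate"
          else if (ratio > threshold) "motor_slowing" else "timing_scaling"
  list(ratio = ratio, threshold = threshold, mode = mode,
       evidence = if (is.na(ratio) || ratio <= 0) NA_real_ else log(ratio) - log(threshold),
       table = dosed[, c("dose", "required", "inc")])
}

#' Recover the planned hold margin from attempt records
#'
#' The planned margin is the median excess of produced holds over the
#' required interval, across all attempts (failed attempts are uncensored
#' draws of the same production process, so including them removes the
#' truncation bias of rewarded-only overshoots). Excesses at or above the
#' reaction-time threshold are excluded: those releases are reactions to the
#' reward, not planned margins.
#'
#' @param attempts attempt table from [simulate_two_interval_trials()] or an
#'   equivalent with `hold` (s) and `required_ms` columns.
#' @param reaction_threshold_ms cutoff separating planned margins from
#'   reactive releases (ms).
#' @return recovered margin (ms).
#' @export
recover_planned_margin <- function(attempts, reaction_threshold_ms = 300) {
  exc <- (attempts$hold - attempts$required_ms / 1000) * 1000
  exc <- exc[exc < reaction_threshold_ms]
  if (!length(exc)) return(NA_real_)
  stats::median(exc)
}

# Kruskal-Wallis across doses on a metric column of a pooled trial table.
kw_by_dose <- function(trials, metric) {
  x <- trials[[metric]]
  keep <- !is.na(x)
  groups <- split(x[keep], trials$dose[keep])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) return(NULL)
  kruskal_wallis(groups)
}

#' Run a full simulated experiment
#'
#' Orchestrates the whole pipeline on simulated cohorts: for each dose,
#' generate `n_sessions` sessions per task, run press detection and trial
#' resolution on the rendered traces (lever tasks) or trajectory scoring
#' (treadmill), aggregate the metrics, and run the rank-based statistics
#' (Kruskal-Wallis across doses; Scheirer-Ray-Hare for dose x interval in the
#' two-interval task; rank LSD post hocs), plus the production-mode
#' discriminator. All randomness derives from `seed` through per-session
#' streams, so a run is fully reproducible from its manifest.
#'
#' @param config a [gen_config()].
#' @param seed master seed (defaults to the config's).
#' @param tasks subset of `c("fixed_interval", "two_interval", "treadmill")`.
#' @param out_dir optional directory; when given, tidy CSV tables, the run
#'   manifest (YAML) and a plain-text summary are written there.
#' @return a list with per-task results, `stats`, `discrimination` and
#'   `manifest`, invisibly when `out_dir` is given.
#' @export
run_experiment <- function(config, seed = config$seed,
                           tasks = c("fixed_interval", "two_interval", "treadmill"),
                           out_dir = NULL) {
  stopifnot(inherits(config, "gen_config"))
  tasks <- match.arg(tasks, several.ok = TRUE)
  t_start <- Sys.time()
  doses <- config$dose_levels
  res <- list(config = config)
  counts <- list()

  if ("fixed_interval" %in% tasks) {
    per_dose <- list()
    ctr <- 0L
    for (d in doses) {
      sess <- lapply(seq_len(config$n_sessions), function(i) {
        simulate_fixed_interval_session(config, d, derive_seed(seed, ctr + i))
      })
      ctr <- ctr + config$n_sessions
      h <- pooled_histogram(sess)
      per_session <- do.call(rbind, lapply(sess, function(s) {
        hs <- pooled_histogram(list(s))
        data.frame(dose = d, auc = histogram_auc(hs),
                   peak_interval_s = peak_interval(hs),
                   median_overshoot_ms = stats::median(s$ground_truth$trials$overshoot_ms),
                   n_trials = nrow(s$ground_truth$trials))
      }))
      per_dose[[as.character(d)]] <- list(
        sessions = per_session, pooled_peak = peak_interval(h),
        pooled_auc = histogram_auc(h))
    }
    fi_sessions <- do.call(rbind, lapply(per_dose, `[[`, "sessions"))
    rownames(fi_sessions) <- NULL
    res$fixed_interval <- list(
      session_table = fi_sessions,
      dose_table = data.frame(
        dose = doses,
        peak_interval_s = vapply(per_dose, `[[`, numeric(1), "pooled_peak"),
        auc = vapply(per_dose, `[[`, numeric(1), "pooled_auc")),
      kw_auc = kw_by_dose(fi_sessions, "auc"),
      kw_peak = kw_by_dose(fi_sessions, "peak_interval_s"))
    counts$fixed_interval_sessions <- nrow(fi_sessions)
  }

  if ("two_interval" %in% tasks) {
    all_trials <- list()
    ctr <- 1000L
    for (d in doses) {
      for (i in seq_len(config$n_sessions)) {
        s <- simulate_two_interval_session(config, d, derive_seed(seed, ctr))
        ctr <- ctr + 1L
        an <- analyze_lever_session(s)
        tr <- an$trials
        tr$dose <- d
        tr$session <- i
        all_trials[[length(all_trials) + 1L]] <- tr
      }
    }
    trials <- do.call(rbind, all_trials)
    trials$overshoot_fraction <- overshoot_fraction(pmax(trials$overshoot_ms, 0),
                                                    trials$required_interval_ms)
    srh <- lapply(
      stats::setNames(nm = c("overshoot_ms", "overshoot_fraction", "interlimb_r",
                             "max_speed_cm_s")),
      function(mm) {
        keep <- !is.na(trials[[mm]])
        if (length(unique(trials$dose[keep])) < 2L ||
            length(unique(trials$required_interval_ms[keep])) < 2L) {
          return(NULL)  # degenerate design (e.g. a single block simulated)
        }
        scheirer_ray_hare(trials[[mm]][keep], trials$dose[keep],
                          trials$required_interval_ms[keep])
      })
    kw <- lapply(stats::setNames(nm = c("overshoot_ms", "overshoot_fraction",
                                        "interlimb_r", "max_speed_cm_s",
                                        "n_attempts", "effort_s")),
                 function(mm) kw_by_dose(trials, mm))
    lsd <- if (length(unique(trials$dose)) > 1L) {
      lsd_posthoc(split(trials$overshoot_ms, trials$dose))
    } else NULL
    disc <- if (length(unique(trials$required_interval_ms)) == 2L &&
                  length(unique(trials$dose)) > 1L) {
      classify_production_mode(trials)
    } else NULL
    agg <- do.call(rbind, lapply(split(trials, list(trials$dose, trials$required_interval_ms)),
                                 function(g) {
                                   a <- aggregate_trial_metrics(g)
                                   a$dose <- g$dose[1]
                                   a$required_interval_ms <- g$required_interval_ms[1]
                                   a
                                 }))
    rownames(agg) <- NULL
    res$two_interval <- list(trials = trials, aggregates = agg, srh = srh,
                             kw = kw, lsd_overshoot = lsd)
    res$discrimination <- disc
    counts$two_interval_trials <- nrow(trials)
  }

  if ("treadmill" %in% tasks) {
    scores <- list()
    ctr <- 2000L
    ref <- NULL
    for (d in doses) {
      sess <- lapply(seq_len(config$n_sessions), function(i) {
        simulate_treadmill_session(config, d, seed = derive_seed(seed, ctr + i))
      })
      ctr <- ctr + config$n_sessions
      if (d == doses[1]) {
        ref <- control_reference(unlist(lapply(sess, `[[`, "trials"),
                                        recursive = FALSE))
      }
      sc <- do.call(rbind, lapply(sess, score_treadmill_session, reference = ref))
      sc$dose <- d
      scores[[as.character(d)]] <- sc
    }
    tread <- do.call(rbind, scores)
    rownames(tread) <- NULL
    res$treadmill <- list(
      trial_table = tread,
      kw_duration = kw_by_dose(tread, "duration_s"),
      kw_peak_speed = kw_by_dose(tread, "peak_speed_cm_s"),
      dose_table = do.call(rbind, lapply(split(tread, tread$dose), function(g) {
        data.frame(dose = g$dose[1],
                   median_duration_s = stats::median(g$duration_s),
                   median_peak_speed = stats::median(g$peak_speed_cm_s),
                   frac_normal = mean(g$strategy == "normal"))
      })))
    counts$treadmill_trials <- nrow(tread)
  }

  res$manifest <- list(
    config_hash = fnv1a_hash(unclass(config)),
    seed = seed, tasks = tasks,
    row_counts = counts,
    package_version = as.character(utils::packageVersion("chronobeh")),
    started = format(t_start, "%Y-%m-%d %H:%M:%OS3"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$fixed_interval)) {
      utils::write.csv(res$fixed_interval$session_table,
                       file.path(out_dir, "fi_sessions.csv"), row.names = FALSE)
      utils::write.csv(res$fixed_interval$dose_table,
                       file.path(out_dir, "fi_dose_table.csv"), row.names = FALSE)
    }
    if (!is.null(res$two_interval)) {
      utils::write.csv(res$two_interval$trials,
                       file.path(out_dir, "ti_trials.csv"), row.names = FALSE)
      utils::write.csv(res$two_interval$aggregates,
                       file.path(out_dir, "ti_aggregates.csv"), row.names = FALSE)
    }
    if (!is.null(res$treadmill)) {
      utils::write.csv(res$treadmill$trial_table,
                       file.path(out_dir, "treadmill_trials.csv"), row.names = FALSE)
    }
    yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
    writeLines(experiment_summary(res), file.path(out_dir, "summary.txt"))
    return(invisible(res))
  }
  res
}

# Plain-text report of the statistical decisions of a run.
experiment_summary <- function(res) {
  ln <- c("chronobeh simulated experiment", "")
  fmt_test <- function(t, label) {
    if (is.null(t)) return(character(0))
    sprintf("  %-28s H/X2 = %8.3f  df = %s  p = %.4g", label,
            t$statistic, paste(t$df, collapse = ","), t$p)
  }
  if (!is.null(res$fixed_interval)) {
    ln <- c(ln, "Fixed-interval task (dose effects):",
            fmt_test(res$fixed_interval$kw_auc, "K-W AUC"),
            fmt_test(res$fixed_interval$kw_peak, "K-W peak interval"), "")
  }
  if (!is.null(res$two_interval)) {
    ln <- c(ln, "Two-interval production task:",
            fmt_test(res$two_interval$kw$overshoot_ms, "K-W overshoot"),
            fmt_test(res$two_interval$srh$overshoot_ms$a, "S-R-H overshoot: dose"),
            fmt_test(res$two_interval$srh$overshoot_ms$b, "S-R-H overshoot: interval"),
            fmt_test(res$two_interval$kw$max_speed_cm_s, "K-W max speed"), "")
  }
  if (!is.null(res$discrimination)) {
    d <- res$discrimination
    ln <- c(ln, sprintf("Production-mode verdict: %s (ratio %.3f vs threshold %.3f)",
                        d$mode, d$ratio, d$threshold), "")
  }
  if (!is.null(res$treadmill)) {
    ln <- c(ln, "Treadmill sequence:",
            fmt_test(res$treadmill$kw_duration, "K-W duration"),
            fmt_test(res$treadmill$kw_peak_speed, "K-W peak speed"))
  }
  ln
}

# --- on-disk session bundles -------------------------------------------------

#' Write or read a lever session bundle
#'
#' A session is stored as a directory: `trace.csv` (time_s, left_cm,
#' right_cm), tidy `events.csv` / `attempts.csv` / `trials.csv` tables from
#' the generator's ground truth, and a `meta.yaml` sidecar (schedule, dose,
#' sampling rate, reward times, block labels, generating parameters).
#'
#' @param session a `lever_session`.
#' @param dir bundle directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()` a
#'   `lever_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "lever_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_s = session$time, left_cm = session$left_pos,
                              right_cm = session$right_pos),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  gt <- session$ground_truth
  if (!is.null(gt$events)) {
    utils::write.csv(gt$events, file.path(dir, "events.csv"), row.names = FALSE)
  }
  if (!is.null(gt$attempts)) {
    utils::write.csv(gt$attempts, file.path(dir, "attempts.csv"), row.names = FALSE)
  }
  if (!is.null(gt$trials)) {
    utils::write.csv(gt$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  }
  yaml::write_yaml(list(schedule = session$schedule, dose = session$dose,
                        fs = session$fs, reward_times = session$reward_times,
                        block_labels = session$block_labels,
                        params = gt$params),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  trace <- utils::read.csv(file.path(dir, "trace.csv"))
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  ev <- rd("events.csv")
  gt <- list(params = meta$params, trials = rd("trials.csv"),
             attempts = rd("attempts.csv"), events = ev)
  if (!is.null(ev)) {
    gt$press_onsets <- list(left = sort(ev$onset[ev$lever == "left"]),
                            right = sort(ev$onset[ev$lever == "right"]))
  }
  new_lever_session(trace, meta$schedule, meta$dose,
                    as.numeric(unlist(meta$reward_times)),
                    as.numeric(unlist(meta$block_labels)), gt)
}
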