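# Generator configuration: dose ladders, clock and motor distortion, task geometry.

#' Configuration for the synthetic session generator
#'
#' Bundles every tunable of the behavioural simulator. Distortions are indexed
#' by dose: `clock_gain` multiplies the subjective time rate (1 = veridical;
#' values above 1 make subjective time run fast, so the animal acts early in
#' objective time; values below 1 make it run slow, so timed productions
#' lengthen), and `motor_scale` multiplies limb and locomotion speeds
#' (1 = control, below 1 = slowed). The default ladders emulate a cannabinoid
#' dose series: rising clock gain (diffuse, early pressing in the
#' fixed-interval task) and falling motor scale (slower, longer movements).
#'
#' @param dose_levels ordered dose labels (mg/kg), ascending.
#' @param clock_gain per-dose subjective time-rate multiplier (> 0). Recycled
#'   if scalar.
#' @param motor_scale per-dose limb/locomotion speed multiplier (> 0). Recycled
#'   if scalar.
#' @param weber_fraction coefficient of variation of timed intervals, in (0, 1).
#' @param planned_margin_ms intended hold duration in excess of the required
#'   interval (ms).
#' @param reaction_time_ms mean latency to release after reward on reactive
#'   (non-planned) trials (ms).
#' @param reactive_fraction fraction of rewarded trials whose release is a
#'   reaction to the reward (release latency around `reaction_time_ms`) rather
#'   than a planned margin.
#' @param press_rate_peak peak rate of checking presses near the subjective
#'   target (presses/s) in the fixed-interval task.
#' @param baseline_press_rate floor rate of checking presses (presses/s).
#' @param sustain_fraction fraction of `press_rate_peak` maintained after the
#'   subjective target has passed without reward (expectation-violation
#'   pressing).
#' @param coordination_noise SD of the inter-lever onset lag (s).
#' @param trace_jitter_cm SD of the correlated positional jitter added to
#'   synthetic traces (cm).
#' @param release_lag_ms motor release-initiation lag under control (ms); its
#'   slowdown by `1/motor_scale` is what lengthens holds additively in
#'   `motor_slowing` mode.
#' @param production_mode how dose lengthens holds in the production tasks:
#'   `"motor_slowing"` adds a dose-dependent, interval-independent increment
#'   (slowed release); `"timing_scaling"` scales the produced interval by
#'   `1/clock_gain` (a slow production clock lengthens holds proportionally).
#' @param lever_rise_speed_cm_s control lever movement speed (cm/s).
#' @param press_amplitude_cm peak displacement of full presses (cm, <= 3.5).
#' @param fi_interval_s fixed-interval duration (s).
#' @param fi_hold_s required hold above the spatial threshold in the
#'   fixed-interval task (s).
#' @param ti_thresholds_ms the two required hold intervals (ms), longest first.
#' @param ti_block_len trials per block in the two-interval schedule.
#' @param iti_s inter-trial interval of the two-interval schedule (s).
#' @param touch_threshold_cm,spatial_threshold_cm detection thresholds (cm).
#' @param treadmill list of treadmill settings, see [treadmill_config()].
#' @param n_trials trials (rewards) per simulated session.
#' @param n_sessions sessions per dose in cohort-level runs.
#' @param seed master seed.
#' @return an object of class `gen_config` (a validated list).
#' @seealso [simulate_fixed_interval_session()], [simulate_two_interval_session()],
#'   [simulate_treadmill_session()], [read_gen_config()]
#' @examples
#' cfg <- gen_config(n_trials = 20)
#' clock_gain_for(cfg, 0.2)
#' @export
gen_config <- function(dose_levels = c(0, 0.01, 0.05, 0.1, 0.2),
                       clock_gain = c(1.00, 1.12, 1.25, 1.42, 1.60),
                       motor_scale = c(1.00, 0.95, 0.85, 0.70, 0.50),
                       weber_fraction = 0.10,
                       planned_margin_ms = 100,
                       reaction_time_ms = 300,
                       reactive_fraction = 0.1,
                       press_rate_peak = 2.5,
                       baseline_press_rate = 0.15,
                       sustain_fraction = 0.4,
                       coordination_noise = 0.02,
                       trace_jitter_cm = 0.003,
                       release_lag_ms = 300,
                       production_mode = c("motor_slowing", "timing_scaling"),
                       lever_rise_speed_cm_s = 26,
                       press_amplitude_cm = 3.0,
                       fi_interval_s = 30,
                       fi_hold_s = 0.75,
                       ti_thresholds_ms = c(1250, 750),
                       ti_block_len = 20,
                       iti_s = 1.5,
                       touch_threshold_cm = 0.1,
                       spatial_threshold_cm = 2.6,
                       treadmill = treadmill_config(),
                       n_trials = 100,
                       n_sessions = 4,
                       seed = 1) {
  production_mode <- match.arg(production_mode)
  nd <- length(dose_levels)
  if (nd < 1L || is.unsorted(dose_levels, strictly = TRUE)) {
    stop("dose_levels must be a non-empty strictly ascending vector")
  }
  clock_gain <- rep_len(clock_gain, nd)
  motor_scale <- rep_len(motor_scale, nd)
  if (any(clock_gain <= 0) || any(motor_scale <= 0)) {
    stop("clock_gain and motor_scale multipliers must all be > 0")
  }
  if (!(weber_fraction > 0 && weber_fraction < 1)) {
    stop("weber_fraction must lie in (0, 1)")
  }
  if (press_amplitude_cm > 3.5) stop("press_amplitude_cm exceeds the 3.5 cm physical maximum")
  if (n_trials < 1L) stop("n_trials must be positive")
  cfg <- list(
    dose_levels = as.numeric(dose_levels),
    clock_gain = as.numeric(clock_gain),
    motor_scale = as.numeric(motor_scale),
    weber_fraction = weber_fraction,
    planned_margin_ms = planned_margin_ms,
    reaction_time_ms = reaction_time_ms,
    reactive_fraction = reactive_fraction,
    press_rate_peak = press_rate_peak,
    baseline_press_rate = baseline_press_rate,
    sustain_fraction = sustain_fraction,
    coordination_noise = coordination_noise,
    trace_jitter_cm = trace_jitter_cm,
    release_lag_ms = release_lag_ms,
    production_mode = production_mode,
    lever_rise_speed_cm_s = lever_rise_speed_cm_s,
    press_amplitude_cm = press_amplitude_cm,
    fi_interval_s = fi_interval_s,
    fi_hold_s = fi_hold_s,
    ti_thresholds_ms = as.numeric(ti_thresholds_ms),
    ti_block_len = as.integer(ti_block_len),
    iti_s = iti_s,
    touch_threshold_cm = touch_threshold_cm,
    spatial_threshold_cm = spatial_threshold_cm,
    treadmill = do.call(treadmill_config, as.list(treadmill)),
    n_trials = as.integer(n_trials),
    n_sessions = as.integer(n_sessions),
    seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  cfg
}

#' Treadmill settings of the generator
#'
#' @param belt_speed_set allowed belt speeds (cm/s).
#' @param goal_time_s required minimum sequence duration (s).
#' @param belt_length_cm passable belt length (cm).
#' @param goal_zone_cm goal-area depth from the front wall (cm).
#' @param rear_position_cm rear-most position reached under the full-transport
#'   strategy (cm).
#' @param peak_speed_gain ground-frame peak speed of the final acceleration as
#'   a multiple of belt speed under control.
#' @param plan_margin_s planned sequence duration in excess of `goal_time_s` (s).
#' @param duration_cv coefficient of variation of the timed sequence duration.
#' @param jitter_cm SD of the correlated positional jitter (cm).
#' @param trot_amplitude_cm amplitude of the position wobble while holding at
#'   the rear (cm).
#' @param strategy compensation strategy under motor slowing: `"shortened_hold"`
#'   keeps the full transport and shrinks the hold; `"partial_transport"` stops
#'   the transport early and keeps a control-like hold; `"auto"` picks
#'   `shortened_hold` while feasible and falls back to `partial_transport`.
#' @return a list of validated treadmill settings.
#' @export
treadmill_config <- function(belt_speed_set = 27:33,
                             goal_time_s = 7,
                             belt_length_cm = 80,
                             goal_zone_cm = 10,
                             rear_position_cm = 78,
                             peak_speed_gain = 2.8,
                             plan_margin_s = 0.15,
                             duration_cv = 0.04,
                             jitter_cm = 0.1,
                             trot_amplitude_cm = 0.3,
                             strategy = c("auto", "shortened_hold", "partial_transport")) {
  strategy <- match.arg(strategy)
  stopifnot(all(belt_speed_set > 0), goal_time_s > 0,
            goal_zone_cm > 0, goal_zone_cm < rear_position_cm,
            rear_position_cm <= belt_length_cm, peak_speed_gain > 0,
            duration_cv >= 0, plan_margin_s >= 0)
  list(belt_speed_set = as.numeric(belt_speed_set), goal_time_s = goal_time_s,
       belt_length_cm = belt_length_cm, goal_zone_cm = goal_zone_cm,
       rear_position_cm = rear_position_cm, peak_speed_gain = peak_speed_gain,
       plan_margin_s = plan_margin_s, duration_cv = duration_cv,
       jitter_cm = jitter_cm, trot_amplitude_cm = trot_amplitude_cm,
       strategy = strategy)
}

dose_index <- function(config, dose) {
  i <- match(dose, config$dose_levels)
  if (is.na(i)) {
    stop("unknown dose label: ", dose, " (configured: ",
         paste(config$dose_levels, collapse = ", "), ")")
  }
  i
}

#' @rdname gen_config
#' @param config a `gen_config` object.
#' @param dose a dose label present in `config$dose_levels`.
#' @export
clock_gain_for <- function(config, dose) config$clock_gain[dose_index(config, dose)]

#' @rdname gen_config
#' @export
motor_scale_for <- function(config, dose) config$motor_scale[dose_index(config, dose)]

#' @export
print.gen_config <- function(x, ...) {
  cat("<gen_config>\n")
  cat("  doses (mg/kg):", paste(x$dose_levels, collapse = ", "), "\n")
  cat("  clock_gain:   ", paste(format(x$clock_gain), collapse = ", "), "\n")
  cat("  motor_scale:  ", paste(format(x$motor_scale), collapse = ", "), "\n")
  cat("  weber_fraction:", x$weber_fraction,
      " production_mode:", x$production_mode, "\n")
  cat("  n_trials:", x$n_trials, " n_sessions:", x$n_sessions,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' Every field of [gen_config()] (including the nested treadmill block) is
#' addressable from the file; omitted fields take their defaults.
#'
#' @param path file path.
#' @return `read_gen_config()` returns a `gen_config`; `write_gen_config()`
#'   returns `path` invisibly.
#' @export
read_gen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(gen_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(gen_config, raw)
}

#' @rdname read_gen_config
#' @param config a `gen_config` object.
#' @export
write_gen_config <- function(config, path) {
  stopifnot(inherits(config, "gen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
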