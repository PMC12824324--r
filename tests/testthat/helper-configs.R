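# Shared fixture builders: everything is generated in code at test time.

# Noise-free limit: deterministic timing, no jitter, no reactive releases.
noise_free_config <- function(...) {
  gen_config(weber_fraction = 1e-6, coordination_noise = 1e-4,
             trace_jitter_cm = 0, reactive_fraction = 0,
             baseline_press_rate = 0.05, press_rate_peak = 1, ...)
}

# Noise-free treadmill settings (exact kinematic construction).
noise_free_treadmill <- function(...) {
  list(duration_cv = 0, jitter_cm = 0, trot_amplitude_cm = 0,
       plan_margin_s = 0, ...)
}

# Simulated multi-session cohort of two-interval trial tables across doses.
make_ti_cohort <- function(config, seed, n_sessions = 8) {
  do.call(rbind, lapply(config$dose_levels, function(d) {
    do.call(rbind, lapply(seq_len(n_sessions), function(i) {
      tr <- simulate_two_interval_trials(
        config, d, derive_seed(seed, match(d, config$dose_levels) * 100 + i))$trials
      tr$dose <- d
      tr
    }))
  }))
}

# Independent closed-form Kruskal-Wallis statistic on mid-ranks (textbook
# rank-sum form with tie correction), used as an oracle.
oracle_kw_h <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / tabulate(factor(g))) - 3 * (N + 1)
  tt <- table(x)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C == 0) 0 else h / C
}
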