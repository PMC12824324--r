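# Internal helpers: seeded RNG streams, grid checks, smoothing.

#' Derive a per-session random seed from a master seed
#'
#' Sessions are seeded from one master seed and an integer counter so that any
#' session of a multi-session cohort can be regenerated on its own. The
#' derivation is a fixed affine congruential step modulo 2^31 - 1; it carries
#' no statistical weight beyond decorrelating streams.
#'
#' @param seed master seed (non-negative integer).
#' @param counter stream counter (non-negative integer).
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  as.integer((as.double(seed) %% 2147483647 * 48271 + counter * 8191 + 1) %% 2147483647)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Uniform-grid check; returns the sampling step.
grid_step <- function(time_s, tol = 1e-6) {
  if (length(time_s) < 2L) stop("time grid needs at least 2 samples")
  d <- diff(time_s)
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * max(1, dt))) {
    stop("non-uniform time grid (max deviation ", format(max(abs(d - dt))), " s)")
  }
  dt
}

# Centered moving average with shrinking window at the edges.
box_smooth <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Correlated positional jitter: white noise smoothed over `width` samples.
smooth_noise <- function(n, sd, width = 3L) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  box_smooth(stats::rnorm(n, 0, sd), width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
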