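# Rank-based statistical stack implemented from first principles: mid-rank tie
# handling throughout, tie correction entering via the total rank mean square.

new_rank_test <- function(test, effect, statistic, df, p, n, tie_factor = NA_real_,
                          extra = list()) {
  out <- c(list(test = test, effect = effect, statistic = unname(statistic),
                df = unname(df), p = unname(min(max(p, 0), 1)), n = n,
                tie_factor = tie_factor), extra)
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$effect, x$statistic, paste(x$df, collapse = ","), x$p))
  invisible(x)
}

# Classic tie-correction factor C = 1 - sum(t^3 - t) / (N^3 - N).
tie_correction <- function(x) {
  t <- table(x)
  1 - sum(t^3 - t) / (length(x)^3 - length(x))
}

#' Kruskal-Wallis rank test
#'
#' One-way rank test across k groups using mid-ranks, with tie correction
#' entering through the total rank mean square:
#' `H = (N - 1) * SS_between / SS_total` on the ranks, which reduces to the
#' textbook `12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 / C` form. The statistic
#' is referred to a chi-square distribution with k - 1 degrees of freedom, or
#' to its exact permutation distribution when `p_method = "exact"` (all
#' reassignments of the pooled observations to the group sizes are
#' enumerated; feasible for small N).
#'
#' @param groups list of numeric samples, each nonempty, at least 2 groups.
#' @param p_method `"chisq"` (default) or `"exact"`.
#' @param max_exact_n largest total N for which exact enumeration is allowed.
#' @return a `rank_test` with the H statistic (identically 0 when all values
#'   are equal, with p = 1).
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "exact"),
                           max_exact_n = 10L) {
  p_method <- match.arg(p_method)
  if (length(groups) < 2L) stop("need at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), n_i)
  H <- kw_statistic(x, g)
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  if (p_method == "exact") {
    N <- length(x)
    if (N > max_exact_n) stop("exact enumeration limited to N <= ", max_exact_n)
    perms <- group_assignments(N, n_i)
    h_all <- vapply(perms, function(gg) kw_statistic(x, gg), numeric(1))
    p <- mean(h_all >= H - 1e-12)
  }
  new_rank_test("Kruskal-Wallis", "group", H, df, p, n = as.list(n_i),
                tie_factor = tie_correction(x),
                extra = list(p_method = p_method))
}

# H as SS_between / MS_total on mid-ranks (exact under ties); 0 for constant data.
kw_statistic <- function(x, g) {
  r <- rank(x)
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot == 0) return(0)
  means <- tapply(r, g, mean)
  n_i <- tabulate(as.integer(factor(g)))
  ss_b <- sum(n_i * (means - mean(r))^2)
  (length(x) - 1) * ss_b / ss_tot
}

# All distinct assignments of N items to groups of sizes n_i (recursive
# combination enumeration); returns a list of group-label vectors.
group_assignments <- function(N, n_i) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    combs <- utils::combn(avail, sizes[1L], simplify = FALSE)
    out <- list()
    for (cc in combs) {
      for (rest in rec(setdiff(avail, cc), sizes[-1L])) {
        out[[length(out) + 1L]] <- c(list(cc), rest)
      }
    }
    out
  }
  lapply(rec(seq_len(N), n_i), function(sets) {
    v <- integer(N)
    for (k in seq_along(sets)) v[sets[[k]]] <- k
    v
  })
}

#' Scheirer-Ray-Hare two-way rank test
#'
#' Two-way extension of the Kruskal-Wallis test: all N observations are
#' ranked (mid-ranks for ties), two-way ANOVA sums of squares are computed on
#' the ranks, and each effect's statistic is
#' `H = SS_effect / MS_total`, where `MS_total = SS_total / (N - 1)` is the
#' variance of the ranks (this is where tie correction enters exactly). Each H
#' is referred to chi-square with the effect's ANOVA degrees of freedom.
#' Balanced designs use the closed-form marginal-mean decomposition;
#' unbalanced designs use Type-II sums of squares on the ranks obtained from
#' nested least-squares fits.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors (e.g. dose and produced interval);
#'   every cell must be nonempty and each factor needs at least 2 levels.
#' @return a list of three `rank_test` objects: `a`, `b`, `interaction`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) stop("each factor needs >= 2 levels")
  if (any(table(fa, fb) == 0L)) stop("empty cell in the two-way design")
  N <- length(values)
  r <- rank(values)
  ms_total <- stats::var(r)
  df_a <- nlevels(fa) - 1L
  df_b <- nlevels(fb) - 1L
  df_ab <- df_a * df_b
  if (ms_total == 0) {
    ss <- c(a = 0, b = 0, ab = 0)
  } else if (length(unique(table(fa, fb))) == 1L) {
    gm <- mean(r)
    ss_a <- sum(tapply(r, fa, length) * (tapply(r, fa, mean) - gm)^2)
    ss_b <- sum(tapply(r, fb, length) * (tapply(r, fb, mean) - gm)^2)
    cell <- interaction(fa, fb, drop = TRUE)
    ss_cells <- sum(tapply(r, cell, length) * (tapply(r, cell, mean) - gm)^2)
    ss <- c(a = ss_a, b = ss_b, ab = ss_cells - ss_a - ss_b)
  } else {
    rss <- function(form) sum(stats::lm(form, data = data.frame(r = r, fa = fa, fb = fb))$residuals^2)
    rss_a <- rss(r ~ fa)
    rss_b <- rss(r ~ fb)
    rss_ab <- rss(r ~ fa + fb)
    rss_full <- rss(r ~ fa * fb)
    ss <- c(a = rss_b - rss_ab, b = rss_a - rss_ab, ab = rss_ab - rss_full)
  }
  h <- if (ms_total == 0) c(0, 0, 0) else ss / ms_total
  mk <- function(effect, H, df) {
    p <- if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
    new_rank_test("Scheirer-Ray-Hare", effect, H, df, p, n = N,
                  tie_factor = tie_correction(values))
  }
  list(a = mk("factor_a", h[1], df_a), b = mk("factor_b", h[2], df_b),
       interaction = mk("interaction", h[3], df_ab))
}

#' Rank-based LSD post hoc comparisons
#'
#' Fisher-LSD-style pairwise comparisons after a rank omnibus test, in the
#' Conover formulation: t statistics on rank means with the pooled rank
#' variance `S^2 (N - 1 - H)/(N - k)`, unadjusted p values on N - k degrees of
#' freedom, gated on omnibus significance. Comparisons against the first
#' group (control) and against the last group (highest dose) carry the
#' conventional star/hash markers.
#'
#' @param groups list of numeric samples (ordered; first = control,
#'   last = highest dose).
#' @param omnibus optional omnibus `rank_test` (defaults to
#'   [kruskal_wallis()] on `groups`).
#' @param alpha significance level for the gate and the markers.
#' @return a data.frame of pairwise rows: `group_i`, `group_j`, `rank_mean_i`,
#'   `rank_mean_j`, `t`, `df`, `p`, `significant`, `marker` (`"*"` vs control,
#'   `"#"` vs highest).
#' @export
lsd_posthoc <- function(groups, omnibus = NULL, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(omnibus)) omnibus <- kruskal_wallis(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  n_i <- lengths(groups)
  rbar <- tapply(r, g, mean)
  s2 <- stats::var(r)
  H <- omnibus$statistic
  gate_open <- omnibus$p < alpha
  pooled <- s2 * (N - 1 - H) / (N - k)
  pooled <- max(pooled, 0)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(pooled * (1 / n_i[i] + 1 / n_i[j]))
    tval <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pt(-abs(tval), df = N - k)
    data.frame(group_i = i, group_j = j,
               rank_mean_i = rbar[i], rank_mean_j = rbar[j],
               t = tval, df = N - k, p = p,
               significant = gate_open && p < alpha)
  }))
  out$marker <- ""
  out$marker[out$significant & out$group_i == 1L] <- "*"
  out$marker[out$significant & out$group_j == k & out$group_i != 1L] <-
    paste0(out$marker[out$significant & out$group_j == k & out$group_i != 1L], "#")
  rownames(out) <- NULL
  out
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with mid-ranks. For small untied samples the p value is exact
#' (all splits of the pooled sample enumerated); otherwise the normal
#' approximation with tie-corrected variance is used (no continuity
#' correction).
#'
#' @param x,y numeric samples, nonempty.
#' @param exact force/forbid exact enumeration; default: exact when
#'   `choose(n + m, n) <= 20000` and there are no ties.
#' @return a `rank_test` with the U statistic of the first sample.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (is.null(exact)) exact <- !ties && choose(n1 + n2, n1) <= 20000
  if (exact && ties) exact <- FALSE
  if (exact) {
    splits <- utils::combn(n1 + n2, n1, simplify = FALSE)
    u_all <- vapply(splits, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2, numeric(1))
    p <- min(1, 2 * min(mean(u_all <= U + 1e-12), mean(u_all >= U - 1e-12)))
    return(new_rank_test("Mann-Whitney", "group", U, NA_real_, p,
                         n = list(n1, n2), extra = list(p_method = "exact")))
  }
  N <- n1 + n2
  t_tab <- table(pooled)
  var_u <- n1 * n2 / 12 * ((N + 1) - sum(t_tab^3 - t_tab) / (N * (N - 1)))
  z <- if (var_u > 0) (U - n1 * n2 / 2) / sqrt(var_u) else 0
  p <- 2 * stats::pnorm(-abs(z))
  new_rank_test("Mann-Whitney", "group", U, NA_real_, p, n = list(n1, n2),
                tie_factor = tie_correction(pooled),
                extra = list(z = z, p_method = "normal"))
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal distribution with moments
#' estimated from the data, with the asymptotic Kolmogorov p value. Because
#' the reference parameters are estimated, the p value is conservative-biased
#' (the Lilliefors correction is not applied); it is used as a descriptive
#' normality screen.
#'
#' @param x numeric sample with at least 3 distinct values.
#' @return a `rank_test` with the D statistic.
#' @export
ks_normality <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F0 <- stats::pnorm(z)
  D <- max(pmax(seq_len(n) / n - F0, F0 - (seq_len(n) - 1) / n))
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  new_rank_test("Kolmogorov-Smirnov", "normality", D, NA_real_, p, n = n)
}
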