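validate_counts <- function(x1, n1, x2, n2) {
  ok <- function(x, n) {
    length(x) == 1L && length(n) == 1L && !is.na(x) && !is.na(n) &&
      n >= 1 && x >= 0 && x <= n && x == round(x) && n == round(n)
  }
  if (!ok(x1, n1) || !ok(x2, n2)) {
    stop_data("invalid two-sample counts: need integer 0 <= x <= n, n >= 1")
  }
  invisible(NULL)
}

#' Cohen's effect size h for two proportions
#'
#' The arcsine-transformed difference
#' `h = | 2 asin(sqrt(p1)) - 2 asin(sqrt(p2)) |`, computed from the
#' unrounded proportions `x1/n1` and `x2/n2` and reported as an absolute
#' value. Defined for all valid counts, including endpoints 0 and 1;
#' `h` lies in `[0, pi]`. Conventional benchmarks: 0.2 small, 0.5
#' medium, 0.8 large.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return Nonnegative scalar.
#' @examples
#' cohen_h(385, 2620, 212, 2380) # ~0.18
#' @export
cohen_h <- function(x1, n1, x2, n2) {
  validate_counts(x1, n1, x2, n2)
  abs(2 * asin(sqrt(x1 / n1)) - 2 * asin(sqrt(x2 / n2)))
}

#' Pooled-variance two-proportion Z test
#'
#' `z = (p1 - p2) / sqrt( pbar (1 - pbar) (1/n1 + 1/n2) )` with
#' `pbar = (x1 + x2) / (n1 + n2)`; two-sided p-value from the standard
#' normal. `z` carries the sign of `p1 - p2`.
#'
#' @inheritParams cohen_h
#' @return A list with `z`, `p_value`, `p1`, `p2`, `diff`.
#' @export
pooled_z_test <- function(x1, n1, x2, n2) {
  validate_counts(x1, n1, x2, n2)
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    stop_data("degenerate pooled proportion (all successes or all failures): no variation to test")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2, diff = p1 - p2)
}

#' Unpooled Wald confidence interval for a difference of proportions
#'
#' `diff +/- z_{1-alpha/2} sqrt(p1 q1 / n1 + p2 q2 / n2)`, clamped to
#' `[-1, 1]`. Degenerate endpoints (x = 0 or x = n in both groups) give a
#' zero-width interval at the observed difference.
#'
#' @inheritParams cohen_h
#' @param alpha Two-sided significance level (default 0.05).
#' @return Numeric vector `c(low, high)`.
#' @export
wald_unpooled_ci <- function(x1, n1, x2, n2, alpha = 0.05) {
  validate_counts(x1, n1, x2, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  half <- qnorm(1 - alpha / 2) * se
  c(max(-1, p1 - p2 - half), min(1, p1 - p2 + half))
}

#' Miettinen-Nurminen score statistic for a proportion difference
#'
#' The score statistic for `H0: p1 - p2 = delta`, using the closed-form
#' maximum-likelihood estimates of `(p1, p2)` restricted to the null and
#' the restricted-MLE variance inflated by `N/(N-1)`:
#' `z(delta) = (p1hat - p2hat - delta) / sqrt(V(delta))`. Vectorised over
#' `delta`; the building block of [mn_score_ci()] and of the extremity
#' ordering in [chan_zhang_ci()].
#'
#' @inheritParams cohen_h
#' @param delta Null difference(s) in `[-1, 1]`.
#' @return Numeric vector of score statistics (infinite where the
#'   restricted variance vanishes and the estimate is off the null).
#' @export
mn_score_z <- function(x1, n1, x2, n2, delta) {
  validate_counts(x1, n1, x2, n2)
  p <- mn_restricted_mle(x1, n1, x2, n2, delta)
  N <- n1 + n2
  v <- (p$p1 * (1 - p$p1) / n1 + p$p2 * (1 - p$p2) / n2) * N / (N - 1)
  num <- x1 / n1 - x2 / n2 - delta
  out <- ifelse(v > 0, num / sqrt(v), ifelse(num == 0, 0, sign(num) * Inf))
  as.numeric(out)
}

# Closed-form restricted MLE of (p1, p2) under p1 - p2 = delta
# (trigonometric solution of the constrained-likelihood cubic).
# Vectorised over delta.
mn_restricted_mle <- function(x1, n1, x2, n2, delta) {
  d <- delta
  N <- n1 + n2
  L2 <- (n1 + 2 * n2) * d - N - (x1 + x2)
  L1 <- (n2 * d - N - 2 * x2) * d + x1 + x2
  L0 <- x2 * d * (1 - d)
  q <- L2^3 / (3 * N)^3 - L1 * L2 / (6 * N^2) + L0 / (2 * N)
  pp <- sqrt(pmax(L2^2 / (3 * N)^2 - L1 / (3 * N), 0))
  pp <- ifelse(q < 0, -pp, pp)
  ratio <- ifelse(pp == 0, 0, q / pp^3)
  a <- (pi + acos(pmin(pmax(ratio, -1), 1))) / 3
  p2 <- 2 * pp * cos(a) - L2 / (3 * N)
  p2 <- pmin(pmax(p2, pmax(0, -d)), pmin(1, 1 - d))
  list(p1 = p2 + d, p2 = p2)
}

#' Miettinen-Nurminen score confidence interval
#'
#' Confidence interval for `p1 - p2` obtained by inverting the
#' restricted-MLE score test of [mn_score_z()]: the bounds are the values
#' of `delta` where `z(delta) = +/- z_{1-alpha/2}`, located by bracketed
#' root search. Bounds exist for all valid counts, including x = 0 and
#' x = n, and always lie inside `[-1, 1]`.
#'
#' @inheritParams wald_unpooled_ci
#' @param tol Root-search tolerance (default 1e-8).
#' @return Numeric vector `c(low, high)`.
#' @export
mn_score_ci <- function(x1, n1, x2, n2, alpha = 0.05, tol = 1e-8) {
  validate_counts(x1, n1, x2, n2)
  diff <- x1 / n1 - x2 / n2
  zc <- qnorm(1 - alpha / 2)
  eps <- 1e-9
  lower <- if (diff <= -1 + eps) -1 else {
    uniroot(
      function(d) mn_score_z(x1, n1, x2, n2, d) - zc,
      lower = -1 + eps, upper = diff, tol = tol
    )$root
  }
  upper <- if (diff >= 1 - eps) 1 else {
    uniroot(
      function(d) mn_score_z(x1, n1, x2, n2, d) + zc,
      lower = diff, upper = 1 - eps, tol = tol
    )$root
  }
  c(lower, upper)
}

#' Exact unconditional test of a proportion difference (Chan-Zhang)
#'
#' One-sided exact unconditional p-values for `H0: p1 - p2 = delta`.
#' Outcomes of the joint binomial space are ordered by the
#' Miettinen-Nurminen score statistic at `delta`; each tail probability is
#' maximised over the nuisance proportion `p2` on a uniform grid of
#' `grid_points` values spanning the delta-feasible range (plain supremum,
#' no confidence-set restriction). Full enumeration restricts use to
#' `n1, n2 <= 200`.
#'
#' @inheritParams cohen_h
#' @param delta Null difference in `[-1, 1]`.
#' @param grid_points Size of the nuisance-parameter grid (default 200).
#' @return A list with `p_upper` (`P(Z >= z_obs)`), `p_lower`
#'   (`P(Z <= z_obs)`), and `z_obs`.
#' @export
chan_zhang_test <- function(x1, n1, x2, n2, delta, grid_points = 200L) {
  validate_counts(x1, n1, x2, n2)
  if (n1 > 200L || n2 > 200L) {
    stop_config(
      "exact unconditional enumeration limited to n1, n2 <= 200; ",
      "use mn_score_ci() for larger samples"
    )
  }
  X1 <- 0:n1
  X2 <- 0:n2
  Z <- outer(X1, X2, function(a, b) mn_score_z_outcomes(a, n1, b, n2, delta))
  z_obs <- Z[x1 + 1L, x2 + 1L]
  upper_set <- Z >= z_obs - 1e-10
  lower_set <- Z <= z_obs + 1e-10
  lo <- max(0, -delta)
  hi <- min(1, 1 - delta)
  ps <- seq(lo, hi, length.out = grid_points)
  p_upper <- 0
  p_lower <- 0
  for (p2 in ps) {
    pr <- outer(
      dbinom(X1, n1, min(max(p2 + delta, 0), 1)),
      dbinom(X2, n2, p2)
    )
    p_upper <- max(p_upper, sum(pr[upper_set]))
    p_lower <- max(p_lower, sum(pr[lower_set]))
  }
  list(p_upper = p_upper, p_lower = p_lower, z_obs = z_obs)
}

# mn_score_z without scalar-count validation, vectorised over outcomes
mn_score_z_outcomes <- function(x1, n1, x2, n2, delta) {
  N <- n1 + n2
  d <- delta
  L2 <- (n1 + 2 * n2) * d - N - (x1 + x2)
  L1 <- (n2 * d - N - 2 * x2) * d + x1 + x2
  L0 <- x2 * d * (1 - d)
  q <- L2^3 / (3 * N)^3 - L1 * L2 / (6 * N^2) + L0 / (2 * N)
  pp <- sqrt(pmax(L2^2 / (3 * N)^2 - L1 / (3 * N), 0))
  pp <- ifelse(q < 0, -pp, pp)
  ratio <- ifelse(pp == 0, 0, q / pp^3)
  a <- (pi + acos(pmin(pmax(ratio, -1), 1))) / 3
  p2 <- 2 * pp * cos(a) - L2 / (3 * N)
  p2 <- pmin(pmax(p2, pmax(0, -d)), pmin(1, 1 - d))
  p1 <- p2 + d
  v <- (p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) * N / (N - 1)
  num <- x1 / n1 - x2 / n2 - d
  ifelse(v > 0, num / sqrt(v), ifelse(num == 0, 0, sign(num) * Inf))
}

#' Exact unconditional (Chan-Zhang) confidence interval
#'
#' Interval for `p1 - p2` formed by the values of `delta` not rejected by
#' the exact unconditional test of [chan_zhang_test()] at level
#' `alpha / 2` per side: the lower bound is the smallest `delta` with
#' upper-tail p-value above `alpha / 2`, the upper bound the largest
#' `delta` with lower-tail p-value above `alpha / 2`, each located by
#' bisection to `tol`. Being exact, the interval is never shorter than the
#' asymptotic score interval at small samples.
#'
#' @inheritParams chan_zhang_test
#' @param alpha Two-sided significance level (default 0.05).
#' @param tol Bisection tolerance on the bounds (default 1e-4).
#' @return Numeric vector `c(low, high)`.
#' @export
chan_zhang_ci <- function(x1, n1, x2, n2, alpha = 0.05, grid_points = 200L,
                          tol = 1e-4) {
  validate_counts(x1, n1, x2, n2)
  a2 <- alpha / 2
  diff <- x1 / n1 - x2 / n2
  p_up <- function(d) chan_zhang_test(x1, n1, x2, n2, d, grid_points)$p_upper
  p_lo <- function(d) chan_zhang_test(x1, n1, x2, n2, d, grid_points)$p_lower
  lower <- if (diff <= -1 + 1e-12) -1 else {
    bisect_boundary(p_up, -1, diff, a2, tol, accept_high = TRUE)
  }
  upper <- if (diff >= 1 - 1e-12) 1 else {
    bisect_boundary(p_lo, diff, 1, a2, tol, accept_high = FALSE)
  }
  c(lower, upper)
}

# boundary between rejected and accepted delta; accept_high = TRUE means the
# acceptance region (p > a2) sits at the high end of [lo, hi]
bisect_boundary <- function(pfun, lo, hi, a2, tol, accept_high) {
  f_lo <- pfun(lo) > a2
  f_hi <- pfun(hi) > a2
  if (accept_high && f_lo) return(lo)
  if (!accept_high && f_hi) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    acc <- pfun(mid) > a2
    if (acc == accept_high) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Two-group McNemar contrast of paired threshold-status change
#'
#' Compares two randomised groups on the net change in threshold-symptom
#' status between a paper pretest and the first online check-in, using the
#' paired 2x2 change tables of [paired_change_counts()]. Per group `g`,
#' with `b_g` pairs moving threshold -> non-threshold, `c_g` pairs moving
#' the other way and `N_g` pairs in total, the net shift toward fewer
#' threshold reports is `d_g = (b_g - c_g) / N_g` with variance
#' `v_g = (b_g + c_g - (b_g - c_g)^2 / N_g) / N_g^2`. The statistic
#' `z = (d_2 - d_1) / sqrt(v_1 + v_2)` is positive when the second (ALERT)
#' group shifts more strongly toward fewer threshold reports; the p-value
#' is two-sided. With one group empty the statistic reduces to the
#' one-sample McNemar net-change z of the other group.
#'
#' @param tab1,tab2 2x2 matrices (rows = pretest `threshold`/
#'   `non_threshold`, columns = first check-in status) for the first
#'   (reference, e.g. CONTROL) and second (e.g. ALERT) group.
#' @return A list with `z`, `p_value`, `d1`, `d2` and the per-group
#'   variances `v1`, `v2`.
#' @export
mcnemar_two_group <- function(tab1, tab2) {
  net <- function(tab) {
    if (!is.matrix(tab) || any(dim(tab) != 2L) || any(tab < 0)) {
      stop_data("each change table must be a nonnegative 2x2 matrix")
    }
    N <- sum(tab)
    if (N == 0) return(list(d = 0, v = 0, disc = 0))
    b <- tab[1L, 2L] # threshold at pretest -> non-threshold at check-in
    cc <- tab[2L, 1L]
    d <- (b - cc) / N
    list(d = d, v = (b + cc - (b - cc)^2 / N) / N^2, disc = b + cc)
  }
  g1 <- net(tab1)
  g2 <- net(tab2)
  if (g1$disc + g2$disc == 0) {
    stop_data("no discordant pairs in either group: net change is degenerate")
  }
  z <- (g2$d - g1$d) / sqrt(g1$v + g2$v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), d1 = g1$d, d2 = g2$d, v1 = g1$v, v2 = g2$v)
}

#' Bundle two-sample proportion comparisons
#'
#' Runs the pooled-variance Z test, Cohen's h and the requested confidence
#' intervals for one pair of binomial counts and returns them as a single
#' record.
#'
#' @inheritParams wald_unpooled_ci
#' @param methods Confidence-interval methods: any of `"wald"`
#'   (unpooled), `"mn"` (Miettinen-Nurminen score) and `"cz"`
#'   (Chan-Zhang exact unconditional).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `prop_comparison`: a list with the counts,
#'   `p1`, `p2`, `diff`, `z`, `p_value`, `h`, `alpha` and a tibble `ci`
#'   (`method`, `low`, `high`).
#' @examples
#' compare_proportions(103, 385, 113, 212, methods = c("wald", "mn"))
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                methods = c("wald", "mn"),
                                alpha = 0.05,
                                labels = c("group1", "group2")) {
  validate_counts(x1, n1, x2, n2)
  methods <- match.arg(methods, c("wald", "mn", "cz"), several.ok = TRUE)
  zt <- tryCatch(pooled_z_test(x1, n1, x2, n2), carealert_data_error = function(e) NULL)
  ci <- lapply(methods, function(m) {
    bounds <- switch(m,
      wald = wald_unpooled_ci(x1, n1, x2, n2, alpha),
      mn = mn_score_ci(x1, n1, x2, n2, alpha),
      cz = chan_zhang_ci(x1, n1, x2, n2, alpha)
    )
    tibble::tibble(method = m, low = bounds[1L], high = bounds[2L])
  })
  structure(
    list(
      labels = labels,
      x1 = x1, n1 = n1, x2 = x2, n2 = n2,
      p1 = x1 / n1, p2 = x2 / n2, diff = x1 / n1 - x2 / n2,
      z = if (is.null(zt)) NA_real_ else zt$z,
      p_value = if (is.null(zt)) NA_real_ else zt$p_value,
      h = cohen_h(x1, n1, x2, n2),
      alpha = alpha,
      ci = dplyr::bind_rows(ci)
    ),
    class = "prop_comparison"
  )
}

#' @export
print.prop_comparison <- function(x, ...) {
  cat("Two-sample proportion comparison\n")
  cat(sprintf(
    "  %s: %d/%d (%.4f)   %s: %d/%d (%.4f)\n",
    x$labels[1L], x$x1, x$n1, x$p1, x$labels[2L], x$x2, x$n2, x$p2
  ))
  cat(sprintf(
    "  diff = %.4f   pooled Z = %.3f   p = %.4g   Cohen h = %.3f\n",
    x$diff, x$z, x$p_value, x$h
  ))
  for (i in seq_len(nrow(x$ci))) {
    cat(sprintf(
      "  %2.0f%% CI [%s]  (%.4f, %.4f)\n",
      100 * (1 - x$alpha), x$ci$method[i], x$ci$low[i], x$ci$high[i]
    ))
  }
  invisible(x)
}

#' @export
as.data.frame.prop_comparison <- function(x, ...) {
  ci <- x$ci
  data.frame(
    method = ci$method,
    x1 = x$x1, n1 = x$n1, x2 = x$x2, n2 = x$n2,
    p1 = x$p1, p2 = x$p2, diff = x$diff,
    z = x$z, p_value = x$p_value, h = x$h,
    ci_low = ci$low, ci_high = ci$high, alpha = x$alpha
  )
}
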