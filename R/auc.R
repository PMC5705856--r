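#' Trapezoidal area under a trajectory
#'
#' `sum over adjacent pairs of (t[k+1] - t[k]) * (y[k] + y[k+1]) / 2`.
#'
#' @param time Strictly increasing numeric abscissae (period midpoints, in
#'   months).
#' @param y Trajectory values (proportions).
#' @return Scalar area.
#' @export
trapezoid_auc <- function(time, y) {
  if (length(time) < 2L || length(y) != length(time)) {
    stop_data("trapezoidal AUC needs at least two (time, y) points")
  }
  if (any(diff(time) <= 0)) stop_data("time points must be strictly increasing")
  sum(diff(time) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Convert two group AUCs to relative proportions
#'
#' `r_i = auc_i / (auc_1 + auc_2)`; the two shares sum to one exactly.
#'
#' @param auc1,auc2 Nonnegative areas, not both zero.
#' @return Numeric vector `c(r1, r2)`.
#' @export
relative_auc <- function(auc1, auc2) {
  if (auc1 < 0 || auc2 < 0) stop_data("AUC values must be nonnegative")
  tot <- auc1 + auc2
  if (tot == 0) stop_data("both AUCs are zero: relative proportions undefined")
  c(auc1, auc2) / tot
}

#' Proportional difference test on relative AUCs
#'
#' Converts the two arms' AUC shares into pseudo-counts
#' `(round(r_i * n_i), n_i)` and delegates to [compare_proportions()]
#' (pooled Z plus the requested intervals). The effective `n_i` is the
#' arm's total relevant denominator over the follow-up window (total
#' threshold symptoms for the improvement index, total assessed symptoms
#' for the threshold index); this approximates the original
#' proportional-difference computation, for which no exact sample-size
#' convention is published.
#'
#' @param auc1,auc2 Per-arm trapezoidal AUCs.
#' @param n1,n2 Effective per-arm denominators (positive integers).
#' @param alpha Two-sided significance level.
#' @param methods CI methods passed to [compare_proportions()].
#' @param labels Group labels.
#' @return An object of class `auc_comparison`: list with `auc`,
#'   `relative`, `effective_n` and the delegated `comparison`
#'   (`prop_comparison`).
#' @export
auc_difference_test <- function(auc1, auc2, n1, n2, alpha = 0.05,
                                methods = c("wald", "mn"),
                                labels = c("group1", "group2")) {
  if (n1 < 1 || n2 < 1) stop_data("effective n must be >= 1 per arm")
  r <- relative_auc(auc1, auc2)
  cmp <- compare_proportions(
    round(r[1L] * n1), n1, round(r[2L] * n2), n2,
    methods = methods, alpha = alpha, labels = labels
  )
  structure(
    list(
      auc = stats::setNames(c(auc1, auc2), labels),
      relative = stats::setNames(r, labels),
      effective_n = stats::setNames(c(n1, n2), labels),
      comparison = cmp
    ),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("Trapezoidal AUC comparison\n")
  cat(sprintf(
    "  AUC: %s = %.4f, %s = %.4f  (relative %.3f / %.3f, effective n %d / %d)\n",
    names(x$auc)[1L], x$auc[1L], names(x$auc)[2L], x$auc[2L],
    x$relative[1L], x$relative[2L], x$effective_n[1L], x$effective_n[2L]
  ))
  print(x$comparison)
  invisible(x)
}

#' AUC comparison of a bimonthly proportion index
#'
#' Builds the two arms' bimonthly trajectories from an aggregated index
#' (see [aggregate_bimonthly()]), computes their trapezoidal AUCs over the
#' period midpoints and runs the proportional difference test. For
#' `outcome = "threshold"` the trajectory is `n_threshold / n_assessed`;
#' for `"improved"` it is `n_improved / n_threshold`. Periods with a zero
#' denominator contribute no point.
#'
#' @param index Bimonthly index tibble.
#' @param outcome `"threshold"` or `"improved"`.
#' @param midpoints Month abscissae of the six periods (default odd
#'   months 1, 3, ..., 11, the bin centres).
#' @inheritParams auc_difference_test
#' @return An `auc_comparison`; its `trajectories` element holds the
#'   per-arm points used.
#' @export
auc_compare_index <- function(index, outcome = c("threshold", "improved"),
                              midpoints = c(1, 3, 5, 7, 9, 11),
                              alpha = 0.05, methods = c("wald", "mn")) {
  outcome <- match.arg(outcome)
  per <- dplyr::filter(index, !is.na(.data$period))
  tot <- dplyr::filter(index, is.na(.data$period))
  num_col <- if (outcome == "threshold") "n_threshold" else "n_improved"
  den_col <- if (outcome == "threshold") "n_assessed" else "n_threshold"
  arms <- c("CONTROL", "ALERT")
  traj <- lapply(stats::setNames(arms, arms), function(a) {
    g <- dplyr::filter(per, .data$arm == a, .data[[den_col]] > 0)
    tibble::tibble(
      month = midpoints[g$period],
      proportion = g[[num_col]] / g[[den_col]],
      weight = g[[den_col]]
    )
  })
  aucs <- vapply(traj, function(tr) trapezoid_auc(tr$month, tr$proportion), numeric(1))
  eff_n <- vapply(stats::setNames(arms, arms), function(a) {
    row <- dplyr::filter(tot, .data$arm == a)
    if (nrow(row) == 1L) row[[den_col]] else sum(dplyr::filter(per, .data$arm == a)[[den_col]])
  }, numeric(1))
  out <- auc_difference_test(
    aucs[["CONTROL"]], aucs[["ALERT"]],
    eff_n[["CONTROL"]], eff_n[["ALERT"]],
    alpha = alpha, methods = methods, labels = arms
  )
  out$outcome <- outcome
  out$trajectories <- traj
  out
}
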