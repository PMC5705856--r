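#' Format a count cell as "n/N (%)"
#'
#' Percentages carry two decimals when the denominator is at least 1000
#' and one decimal otherwise, mirroring the mixed precision of published
#' bimonthly tables; a zero denominator renders as "0/0 (-)".
#'
#' @param x Numerator count(s).
#' @param n Denominator count(s).
#' @return Character vector.
#' @examples
#' format_count_cell(1269, 8810) # "1269/8810 (14.40)"
#' format_count_cell(14, 350) # "14/350 (4.0)"
#' @export
format_count_cell <- function(x, n) {
  mapply(function(xi, ni) {
    if (ni == 0) return(sprintf("%d/0 (-)", xi))
    digits <- if (ni >= 1000) 2L else 1L
    sprintf("%d/%d (%.*f)", xi, ni, digits, 100 * xi / ni)
  }, x, n, USE.NAMES = FALSE)
}

#' Render a data frame as an aligned text table
#'
#' @param tbl Data frame of printable columns.
#' @param title Optional heading line.
#' @return Character vector of lines.
#' @export
render_table <- function(tbl, title = NULL) {
  cols <- lapply(names(tbl), function(nm) {
    format(c(nm, as.character(tbl[[nm]])), justify = "left")
  })
  lines <- do.call(paste, c(cols, sep = "  "))
  lines <- c(lines[1L], strrep("-", nchar(lines[1L])), lines[-1L])
  c(title, lines)
}

period_label <- function(period) {
  ifelse(is.na(period), "Total", paste0("Month ", 2L * period))
}

# one published-style table: per-period cells per arm plus Cohen h
build_proportion_table <- function(index, num_col, den_col) {
  wide <- index |>
    dplyr::mutate(
      cell = format_count_cell(.data[[num_col]], .data[[den_col]]),
      x = .data[[num_col]], n = .data[[den_col]]
    ) |>
    dplyr::select("arm", "period", "cell", "x", "n") |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("cell", "x", "n"))
  h <- mapply(function(x1, n1, x2, n2) {
    if (n1 == 0 || n2 == 0) NA_real_ else cohen_h(x1, n1, x2, n2)
  }, wide$x_CONTROL, wide$n_CONTROL, wide$x_ALERT, wide$n_ALERT)
  tibble::tibble(
    period = period_label(wide$period),
    CONTROL = wide$cell_CONTROL,
    ALERT = wide$cell_ALERT,
    effect_size = ifelse(is.na(h), "-", sprintf("%.2f", h))
  )
}

#' Run the full check-in analysis pipeline
#'
#' Ingests a check-in CSV or simulates a cohort, applies the eligibility
#' rule, labels transitions, aggregates bimonthly indices, and produces
#' the trial's report set: per-period reporting-caregiver counts, the
#' threshold/assessed and improved/threshold proportion tables with Cohen
#' h effect sizes, the pretest versus first-check-in response-bias
#' contrast (including the two-group McNemar statistic), totals-based
#' proportion comparisons, and the AUC trajectory comparisons. When
#' `output_dir` is given the bundle is written there (CSV tables, a plain
#' text report, and a JSON manifest recording configuration, seed and
#' package version, from which every number is reproducible).
#'
#' @param config A [cohort_config()] for simulation (exclusive with
#'   `input`).
#' @param input Path to a check-in CSV (exclusive with `config`).
#' @param output_dir Optional directory for the written bundle.
#' @param terminal_policy Passed to [aggregate_bimonthly()].
#' @param bin_days Passed to [aggregate_bimonthly()].
#' @param alpha Two-sided significance level.
#' @param methods CI methods for the comparisons.
#' @return A list of class `checkin_report` with elements `records`,
#'   `exclusions`, `caregiver_counts`, `index`, `alerts`,
#'   `threshold_table`, `improved_table`, `bias`, `volume`, `totals`,
#'   `auc`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, input = NULL, output_dir = NULL,
                         terminal_policy = c("include", "exclude"),
                         bin_days = 61L, alpha = 0.05,
                         methods = c("wald", "mn")) {
  terminal_policy <- match.arg(terminal_policy)
  if (is.null(config) == is.null(input)) {
    stop_config("specify exactly one of `config` (simulate) or `input` (CSV path)")
  }
  records <- if (!is.null(input)) read_checkins(input) else generate_cohort(config)

  eligible <- filter_eligible(records)
  exclusions <- attr(eligible, "exclusions")
  transitions <- label_transitions(eligible)
  index <- aggregate_bimonthly(transitions, bin_days = bin_days, terminal_policy = terminal_policy)
  alerts <- emit_alerts(records)
  volume <- per_caregiver_volume(eligible)

  # reporting caregivers per period (pretest counts all enrolled dyads)
  pretest_counts <- records |>
    dplyr::filter(.data$source == "PRETEST") |>
    dplyr::distinct(.data$dyad_id, .data$arm) |>
    dplyr::count(.data$arm, name = "n_caregivers") |>
    dplyr::mutate(period = NA_integer_, stage = "Pretest")
  period_counts <- transitions |>
    dplyr::filter(.data$day <= 6L * bin_days) |>
    dplyr::mutate(period = pmin(as.integer(ceiling(.data$day / bin_days)), 6L)) |>
    dplyr::distinct(.data$arm, .data$period, .data$dyad_id) |>
    dplyr::count(.data$arm, .data$period, name = "n_caregivers") |>
    dplyr::mutate(stage = period_label(.data$period))
  caregiver_counts <- dplyr::bind_rows(pretest_counts, period_counts) |>
    dplyr::select("arm", "stage", "n_caregivers")

  threshold_table <- build_proportion_table(index, "n_threshold", "n_assessed")
  improved_table <- build_proportion_table(index, "n_improved", "n_threshold")

  # response-bias contrast: pretest vs first online check-in
  pc <- paired_change_counts(eligible)
  pairs <- attr(pc, "pairs")
  bias_stage <- function(col, stage) {
    per_arm <- pairs |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(x = sum(.data[[col]] >= 7L), n = dplyr::n(), .groups = "drop")
    ctl <- dplyr::filter(per_arm, .data$arm == "CONTROL")
    alt <- dplyr::filter(per_arm, .data$arm == "ALERT")
    z <- tryCatch(
      pooled_z_test(ctl$x, ctl$n, alt$x, alt$n),
      carealert_data_error = function(e) NULL
    )
    tibble::tibble(
      stage = stage,
      CONTROL = format_count_cell(ctl$x, ctl$n),
      ALERT = format_count_cell(alt$x, alt$n),
      effect_size = sprintf("%.2f", cohen_h(ctl$x, ctl$n, alt$x, alt$n)),
      p_value = if (is.null(z)) NA_real_ else z$p_value
    )
  }
  bias_table <- dplyr::bind_rows(
    bias_stage("pre_rating", "Pretest"),
    bias_stage("first_rating", "Initial check-in")
  )
  bias_mcnemar <- tryCatch(
    mcnemar_two_group(pc$CONTROL, pc$ALERT),
    carealert_data_error = function(e) NULL
  )

  # degenerate inputs (e.g. no threshold symptoms in an arm) yield NULL
  # entries rather than aborting the bundle
  soft <- function(expr) {
    tryCatch(expr,
      carealert_data_error = function(e) NULL,
      carealert_config_error = function(e) NULL
    )
  }
  totals <- dplyr::filter(index, is.na(.data$period))
  tot <- function(col, a) totals[[col]][totals$arm == a]
  totals_cmp <- list(
    threshold = soft(compare_proportions(
      tot("n_threshold", "CONTROL"), tot("n_assessed", "CONTROL"),
      tot("n_threshold", "ALERT"), tot("n_assessed", "ALERT"),
      methods = methods, alpha = alpha, labels = c("CONTROL", "ALERT")
    )),
    improved = soft(compare_proportions(
      tot("n_improved", "CONTROL"), tot("n_threshold", "CONTROL"),
      tot("n_improved", "ALERT"), tot("n_threshold", "ALERT"),
      methods = methods, alpha = alpha, labels = c("CONTROL", "ALERT")
    ))
  )
  auc <- list(
    threshold = soft(auc_compare_index(index, "threshold", alpha = alpha, methods = methods)),
    improved = soft(auc_compare_index(index, "improved", alpha = alpha, methods = methods))
  )

  manifest <- list(
    package = "carealert",
    version = as.character(utils::packageVersion("carealert")),
    source = if (!is.null(input)) list(input = input) else list(config = unclass(config)),
    terminal_policy = terminal_policy,
    bin_days = bin_days,
    alpha = alpha,
    methods = methods
  )

  bundle <- structure(
    list(
      records = records, exclusions = exclusions,
      caregiver_counts = caregiver_counts, index = index, alerts = alerts,
      threshold_table = threshold_table, improved_table = improved_table,
      bias = list(table = bias_table, change_tables = pc[], mcnemar = bias_mcnemar),
      volume = volume, totals = totals_cmp, auc = auc, manifest = manifest
    ),
    class = "checkin_report"
  )
  if (!is.null(output_dir)) write_report_bundle(bundle, output_dir, simulated = is.null(input))
  bundle
}

write_report_bundle <- function(bundle, output_dir, simulated) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  if (simulated) write_checkins(bundle$records, p("checkins.csv"))
  readr::write_csv(bundle$index, p("bimonthly_index.csv"))
  readr::write_csv(bundle$alerts, p("alerts.csv"))
  readr::write_csv(bundle$caregiver_counts, p("caregiver_counts.csv"))
  readr::write_csv(bundle$exclusions, p("exclusions.csv"))
  cmp_parts <- list(
    threshold = bundle$totals$threshold,
    improved = bundle$totals$improved,
    auc_threshold = bundle$auc$threshold$comparison,
    auc_improved = bundle$auc$improved$comparison
  )
  cmp_parts <- Filter(Negate(is.null), cmp_parts)
  if (length(cmp_parts)) {
    cmp <- dplyr::bind_rows(lapply(names(cmp_parts), function(nm) {
      dplyr::mutate(as.data.frame(cmp_parts[[nm]]), outcome = nm)
    }))
    readr::write_csv(cmp, p("comparisons.csv"))
  }
  jsonlite::write_json(
    bundle$manifest, p("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  lines <- c(
    render_table(bundle$threshold_table, "Threshold symptoms / assessed symptoms"),
    "",
    render_table(bundle$improved_table, "Improved threshold symptoms / threshold symptoms"),
    "",
    render_table(
      dplyr::mutate(bundle$bias$table, p_value = sprintf("%.3g", .data$p_value)),
      "Threshold symptoms at pretest vs initial check-in"
    )
  )
  if (!is.null(bundle$bias$mcnemar)) {
    lines <- c(lines, sprintf(
      "Two-group McNemar (net shift toward fewer thresholds, ALERT - CONTROL): z = %.3f, p = %.3g",
      bundle$bias$mcnemar$z, bundle$bias$mcnemar$p_value
    ))
  }
  writeLines(lines, p("report.txt"))
  invisible(output_dir)
}

#' @export
print.checkin_report <- function(x, ...) {
  writeLines(render_table(x$threshold_table, "Threshold symptoms / assessed symptoms"))
  cat("\n")
  writeLines(render_table(x$improved_table, "Improved threshold symptoms / threshold symptoms"))
  if (!is.null(x$totals$improved)) {
    cat("\nTotals (improved threshold symptoms):\n")
    print(x$totals$improved)
  }
  invisible(x)
}

#' Plot bimonthly proportion trajectories
#'
#' Simple per-arm trajectory figure of a bimonthly proportion index.
#' Requires ggplot2.
#'
#' @param auc_cmp An `auc_comparison` from [auc_compare_index()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(auc_cmp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ggplot2 is required for plotting")
  }
  df <- dplyr::bind_rows(auc_cmp$trajectories, .id = "arm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$proportion, colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(1, 11, 2)) +
    ggplot2::labs(
      x = "Month (period midpoint)",
      y = if (identical(auc_cmp$outcome, "improved")) {
        "Improved / threshold symptoms"
      } else {
        "Threshold / assessed symptoms"
      },
      colour = "Arm"
    ) +
    ggplot2::theme_minimal()
}
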