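#' Apply the minimum-data eligibility rule
#'
#' Caregivers who completed fewer than two online check-ins supply no
#' before/after pair and are excluded from the longitudinal analysis: all
#' their ONLINE records are dropped. PRETEST records are always retained
#' (the response-bias analysis needs them). The removed caregivers are
#' recorded in the `"exclusions"` attribute of the result.
#'
#' @param records Check-in tibble.
#' @return The filtered tibble, with attribute `exclusions` (a tibble of
#'   `dyad_id`, `n_online_checkins`).
#' @export
filter_eligible <- function(records) {
  online <- dplyr::filter(records, .data$source == "ONLINE")
  counts <- dplyr::count(
    dplyr::distinct(online, .data$dyad_id, .data$checkin_index),
    .data$dyad_id,
    name = "n_online_checkins"
  )
  excluded <- dplyr::filter(counts, .data$n_online_checkins < 2L)
  out <- dplyr::filter(
    records,
    .data$source != "ONLINE" | !.data$dyad_id %in% excluded$dyad_id
  )
  attr(out, "exclusions") <- excluded
  out
}

#' Label threshold status and one-step transitions
#'
#' Produces one row per (dyad, symptom, online check-in). A rating >= 7 is
#' a threshold symptom. The transition compares the rating with the same
#' symptom's rating at the immediately following completed online check-in,
#' regardless of the calendar gap: strictly lower is `IMPROVED`, strictly
#' higher `WORSENED`, equal `SAME`; the final check-in of a dyad, which has
#' nothing to compare against, is `TERMINAL`.
#'
#' @param records Eligible check-in tibble (see [filter_eligible()]).
#' @return A tibble with `dyad_id`, `arm`, `symptom`, `checkin_index`,
#'   `day`, `rating`, `is_threshold`, `next_rating`, `transition`.
#' @export
label_transitions <- function(records) {
  online <- dplyr::filter(records, .data$source == "ONLINE")
  if (anyDuplicated(online[c("dyad_id", "checkin_index", "symptom")])) {
    stop_data("duplicate (dyad_id, checkin_index, symptom) among online records")
  }
  online |>
    dplyr::arrange(.data$dyad_id, .data$symptom, .data$checkin_index) |>
    dplyr::group_by(.data$dyad_id, .data$symptom) |>
    dplyr::mutate(next_rating = dplyr::lead(.data$rating)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      is_threshold = .data$rating >= 7L,
      transition = dplyr::case_when(
        is.na(.data$next_rating) ~ "TERMINAL",
        .data$next_rating < .data$rating ~ "IMPROVED",
        .data$next_rating > .data$rating ~ "WORSENED",
        TRUE ~ "SAME"
      )
    ) |>
    dplyr::select(
      "dyad_id", "arm", "symptom", "checkin_index", "day", "rating",
      "is_threshold", "next_rating", "transition"
    )
}

#' Aggregate labelled transitions into bimonthly indices
#'
#' Check-ins are assigned to six fixed-width periods of `bin_days` days
#' (period `ceiling(day / bin_days)`, clamped to 1-6); check-ins beyond the
#' 12-month window (`day > 6 * bin_days`) are discarded with a warning.
#' Counts per arm x period: `n_assessed` (all rated symptoms, ten per
#' check-in), `n_threshold` (ratings >= 7) and its improved/same/worsened
#' decomposition. A totals row per arm (`period = NA`) is appended.
#'
#' Terminal threshold observations have no follow-up rating. Under
#' `terminal_policy = "include"` (default) they stay in `n_threshold` and
#' are tallied under `n_same`, so the improvement denominator equals the
#' threshold count; under `"exclude"` they are dropped from `n_threshold`
#' and the decomposition (never from `n_assessed`).
#'
#' @param transitions Output of [label_transitions()].
#' @param bin_days Period width in days (default 61; 6 x 61 = 366 covers a
#'   year).
#' @param terminal_policy `"include"` or `"exclude"`.
#' @return A tibble with `arm`, `period` (1-6, `NA` = total), `n_assessed`,
#'   `n_threshold`, `n_improved`, `n_same`, `n_worsened`.
#' @export
aggregate_bimonthly <- function(transitions, bin_days = 61L,
                                terminal_policy = c("include", "exclude")) {
  terminal_policy <- match.arg(terminal_policy)
  if (any(transitions$day <= 0L)) {
    stop_data("online check-ins must have day >= 1")
  }
  over <- transitions$day > 6L * bin_days
  if (any(over)) {
    warning(sum(over), " observation(s) beyond day ", 6L * bin_days, " discarded")
    transitions <- transitions[!over, , drop = FALSE]
  }
  transitions$period <- pmin(as.integer(ceiling(transitions$day / bin_days)), 6L)

  count_one <- function(df) {
    thr <- df$is_threshold
    if (terminal_policy == "exclude") thr <- thr & df$transition != "TERMINAL"
    tibble::tibble(
      n_assessed = nrow(df),
      n_threshold = sum(thr),
      n_improved = sum(thr & df$transition == "IMPROVED"),
      n_same = sum(thr & df$transition %in% c("SAME", "TERMINAL")),
      n_worsened = sum(thr & df$transition == "WORSENED")
    )
  }
  by_period <- transitions |>
    dplyr::group_by(.data$arm, .data$period) |>
    dplyr::group_modify(~count_one(.x)) |>
    dplyr::ungroup()
  totals <- transitions |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(~count_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(period = NA_integer_, .after = "arm")
  dplyr::arrange(dplyr::bind_rows(by_period, totals), .data$arm, is.na(.data$period), .data$period)
}

#' List clinician alert events
#'
#' In the ALERT arm every completed online check-in containing at least one
#' rating at or above the severity threshold 7 triggers one alert listing
#' all such symptoms. CONTROL-arm check-ins never alert (their reports were
#' not sent to clinicians).
#'
#' @param records Check-in tibble.
#' @return A tibble with `dyad_id`, `day`, `symptom`, `rating` (one row per
#'   alerted symptom; rows sharing `dyad_id` and `day` form one alert).
#' @export
emit_alerts <- function(records) {
  records |>
    dplyr::filter(.data$arm == "ALERT", .data$source == "ONLINE", .data$rating >= 7L) |>
    dplyr::select("dyad_id", "day", "symptom", "rating") |>
    dplyr::arrange(.data$dyad_id, .data$day, .data$symptom)
}

#' Per-caregiver reporting volume
#'
#' Number of assessed symptoms (ten per completed online check-in) per
#' reporting caregiver, and the per-arm mean over caregivers with at least
#' one retained check-in. This is the contrast behind "symptoms reported
#' per reporting caregiver" in reporting-bias summaries.
#'
#' @param records Eligible check-in tibble.
#' @return A list with `per_dyad` (tibble of `dyad_id`, `arm`,
#'   `n_checkins`, `n_assessed`) and `per_arm` (tibble of `arm`,
#'   `n_caregivers`, `total_assessed`, `mean_assessed`).
#' @export
per_caregiver_volume <- function(records) {
  per_dyad <- records |>
    dplyr::filter(.data$source == "ONLINE") |>
    dplyr::distinct(.data$dyad_id, .data$arm, .data$checkin_index) |>
    dplyr::count(.data$dyad_id, .data$arm, name = "n_checkins") |>
    dplyr::mutate(n_assessed = 10L * .data$n_checkins)
  per_arm <- per_dyad |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_caregivers = dplyr::n(),
      total_assessed = sum(.data$n_assessed),
      mean_assessed = mean(.data$n_assessed),
      .groups = "drop"
    )
  list(per_dyad = per_dyad, per_arm = per_arm)
}

#' Paired pretest vs first-check-in change tables
#'
#' For each arm, cross-classifies every (dyad, symptom) pair observed both
#' at pretest and at the dyad's first completed online check-in by
#' threshold status (rating >= 7) at the two occasions, yielding the 2x2
#' change table consumed by [mcnemar_two_group()]. Only dyads with both a
#' pretest record and at least one online record contribute.
#'
#' @param records Check-in tibble (apply [filter_eligible()] first to match
#'   the analysed population).
#' @return Named list of 2x2 matrices (`CONTROL`, `ALERT`), rows = pretest
#'   `threshold`/`non_threshold`, columns = first check-in status. The
#'   `"pairs"` attribute holds the underlying paired tibble.
#' @export
paired_change_counts <- function(records) {
  pre <- records |>
    dplyr::filter(.data$source == "PRETEST") |>
    dplyr::select("dyad_id", "arm", "symptom", pre_rating = "rating")
  first_on <- records |>
    dplyr::filter(.data$source == "ONLINE") |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::filter(.data$checkin_index == min(.data$checkin_index)) |>
    dplyr::ungroup() |>
    dplyr::select("dyad_id", "symptom", first_rating = "rating")
  pairs <- dplyr::inner_join(pre, first_on, by = c("dyad_id", "symptom"))
  lv <- c("threshold", "non_threshold")
  tabs <- lapply(c(CONTROL = "CONTROL", ALERT = "ALERT"), function(a) {
    g <- dplyr::filter(pairs, .data$arm == a)
    table(
      pretest = factor(ifelse(g$pre_rating >= 7L, lv[1L], lv[2L]), levels = lv),
      checkin = factor(ifelse(g$first_rating >= 7L, lv[1L], lv[2L]), levels = lv)
    ) |> unclass()
  })
  attr(tabs, "pairs") <- pairs
  tabs
}
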