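test_that("caregivers with fewer than two online check-ins lose their online records only", {
  one <- make_dyad("d1", "CONTROL", rbind(rating_row(pain = 8)), pretest = rating_row())
  two <- make_dyad("d2", "CONTROL", rbind(rating_row(), rating_row()), pretest = rating_row())
  rec <- dplyr::bind_rows(one, two)
  out <- filter_eligible(rec)
  expect_false(any(out$dyad_id == "d1" & out$source == "ONLINE"))
  expect_true(any(out$dyad_id == "d1" & out$source == "PRETEST"))
  expect_equal(sum(out$dyad_id == "d2"), 30L) # boundary case fully retained
  expect_equal(attr(out, "exclusions")$dyad_id, "d1")

  all_ok <- dplyr::bind_rows(two, make_dyad("d3", "ALERT", rbind(rating_row(), rating_row())))
  expect_equal(nrow(filter_eligible(all_ok)), nrow(all_ok))
  expect_equal(nrow(filter_eligible(rec[0, ])), 0L)
})

test_that("transition labels follow the one-step improvement definition", {
  rec <- make_dyad("d1", "ALERT", rbind(
    rating_row(pain = 9, nausea = 7, fatigue = 7),
    rating_row(pain = 8, nausea = 6, fatigue = 7),
    rating_row(pain = 8, nausea = 6, fatigue = 9)
  ))
  tr <- label_transitions(rec)
  get <- function(sym, idx) tr[tr$symptom == sym & tr$checkin_index == idx, ]

  expect_true(get("pain", 0)$is_threshold)
  expect_equal(get("pain", 0)$transition, "IMPROVED") # 9 then 8
  expect_equal(get("nausea", 0)$transition, "IMPROVED") # 7 then 6
  expect_false(get("nausea", 1)$is_threshold)
  expect_equal(get("fatigue", 0)$transition, "SAME") # tie is not improvement
  expect_equal(get("fatigue", 1)$transition, "WORSENED")
  expect_equal(get("pain", 2)$transition, "TERMINAL") # last check-in
  expect_equal(nrow(tr), 30L)

  dup <- dplyr::bind_rows(rec, rec[11, ])
  expect_error(label_transitions(dup), class = "carealert_data_error")
})

test_that("bimonthly aggregation reproduces a hand-counted example", {
  rec <- make_dyad("d1", "CONTROL", rbind(
    rating_row(pain = 8),
    rating_row(pain = 5)
  ), days = c(7, 14))
  idx <- aggregate_bimonthly(label_transitions(rec))
  p1 <- idx[!is.na(idx$period) & idx$period == 1, ]
  expect_equal(p1$n_assessed, 20L)
  expect_equal(p1$n_threshold, 1L)
  expect_equal(p1$n_improved, 1L)
  expect_equal(p1$n_same + p1$n_worsened, 0L)
  total <- idx[is.na(idx$period), ]
  expect_equal(total$n_assessed, 20L)
})

test_that("terminal threshold observations follow the configured policy", {
  rec <- make_dyad("d1", "CONTROL", rbind(
    rating_row(pain = 9),
    rating_row(pain = 8) # terminal, still at threshold
  ), days = c(7, 14))
  tr <- label_transitions(rec)

  inc <- aggregate_bimonthly(tr, terminal_policy = "include")
  inc1 <- inc[!is.na(inc$period) & inc$period == 1, ]
  expect_equal(inc1$n_threshold, 2L)
  expect_equal(inc1$n_improved, 1L)
  expect_equal(inc1$n_same, 1L) # terminal tallied as no-change
  expect_equal(inc1$n_improved + inc1$n_same + inc1$n_worsened, inc1$n_threshold)

  exc <- aggregate_bimonthly(tr, terminal_policy = "exclude")
  exc1 <- exc[!is.na(exc$period) & exc$period == 1, ]
  expect_equal(exc1$n_threshold, 1L)
  expect_equal(exc1$n_improved, 1L)
  expect_equal(exc1$n_assessed, inc1$n_assessed) # n_assessed never changes
})

test_that("aggregation guards the analysis window", {
  rec <- make_dyad("d1", "CONTROL", rbind(rating_row(), rating_row()), days = c(7, 400))
  tr <- label_transitions(rec)
  expect_warning(idx <- aggregate_bimonthly(tr), "discarded")
  expect_equal(idx$n_assessed[is.na(idx$period)], 10L)

  bad <- tr
  bad$day[1] <- 0L
  expect_error(aggregate_bimonthly(bad), class = "carealert_data_error")
})

test_that("counts partition and scale with check-ins on a generated cohort", {
  cfg <- cohort_config(n_dyads_per_arm = 15, study_days = 180, seed = 33)
  rec <- filter_eligible(generate_cohort(cfg))
  tr <- label_transitions(rec)
  idx <- aggregate_bimonthly(tr)
  expect_true(all(idx$n_improved + idx$n_same + idx$n_worsened == idx$n_threshold))
  expect_true(all(idx$n_threshold <= idx$n_assessed))
  expect_true(all(idx$n_assessed %% 10L == 0L))
  n_checkins <- nrow(dplyr::distinct(dplyr::filter(rec, source == "ONLINE"), dyad_id, checkin_index))
  expect_equal(sum(idx$n_assessed[is.na(idx$period)]), 10L * n_checkins)
})

test_that("alerts fire exactly for ALERT-arm check-ins containing threshold ratings", {
  alert <- make_dyad("a1", "ALERT", rbind(
    rating_row(pain = 7, nausea = 9),
    rating_row()
  ), days = c(7, 14))
  control <- make_dyad("c1", "CONTROL", rbind(rating_row(pain = 10), rating_row(pain = 10)))
  ev <- emit_alerts(dplyr::bind_rows(alert, control))
  expect_equal(nrow(ev), 2L) # one event listing both symptoms of concern
  expect_setequal(ev$symptom, c("pain", "nausea"))
  expect_true(all(ev$dyad_id == "a1" & ev$day == 7L))
  expect_true(all(ev$rating >= 7L))

  # every ALERT-arm threshold observation belongs to exactly one event row
  cfg <- cohort_config(n_dyads_per_arm = 10, study_days = 90, seed = 12)
  rec <- generate_cohort(cfg)
  tr <- label_transitions(filter_eligible(rec))
  thr <- dplyr::filter(tr, arm == "ALERT", is_threshold)
  ev2 <- emit_alerts(rec)
  joined <- dplyr::inner_join(
    thr, dplyr::mutate(ev2, alerted = TRUE),
    by = c("dyad_id", "day", "symptom", "rating")
  )
  expect_equal(nrow(joined), nrow(thr))
})

test_that("per-caregiver reporting volume averages assessed symptoms over reporters", {
  rec <- dplyr::bind_rows(
    make_dyad("c1", "CONTROL", rbind(rating_row(), rating_row(), rating_row())),
    make_dyad("c2", "CONTROL", rbind(rating_row(), rating_row())),
    make_dyad("a1", "ALERT", rbind(rating_row(), rating_row()))
  )
  vol <- per_caregiver_volume(rec)
  expect_equal(vol$per_dyad$n_assessed[vol$per_dyad$dyad_id == "c1"], 30L)
  ctl <- vol$per_arm[vol$per_arm$arm == "CONTROL", ]
  expect_equal(ctl$n_caregivers, 2L)
  expect_equal(ctl$mean_assessed, 25)
})

test_that("paired change tables cross-classify pretest and first check-in status", {
  rec <- dplyr::bind_rows(
    make_dyad("c1", "CONTROL",
      rbind(rating_row(pain = 8, nausea = 2), rating_row()),
      pretest = rating_row(pain = 9, fatigue = 7)
    ),
    make_dyad("a1", "ALERT",
      rbind(rating_row(), rating_row()),
      pretest = rating_row(anxiety = 8)
    )
  )
  pc <- paired_change_counts(rec)
  expect_equal(pc$CONTROL["threshold", "threshold"], 1) # pain stays >= 7
  expect_equal(pc$CONTROL["threshold", "non_threshold"], 1) # fatigue drops
  expect_equal(pc$CONTROL["non_threshold", "non_threshold"], 8)
  expect_equal(sum(pc$CONTROL), 10)
  expect_equal(pc$ALERT["threshold", "non_threshold"], 1)
  expect_equal(sum(pc$ALERT), 10)
})
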