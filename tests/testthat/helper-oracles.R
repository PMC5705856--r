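# Independent brute-force oracles used against the package implementation.

# Recount bimonthly indices directly from raw CSV rows with base R loops,
# independently of the dplyr pipeline.
oracle_recount <- function(path, bin_days = 61, terminal_policy = "include") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  on <- df[df$source == "ONLINE", , drop = FALSE]
  acc <- list()
  bump <- function(arm, period, field, by = 1L) {
    key <- paste(arm, period, sep = "|")
    if (is.null(acc[[key]])) {
      acc[[key]] <<- c(n_assessed = 0L, n_threshold = 0L, n_improved = 0L,
                       n_same = 0L, n_worsened = 0L)
    }
    acc[[key]][field] <<- acc[[key]][field] + by
  }
  for (dyad in unique(on$dyad_id)) {
    drec <- on[on$dyad_id == dyad, , drop = FALSE]
    if (length(unique(drec$checkin_index)) < 2L) next # eligibility rule
    arm <- drec$arm[1L]
    for (sym in unique(drec$symptom)) {
      srec <- drec[drec$symptom == sym, , drop = FALSE]
      srec <- srec[order(srec$checkin_index), , drop = FALSE]
      for (i in seq_len(nrow(srec))) {
        day <- srec$day[i]
        if (day > 6 * bin_days) next
        period <- min(ceiling(day / bin_days), 6)
        r <- srec$rating[i]
        terminal <- i == nrow(srec)
        for (per in c(period, "ALL")) {
          bump(arm, per, "n_assessed")
          if (r >= 7) {
            if (terminal && terminal_policy == "exclude") next
            bump(arm, per, "n_threshold")
            if (terminal) {
              bump(arm, per, "n_same")
            } else {
              nxt <- srec$rating[i + 1L]
              if (nxt < r) bump(arm, per, "n_improved")
              if (nxt == r) bump(arm, per, "n_same")
              if (nxt > r) bump(arm, per, "n_worsened")
            }
          }
        }
      }
    }
  }
  keys <- names(acc)
  out <- data.frame(
    arm = sub("\\|.*", "", keys),
    period = sub(".*\\|", "", keys),
    do.call(rbind, acc),
    row.names = NULL
  )
  out$period[out$period == "ALL"] <- NA
  out$period <- as.integer(out$period)
  out[order(out$arm, is.na(out$period), out$period), , drop = FALSE]
}

# Discretised-normal mass of ratings >= thr via quadrature of the density
# over the rounding/clamping map (independent of any closed-form tail).
oracle_threshold_mass <- function(mean, sd, thr = 7) {
  x <- seq(mean - 12 * sd, mean + 12 * sd, length.out = 400001)
  w <- stats::dnorm(x, mean, sd)
  w <- w / sum(w)
  r <- pmin(10, pmax(0, round(x)))
  sum(w[r >= thr])
}

# Grid inversion of the MN score statistic: keep deltas not rejected.
oracle_mn_grid_ci <- function(x1, n1, x2, n2, alpha = 0.05, step = 1e-5) {
  d <- seq(-1 + step, 1 - step, by = step)
  z <- mn_score_z(x1, n1, x2, n2, d)
  keep <- abs(z) <= stats::qnorm(1 - alpha / 2)
  c(min(d[keep]), max(d[keep]))
}

# Build long-format check-in records for one dyad from a ratings matrix
# (rows = check-ins, cols = 10 symptoms).
make_dyad <- function(dyad_id, arm, ratings, days = NULL, pretest = NULL,
                      symptoms = carealert::esas_symptoms) {
  ratings <- as.matrix(ratings)
  stopifnot(ncol(ratings) == 10L)
  if (is.null(days)) days <- 7L * seq_len(nrow(ratings))
  rows <- list()
  idx <- 0L
  if (!is.null(pretest)) {
    rows[[1L]] <- tibble::tibble(
      dyad_id = dyad_id, arm = arm, checkin_index = 0L, day = 0L,
      source = "PRETEST", symptom = symptoms, rating = as.integer(pretest)
    )
    idx <- 1L
  }
  for (i in seq_len(nrow(ratings))) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      dyad_id = dyad_id, arm = arm, checkin_index = idx + i - 1L,
      day = as.integer(days[i]), source = "ONLINE", symptom = symptoms,
      rating = as.integer(ratings[i, ])
    )
  }
  dplyr::bind_rows(rows)
}

# Quiet ratings row: all symptoms low except named overrides.
rating_row <- function(...) {
  r <- stats::setNames(rep(1L, 10L), carealert::esas_symptoms)
  ov <- c(...)
  r[names(ov)] <- as.integer(ov)
  r
}
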