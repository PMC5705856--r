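#' Default symptom names of the modified ESAS
#'
#' The ten items of the modified Edmonton Symptom Assessment Scale used at
#' each check-in: three physical items of the original scale (activity,
#' drowsiness, well-being) are replaced by fatigue, constipation and
#' diarrhea. Names are configurable via [cohort_config()]; the count is
#' fixed at ten.
#'
#' @format Character vector of length 10.
#' @export
esas_symptoms <- c(
  "pain", "fatigue", "nausea", "depression", "anxiety", "appetite",
  "shortness_of_breath", "constipation", "diarrhea", "sleep"
)

#' Configuration for a synthetic caregiver check-in cohort
#'
#' Defines the generative law of [generate_cohort()]. Each dyad (patient +
#' family caregiver) completes a paper pretest at enrollment and then online
#' check-ins every `checkin_interval_days` days, rating the ten symptoms on
#' a 0-10 severity scale. Ratings arise from a stationary latent Gaussian
#' process per (dyad, symptom): a persistent component with marginal
#' `N(baseline_mean, baseline_sd^2)` and lag-one serial correlation
#' `persistence`, plus independent transient noise with sd `shock_sd`;
#' the sum is rounded to the nearest integer and clamped to 0-10. Rounding
#' realises the carry-forward behaviour of the instrument: a rating changes
#' between consecutive check-ins only when the latent process moves it by
#' at least one level.
#'
#' The ALERT arm carries the trial's two hypothesised reporting-bias
#' mechanisms: each due online check-in is completed only with probability
#' `bias_report_prob`, and online latent values are shifted by
#' `bias_rating_shift` (<= 0) before rounding. Pretest records are never
#' thinned or shifted (pretest ratings were not forwarded to clinicians).
#' Clinical response to alerts is modelled memorylessly: a symptom rated at
#' or above the alert threshold 7 has its next rating forced strictly lower
#' with probability `improvement_prob_given_alert` in the ALERT arm
#' (`improvement_prob_control` in CONTROL), and otherwise forced not lower.
#' Setting an improvement probability to `NA` disables the override for
#' that arm, leaving the pure latent process.
#'
#' Defaults reproduce the pooled trial's observed conditions: ~110 dyads
#' per arm followed 12 months at a weekly cadence, a baseline law giving
#' about 17.5% threshold symptoms at pretest, improvement probabilities
#' 0.53 (alert) and 0.26 (control) as observed in the aggregate totals,
#' per-check-in attrition of 2%, and ALERT-arm report probability 0.65
#' matching the observed ratio of completed symptom reports.
#'
#' @param n_dyads_per_arm Positive integer; dyads randomised to each arm.
#' @param study_days Integer; follow-up window in days (default 365).
#' @param checkin_interval_days Integer; days between due check-ins.
#' @param baseline_mean,baseline_sd Mean and sd of the persistent latent
#'   severity component, on the 0-10 scale.
#' @param persistence Serial correlation in `[0, 1)` of the persistent
#'   component across consecutive check-ins.
#' @param shock_sd Sd (>= 0) of transient per-check-in noise.
#' @param improvement_prob_given_alert,improvement_prob_control Probability
#'   in `[0, 1]` (or `NA` to disable) that a threshold symptom is rated
#'   strictly lower at the next completed check-in.
#' @param attrition_hazard_per_checkin Probability in `[0, 1]` that a dyad
#'   drops out before each successive due check-in (geometric dropout).
#' @param bias_report_prob Probability in `[0, 1]` that an ALERT-arm
#'   caregiver completes a due online check-in.
#' @param bias_rating_shift Nonpositive mean shift applied to ALERT-arm
#'   online latent values before rounding.
#' @param symptom_names Character vector of exactly 10 symptom names.
#' @param seed Integer master seed; per-dyad substreams are derived from it
#'   by stable hashing of the dyad id, so cohorts are reproducible.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_dyads_per_arm = 110,
                          study_days = 365L,
                          checkin_interval_days = 7L,
                          baseline_mean = 4.3,
                          baseline_sd = 2.35,
                          persistence = 0.8,
                          shock_sd = 0.6,
                          improvement_prob_given_alert = 0.53,
                          improvement_prob_control = 0.26,
                          attrition_hazard_per_checkin = 0.02,
                          bias_report_prob = 0.65,
                          bias_rating_shift = -1.2,
                          symptom_names = esas_symptoms,
                          seed = 1L) {
  cfg <- list(
    n_dyads_per_arm = as.integer(n_dyads_per_arm),
    study_days = as.integer(study_days),
    checkin_interval_days = as.integer(checkin_interval_days),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    persistence = as.numeric(persistence),
    shock_sd = as.numeric(shock_sd),
    improvement_prob_given_alert = as.numeric(improvement_prob_given_alert),
    improvement_prob_control = as.numeric(improvement_prob_control),
    attrition_hazard_per_checkin = as.numeric(attrition_hazard_per_checkin),
    bias_report_prob = as.numeric(bias_report_prob),
    bias_rating_shift = as.numeric(bias_rating_shift),
    symptom_names = as.character(symptom_names),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_dyads_per_arm) || cfg$n_dyads_per_arm < 1L) {
    stop_config("n_dyads_per_arm must be a positive integer")
  }
  if (cfg$checkin_interval_days < 1L || cfg$checkin_interval_days > cfg$study_days) {
    stop_config("checkin_interval_days must be in [1, study_days]")
  }
  if (length(cfg$symptom_names) != 10L || anyDuplicated(cfg$symptom_names)) {
    stop_config("symptom_names must be 10 distinct names (the modified ESAS has exactly 10 items)")
  }
  probs <- c(
    attrition_hazard_per_checkin = cfg$attrition_hazard_per_checkin,
    bias_report_prob = cfg$bias_report_prob
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("attrition_hazard_per_checkin and bias_report_prob must lie in [0, 1]")
  }
  for (nm in c("improvement_prob_given_alert", "improvement_prob_control")) {
    p <- cfg[[nm]]
    if (!is.na(p) && (p < 0 || p > 1)) stop_config(nm, " must lie in [0, 1] (or be NA)")
  }
  if (is.na(cfg$persistence) || cfg$persistence < 0 || cfg$persistence >= 1) {
    stop_config("persistence must lie in [0, 1)")
  }
  if (is.na(cfg$shock_sd) || cfg$shock_sd < 0) stop_config("shock_sd must be >= 0")
  if (is.na(cfg$baseline_sd) || cfg$baseline_sd <= 0) stop_config("baseline_sd must be > 0")
  if (is.na(cfg$bias_rating_shift) || cfg$bias_rating_shift > 0) {
    stop_config("bias_rating_shift must be <= 0")
  }
  invisible(cfg)
}

#' Read a cohort configuration from a flat YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; missing keys take the
#' defaults. `symptom_names` may be a YAML list.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_config("unknown configuration keys: ", paste(extra, collapse = ", "))
  do.call(cohort_config, raw)
}

# stable 31-ary string hash of (master seed, dyad id), kept below 2^31 so it
# can seed R's RNG; hashing the combined key keeps substreams unrelated across
# both dyads and master seeds
dyad_substream_seed <- function(seed, dyad_id) {
  key <- paste0(seed, ":", dyad_id)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h) + 1L
}

#' Generate a synthetic caregiver check-in cohort
#'
#' Simulates one pretest plus weekly online check-ins per dyad under the
#' generative law described in [cohort_config()], and returns them in the
#' long check-in schema (one row per rating, ten rows per check-in).
#'
#' Dyads are assigned 1:1 to the CONTROL and ALERT arms. Per dyad: dropout
#' is geometric with the configured per-check-in hazard; ALERT-arm due
#' check-ins are thinned with probability `1 - bias_report_prob`; ratings
#' come from the rounded, clamped latent process with the ALERT-arm online
#' shift; the alert-response override then acts on consecutive completed
#' check-ins. Each dyad is simulated on its own RNG substream derived from
#' the master seed and the dyad id, so the output is reproducible and
#' insensitive to dyad ordering. The function sets the RNG state.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `dyad_id`, `arm` (`"CONTROL"`/`"ALERT"`),
#'   `checkin_index` (0 = pretest), `day`, `source`
#'   (`"PRETEST"`/`"ONLINE"`), `symptom`, `rating` (integer 0-10).
#' @examples
#' records <- generate_cohort(cohort_config(n_dyads_per_arm = 3, study_days = 28, seed = 7))
#' dplyr::count(records, arm, source)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  width <- max(3L, nchar(as.character(config$n_dyads_per_arm)))
  parts <- vector("list", 2L * config$n_dyads_per_arm)
  k <- 0L
  for (arm in c("CONTROL", "ALERT")) {
    prefix <- if (arm == "CONTROL") "control" else "alert"
    for (i in seq_len(config$n_dyads_per_arm)) {
      dyad_id <- sprintf("%s-%0*d", prefix, width, i)
      k <- k + 1L
      parts[[k]] <- simulate_dyad(config, dyad_id, arm)
    }
  }
  # assemble one long tibble from plain vectors (ten rows per record)
  n_rec <- vapply(parts, function(p) length(p$day), integer(1))
  tibble::tibble(
    dyad_id = rep(vapply(parts, `[[`, "", "dyad_id"), times = n_rec * 10L),
    arm = rep(vapply(parts, `[[`, "", "arm"), times = n_rec * 10L),
    checkin_index = unlist(lapply(n_rec, function(k) rep(seq_len(k) - 1L, each = 10L))),
    day = unlist(lapply(parts, function(p) rep(p$day, each = 10L))),
    source = unlist(lapply(n_rec, function(k) {
      rep(c("PRETEST", rep("ONLINE", k - 1L)), each = 10L)
    })),
    symptom = rep(config$symptom_names, times = sum(n_rec)),
    rating = unlist(lapply(parts, function(p) as.integer(t(p$rmat))))
  )
}

simulate_dyad <- function(cfg, dyad_id, arm) {
  set.seed(dyad_substream_seed(cfg$seed, dyad_id))
  n_due <- cfg$study_days %/% cfg$checkin_interval_days
  # geometric dropout: check-in k happens only if all k hazards are survived
  completed_due <- n_due
  if (cfg$attrition_hazard_per_checkin > 0 && n_due > 0L) {
    surv <- runif(n_due) >= cfg$attrition_hazard_per_checkin
    first_drop <- match(FALSE, surv)
    if (!is.na(first_drop)) completed_due <- first_drop - 1L
  }
  # ALERT-arm thinning of due check-ins
  due_idx <- seq_len(n_due)
  reported <- due_idx <= completed_due
  if (arm == "ALERT" && n_due > 0L) {
    reported <- reported & (runif(n_due) < cfg$bias_report_prob)
  }
  sched <- due_idx[reported] # scheduled slots actually completed

  # latent process over pretest (t = 0) and every due slot, 10 symptoms
  rho <- cfg$persistence
  n_t <- n_due + 1L
  s <- matrix(0, n_t, 10L)
  s[1L, ] <- rnorm(10L, cfg$baseline_mean, cfg$baseline_sd)
  if (n_t > 1L) {
    innov_sd <- cfg$baseline_sd * sqrt(1 - rho^2)
    for (t in 2:n_t) {
      s[t, ] <- cfg$baseline_mean + rho * (s[t - 1L, ] - cfg$baseline_mean) +
        rnorm(10L, 0, innov_sd)
    }
  }
  latent <- s + matrix(rnorm(n_t * 10L, 0, cfg$shock_sd), n_t, 10L)
  if (arm == "ALERT" && n_t > 1L) {
    latent[-1L, ] <- latent[-1L, ] + cfg$bias_rating_shift
  }
  ratings <- matrix(pmin(10L, pmax(0L, as.integer(round(latent)))), n_t, 10L)

  # realized records: pretest row + completed online slots
  rows <- c(1L, sched + 1L)
  rmat <- ratings[rows, , drop = FALSE]

  # alert-response override on consecutive completed online check-ins
  p_imp <- if (arm == "ALERT") cfg$improvement_prob_given_alert else cfg$improvement_prob_control
  n_on <- length(sched)
  if (!is.na(p_imp) && n_on >= 2L) {
    for (j in seq_len(n_on - 1L) + 1L) { # rmat row j is the j-1-th online check-in
      cur <- rmat[j, ]
      hot <- which(cur >= 7L)
      if (!length(hot)) next
      u <- runif(length(hot))
      red <- sample(1:3, length(hot), replace = TRUE, prob = c(0.6, 0.3, 0.1))
      imp <- u < p_imp
      nxt <- rmat[j + 1L, hot]
      nxt[imp] <- pmax(0L, cur[hot][imp] - red[imp])
      nxt[!imp] <- pmax(nxt[!imp], cur[hot][!imp])
      rmat[j + 1L, hot] <- nxt
    }
  }

  list(
    dyad_id = dyad_id,
    arm = arm,
    day = c(0L, sched * cfg$checkin_interval_days),
    rmat = rmat
  )
}
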