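---
title: "Scoring and comparing caregiver-reported symptom check-ins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and comparing caregiver-reported symptom check-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carealert)
```

## The setting

Family caregivers of patients with advanced cancer complete a short online
check-in at first log-in and weekly thereafter, rating ten patient symptoms
(a modified Edmonton Symptom Assessment Scale) on a 0--10 severity scale.
Forms are pre-populated with the previous ratings, so caregivers change
only what differs. A rating of **7 or higher** defines a *threshold
symptom*: severe enough that, in the intervention (ALERT) arm, the system
alerts the clinical team. In the control arm the same ratings are collected
but never forwarded.

The analysis asks two questions per arm and 2-month period:

1. *Symptom management*: of all threshold symptoms, what fraction is rated
   strictly lower at the next check-in (**improved**)?
2. *Reporting behaviour*: of all assessed symptoms (ten per check-in), what
   fraction is at threshold?

Because caregivers in the alerting arm know a severe rating contacts the
clinician, the second index is also a probe of *response bias* — caregivers
may skip check-ins or shade ratings downward to avoid "bothering" the team.

## Scoring rules

`filter_eligible()` removes the online records of caregivers with fewer
than two online check-ins (they contribute no before/after pair); pretest
records are kept for the bias analysis. `label_transitions()` emits one
observation per (dyad, symptom, check-in); the transition compares the
rating with the same symptom's rating at the immediately following
*completed* check-in, regardless of the calendar gap — the improvement
definition is check-in-relative, not calendar-relative. Ties are `SAME`;
the last check-in is `TERMINAL`.

`aggregate_bimonthly()` assigns each check-in to period
`ceiling(day / bin_days)` with `bin_days = 61` by default: six fixed
61-day bins (366 days) tile a year reproducibly, whereas calendar months
are ragged. A threshold symptom is attributed to the bin of its own
check-in even when its follow-up rating falls in the next bin.

**Terminal policy.** Ratings at a dyad's final check-in have no follow-up.
Published bimonthly tables of this design use improvement denominators
equal to the full threshold counts, implying terminal threshold
observations stay in the denominator; the package therefore defaults to
`terminal_policy = "include"`, tallying them under `n_same` (a symptom
that cannot be observed to improve is counted as not improved). The
alternative reading — drop them from both the threshold count and the
decomposition — is available as `terminal_policy = "exclude"` and is the
right choice when the improvement proportion is interpreted as a
conditional probability of improvement, e.g. when validating against a
generative model, because terminal observations never received a
follow-up. `n_assessed` is unaffected by the policy.

## The synthetic cohort generator

No individual-level data from such trials are public, so
`generate_cohort()` simulates cohorts with the structure the analysis
assumes. Per (dyad, symptom) the latent severity is

$$ X_t = S_t + \varepsilon_t, \qquad
   S_t = \mu + \rho\,(S_{t-1} - \mu) + \eta_t, $$

with $S_t$ a *stationary* AR(1) — marginal
$N(\mu, \sigma_b^2)$, lag-one correlation $\rho$ — and
$\varepsilon_t \sim N(0, \sigma_s^2)$ independent transient noise.
Ratings are $X_t$ rounded to the nearest integer and clamped to 0--10.
Rounding reproduces the carry-forward phenomenon: a rating changes only
when the latent process moves it by at least one level. The stationary
parameterisation keeps every check-in's marginal equal to the baseline
law, so with $\rho = 0,\ \sigma_s = 0$ the threshold prevalence equals
the discretised normal tail mass exactly — the property the generator
tests verify by quadrature.

Arm-specific mechanisms:

* **Attrition**: geometric per-check-in dropout hazard; a dropped dyad
  produces no further records.
* **Reporting bias** (ALERT arm only, online records only): each due
  check-in is completed with probability `bias_report_prob`, and latent
  values are shifted by `bias_rating_shift` before rounding. Pretest
  records are never thinned or shifted — pretest surveys were on paper and
  known not to reach clinicians.
* **Alert response** (memoryless, matching the one-step improvement
  definition): a symptom rated $\ge 7$ at a completed check-in has its
  next completed rating forced strictly lower with probability
  `improvement_prob_given_alert` (ALERT) or `improvement_prob_control`
  (CONTROL), and otherwise forced not lower. The forced two-sided draw
  makes the conditional improvement probability exactly the configured
  value, which is what the parameter-recovery tests check. Setting a
  probability to `NA` disables the override and leaves the pure latent
  process.

### Default parameters and their rationale

| Parameter | Default | Why |
|---|---|---|
| `n_dyads_per_arm` | 110 | enrolment scale of the pooled trials (117/118) |
| `study_days`, `checkin_interval_days` | 365, 7 | 12-month window, weekly cadence |
| `baseline_mean`, `baseline_sd` | 4.3, 2.35 | puts the discretised tail mass P(rating >= 7) near 17.5%, the observed pretest threshold prevalence |
| `persistence` | 0.8 | strong week-to-week carry-forward; most ratings unchanged between check-ins |
| `shock_sd` | 0.6 | occasional one-level transient flickers |
| `improvement_prob_given_alert` | 0.53 | observed 12-month improved/threshold proportion, alert arm |
| `improvement_prob_control` | 0.26 | same, control arm |
| `attrition_hazard_per_checkin` | 0.02 | reproduces the roughly 13% per-2-month decline in reporting caregivers |
| `bias_report_prob` | 0.65 | observed ratio of completed symptom reports (5750 / 8810) |
| `bias_rating_shift` | -1.2 | moves the online tail mass from ~18% to ~8%, the observed alert-arm threshold rate |

One caution for interpreting simulations at these defaults: the
"not improved" branch of the alert-response override keeps a threshold
symptom at or above its current level, so threshold states persist longer
than the pure AR(1) would give, and the whole-stream threshold prevalence
exceeds the marginal tail mass. The generator is a structural testbed for
the scoring and inference machinery, not a calibrated disease model.

**Seeding.** One master seed; each dyad is simulated on an RNG substream
seeded by a stable hash of the combined `"seed:dyad_id"` key. Cohorts are
therefore byte-reproducible, insensitive to dyad ordering, and replicate
cohorts with different master seeds share no substreams.

## Two-sample inference

All group comparisons reduce to two independent binomial counts
$(x_1, n_1), (x_2, n_2)$.

* `pooled_z_test()` uses the pooled-variance form
  $z = (\hat p_1 - \hat p_2) / \sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}$.
* `wald_unpooled_ci()` uses the unpooled variance for the interval.
  Trials of this design conventionally report the pooled statistic with
  an unpooled interval, and that pairing reproduces the published
  statistics from the published counts; both forms are exposed.
* `mn_score_ci()` inverts the Miettinen--Nurminen score test: the
  restricted MLE of $(p_1, p_2)$ under $p_1 - p_2 = \delta$ (closed-form
  trigonometric solution of the likelihood cubic, verified in the tests
  against direct numerical maximisation), variance inflated by
  $N/(N-1)$ per the original formulation, bounds located by bracketed
  root search to `1e-8`. Score intervals are near-nominal even at small
  n and never leave $[-1, 1]$.
* `chan_zhang_ci()` is the exact unconditional interval: for candidate
  $\delta$ the one-sided p-value is the supremum over the nuisance
  proportion (plain uniform grid, 200 points, no confidence-set
  restriction) of the exact tail probability of outcomes at least as
  extreme as observed, extremity ordered by the MN score statistic; the
  interval collects the non-rejected $\delta$ (bisection to `1e-4`,
  comparable to the nuisance-grid resolution). Full enumeration of the
  joint outcome space restricts it to $n \le 200$ per group; beyond
  that the score interval is the practical choice and the error message
  says so.
* `cohen_h()` is $|2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}|$ from
  unrounded proportions, reported as an absolute value as is conventional
  in these tables.
* `mcnemar_two_group()` contrasts two randomised groups on paired
  pretest/first-check-in threshold status. Per group the net shift toward
  fewer threshold reports is $d_g = (b_g - c_g)/N_g$ ($b$ = pairs moving
  threshold to non-threshold, $c$ the reverse) with the standard
  McNemar net-change variance. The statistic is
  $z = (d_2 - d_1)/\sqrt{v_1 + v_2}$, oriented so that a *positive* z
  means the second (ALERT) group sheds threshold reports more strongly —
  the direction a down-rating response bias predicts. The exact
  "multiple-sample McNemar" formulation cited in this literature is not
  published in reconstructible form; this net-change difference is the
  natural two-group generalisation, and its type-I error calibration is
  verified by simulation in the test suite.

## Trajectory (AUC) comparison

`auc_compare_index()` summarises each arm's six bimonthly proportions by
the trapezoidal area over the period midpoints (months 1, 3, ..., 11;
periods with a zero denominator contribute no point), converts the two
areas to relative proportions $r_i = \mathrm{AUC}_i / \sum_j
\mathrm{AUC}_j$, and tests them with the same two-sample machinery on
pseudo-counts $(\mathrm{round}(r_i n_i), n_i)$. The effective $n_i$ is
deliberately the arm's total relevant denominator over the 12 months
(threshold symptoms for the improvement index, assessed symptoms for the
threshold index) — the same denominators as the totals-based tests. The
original analyses used a proprietary proportional-difference procedure
whose sample-size convention is unpublished; this choice is documented as
an approximation, and the AUC stage is validated by its mathematical
properties (scale equivariance, analytic integration oracle, permutation
null) rather than against printed values, none of which exist.

## Numerical and degenerate-input choices

* Equal consecutive ratings are `SAME`; a missing symptom in a check-in
  is a data error (the instrument forces completion of all ten items).
* Online check-ins beyond day `6 * bin_days` are outside the 12-month
  window and are discarded with a warning.
* Degenerate totals (an arm with no threshold symptoms) make the
  affected comparison `NULL` in the report bundle instead of aborting it.
* The pooled Z is undefined when the pooled proportion is 0 or 1; that is
  a data error, as is a McNemar contrast with no discordant pairs.
* Wald intervals are clamped to $[-1, 1]$; `x_1 = x_2 = 0` gives the
  degenerate interval $(0, 0)$.
* Report tables render percentages with two decimals when the
  denominator is at least 1000 and one decimal otherwise, matching the
  mixed precision of the published tables; raw counts are always emitted
  alongside, so no information is lost to rounding.

## What the tests do and do not show

The test suite validates the machinery at deliberately modest problem
sizes chosen for a desk-scale run: tiny cohorts (up to 5 dyads) against
a brute-force recount written directly over the CSV rows; score-interval
bounds against grid inversion at step `1e-5` on a 50-table panel;
exact-interval coverage over 2000 simulated 20-per-arm tables (decisions
memoised over the 441 distinct outcomes); improvement-probability
recovery over 20 replicate cohorts of 100 dyads per arm (under
`terminal_policy = "exclude"`, since terminal observations carry no
improvement draw); and null calibration of the pooled Z and two-group
McNemar tests over 2000 neutral replicate cohorts. The null-calibration
Z test is applied to the first-check-in contrast, where generator
observations are independent across dyads and symptoms; applied to
whole-stream pooled totals the same test would inherit the serial
dependence of the latent process (a clustering phenomenon real trials
share), which is a property of pooled-count testing, not of the
statistic's implementation.

Passing tests show the scoring is exact, the intervals have their
advertised coverage, and the pipeline recovers generating parameters
under the generator's assumptions. They do not show that real caregiver
data satisfy those assumptions: real symptoms are correlated with each
other, dropout is likely informative, clinician response is not
memoryless, and reporting bias need not act as a uniform shift.

## Known limitations

* The improvement proportion of a finite cohort is a ratio estimator
  under feedback (non-improved threshold symptoms persist and contribute
  further trials), so per-cohort estimates carry a small negative
  finite-sample bias that vanishes as cohorts grow or counts are pooled.
* The exact unconditional interval's plain grid supremum can be slightly
  conservative; a Berger--Boos restriction is out of scope.
* The AUC effective-n convention is an approximation, as discussed above.
* Fixed 61-day bins differ from calendar months by up to a day per bin.
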