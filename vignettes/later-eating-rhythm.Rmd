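---
title: "Deriving later-eating-rhythm variables from timed food diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving later-eating-rhythm variables from timed food diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lerkit)
```

## The problem

Multi-day food diaries in children record, for every food or drink, the
clock time and energy content. From these, researchers want comparable
measures of *later eating rhythm* (LER): how late a child eats, how much
of the day's energy falls in the evening, and how often evening eating
occurs. `lerkit` implements the full derivation — from raw records and
usual bedtimes to 13 per-child variables per day-type stratum — together
with the calibration machinery used to choose the definitions in the first
place, and a synthetic cohort generator so every stage is testable without
access to restricted cohort data.

## Model and definitions

All clock times are integer minutes since midnight (exact arithmetic, no
float drift); the diary day runs 00:00–23:59 and no record crosses
midnight — young children are assumed not to rise and eat after bedtime,
so post-midnight carryover is out of scope.

An **eating occasion** (EO) is the set of records sharing one recorded
time within a child-day; its energy is their sum. Within each daypart —
first-thing 00:00–05:59, morning 06:00–11:59, afternoon 12:00–16:59,
evening 17:00–23:59 — the largest-energy EO is the **main meal** (ties
break to the earliest time, a deterministic convention consistent with the
earliest-occasion rule used in time keying). All other EOs are snacks;
first-thing EOs count toward daily energy but are never main meals, since
the meal windows do not cover them. A meal is **skipped** on a day when no
EO falls in its usual slot (breakfast 06:00–09:59, lunch 12:00–14:59,
dinner 17:00–18:29) — a child who eats dinner only after 18:29 counts as a
dinner skipper, a known over-estimation inherent to fixed slots.

Two aggregation rules apply everywhere. Timing variables are means of
per-day minute values over the days where the quantity exists. Energy
variables are **ratios of sums**: summed window energy over summed TDEI
across stratum days, times 100. The two differ whenever TDEI varies by
day; the ratio-of-sums form is the explicit study definition and gives the
exact partition `E2 + E3 = E1a` because evening main-meal and
evening-snack energy partition evening energy. Night-eating day counts
(E1c1/E1c2) are the exception: each day is classified against its *own*
TDEI (≥30 %TDEI after 18:00; ≥25 %TDEI within 2 h before bedtime), then
counted. The comparison is `>=` (the operational variable definitions are
written that way; prose saying "over" notwithstanding), switchable via
`ne_strict`.

### Strata

Children enter the whole-week stratum with exactly 3 recorded days
(whatever the weekday/weekend mix), the weekday stratum with ≥2 weekday
days (weekday days only), and the weekend stratum with ≥1 weekend day.
A child in no stratum is reported in the exclusion list, never silently
dropped.

### Bedtimes

Bedtime-relative variables use the day-type's bedtime: the weekday bedtime
for weekday days and the weekend bedtime for weekend days, whether
individual (T1a, E1b, E1c2) or the configured population averages
(T1b; defaults 20:03 weekday, 20:42 weekend — the tabulated values, which
a rounded prose mention puts at "20:00"). "Eating around bedtime" means an
EO strictly after the bedtime on the same calendar day. The E1b window is
inclusive, `[bedtime − 120, bedtime]`; EOs after bedtime belong to T1a,
not E1b. A missing individual bedtime makes T1a/E1b/E1c2 missing for the
child (flagged), matching the reduced denominators such variables have in
practice.

### Sentinel records

Historically-keyed diaries carry two time sentinels: 99 (food found, no
recorded time) and 88 (database food unmatched in the diary). Sentinel
records are retained at read time; the derivation policy
(`sentinel_energy`) defaults to `include_in_tdei` — their energy counts
toward TDEI but toward no clock window, preserving energy conservation —
and can be set to `exclude`. Whether the original analysis kept such
energy is unknowable from the record format alone, hence the switch.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `daypart_starts` | 0/360/720/1020 | min | daypart boundaries |
| `usual_slots` | see above | min | meal-skip windows |
| `ne1_start`, `ne1_criterion` | 1080, 30 | min, %TDEI | NE1 window and energy criterion |
| `ne2_width`, `ne2_criterion` | 120, 25 | min, %TDEI | NE2 pre-bedtime window and criterion |
| `avg_bedtime` | 1203/1242 | min | population-average bedtimes |
| `sentinel_energy` | include_in_tdei | — | TDEI policy for sentinel records |
| `skew_threshold` | 0.5 | — | signed skewness routing mean/median display |
| `rare_top_bin_pct` | 4 | % | merge threshold for top count bins |
| `profile_epsilon` | 0.5 | %TDEI/bin | trough threshold in boundary inference |
| `slot_frac` | 0.2 | — | fraction of peak height delimiting usual slots |
| `ne_percentile`, `ne_rounding`, `ne_band` | 75, 5, [12.8, 37.0] | — | NE calibration |

All study constants live in `ler_config()` (JSON-serialisable), never
hard-coded, so definition-sensitivity analyses are first-class.

## Calibration machinery

`compute_ei_profile()` bins each child-day's energy into 48 half-hour
bins as shares of that day's timed energy (shares sum to 100 by
construction) and averages across child-days. `infer_window_boundaries()`
operationalises "troughs approaching zero": bins at or above
`profile_epsilon` form active runs; the three largest-mass runs are the
meal blocks, and each daypart boundary is the start of its block's first
bin — equivalently the end of the sub-epsilon trough preceding the peak.
The exact trough-to-boundary rule is not documented for the original
analysis; this is one defensible operationalisation, and it recovers the
generator's boundaries exactly at bin resolution. Usual slots are the
maximal bin runs at ≥ `slot_frac` of peak height around each peak.
Degenerate profiles (uniform, single-peak) raise errors suggesting an
epsilon change rather than guessing.

`compare_candidate_windows()` reports per-candidate quartiles of the
per-child share and flags a candidate whose three quartiles all lie
within `dup_tol` of an earlier one — the mechanism by which after-16:00
duplicates after-17:00 (no intake in 16:00–16:59) and after-19:00
duplicates evening snacks.

`calibrate_ne_threshold()` sets the energy criterion as the configured
percentile (default 75th, type-7 linear interpolation) of the per-child
ratio-of-sums window share, rounded to the nearest `ne_rounding` points
(5, reproducing criteria like 25/30 from continuous quantiles). The
implied prevalence is the share of children meeting the criterion on at
least `prevalence_min_days` day(s). Note: with the default of 1 day,
realistic cohorts yield prevalences around 60% — far above the reference
band of 12.8–37% that single-day questionnaire studies report — so the
decision is literally `accepted = FALSE`; the in-band figures in such
cohorts are *recurrent* (≥2-day) prevalences. The definition is kept
literal and the minimum-days knob exposed rather than silently redefining
prevalence.

## The synthetic world

`gen_params()` states one cohort model; its defaults are commitments, not
dials:

* **Days**: 3 recorded days per child (2 weekday + 1 weekend), with 17%
  of children recording only 1–2 days (the observed incompleteness rate).
* **Occasion times**: truncated normals inside daypart windows —
  breakfast 08:00 ± 30 (with a 10% early-riser component at 06:30 so the
  06:00 bin is populated), lunch 12:45 ± 30, dinner 17:45 ± 30 plus a
  child-level habitual evening shift (± 20) shared with the evening snack
  (21:00 ± 40, truncated ≥ 18:30); weekend dinner 6 min later. This
  reproduces near-zero troughs at 06:00/12:00/17:00 with peaks inside the
  usual slots, giving boundary inference a recoverable target.
* **Energy**: per-occasion mean shares (breakfast .21, lunch .26, dinner
  .27, snacks .08/.09/.09) summing to 1 before noise, lognormal noise
  (meals sdlog 0.25, snacks 0.6), renormalised and scaled by
  TDEI ~ N(1650, 250) kcal (typical intake at this age), rounded to whole
  kcal with TDEI equal to the record sum exactly. With snack
  probabilities 0.7/0.8/0.7 this puts ≈35% of TDEI after 17:00.
* **Snacking heterogeneity**: per-child snack probabilities are Beta
  around the daypart means (concentration 2) and a child-level lognormal
  (0.6) portion multiplier; chosen against the printed day-count
  distribution of evening snacking (≈13% of children with none on any
  day) and evening-snack quartiles. This over-dispersion is what makes
  the frequency variables behave like diary data rather than a common
  binomial.
* **Bedtimes**: child-level, N(20:03, 25 min) on weekdays, weekend =
  weekday + 39 min + noise (so weekend bedtimes stochastically dominate);
  18% of children have both missing (the observed bedtime missingness),
  simulated child-wise because bedtime is a usual, per-child quantity.
* **Keying artefacts**: each occasion splits into 1 + Poisson(0.6)
  records whose integer energies sum exactly; 1% of records get sentinel
  99, 0.5% sentinel 88.

Truth tables carry the generated per-day and per-child quantities
(pre-masking) so recovery is tested against ground truth, not re-derived
values. `gen_params_ne_calibration()` freezes a parameterisation whose
after-18:00 75th percentile sits in the 30%-criterion rounding cell
(dinner centred 17:55, share .28), for exercising threshold calibration
end-to-end.

**What the world does not emulate** — and hence what a green test does
not establish: correlation of eating timing with covariates (sex, BMI,
education); seasonal or secular trends; post-midnight eating;
reporting/recall error in energies; real food names; day-to-day bedtime
variation (bedtime is "usual", as in the source data). Tests green on
this world establish correctness of the *derivation machinery* and
recovery of *stated* distributional features, not epidemiological
validity.

## Numerical and design choices

* **Quantiles**: type-7 (linear interpolation) everywhere, R's default.
* **Chi-square**: Pearson, no continuity correction — this reproduces
  printed baseline statistics computed from full contingency tables.
* **Paired tests**: t-test with 95% CI of the mean difference for
  continuous variables; Wilcoxon signed-rank (normal approximation, no
  correction) for counts; chi-square for categorical variables on the
  common 0 vs ≥1-day dichotomy, since the weekday (0/1/≥2) and weekend
  (0/≥1) category schemes differ. Degenerate paired inputs (zero variance
  of differences) return statistic 0 / p 1 rather than erroring. No
  multiple-testing adjustment is applied; p-values are reported raw.
* **Display routing**: the original choice between mean (SD) and median
  (IQR) was made by visual histogram inspection. The reproducible
  surrogate here is *signed* moment skewness > 0.5 → median path.
  Unsigned |skew| > 1 was tried first and proven unusable: ratio-of-sums
  %TDEI variables are bounded and self-normalising, so even worlds
  matched to the printed evening-snack quartiles cap its skewness near
  0.7, while the timing mean's mild *left* skew (a mixture artifact of
  snackless days) should stay on the mean path. The signed 0.5 rule
  routes the evening-main-meal time and pre-bedtime share to the median
  path and the symmetric variables to the mean path, matching the
  published treatment; the threshold is configurable.
* **Rare bins**: a top count bin holding < 4% of children is merged into
  the bin below (e.g. "2 days" + "3 days" → "≥2"), the published grouping
  rule.
* **Spearman**: average ranks, pairwise-complete observations, pairwise n
  recorded; constant variables yield flagged `NA` cells, never silent
  zeros.
* **Historical slot coder**: the seven printed slots partition the day
  with inclusive endpoints. Two nominal slot times (Tea → 17:00, Evening
  meal → 20:00) lie outside their own intervals as printed, so degrading
  already-degraded data moves those records onward; the coder follows the
  table as printed rather than "repairing" it.

## Known limitations

* T3 ≥ T2 holds day-wise by construction, but the stratum *means* can
  cross when a day contributes to T3 and not to T2 (no evening occasion,
  e.g. after sentinel masking); the invariant is only guaranteed when
  every day has an evening EO.
* E3 is defined as all evening snacks (the complement of the main meal
  within the evening), which is what makes `E2 + E3 = E1a` exact; a
  reading that counts only snacks *after* the main meal would differ on
  days with pre-main evening snacks.
* Meal-skip prevalence inherits the fixed-slot overestimation (dinner
  after 18:29 counts as skipped).
* The chi-square used for week-vs-weekend categorical comparisons treats
  the two strata as independent samples (as in the published layout),
  although the children are paired.
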