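# lerkit — later eating rhythm variables from timed child food diaries

**Later eating rhythm** (LER) is the umbrella term for eating *later*
(timing), eating *more in the evening* (energy), and eating *more often in
the evening* (frequency). Evidence links these behaviours to circadian
disruption and adiposity, but studies define "late eating" in incompatible
ways. `lerkit` implements a complete, reusable pipeline that turns
time-stamped child food-diary records and parent-reported usual bedtimes
into a harmonised set of 13 LER variables, for epidemiologists working with
multi-day diet diaries.

## What it computes

An **eating occasion** (EO) is all food/drink records sharing one recorded
clock time within a child-day. Within each daypart window — morning
06:00–11:59, afternoon 12:00–16:59, evening 17:00–23:59 — the
largest-energy EO is the **main meal**; all other EOs are **snacks**.
Usual mealtime slots (breakfast 06:00–9:59, lunch 12:00–14:59, dinner
17:00–18:29) define meal skipping as the absence of any EO in the slot.

Per child and day-type stratum (whole week = 3 recorded days; weekdays =
≥2 weekday days; weekend = ≥1 weekend day), the 13 variables are:

| domain | variables |
|---|---|
| Timing | T1a/T1b days eating after individual/average bedtime; T2 evening main-meal time; T3 last-EO time |
| Energy | E1a evening %TDEI; E1b %TDEI within 2 h before bedtime; E2 main-meal %TDEI; E3 evening-snack %TDEI; E1c1/E1c2 night-eating day counts (≥30 %TDEI after 18:00 / ≥25 %TDEI pre-bedtime) |
| Frequency | F1 median evening EOs/day; F2 days with a dinner-slot EO; F3 days with post-main-meal EOs |

Timing variables are means of per-day minute values,

    T = (1/n) * sum_k t_k ,

and every %TDEI variable is a **ratio of sums** across the stratum days
(never a mean of daily percentages):

    E = 100 * sum_k EI_k / sum_k TDEI_k ,

so the partition identity `E2 + E3 = E1a` holds exactly. Night-eating day
counts compare each day against its own TDEI.

The package also ships the definition-selection machinery: half-hour
energy-intake profiles, daypart-boundary inference from the profile's
troughs, candidate-window quartile comparison, and calibration of the
night-eating energy criterion as a rounded percentile of the per-child
window share — plus a summary layer (skewness-routed mean/median display,
paired week-vs-weekend tests, Pearson chi-square, Spearman
inter-correlations, sample-flow accounting) and a synthetic cohort
generator stating a realistic world (trimodal eating-time density,
child-level snacking heterogeneity, historical meal-slot coding, sentinel
time codes 99/88, missing bedtimes) so everything is testable without
managed-access data.

## Worked example

```r
library(lerkit)

coh      <- generate_cohort(gen_params(n_children = 500, seed = 42))
profiles <- derive_all(coh)
summarise_ler(profiles, "whole_week")
```

```
LER summary, stratum: whole_week
  T1a  n=335  0: 160 (47.8%)  1: 102 (30.4%)  2: 57 (17.0%)  3: 16 (4.8%)
  T1b  n=403  0: 187 (46.4%)  1: 140 (34.7%)  >=2: 76 (18.9%)
  T2   n=403  median 1076.00 (IQR 1059.33, 1096.50)
  T3   n=403  mean 1160.92 (SD 51.36)
  E1a  n=403  mean 35.35 (SD 5.65)
  E1b  n=335  median 11.81 (IQR 4.82, 19.06)
  E1c1 n=403  0: 163 (40.4%)  1: 152 (37.7%)  >=2: 88 (21.8%)
  E1c2 n=335  0: 163 (48.7%)  1: 108 (32.2%)  >=2: 64 (19.1%)
  E2   n=403  mean 28.62 (SD 5.04)
  E3   n=403  median 6.01 (IQR 2.98, 10.23)
  F1   n=403  median 2.00 (IQR 1.00, 2.00)
  F2   n=403  0: 2 (0.5%)  1: 23 (5.7%)  2: 92 (22.8%)  3: 286 (71.0%)
  F3   n=403  0: 52 (12.9%)  1: 83 (20.6%)  2: 123 (30.5%)  3: 145 (36.0%)
```

Reading this: of the 500 simulated children, 403 recorded all 3 days
(whole-week stratum) and 335 of those also had a usual bedtime. The median
evening main meal is at minute 1076 ≈ 17:56, the mean last eating occasion
at minute 1161 ≈ 19:21, and children take 35.4% of their daily energy
after 17:00 — 28.6 points from the evening main meal and ~6 from snacks.
Bins are merged upward (e.g. `>=2`) when the top category holds under 4%
of children. Calibration on the same cohort:

```r
calibrate_ne_threshold(coh)
#> NE threshold decision (after 18:00): p75 = 25.64%TDEI -> criterion 25%
#>   implied prevalence 61.8% vs band [12.8, 37]: not accepted
infer_window_boundaries(compute_ei_profile(coh))$boundaries
#>   morning afternoon   evening
#>       360       720      1020
```

The profile's troughs recover the generated daypart boundaries (06:00,
12:00, 17:00) exactly. The Spearman matrix shows, e.g., a strong positive
correlation between the last-EO time and eating around bedtime
(`rho(T3, T1a) = 0.65`).

## Command line

```sh
ler simulate  --n 2000 --seed 7 --out-dir cohort/
ler validate  --diary cohort/diary.csv --bedtimes cohort/bedtimes.csv
ler derive    --diary cohort/diary.csv --bedtimes cohort/bedtimes.csv --out profiles.csv
ler calibrate --diary cohort/diary.csv --bedtimes cohort/bedtimes.csv --out report.json
ler run       --config run.json
```

(`inst/cli/ler`; exit codes: 0 success, 2 validation failure, 3 config
error.)

## Documentation

The methods vignette (`vignettes/later-eating-rhythm.Rmd`) describes the
model and its assumptions, every tunable threshold with units and
defaults, what the synthetic world does and does not emulate, and the
numerical choices (tie-breaks, sentinel policy, degenerate inputs).
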