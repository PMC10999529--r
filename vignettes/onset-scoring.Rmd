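---
title: "Composite onset scoring for SOD1-G93A phenotyping: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite onset scoring for SOD1-G93A phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsonset)
```

## The measurement model

`alsonset` works on longitudinal phenotype tables from four-arm exercise
studies in the SOD1-G93A mouse: genotype (WT / G93A) crossed with activity
(sedentary / trained on a motorized treadmill), n = 12 per group, measured
twice a week from 35 days of age (training start, well before symptoms) to
91 days (endpoint). Four readouts enter the analysis:

* **body weight** (g), measured before each training session;
* **grip strength**: three pulling attempts on a grid net, whose mean is
  normalized to the same-day body weight (`normalize_grip()`);
* **hind-limb extension reflex** and **gait**, scored by a blinded
  observer on an ordinal rubric from 5 (normal) to 0.5 (humane endpoint)
  with steps of 0.25 near the top and 0.5 below (`rubric_levels()`).

### Indicators and the composite score

At each measurement day four binary impairment indicators are computed.
The weight and grip criteria both use a 20% deficit with a *strict*
inequality: a value exactly at 80% of its reference does not count as
impaired (tested explicitly at the boundary). The motor criterion fires as
soon as a rubric score reaches 4.75, the first sub-normal level — rubric
scores only move down the scale as disease progresses, so "reached 4.75"
is implemented as `score <= 4.75`.

The composite total weights the quantitative tests by 3 and the
observer-scored tests by 1.5,

$$S(t) = 3\,I_w(t) + 3\,I_g(t) + 1.5\,I_r(t) + 1.5\,I_{ga}(t) \in \{0, 1.5, \dots, 9\},$$

and onset is the first day with $S(t) \ge 6$. The down-weighting of the
qualitative scores means a single observer misjudgment can never decide
onset: of the 16 indicator combinations, exactly six reach 6, and each
includes either both quantitative deficits or three of the four criteria.

```{r}
onset_reaching_combinations(6)
```

### Reference policies

Two references are under-determined by the measurement protocol alone, so
they are explicit, run-level configuration (`reference_policy()`):

* **Weight reference.** "20% below the wild-type mean" is taken, by
  default, against the contemporaneous *sedentary* wild-type group mean at
  the same measurement day — training itself alters WT weight, so the
  sedentary arm is the cleaner yardstick. A pooled-WT option exists.
* **Grip baseline.** The 100% level that a "20% reduction" refers to is,
  by default, the running maximum of the animal's own normalized grip up
  to the current day. This captures "reduction from what this animal could
  do" without assuming the day-35 value is the peak (young mice often gain
  strength before declining). Day-one baseline and WT-mean options are
  provided.
* **Latching.** Indicators are re-evaluated each day and may switch off
  again if a value recovers; an optional latching mode ("once impaired,
  always impaired") is available but off by default, so that transient
  dips are handled by the separate `persistence` argument of
  `detect_onset()` (onset requires `persistence` consecutive qualifying
  measurements; default 1).

A policy is fixed for a whole analysis run and recorded in the run
manifest.

## The synthetic cohort

The simulator exists so every downstream stage can be tested against known
ground truth. Its defaults encode the study conditions the package targets;
they are not fitting knobs.

### Trajectory shapes

Only breakpoint ages and directions of change are reliably known for this
design, so trajectories are piecewise linear with hard breakpoints:

* **Weight** rises from 18 ± 1 g at day 35 by 0.10 g/day; transgenic
  groups stop gaining at their plateau day (70 trained, 77 sedentary),
  wild-type groups never plateau. Weighing error: SD 0.5 g.
* **Normalized grip** starts at 1.0 ± 0.08 (arbitrary consistent force/g
  units — the absolute scale of a grid-net reading is rig-specific, only
  relative change matters) and moves linearly: +0.003/day for trained WT
  (training improves WT strength), 0 for sedentary WT, −0.006/day for
  sedentary G93A and −0.0075/day for trained G93A. The three attempts are
  simulated as latent normalized grip × same-day weight plus per-attempt
  force noise (SD 0.4), so the scoring module's normalization is exercised
  end to end.
* **Latent motor score** holds at 5 until the group's decline-start day
  (reflex: 52 trained / 66 sedentary; gait: 59 trained / 70 sedentary;
  never for WT), then falls at 0.15 score units/day, floored at 0.5. The
  decline is anchored so the score is already *below* 5 on the
  decline-start day itself: the landmark age is defined as the first
  measurement at which the group mean has left the normal level, so the
  first impaired observation must fall on that day, not one grid step
  later. Observed scores are the latent value snapped to the rubric
  (ties round toward the worse score) plus a one-step symmetric observer
  error with probability 0.08, clamped to the scale — a minimal ordinal
  error model for blind qualitative scoring.
* **Endpoint motor-neuron percentage** (ventral-horn counts relative to
  the sedentary-WT mean) is Gaussian truncated at zero, means
  100/100/80/50 for SD WT / TR WT / SD G93A / TR G93A, SD 8 — i.e. a ~20%
  loss in sedentary and ~50% loss in trained transgenic mice.

Motor-skill tests are simulated on the same twice-weekly grid as weight
(their real-world frequency is configurable, as it is rarely reported),
and the measurement grid alternates +3/+4 days from day 35 so that every
landmark age above falls on a scheduled day.

### Calibration

The decline starts, plateau days, group sizes and schedule are fixed study
conditions. The remaining free rates (grip slopes, motor decline rate)
were calibrated once, analytically, so that the noise-free composite onset
lands at 63 days (trained G93A: gait completes the motor pair at 59, the
grip deficit crosses 20% just before the day-63 measurement) and at 70
days (sedentary G93A: gait and grip both first qualify at day 70) — the
onset ages such a study reports, on its own measurement grid. With noise
on, first-passage jitter and observer error shift the 200-cohort grand
means by a few tenths of a day (≈ 63.5 / 71.3); the landmark ages are
reproduced exactly by construction:

```{r}
days <- default_schedule()
p <- default_params()
weight_plateau_day(days, mean_weight_curve(p, "G93A", "trained", days))
decline_onset_day(days, latent_motor_curve(p, "G93A", "trained", days, "reflex"))
```

### What the simulator does and does not emulate

It reproduces the group-level trajectory geometry, measurement cadence,
ordinal scoring artifacts and endpoint effect sizes of the target design.
It does **not** model a biomechanical or physiological dose–response
(training dose enters only as a covariate via `weekly_distance()`),
within-animal correlation beyond the random start values, attrition or
humane-endpoint censoring before day 91, or any molecular readouts.
Passing tests on simulated cohorts therefore validate the *pipeline* —
scoring, detection, statistics, determinism — not the biological fidelity
of any particular rate parameter.

## The statistical stage

Onset records (event day, or censoring at the last observation — under
default conditions every transgenic mouse reaches onset by day 91 and both
WT arms are fully censored) feed:

* `km_curve()` — product-limit estimate per group;
* `logrank_test()` — Mantel–Cox chi-square (1 df) between two groups;
* `logrank_trend_test()` — the 1-df contrast of groupwise observed-minus-
  expected event counts with ordered numeric scores, for dose-ordered
  groups;
* `mann_whitney_test()` — two-sided comparison of observed onset ages,
  exact by enumeration when min(n) ≤ 12 and there are no ties, otherwise
  the mid-rank normal approximation with tie correction (onset ages live
  on a discrete grid, so ties are the norm at n = 12);
* `anova2_tukey()` — genotype × activity ANOVA with interaction on the
  balanced four-cell layout (sums-of-squares types coincide under
  balance), Tukey studentized-range post hoc on the cell means;
* `shapiro_normality()`, `group_summary()` — normality screening and
  mean ± SEM reporting.

These are standard procedures and are delegated to `survival` and `stats`;
the package's tests still verify each against an independent route — a
hand product-limit computation, full enumeration of group assignments for
Mann–Whitney, a permutation tail for the log-rank p, and closed-form
balanced-design sums of squares for the ANOVA (agreement to 1e-8).

Tukey adjustment is applied only within an ANOVA family; no study-wide
multiplicity correction is imposed, matching common practice in this
design. Onset comparisons use events only.

## Numerical choices and degenerate inputs

* The strict 20% thresholds carry a 1e-9 relative slack so an exactly-80%
  value never fires through floating-point rounding.
* `discretize_score()` resolves exact midpoints toward the worse level;
  inputs outside [0, 5] are errors, not clamped.
* `weight_plateau_day()` takes a tolerance (default 0 g) for "no later
  value exceeds this one", so small late wiggles can be absorbed
  explicitly rather than silently.
* Degenerate statistical inputs fail loudly: no events for a log-rank
  test, empty groups, all-identical Shapiro–Wilk samples, empty design
  cells. A single-observation group reports SEM 0 by convention.
* All simulation randomness flows through one user-supplied seed
  (`withr::with_seed`), and pipeline stages hash their configuration and
  outputs into a manifest, so identical config + seed gives byte-identical
  data files.

## Problem sizes

The package's own verification uses 200 simulated default cohorts
(4 × 12 mice × 17 days) for the stochastic checks — enough to pin the
grand-mean onset ages to within ±0.1 day — plus small-n fixtures wherever
an exact enumeration or permutation oracle is the comparator. A full
200-cohort simulate–score–detect sweep runs in well under a minute on one
CPU.

## Known limitations

* The weight criterion needs wild-type reference animals in the same
  table; purely transgenic datasets must supply a WT reference cohort or
  use a precomputed reference curve upstream.
* The simulator's linear decline with a hard floor is a caricature of late
  disease; conclusions about behavior *after* onset (e.g. progression
  slopes near day 91) should not lean on it.
* `detect_onset()` assumes a strictly increasing measurement grid per
  animal and does not impute missed visits.
* Humane-endpoint survival (rubric 0.5) is out of scope: the study window
  ends at day 91 and the package models onset, not survival to death.
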