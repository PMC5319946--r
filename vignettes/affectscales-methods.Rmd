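---
title: "Methods: composite affect scales, trajectory metrics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite affect scales, trajectory metrics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectscales)
```

## Overview

`affectscales` implements a complete analysis chain for rodent affect
phenotyping in a four-group chronic-migraine design: raw measurements →
behavioural indices → composite depression (0–25) and anxiety (0–28)
scores → group statistics, plus a synthetic cohort generator that makes
every stage testable without animal data. This vignette documents the
models, the tunable parameters and the decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The rating scales

Each scale item is an ordered list of half-open intervals `[lo, hi)`
mapping a raw index to integer points (`scale_table`). Two conventions
matter:

* **Interval closure.** Every bin is lower-closed, upper-open, matching
  the tables' "a ≤ < b" notation. Prose phrases such as ">95%" or
  ">20 m" at full-score edges are normalised to "≥" so the partition has
  no gaps. The single exception is the degenerate `[0, 0]` bin of the
  distance and rearing items ("0 → 0 points, 0 < x < 5 → 1 point"): an
  exactly motionless rat scores 0, any movement at all scores 1.
* **No pre-rounding.** Raw values are binned at full floating precision:
  a 94.999% sucrose preference scores 9, not 10. Rounding a measurement
  before scoring would move bin edges by half a unit.

The tables ship as editable CSV files
(`system.file("extdata/scales", package = "affectscales")`), so
`validate_scale()` can be run on user-modified scales. The validator
checks disjointness, gap-free coverage and attainment of each item's
declared maximum, and can compare a table against an arithmetic rule on a
dense grid.

### Text-vs-table conflicts

The scale definitions exist twice — as printed tables and as prose rules —
and the two disagree in documented places:

* **Weight extremes.** The prose assigns 0 points below 300 g and above
  390 g; the table prints 1 for both extreme rows. The table is taken as
  normative (default `mode = "table"`); `mode = "prose"` applies the prose
  reading. Neither is silently chosen: `validate_builtin_scales()` reports
  both discrepant regions. At exactly 390 g the prose says ">390 g", which
  is normalised to "≥ 390" to keep the partition gap-free.
* **OE% increments.** The OE% item gives 1 point to the whole 1–20% band
  and then climbs 1 point per 5%; a literal "+1 point per 5% increase"
  from the 1% floor cannot generate that flat band. The table is used; the
  strict-increment reading is reported as a discrepancy.

## Behavioural indices

**Sucrose preference** is `100 · s/(s + w)` with both consumptions in
grams. The ratio is computed before the multiplication so the result can
never exceed 100 by floating-point rounding. Zero total intake is a
distinct "no-intake" error: the index is undefined, not zero.

**Von Frey 50% threshold.** The measurement protocol defines only the
observable (filament forces 15, 10, 8, 6, 4, 2 g; positive withdrawal or
not), not the estimator. Two estimators are provided, neither asserted as
the source protocol's intent:

* `"ascending"` (default): the lowest force whose empirical
  positive-response fraction reaches 0.5. It is computable from any
  response table, invariant to permuting applications of equal force, and
  monotone: making any response positive can never raise the estimate.
* `"updown"`: a Dixon-style staircase estimator, the geometric mean of
  the forces flanking each response reversal. It assumes a staircase
  protocol and is offered behind the `method` flag.

All-negative series return the maximum force flagged `"ceiling"`;
all-positive series the minimum force flagged `"floor"`. Both estimators
are bounded by the force set, so a threshold is always reportable.

## Trajectory metrics

The animal position is the tracked centre point; no body-contour rule is
modelled. Key numerical choices:

* **Exact boundary splitting (open field).** A segment crossing the
  inner-circle boundary is split at the exact segment–circle
  intersection; time and distance are apportioned to the sub-segments
  assuming constant speed along the segment. This removes the dependence
  of ID%/IT% on the sampling rate that per-sample attribution would have.
* **Fixed 300-s denominator.** IT% and OT% divide by the trial duration
  verbatim even if the trace is shorter; `strict = TRUE` errors on
  truncated traces instead.
* **Stationary trials.** Zero total distance makes ID% formally 0/0; it
  is defined as 0 with a `"stationary"` flag so scoring can proceed — a
  motionless rat is maximally scorable as depressed, not missing data.
* **Entry debounce (EPM).** An arm entry is a transition of the effective
  zone into an arm; a visit shorter than the debounce window (default
  0.5 s) neither counts nor changes the effective zone, suppressing
  tracking jitter. `debounce = 0` reduces exactly to a naive transition
  count, which the tests exploit as an oracle.
* **Undefined OE%.** A rat that never enters any arm has no entry ratio.
  The default scoring policy assigns 0 points with a flag, on the
  rationale that refusing every arm is maximal avoidance; a `"missing"`
  policy excludes the item instead.
* **EPM geometry.** Only the wall height, ledge and elevation of the maze
  are stated by the source protocol, not the arm footprint; the default
  50 × 10 cm arms are configuration, not constants. The four percentage
  formulas are dimension-independent, but zone classification is not.

## The synthetic cohort: a stated world

The generator emulates the published design — groups CON, IS
(inflammatory soup), IS_AMI, AMI at n = 10 each over 21 days; daily von
Frey testing, weekly weight and sucrose tests, open field and EPM at day
21 — with the published effect *directions*: IS lowers sucrose
preference, distance, rearing, ID%, OE% and the withdrawal threshold;
weight, IT% and OT% are unaffected; IS_AMI recovers locomotion, ID%, OE%
and the threshold but not sucrose preference. One optional dropout
reproduces the single IS-group death.

No variability estimates were published for any endpoint, so the default
means and standard deviations are this package's own choices of what a
behavioural scientist would call realistic; the only constraint adopted
from the stated world is that affected endpoints separate by at least
1.5 within-group sd. Chosen once and not revisited:

| endpoint | CON | IS | IS_AMI | AMI | sd |
|---|---|---|---|---|---|
| weight day-0 base (g), gain (g/day) | 290, 2.4 | same | same | same | 10, 0.25 |
| sucrose preference day 21 | 0.90 | 0.70 | 0.72 | 0.90 | 0.05 |
| von Frey truth (g): floor / day-21 | 12 / 12 | 2 / 2 | 2 / 8 | 12 / 12 | 0.12 (log) |
| OF distance (m) | 25 | 12 | 22 | 25 | 4 |
| rearing (count) | 18 | 8 | 16 | 18 | 3.5 |
| ID% | 8 | 3 | 8 | 8 | 2.5 |
| IT% | 12 | 12 | 12 | 12 | 4 |
| OT% | 10 | 10 | 10 | 10 | 4 |
| OE% | 35 | 18 | 32 | 35 | 8 |
| total arm entries | 14 | 8 | 13 | 14 | 3 |

The von Frey truth declines linearly to its floor over the first week and
(IS_AMI only) recovers linearly from day 7, mirroring the published
time-course qualitatively. The responder is logistic on the log-force
scale with probability 0.5 at the true threshold (slope 8; `slope = Inf`
is the step responder).

**Seeds.** A single master seed deterministically derives a substream
seed for every (rat, stream, day) combination via a rolling string hash
(`substream_seed()`), so adding a rat to a design never perturbs the
draws of the others, and identical seeds give byte-identical cohorts.

### Two trajectory generators, and why

`simulate_trajectory()` is the *emission model*: a biased correlated
random walk with reflecting boundaries whose heading is blended toward
(or away from) the preferred region with gain
`tanh(0.4 · log(inner_zone_bias))`. In the corridor geometry of the EPM
the same idea is specialised to a skeleton walk along the arm axes, with
arm choice odds `bias : 1` (open : closed) at the centre — a free 2-D
walk in 10-cm corridors would lose most of its step length to wall
rejections. Step lengths carry multiplicative gamma noise (cv 1/3) with
the profile's mean; in the EPM the per-visit speed is constant because
slow visits last longer, which would bias the realised (time-weighted)
mean speed toward the harmonic mean.

A single bias knob, however, moves ID% and IT% (or OE% and OT%)
*together*, while the design's stated world needs them decoupled (ID%
affected, IT% not). `simulate_cohort()` therefore draws per-rat endpoint
targets from the design's means and sds and *composes* trajectories that
realise them: alternating inner/outer confined walk bouts joined by short
radial bridges (open field), or a shuffled schedule of arm visits with
depths and dwells solved from the time budget (EPM). Realisation error is
a few percent (bridges cross the boundary; reflections bend steps), which
is small against the between-rat sds. The emission model remains the
first-class, tested generator for single trials; the composer is the
generative counterpart of the metric definitions.

### What a green test does and does not establish

The generator produces independent Gaussian endpoints with linear trends,
logistic von Frey responders and geometrically tidy trajectories. Real
data have correlated endpoints within rat, heavy-tailed locomotion, drift
within trials, and tracking artefacts beyond label jitter. Green
calibration and power tests therefore establish that the *pipeline* is
correct and well-calibrated under its stated assumptions — not that the
scales are validated psychometric instruments, and not that any
particular published F or p value is reproduced (no per-animal data were
ever deposited, so those are not reproducible in principle).

## Statistics

* One-way ANOVA with the classical between/within decomposition; the
  degenerate zero-within-variance cases are handled explicitly
  (`F = 0, p = 1` when all values are identical; `F = Inf, p = 0` when
  means differ with zero noise).
* SNK post-hoc: means ranked; a pair spanning `p` ranks is tested against
  `qtukey(1 − α, p, df_within)`; every pair inside a non-significant span
  is blocked (step-down non-rejection blocking). Unbalanced groups — the
  n = 9 IS group after the dropout — use the harmonic mean of the two
  sample sizes. Critical values are computed numerically from
  `ptukey`/`qtukey`, with a regression test against published table
  values at k ≤ 6, df ≤ 30. Ties in means are ordered stably by group
  label.
* Two-group comparisons default to the pooled-variance two-sided
  Student's t at α = 0.05 — the convention of the era, since no variance
  assumption was stated — with a Welch variant behind a flag.
* The depression–anxiety association is the Pearson correlation of the
  two totals with the t-transform p value; zero variance in either total
  returns `NA` with a flag rather than a spurious coefficient.
* Weekly endpoints are compared without cross-week multiplicity
  correction (none was described); the text report flags this.

## Provenance

`run_pipeline()` echoes the full configuration (including any replacement
scale files) into the output directory and stamps the report with an md5
hash of that echo, so re-running with a changed scale file changes the
hash. The hash is carried in the config echo and the text report rather
than being injected into every CSV, which would break strict tabular
round-trips.

## Known limitations

* The composers realise endpoint targets only approximately (couple of
  percent); exactness was traded for continuous, physically plausible
  paths.
* The EPM walk moves along arm centrelines; lateral within-arm position
  is not modelled, so wall-following inside arms cannot be studied.
* The Dixon-style estimator uses reversal averaging, not the
  k-table maximum-likelihood variant; for the six-filament protocol the
  ascending rule is the recommended default.
* Group sizes below 2 are rejected for inference; the pipeline assumes
  the four-group naming (CON/IS/IS_AMI/AMI) only for the convenience
  IS-vs-CON flag, everything else is name-agnostic.
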