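---
title: "Drinking microstructure from home-cage lickometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drinking microstructure from home-cage lickometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickometry)
```

## The problem

Limited-access ("drinking in the dark") paradigms measure how much ethanol a
mouse drinks, but a bottle weight alone says nothing about *how* it was
drunk. Capacitance lickometers time-stamp every tongue-spout contact at
millisecond resolution, which makes the microstructure of drinking
observable: licks, their contact durations, the clustering of licks into
bouts, and how drinking is distributed over the session (frontloading early,
or density shifts late). This package implements that processing chain end
to end, together with the group-level inference used to compare genotypes or
treatments, and a seeded generative model of sessions so that the entire
pipeline can be exercised and tested without any recorded data.

The motivating biology is peripheral ethanol metabolism: animals lacking
alcohol dehydrogenase 1 (ADH1), the enzyme that clears most ingested
ethanol, accumulate blood ethanol about twice as fast per unit consumed,
drink roughly half as much, and show a characteristically degraded bout
structure (fewer bouts, fewer licks per bout, a smaller fraction of licks
inside bouts) with *longer* individual contacts outside bouts. The synthetic
presets encode exactly these contrasts.

## Event detection and lick construction

The acquisition firmware registers a **touch** when a capacitance reading is
at least `delta` counts above the previous reading and a **release** when it
is at least `delta` below (default `delta = 12` counts, the firmware value).
`detect_transitions()` implements the same rule in software for raw sampled
logs. Two deliberate readings of the rule:

* it compares *consecutive samples*, never a running baseline, so a slow
  ramp whose steps all stay below `delta` emits nothing;
* emissions alternate starting from the untouched state; repeated crossings
  of the same polarity collapse to the first.

`build_licks()` pairs each touch with the next release; the pairing is
conservative and never invents contact time: a release before any touch is
dropped, a second touch before any release supersedes the first (the kept
touch is the one closest to the eventual release), and an unclosed trailing
touch is dropped. All drops are reported. `filter_licks()` applies inclusive
duration bounds, defaulting to 5 ms-10 s. The upper bound is deliberately
permissive: ADH1-deficient animals produce non-bout contacts roughly twice
as long as controls, and an aggressive filter would truncate the very effect
of interest. These bounds are declared package defaults, not values taken
from any particular acquisition system.

## Bout segmentation

A bout initiates at the first lick of a run of `init_n = 3` licks whose
consecutive inter-lick intervals are all at most `init_ili_max = 1` s, and
extends to every subsequent lick arriving within `term_gap = 3` s of the
previous one; a quiet gap longer than `term_gap` terminates it
(`segment_bouts()`). Three boundary decisions are fixed and shared by the
brute-force reference implementation in the test suite:

* "within 1 second of each other" means consecutive inter-lick intervals,
  not a 1-s sliding window over the initiating run — the common convention
  in the lick-bout literature;
* comparisons are inclusive: an interval of exactly 1.0 s initiates, a gap
  of exactly 3.0 s continues; termination requires a gap strictly greater
  than `term_gap`, matching the "at least 3 seconds of no licking" phrasing;
* licks immediately *preceding* an initiating run never retro-join the bout,
  even when their gap to it is within `term_gap`: a bout's first lick is the
  first lick of its initiating run. This keeps the algorithm a single
  reproducible forward pass.

Duplicate timestamps are invalid input; upstream, `assign_bouts()` nudges
duplicates forward by one millisecond quantum with a warning. Bout
memberships and the non-bout set always partition the session's licks, a
property asserted across the test suite.

## Microstructure and temporal summaries

`summarize_session()` computes the per-session metrics: total licks and
total contact time, bout count, mean licks per bout, mean **total** contact
time per bout ("lick duration per bout" is the sum over the bout's licks,
since the group contrast of interest is overall drinking time within bout
structures; the per-lick mean within bouts is reported separately), percent
of licks in bouts, non-bout lick count, and mean single-lick durations
inside and outside bouts. Means over empty sets are `NA` sentinels, never
zero; with zero bouts the in-bout percentage is 0.

The frontloading window is half-open, `[0, 1800)` s: a lick at exactly 30
min is post-frontload, so windows compose without double counting. A lick's
own onset, not its bout's start, decides its window. `cumulative_curve()`
counts onsets at or before each grid point; `pooled_time_distribution()`
pools, per group, every lick onset and every within-session cumulative index
for distribution comparison.

## Inference

* `ks_two_sample()` — two-sample Kolmogorov-Smirnov; the statistic is the
  maximum absolute ECDF difference over the pooled sample, the p-value
  asymptotic.
* `kde()` — Gaussian-kernel density with Scott's rule by default (the
  bandwidth rule used for the published figures is unknown, so it is
  configurable: Scott, Silverman, or fixed). The grid spans the data ± 3
  bandwidths and is refined until its spacing is at most a quarter
  bandwidth; the density is renormalized over that support, because the
  kernel tail mass beyond the margin (up to ~1.3e-3 for edge-clustered
  samples) would otherwise violate the unit-integral contract.
* `location_test()` — Mann-Whitney U reported as a continuity- and
  tie-corrected z, or Welch's t. The published analyses mix the two without
  stating a rule, so `method = "auto"` applies an explicit one — Shapiro-Wilk
  on each group at alpha = 0.05, any rejection routes to ranks — and either
  test can be forced.
* `fit_mixed_model()` — lme4 REML fit with a per-animal random intercept.
  "All other variables as random effects" is under-determined; the
  intercept-per-animal structure is the minimal one consistent with
  repeated sessions per mouse. The interaction is tested with a Wald F
  whose denominator degrees of freedom use a between-within approximation,
  `ddf = n_obs − n_groups − (p − 1)`; the convention is recorded in the
  output because published F/df values depend on an unstated convention and
  are not exactly reproducible even in principle.
* `mixed_anova()` — classical two-way mixed-design ANOVA via the
  subject-stratified sum-of-squares decomposition, with per-within-level
  Welch contrasts. Effects whose sum of squares is zero at the response
  scale report F = 0 rather than 0/0.
* No multiple-testing correction is applied: the analyses mirror per-test
  reporting. (Adjust downstream if desired.)

## Intake and blood-ethanol accumulation

`compute_intake()` converts bottle masses to an ethanol dose:
`(pre − post) / solution_density × vol_fraction × ethanol_density /
(body_mass/1000)` in g/kg, with `solution_density = 0.97` g/mL for 20% v/v
ethanol (standard ethanol-water density tables; the conversion constants are
exposed because no single convention is universal). `fit_accumulation()`
fits per-group ordinary least squares of blood-ethanol concentration on
intake, with a free intercept by default (a through-origin option exists).
Concentration units are carried opaquely — slopes are per g/kg in whatever
unit the assay reports — so the headline quantity, the **slope ratio**
between groups, is unit-free. `slope_ratio()` attaches a seeded bootstrap
percentile interval, resampling animals within groups (2000 replicates).

For sessions without ethanol the pipeline's `intake` column is the consumed
solution mass in grams. Scaling a non-dosed fluid per kilogram would give
every animal its own intake-per-lick slope via the body-mass division, which
a random-intercept model cannot absorb and which measurably inflates the
null genotype-interaction test in the specificity analyses; in grams the
generating relation has a common slope and the test holds its size.

## The generator: a stated world

`simulate_session()` draws bout anchors from a piecewise-constant-intensity
Poisson process over the segments 0-30, 30-120, 120-150 and 150-240 min —
the simplest process supporting both frontloading and a late-session density
shift, with segment edges matching the analysis windows. Bout sizes are
shifted-geometric (minimum 1; sub-threshold "bouts" of 1-2 licks become
non-bout licks, as in real data); within-bout inter-lick intervals are gamma
(mean 0.15 s, shape 4 — about 7 Hz, the physiological mouse lick rate)
truncated at `init_ili_max`, so every generated bout of size ≥ 3 satisfies
the detection criteria by construction and bout recovery is exact and
testable. Contact durations are lognormal, capped at 90% of the gap to the
next lick (contacts on a single spout cannot overlap). Isolated licks are
placed uniformly and rejected within `term_gap` of any other lick, so they
can neither join nor seed a bout. Intake is the summed per-lick volume
(1.5 ± 0.3 µL), inverted into bottle masses exactly consistent with
`compute_intake()`; blood ethanol is `bec_slope × intake` plus Gaussian
noise.

Preset defaults (declared values; only the ratios are anchored to the
phenotype being emulated):

| parameter | wild type | ADH1 knockout |
|---|---|---|
| bout rate, /h by segment | 14, 5, 4, 3 | 7, 4.3, 8, 2 |
| bout size mean, licks | 30 | 20 |
| non-bout duration median, s | 0.05 | 0.10 |
| BEC slope, conc per g/kg | 40 | 80 |
| isolated lick rate, /h | 20 | 20 |

The knockout preset encodes: lower bout rate with the 120-150 min elevation
(denser than its own frontload period, visible only in 4-h sessions), fewer
licks per bout, doubled non-bout contact duration, doubled accumulation
slope, and an identical isolated-lick rate (non-bout lick *counts* do not
differ between genotypes). The wild-type frontload rate (14/h vs 7/h) and
the two size/duration/slope ratios jointly put expected knockout intake at
~50% of wild type, the published contrast. The `saccharin` preset is one
shared parameter set for both genotypes: no genotype differences for the
non-caloric sweetener, which is the surface the specificity analyses test.

What the generator does **not** emulate: escalation across days, circadian
structure beyond the session, sex differences, lick-rate rhythms within
bouts, and any tissue pharmacokinetics. A green contrast suite therefore
establishes that the pipeline recovers the programmed phenotype from raw
lick trains — not that the phenotype model is complete.

Ambiguities in the contrast suite were resolved as follows: group *order*
checks (knockout below wild type) are evaluated per seeded cohort on group
means and required in ≥ 95% of seeds; the two ratio-band checks (non-bout
duration ratio in [1.6, 2.4], slope ratio in [1.8, 2.2]) are evaluated on
the mean over seeds, consistent with the seed-averaged acceptance targets.

## Numerical choices and degenerate inputs

* Timestamps are seconds from the session start (millisecond quantum)
  everywhere; the session epoch comes from the manifest/dialect, never from
  the first event. ISO-datetime logs are rounded to the millisecond after
  epoch subtraction (POSIXct doubles carry ~1e-4 s noise at current dates).
* The non-bout sentinel in the lick table is the literal string `"none"`,
  robust to delimiter-trimming readers.
* Synthetic raw-signal jitter is rounded Gaussian clamped to ±5 counts so
  consecutive-sample steps stay below the default delta of 12: sub-delta
  jitter is a *guarantee*, not a tendency (unbounded Gaussian jitter at
  sd 3 would cross the threshold thousands of times per million samples).
* Zero-residual model fits (exact synthetic constructions) report
  unboundedly large F with p = 0 rather than failing.
* Multi-channel logs are processed per channel; the default analyses use
  channel 0, matching a single-bottle paradigm.

## A worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_spec(n_per_group = 12, seed = 1))
processed <- process_cohort(cohort)
report <- run_analyze(processed$summaries, processed$licks)
run_report(report)
```

Every number the report prints is recomputed at run time from the simulated
cohort; neither this vignette nor the README states results the code does
not itself produce.

## Known limitations

Published inferential statistics from the motivating dataset (specific KS,
F and z values) depend on that dataset and on unstated random-effects and
degrees-of-freedom conventions, and are not targets of this package; only
the ratio/ordering contrasts are. The on-disk log schema of the original
acquisition system is not published; the two dialects here are a
reconstruction, and users aligning to a specific device should add a
dialect rather than change the defaults. Burst-within-bout hierarchies,
electrical-contact lickometers, and live acquisition are out of scope.
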