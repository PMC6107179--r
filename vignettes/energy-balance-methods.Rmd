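---
title: "Energy-balance methods for circuit-training trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-balance methods for circuit-training trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enerbal)
```

## The problem

Exercise interventions for weight management succeed or fail through the
energy ledger: the daily difference between what a participant eats and
what she expends at rest, in habitual movement, and in the training
sessions themselves.  `enerbal` implements that ledger end to end for the
common three-arm longitudinal design — a control arm, a training arm, and
a training-detraining arm, each assessed at baseline, mid-intervention and
post-intervention — together with the physiological sub-computations the
ledger needs and the repeated-measures statistics used to test group-by-time
effects.  A deterministic synthetic-trial generator with known ground truth
makes every stage testable without access to participant data.

## Physiological model

**Resting metabolic rate.** Resting gas exchange (steady-state VO~2~ and
VCO~2~, L/min) converts to a 24-hour RMR by the Weir equation,

$$\mathrm{RMR} = (3.941\,\dot VO_2 + 1.106\,\dot VCO_2)\times 1440
\ \mathrm{kcal/day}.$$

The coefficients are the classic 1949 values; they are stored in the
constants object (`eb_constants()`) rather than hard-coded, as are all
other energy constants, and every pipeline report embeds the constants it
was computed with.

**Session energy decomposition.** The total energy cost of a monitored
session is the sum of three components:

* *Aerobic*: mean exercise VO~2~ (mL/kg/min) × body mass × duration,
  converted at 5.05 kcal (21.14 kJ) per litre of oxygen.  The aerobic
  integration uses the full monitored session duration per phase
  (23/38/41/41 min), since oxygen uptake remains elevated through the
  timed recovery intervals of a circuit session.
* *Anaerobic*: net blood-lactate accumulation (post − pre, mM) converted
  to an oxygen equivalent, by default 3.0 mL O~2~/kg/mM (the di Prampero
  convention), then to kilocalories.  Negative accumulation clips to zero
  — recovery-flavoured sessions can end below baseline.  The equivalent is
  deliberately a configuration constant: group-level anaerobic energies
  reported for this style of protocol imply effective constants nearer
  7 mL/kg/mM, and no single standard value reproduces them, so the
  package keeps the conventional default and leaves the constant visible.
* *EPOC*: the excess post-exercise oxygen volume, either a minute-sampled
  trace integrated by the trapezoid rule or a pre-integrated litre volume,
  times the same caloric equivalent.

**Training load.** Session intensity in METs is VO~2~/3.5.  MET-hours per
session multiply METs by the *metabolic duration* — the span over which
session METs and kcal/min are expressed — which defaults to 18/30/36/36 min
for the four phases: the unique values jointly consistent with the
MET-hour and kcal-per-minute chains of this protocol family.  The circuit
arithmetic (rounds × exercises × 1 min: 20/33/36/36) is retained as a
selectable alternative.  Weekly load is per-session MET-hours × 3
sessions/week.  Heart-rate intensity is expressed both as %max (against
the treadmill-test maximum) and as %heart-rate-reserve, with a flag for
the ≥65 %HRR prescription.

## Accelerometry

Sixty-second epoch count streams are processed in four steps.

1. *Non-wear detection* on vector magnitude: a minute is non-wear when it
   lies in a run of ≥90 zero minutes, tolerating nonzero interruptions of
   ≤2 min flanked by ≥30 zeros on each side.  The detector is a pure
   function of the stream (idempotent), and the test suite proves it
   equivalent to an O(n²) brute-force scanner.
2. *Intensity classification* at the vector-magnitude cut-points
   sedentary ≤199, light 200–2689, moderate 2690–6166, vigorous ≥6167
   counts/min; MVPA is ≥2690.  The published band list leaves 199–200
   unassigned and caps vigorous at 9642; we close the gap by defining
   sedentary as ≤199 and treat 9642 as a reporting edge, not a cap, so the
   bands partition all counts.
3. *Daily summaries* over wear time only: steps, band minutes (which
   partition wear time exactly), activity kilocalories from a
   Freedson-style vertical-axis equation gated at >1951 counts/min, and
   mean METs.  The kcal/MET equations are configuration constants: the
   exact proprietary algorithm behind published daily-kilocalorie tables
   is unstated, and these forms land synthetic days inside the published
   group range (≈160–215 kcal/day), which is all we claim.
4. *Wear validity*: a subject-assessment is retained when ≥4 days carry
   ≥600 wear minutes (boundaries inclusive); partial first/last days are
   excluded from the count.

## Intake and the ledger

Diet-recall days carry macro grams; energy is always recomputed at
Atwater factors (4/4/9 kcal/g), so macro shares computed on energy sum to
100 by construction.  Supplied kilocalorie columns are cross-checked and
flagged beyond 5%.  The isocaloric target multiplies RMR by an activity
factor (default 1.3, flagged as an assumption; the dietitian's actual
multiplier in such trials is rarely reported).

The ledger itself is an accounting identity, not a physiological model:
`balance = intake − (RMR + habitual activity + exercise)`, per day, typed
exercise or non-exercise; weeks compose as 3 exercise + 4 non-exercise
days; cumulative balances convert to fat-mass equivalents at 7700 kcal/kg
(configurable — published round numbers for comparable deficits imply
≈7490 kcal/kg).  The thermic effect of food is excluded by default,
mirroring designs that do not measure it (an optional fixed-fraction hook
exists), and no double-counting correction is applied between RMR and
accelerometer kilocalories — a fidelity-over-physiology choice that
reproduces how such studies sum the components.

## Trial statistics

The two-way treatment×time analysis is implemented as a mixed (split-plot)
ANOVA — group between subjects, timepoint within — which matches the data
structure of this design.  Sphericity is tested with Mauchly's test; when
violated at α = 0.05 the within-effect degrees of freedom are
Greenhouse-Geisser corrected (an always-correct mode is available).  The
epsilon estimate uses the pooled within-group covariance of the repeated
measures.  Subjects missing any timepoint are dropped with a logged count,
mirroring complete-case trial practice.  Post-hoc comparisons are
Bonferroni-adjusted over the family of all between-group contrasts within
timepoint plus all within-group timepoint contrasts.

Effect sizes are bias-corrected Hedges' g with pooled n−1-weighted SD,
J = 1 − 3/(4N − 9), and the standard normal-theory CI.  Published
phase-contrast effect sizes for this protocol family are *not* exactly
reproducible from published means and SDs under any standard pooled-g
formula (the generating n and variance model are unstated); the package
reports its own g and documents the divergence rather than matching
printed values.  Qualitative bands are none/small/medium/large at
0.2/0.5/0.8 on |g|.

ANCOVA adjustment (body mass by daily intake and steps) fits a linear
model with covariates entered first, so sequential F tests for the design
factors are covariate-adjusted; adjusted cell means are predictions at
covariate grand means, and collinear covariates are flagged.

## The synthetic trial

The generator's defaults are data, not code: a versioned YAML
(`inst/extdata/trial_defaults.yaml`) holding the emulated study's group
sizes (21/14/14), baseline distributions, per-phase session physiology,
activity and intake targets, and per-group per-timepoint outcome means
and SDs for eleven outcomes.

Design choices worth knowing:

* Baselines are truncated normals (±3 SD).  Height is additionally
  truncated, given the drawn mass, so BMI lands inside the 25.1–34.9
  inclusion window — an eligibility screen.  Screening shifts the height
  marginal by under a centimetre while keeping the mass marginal exact.
* Session lactates enforce pre < mid ≈ post by lower-truncated draws;
  phase targets rise monotonically over phases 1–3; the detraining arm
  generates no phase-4 sessions.
* Activity streams are two-state Markov chains (persistence 0.75) over
  full-day wear with lognormal counts within state; in-state count levels
  keep a safety margin to the band edges so integer axis rounding cannot
  move an epoch across a cut-point.  Step cadences are calibrated so
  expected daily steps hit the subject's target; MVPA minutes hit their
  target in expectation through the state mixture.
* Intake uses a 6% day-level CV — deliberately low, describing adherence
  to a prescribed isocaloric diet rather than free-living intake — and
  jitters the macro split inside the prescription bands.
* Outcome trajectories are group-timepoint means plus a subject random
  intercept and residual noise scaled to the per-timepoint SDs, giving a
  compound-symmetric within-subject correlation of 0.7 (ICC); sphericity
  violations for testing the Mauchly/Greenhouse-Geisser path are created
  by heteroscedastic occasion noise in the test suite.

All randomness flows from a single seed; identical (config, seed) pairs
give byte-identical output files.

What the generator does *not* emulate: within-session heart-rate time
series, dropout/attrition processes, seasonal or day-of-week activity
structure, and free-living dietary variance.  Passing round-trip tests
therefore demonstrate that the analysis stack recovers the generator's
targets under clean compound-symmetric, truncated-normal conditions — not
that it is robust to every pathology of field data.

## Numerical choices and degenerate inputs

* A constant outcome panel returns F = 0, p = 1 rather than 0/0.
* Greenhouse-Geisser ε is clamped to (1/(k−1), 1].
* EPOC traces of length one integrate as one minute at that rate; empty
  traces are zero.
* Zero-wear days are returned flagged with undefined mean METs rather
  than dropped silently.
* All-zero intake fails every prescription criterion instead of erroring;
  macro shares that do not sum to ~100 (±2) are rejected before banding.
* Negative lactate accumulation clips to zero; negative counts, grams or
  gas volumes are validation errors with the offending row reported.

## Problem sizes in the test suite

The bundled tests run the heavy property checks at sizes chosen to
exercise the asymptotics while staying desk-scale: 500 null trials for
type-I calibration of the interaction test (Kolmogorov–Smirnov at
α = 0.01), exhaustive cut-point lookup over counts 0–20000, brute-force
non-wear scans over random 1440-minute days, 280-day ledger conservation,
15 replicate weeks for step/MVPA recovery, 500 simulated sessions for the
phase-2 energy chain, and 300 replicates of the 49-subject trial for
direction recovery of all eleven outcome effects.  The weakest configured
effect (fat-free mass, +1.5 kg against a ≈3.3 kg change SD at n = 14)
sits almost exactly at the 95% recovery boundary; that is a property of
the emulated effect sizes, not of the implementation.

## Limitations

The ledger ignores adaptive thermogenesis and treats RMR, habitual
activity and exercise cost as independently additive.  The anaerobic
component inherits the uncertainty of the lactate-oxygen equivalent.  The
statistics module implements the split-plot ANOVA/ANCOVA family only —
no random-slope mixed models, and no fully-within designs.
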