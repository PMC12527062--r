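---
title: "Model-based stride length and walking distance from smart insoles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based stride length and walking distance from smart insoles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolestride)
```

## The problem

Clinical walking tests such as the six-minute walk test (6-MWT) summarize a
patient's capacity as a total distance. A smart insole — a shoe insert with a
3-axis accelerometer and four plantar pressure sensors (heel, great toe,
first and fifth metatarsal heads), sampled at 40 Hz — can estimate that
distance without cameras or GPS if it can estimate the *average stride
length* `L`, because

```
Td = L * Ns
```

where `Ns` is the stride count. This package implements two model-based
estimators of `L` from a single antero-posterior (AP) acceleration channel
plus the pressure channels, the gait-event segmentation they require, a
synthetic-signal generator with ground truth, and the validation statistics
used to compare estimated and actual outcomes.

## The reference gait model

Between two consecutive toe-offs of the same foot, the AP foot position is
modelled as a cubic polynomial

```
P(t) = c1 t^3 + c2 t^2 + c3 t + c4,   t in [0, T]
```

with boundary conditions `P(0) = 0` (the toe-off opens the cycle at the
origin), `V(0) = V(T) = 0` (the foot is momentarily at rest at both
toe-offs), and `P(T) = L`. These force `c3 = c4 = 0` and give the closed
form `c1 = -2L/T^3`, `c2 = 3L/T^2`. Velocity and acceleration follow by
differentiation; the acceleration `A(t) = 6 c1 t + 2 c2` is *linear* in
time, and its slope `6 c1 = -12 L / T^3` — the *director coefficient* — is
the model quantity both estimators exploit.

Because the original reference trajectory (one participant's short motion
capture walk) is not needed to use the method, the package supports both an
analytic constructor (`analytic_reference_model(L, T)`, fully determined by
the stride length and period) and a least-squares fit to a measured
trajectory (`fit_reference_polynomial()`). The constrained fit imposes the
terminal-velocity condition *exactly*, by variable elimination
(`c2 = -1.5 c1 T`), rather than via penalty terms: the boundary conditions
are invariants of the model, not soft preferences. The analytic form is the
default reference in all tests.

The cubic is known to misfit the very start of a measured cycle (a few
centimetres in the first ~0.15 s); no correction is applied because none is
defined — the model is used as stated.

## Event detection

* **Toe-off (insole)**: peaks of the great-toe pressure are found with a
  minimum separation (default 0.4 s — a stride at fast walking speed still
  lasts > 0.5 s) and a prominence threshold (default 0.2 of the channel
  range, which makes detection invariant to uniform pressure scaling). The
  event is the first sample after the peak where pressure drops below half
  the peak value: "the end of the maximum pressure". Both fractions are
  configurable because the qualitative rule admits several operational
  forms.
* **Heel-strike (insole)**: within each toe-off-to-toe-off window, the
  sample of maximum AP acceleration that is also a local maximum (the
  impact transient). Windows with no local maximum are skipped and logged.
* **Motion-capture rules** (used only to segment reference trajectories):
  toe-off is the vertical-displacement minimum searched 0.1-0.8 s after the
  previous toe-off; heel-strike is the onset of the per-cycle AP
  displacement plateau (derivative below 0.02 m/s for at least 3
  consecutive samples, after the cycle's velocity peak).

Ties in maxima/minima resolve to the earliest sample. Indices are 1-based
(the R convention); cycle windows are half-open `[toe_off, next_toe_off)`,
and the swing window is half-open `[toe_off, heel_strike)` so that the
heel-strike impact spike — which is the *detection feature* for the event —
never contaminates the swing-phase line fit.

## Approach 1: director-coefficient ratio

Per cycle, the straight line best fitting the swing-phase AP acceleration
(ordinary least squares, after centering) gives a measured director
coefficient; its ratio to the model's `|6 c1|` is `R_i`; `L = Px * mean(R)`
with `Px` the model stride length.

**Cadence normalization.** The director coefficient scales as `T^-3`, so a
raw ratio conflates stride length with cycle duration. The package
therefore re-times the model to each cycle's measured duration before
forming the ratio: the denominator is `|6 c1| * (T_model / T_cycle)^3`,
equivalently the director coefficient of the same-`Px` model with the
cycle's own period. This makes the ratio a pure amplitude/length ratio: on
signals generated from the model itself the estimator recovers the true
stride length to machine precision at any cadence. The literal
un-normalized ratio is available with `time_normalize = FALSE`. Absolute
values are used on both sides of the ratio because the model's `6 c1` is
negative under the boundary conditions while a measured slope can carry
either sign; the inverse ratio convention is available as a flag.

## Approach 2: DTW scaling

Per cycle, `d_i = DTW(A_model_swing, A_insole_swing)` — classic dynamic
programming with absolute-difference local cost, unconstrained band,
match/insert/delete steps, and the raw (un-normalized) cumulative cost;
path-length normalization and squared local cost are available as options
since the method is named but not parameterized. The scaling coefficient
`S = 1 / ||A_swing||` uses the mean absolute value of the pooled swing
acceleration by default (`S` is computed once, before the per-cycle loop;
Euclidean and max-absolute norms, and a per-cycle `S`, are options). Then
`E = mean(d) * S` and `L = Px * E`.

The model swing segment is the first 60% of the model cycle by default
(configurable), sampled at the insole rate; each insole swing window is
linearly resampled onto that grid before alignment so that DTW cost does
not grow mechanically with cadence.

Taken literally, this formulation gives `L = 0` when the insole
acceleration coincides with the model's (all `d_i = 0`). That degeneracy is
inherent to the stated equations; the package implements them as stated,
emits a degenerate-similarity warning, and invents no corrective
calibration. Consequently the synthetic recovery guarantees in the test
suite apply to Approach 1 only; Approach 2 is verified against
hand-executed values of its own equations.

## Validation statistics

* **Accuracy**: `(1 - |actual - estimated| / actual) * 100%`, reported at
  2 decimals alongside the unrounded value. It is deliberately asymmetric
  in its arguments (a test guards against "symmetrized" rewrites).
* **Median / interquartile**: median plus `Q3 - Q1` under the SPSS
  weighted-average percentile rule (position `(n+1)p`; R quantile type 6),
  with Tukey hinges as the alternative. The printed interquartiles in the
  reference tables are internally inconsistent across tables, so IQRs are
  reported but never regression-tested.
* **Mann-Whitney U**: midrank-based, reporting `min(U1, U2)` (the SPSS
  convention). The exact two-sided p-value is the permutation tail
  `P(min(U1, U2) <= U_obs)` over all group assignments (used when both
  groups have <= 10 observations); this convention reproduces every
  published p-value of the reference tables to three decimals. The
  asymptotic p uses the tie-corrected normal approximation without
  continuity correction. Both are always returned.
* **ICC**: single-measures intraclass correlation from the two-way ANOVA
  decomposition; default form is two-way random effects, absolute
  agreement (ICC(A,1)), with consistency (ICC(C,1)) and one-way forms
  selectable, 95% CIs from F-distribution bounds, and the interpretation
  bands excellent (> 0.90) / good (0.75-0.90) / moderate (0.50-0.74) /
  poor (< 0.50). The reference publication does not state which ICC form it
  used and its printed ICCs do not match any standard single-measures form
  computed from its printed tables, so ICCs are checked against this
  package's own closed-form ANOVA oracle, never against the printed values.

## The synthetic world

`generate_recording()` emulates the study protocol: by default strides of
1.591 m (the cohort's median actual stride length) with 0.9 s cycles
(1.77 m/s, inside the cohort's 1.62-2.22 m/s speed range), 60% swing,
40 Hz. Per stride, the swing-phase AP acceleration *is* the model's linear
acceleration for that stride's `(L, T)`; the heel-strike is a short
dominant acceleration spike; great-toe pressure is a rise-plateau pulse
ending exactly at toe-off and heel pressure starts at heel-strike
(raised-cosine shapes, amplitude 100 arbitrary units, since the insole's
pressure units are unspecified). Gaussian noise is added per the profile;
one private RNG stream per call makes output bitwise-reproducible given the
seed. Event times are snapped to the sampling grid *before* waveform
synthesis, so ground-truth indices are exact integers and duration
round-off cannot leak into the recovery tests.

`generate_mocap_trajectory()` emulates the 100 Hz reference capture
(default six 0.5 m cycles — a 3 m walk): the AP displacement follows the
constrained cubic over the swing window and holds a stance plateau, and the
vertical channel is a smooth arch whose unique per-cycle minimum falls
exactly at toe-off. The default 0.7 s period stays below the 0.8 s
upper search lag of the toe-off rule.

What a green test on this world establishes: the estimators, detectors and
statistics implement their stated equations, and the whole pipeline is
self-consistent (noise-free recovery to machine precision, graceful
degradation under noise). What it does not establish: performance on real
gait — the generator has no turns, no drift, no inter-stride variability
beyond what the profile states, no pathological patterns, and its swing
acceleration is exactly model-shaped, which flatters Approach 1.

## Numerical and design choices

* Constrained fitting by exact variable elimination, not penalties.
* OLS slope with explicit centering; zero time-variance is an error, a
  zero slope contributes a zero ratio with a warning.
* DTW cost matrix in plain R (windows are ~20-60 samples; no need for
  compiled code).
* Exact U enumeration via `combn` on midranks (feasible through
  10 + 10); beyond that the tie-corrected normal approximation is used.
* Ties everywhere resolve to the earliest sample; comparisons on
  enumerated U values carry a 1e-9 guard against floating midranks.
* Degenerate inputs (flat pressure, all-zero swing, zero between-subject
  variance, zero-length models) raise classed errors or warnings rather
  than producing silent numbers.

## Known limitations

* Approach 2 is implemented exactly as specified and therefore measures
  dissimilarity-scaled length, not calibrated length; it returns 0 for a
  perfect model match.
* Turn segments of a back-and-forth walk are not detected or removed.
* Only the AP axis is used; rotation information is discarded.
* The bundled reference tables contain a small number of cells that an
  independent oracle cannot confirm (one inconsistent stride count, three
  last-digit accuracy roundings, one half-ulp product rounding, two U
  statistics); these are shipped in a `known_discrepancies()` manifest and
  excluded from regression, never silently corrected.
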