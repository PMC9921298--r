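---
title: "Detecting within-person gait change from a single thigh gyroscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-person gait change from a single thigh gyroscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridewarp)
```

## The problem

Gait rehabilitation — for example physiotherapy for people with lower-limb
amputations — needs an objective way to tell whether a person's walking
pattern actually changed over a training session. Conventional gait analysis
answers this with batteries of discrete spatiotemporal and kinematic
parameters, which require multi-sensor systems and a pre-committed choice of
what to measure. `stridewarp` implements the complementary
continuous-signal approach: treat each gait cycle of the angular-velocity
magnitude from a *single* thigh-worn gyroscope as a curve, and ask whether
the curves recorded after training are distinguishable from the curves
recorded before, for that one person. Because the model is person-specific —
trained and evaluated on one individual's strides only — it makes no
assumption about what "typical" gait looks like and needs no normative
database, which matters for clinically heterogeneous populations.

A session is described by four walking conditions: `PRE_NP` (baseline, no
prompting), `MID_P` (mid-training, with therapist prompting), `POST_P`
(immediately post-training, with prompting), and `POST_NP` (post-training
after a short rest, no prompting). The classifier learns the contrast
`PRE_NP` vs `POST_P`; the two intermediate conditions are then scored
against those two references, which turns the classifier into a probe of
*where* mid-training and post-rest gait sit between baseline and trained
gait.

## The pipeline

1. **Segmentation.** The tri-axial recording is cut into gait cycles at
   successive same-side foot strikes taken from an event table. Event times
   map to sample indices by `floor(t * fs)` and windows are half-open, so
   the cycles partition the samples between the first and last strike
   exactly (`segment_strides()`).
2. **Time normalization.** Each axis of each cycle is linearly resampled
   onto `L` points spanning 0–100% of the cycle (`time_normalize()`),
   removing cadence and speed differences so the comparison is about shape.
3. **Magnitude.** The three axes collapse to the per-sample norm
   $|v| = \sqrt{v_x^2 + v_y^2 + v_z^2}$ (`stride_magnitude()`), which
   removes sensitivity to sensor yaw about the signal direction. Axes are
   resampled before the norm is taken; the two orders differ only by
   interpolation error, and the resample-then-magnitude order follows the
   pipeline this package models.
4. **Distances.** Two stride-to-stride metrics (`pairwise_distances()`):
   - *normed Euclidean*: $\|x - y\|_2 = \sqrt{\sum_i (x_i - y_i)^2 / n}$,
     the RMS pointwise difference;
   - *dynamic time warping*: the accumulated cost
     $\Theta(i,j) = D(i,j) + \min[\Theta(i-1,j-1), \Theta(i-1,j),
     \Theta(i,j-1)]$ with squared local errors
     $D(i,j) = (x_i - y_j)^2$, a monotone and complete matching, and a
     Sakoe–Chiba band $|i - j| \le w$. The returned value is the raw
     terminal cost $\Theta(n,m)$; any strictly monotone transform of the
     distances leaves nearest-neighbor decisions unchanged, so no path
     normalization is applied.
5. **Classification.** The pairwise distance is the lone feature: a
   k-nearest-neighbor vote over the training strides (`knn_label()`), with
   stratified five-fold cross-validation over equal-sized classes
   (`cross_validate()`), per-class accuracies, and F1 with `POST_P`
   positive. `MID_P`/`POST_NP` strides are labeled against the full
   equalized training sets (`classify_condition()`), reported as the two
   classified fractions (summing to one by construction).
6. **Validation layer.** Ten common gait parameters (stance times, stance
   symmetry, double support, step lengths, hip/knee flexion–extension ROM)
   are computed per stride and tested across conditions with a one-way
   ANOVA followed by Tukey HSD (`significance_report()`); a participant's
   gait is deemed changed overall when at least half of the testable
   parameters differ between `PRE_NP` and `POST_P`.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `L` | 101 | Normalized stride length: 0–100% of the cycle in 1% steps, the conventional grid in gait analysis. The source pipeline does not state its value. |
| DTW `window` | `ceiling(0.10 * L)` = 11 samples | Warping band half-width. The source work chose its window empirically and does not report it; a 10% band is the standard default for constrained DTW. Window 0 reduces DTW to `n` times the squared normed Euclidean distance; `Inf` removes the constraint. |
| `k` | 1 | Neighbor count. The distance-based lineage this method follows is a nearest-neighbor one, so plain 1-NN is the default; `k` is constrained odd so a two-class vote cannot tie. |
| folds | 5 | 20% of each class held out per fold. |
| fold `seed` | 17 | Fold shuffling is the only randomness in the analysis path; it is always explicit. |
| `alpha` | 0.05 | Level for the omnibus ANOVA and the Tukey-adjusted pairwise tests. |

Resampling is linear by default (cubic available behind
`method = "cubic"`): the interpolant used originally is unstated, and the
linear rule keeps the reference pipeline deterministic, shape-preserving,
and exactly idempotent at length `L`. No stride-amplitude normalization is
applied anywhere (none is described for the original pipeline); stride
admission applies no outlier rejection by default, with
`max_duration_factor` available as an explicit hook.

Class sizes are equalized by truncating the larger class, dropping the
latest-collected strides — keeping the earliest, most-rested gait — because
the equalization method is not specified in the source description and
truncation is deterministic. The decision rule reading of "the distance is
the lone feature" is the per-stride kNN vote; the alternative reading (the
mean distance to each class as a scalar summary) ships as
`rule = "nearest-centroid-distance"` but is not the default.

## The synthetic session generator

The original recordings are not publicly available, so the package carries a
first-class generator (`generate_session()`) that emulates the study
conditions end to end: four conditions, 100–125 strides each at 100 Hz,
stride durations Normal(1.1 s, 0.05 s) truncated above 0.3 s.

Each stride's magnitude profile is a baseline floor (25 deg/s) plus two
Gaussian bumps in normalized time — a moderate early-stance bump (center
0.12, amplitude 120 deg/s) and a dominant swing bump (center 0.72,
amplitude 260 deg/s) — the qualitative shape of a thigh angular-velocity
magnitude. The sum-of-bumps family was chosen over a harmonic series
because each clinically meaningful change (a peak's height or timing) is
one parameter, making effect sizes interpretable. The changed class shifts
bump amplitudes by (+40, +60) deg/s and centers by (+0.02, −0.03); the
intermediate conditions interpolate with blends `mid_blend` (default 0.75:
training largely but not fully consolidated mid-session) and
`postnp_blend` (default 1: short-term retention). With the default
per-stride jitter (amplitude SD 8 deg/s, center SD 0.01) and per-axis
sensor noise (SD 6 deg/s), the between-class mean separation is roughly
250 deg/s in stride-curve L2 norm against a within-class spread of roughly
40, i.e. a Bayes error far below $10^{-3}$ by construction — the default
session is meant to emulate a participant whose gait clearly changed.
Setting the class shift to zero gives the matching no-change control
(`generate_no_change_session()`), for which cross-validated accuracy is
chance-level by symmetry.

Two design points deserve emphasis:

- **Magnitude reconstruction.** The scalar profile is written onto fixed
  direction cosines (0.8, 0.5, 0.33)/norm, so the per-sample norm recovers
  the profile exactly before noise; noise is then added per axis.
- **The variance knob is exact.** `variance_ratio` scales the changed
  class's stride-to-stride waveform *deviation field* (the baseline shape's
  response to the jittered bump parameters) plus its sensor noise, rather
  than the jitter SDs themselves. Scaling the center-jitter SD directly
  changes per-timepoint SD sublinearly (bump displacement is a nonlinear
  map), and the class shape shift would otherwise leak into the dispersion
  ratio; with the deviation-field formulation the post/pre mean
  per-timepoint SD ratio equals the knob essentially exactly, so a
  configured ratio of 2.13 reproduces a dispersion F-value of about 2.13.

The kinematic layer writes per-stride raised-cosine joint-angle arcs whose
per-cycle ROM is the configured per-class target plus jitter, and foot
positions that stay planted through stance and advance linearly through
swing, reaching each new plant two samples before the strike so that
nearest-sample lookups at strike instants read the plant exactly. Stance
occupies 0.62 of the cycle with a 0.5-cycle contralateral lag — standard
gait physiology — which fixes the true double-support fraction at about
24% of the cycle. The default changed class moves both step lengths
(+0.08/+0.06 m) and all four ROMs (+4–6°), so six of the ten parameters
change: a generated "changed" session also *tests* as changed under the
50% rule, mirroring how the classifier's two-class premise was validated
against gait parameters in the source study.

What the generator does **not** emulate: real thigh gyroscope harmonics
beyond two bumps, within-session drift or fatigue trends, event-detection
errors (events are exact), turning strides at walkway ends, and any
coupling between the waveform and the kinematic layer (they are generated
independently given the condition). Passing tests on synthetic sessions
therefore demonstrate the correctness and calibration of the machinery,
not clinical performance on real recordings.

## Numerical choices and degenerate inputs

- Distance ties in the kNN vote break by lower training index, making every
  decision deterministic; classified fractions are computed as `f` and
  `1 - f` so conservation is exact in floating point.
- The same fold permutation is applied to both (equal-sized) classes, which
  makes label-swap symmetry exact rather than statistical.
- DTW treats out-of-band cells as `+Inf`; a band narrower than the length
  difference of the two inputs is an error, not a silent fallback.
- Readers never resample: a declared sampling rate inconsistent with the
  median inter-sample interval by more than 1% is an error.
- Degenerate inputs fail loudly: strides of fewer than two samples, stride
  sets of fewer than two strides for SD summaries, empty distance rows,
  truth vectors with no positive instances for F1.
- The omnibus ANOVA is the calibrated gate: under the null it rejects at
  `alpha` by construction, while the Tukey-gated `PRE_NP` vs `POST_P`
  `changed` flag is familywise-controlled across the six condition pairs
  and is therefore deliberately conservative (its null rate is well below
  `alpha`). The per-stride samples are treated as independent replicates
  within conditions — the closest implementable stride-level reading of a
  within-participant repeated-conditions design.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at the protocol scale (100–125
strides per condition, `L = 101`) for single-session checks, and use 20
generator seeds for the calibration properties (chance-level accuracy under
no change, even splits of a half-blended condition, the dispersion-ratio
knob) and 200 replicates for the type-I calibration of the omnibus test.
The DTW implementation is verified exactly against brute-force enumeration
of all monotone complete warping paths on 200 random integer pairs of
length at most 8 — small enough for exhaustive enumeration, large enough to
exercise every step pattern.

## Known limitations

- Events must come from an external source; the package does not detect
  foot strikes from the gyroscope itself.
- The two-class premise is binary: a gait that changed in a way that loops
  back to a baseline-like waveform would be scored as unchanged.
- Unequal class variance biases kNN toward the tighter class — visible in
  real data when the newly trained gait is still consolidating; the
  `variance_ratio` knob exists precisely to study this regime.
- Per-stride ANOVA treats strides as exchangeable; serial correlation
  within passes would make the tests anti-conservative on real data.
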