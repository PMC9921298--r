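# stridewarp

Person-specific classification of gait change from a single thigh-worn
gyroscope.

## What it is for

Gait rehabilitation needs an objective answer to a simple question: did this
person's walking pattern actually change over a training session?
`stridewarp` answers it from the continuous angular-velocity signal of one
inertial sensor on the thigh, with no predefined gait parameters and no
normative database. It is aimed at wearable-sensor and rehabilitation
researchers who have per-trial gyroscope recordings plus foot-contact
events, and want a within-person, stride-level change score — together with
a conventional gait-parameter validation layer to check that a detected
change is clinically real.

## The method

Each recording is segmented into gait cycles at same-side foot strikes.
Every cycle is resampled to a fixed length *L* (0–100% of the gait cycle)
and collapsed to its angular-velocity magnitude

$$|v| = \sqrt{v_x^2 + v_y^2 + v_z^2}.$$

Strides from two conditions — baseline (`PRE_NP`) and post-training
(`POST_P`) — are compared with either the normed Euclidean distance

$$\lVert x-y \rVert_2 = \sqrt{\tfrac{1}{n}\textstyle\sum_i (x_i-y_i)^2}$$

or banded dynamic time warping with squared local errors,

$$\Theta(i,j) = (x_i - y_j)^2 + \min\left[\Theta(i{-}1,j{-}1),\ \Theta(i{-}1,j),\ \Theta(i,j{-}1)\right],\qquad |i-j|\le w,$$

whose terminal cost $\Theta(n,m)$ is the distance. The pairwise distance is
the lone feature of a k-nearest-neighbor classifier (default 1-NN)
evaluated with stratified five-fold cross-validation on equal-sized
classes; mid-training (`MID_P`) and post-rest (`POST_NP`) strides are then
assigned to whichever reference condition they resemble. A parallel layer
computes ten common spatiotemporal/kinematic parameters per stride and
tests them across conditions (one-way ANOVA + Tukey HSD, with a ≥50%-of-
parameters rule for overall change). A synthetic session generator with
controllable class separation, blend conditions, and variance structure
makes the whole pipeline testable without clinical data.

## Worked example

```r
library(stridewarp)

cfg <- synth_config(seed = 42)          # a session whose gait clearly changes
session <- generate_session(cfg)
session
#> <synth_session>
#>   PRE_NP: 105 cycles, 11690 samples @ 100 Hz
#>   MID_P: 103 cycles, 11434 samples @ 100 Hz
#>   POST_P: 121 cycles, 13378 samples @ 100 Hz
#>   POST_NP: 109 cycles, 12065 samples @ 100 Hz

sets <- lapply(session$conditions,
               function(cd) build_stride_set(cd$recording, cd$events))

res <- cross_validate(sets$PRE_NP, sets$POST_P,
                      metric = "dtw", config = dtw_config(11))
res$fractions$MID_P  <- classify_condition(sets$MID_P,  sets$PRE_NP, sets$POST_P,
                                           metric = "dtw", config = dtw_config(11))
res$fractions$POST_NP <- classify_condition(sets$POST_NP, sets$PRE_NP, sets$POST_P,
                                            metric = "dtw", config = dtw_config(11))
res
#> <classification_result> metric=dtw k=1 folds=5 (n=105/class)
#>   accuracy PRE_NP 1.000 +/- 0.000 | POST_P 0.990 +/- 0.021 | F1 0.995
#>   MID_P: 0.000 PRE_NP / 1.000 POST_P
#>   POST_NP: 0.000 PRE_NP / 1.000 POST_P

variance_summary(sets$PRE_NP, sets$POST_P)
#> <variance_summary> mean per-timepoint SD: pre 10.2480, post 10.8293; F = 1.0567

significance_report(session_parameters(session))
#> <significance_report> 6/10 parameters changed (alpha=0.05) -> overall CHANGED
```

Reading the output: cross-validated accuracy near 1 on both reference
conditions means the pre- and post-training stride shapes are cleanly
separable; the `MID_P`/`POST_NP` fractions say those strides look like
trained gait (here, blends of 0.75 and 1.0 toward the post waveform were
simulated); the dispersion F-value near 1 says stride-to-stride variability
did not change; and 6 of 10 gait parameters differing between `PRE_NP` and
`POST_P` confirms the session as changed under the ≥50% rule.

`run_report()` bundles all of the above (plus per-condition mean ± SD
magnitude curves) into one JSON/CSV report directory, and
`inst/scripts/stridewarp` exposes `simulate` and `report` subcommands for
shell use.

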