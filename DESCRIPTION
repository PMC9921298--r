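Package: stridewarp
Title: Person-Specific Classification of Gait Change from a Single Gyroscope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting within-person changes in walking pattern from
    the angular-velocity signal of a single thigh-worn gyroscope. Raw tri-axial
    recordings are segmented into gait cycles at foot-strike events, each cycle
    is time-normalized to a fixed length and collapsed to its angular-velocity
    magnitude, and cycles from two walking conditions are compared with either
    a normed Euclidean distance or banded dynamic time warping with squared
    local errors. A distance-based nearest-neighbor classifier with stratified
    five-fold cross-validation scores how separable the two conditions are, and
    intermediate conditions are assigned to whichever reference condition they
    resemble. A companion layer computes common spatiotemporal and kinematic
    gait parameters (stance times, stance-time symmetry, double support, step
    lengths, hip and knee range of motion) and tests them across conditions
    with one-way ANOVA and Tukey HSD. A synthetic gait-session generator with
    controllable class separation, stride-to-stride variance structure, and
    blend conditions makes the full pipeline testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
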