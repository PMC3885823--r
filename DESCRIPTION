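Package: microtd
Title: Microstimulus Temporal-Difference Models of Dopamine and Interval Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for reinforcement-learning accounts of interval timing in
    the basal ganglia. Implements temporal-difference TD(lambda) learning with
    eligibility traces over two time representations (the complete serial
    compound and microstimulus temporal basis functions), a softmax actor for
    instrumental timing tasks (peak procedure and temporal bisection), gain
    profiles over early versus late microstimuli that model dopaminergic
    manipulations, and a rectified scalar-noise model of semi-Markov
    prediction-error distributions. Provides task generators, per-time-step
    prediction-error records, response-curve and psychometric analyses, and
    reproducible experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
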