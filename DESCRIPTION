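Package: reacharm
Title: Planar Upper-Limb Reaching Simulator with Age-Parameterized Passive Muscle Stiffness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates goal-directed reaching of a planar four-segment upper limb
    (fixed upper chest; moving upper arm, forearm and hand) driven by six Hill-type
    muscles with an exponential passive force-length element whose scale, rate and
    slack-length parameters emulate age-related intramuscular connective tissue
    stiffening. Reaches track straight minimum-jerk paths under a predictive PD
    controller with inverse-dynamics feedforward and a no-co-excitation rule. The
    package maps homing-in and movement errors over the reachable workspace, computes
    per-joint co-activation and failure taxonomies (stopping short vs oscillatory),
    and tunes the seven controller parameters with a mixed-integer genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    mgcv,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
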