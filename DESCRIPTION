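Package: rmhebb
Title: Reward-Modulated Hebbian Learning in Chaotic Recurrent Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and training of continuous-time recurrent rate networks
    in the early chaotic regime with a reward-modulated Hebbian plasticity rule:
    random activation perturbations drive exploration, a supralinear (cubic)
    amplification of Hebbian co-fluctuations builds a per-synapse eligibility
    trace, and a delayed, per-trial-type reward prediction error converts the
    trace into weight changes. Includes the delayed nonmatch-to-sample and
    context-cued selective-integration working-memory tasks, gradient-ablation
    experiments comparing the rule against node-perturbation and
    Exploratory-Hebbian variants, and population analyses of trained networks
    (cross-temporal maximal-correlation decoding and orthogonal decoding of
    task variables via per-feature regression and QR orthogonalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
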