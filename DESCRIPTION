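Package: maskddm
Title: Drift-Diffusion Analysis of Emotion Judgments of Masked Faces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how face masks reshape the perception of facial
    expressions of emotion, built around the drift-diffusion model (DDM) of
    two-alternative forced-choice decisions. Provides counterbalanced
    stimulus-block and round-schedule generation for masked-expression rating
    tasks, a diffusion-process simulator that produces complete synthetic study
    datasets with known ground truth (condition-specific drift rates,
    participant heterogeneity, fast-guess contaminants, attention-check
    failures), pre-registered exclusion rules and response-time transforms, a
    Wiener first-passage-time likelihood kernel with inter-trial variability,
    hierarchical Bayesian estimation of mask-condition drift-rate and
    boundary-separation coefficients by adaptive Metropolis-within-Gibbs MCMC,
    posterior-probability hypothesis tests, cluster-bootstrap mixed-effect
    regressions of ratings and response times, and a seeded end-to-end
    pipeline with validation of every emitted table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
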