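Package: fatiguecast
Title: Survey-Fatigue-Adjusted Contact Intensity Estimation for
    Longitudinal Social Contact Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian negative-binomial models for longitudinal social
    contact surveys that are subject to survey fatigue, the progressive
    under-reporting of contacts with repeated participation. Provides
    sparsity-based (regularized horseshoe) selection of contact-intensity
    and fatigue determinants, four functional forms for fatigue dynamics
    over the number of repeat participations (notably a three-parameter
    Hill dose-response curve), an age-resolved fatigue-correcting model
    with a Hilbert-space approximate Gaussian process age effect and
    post-stratified intensity estimates, sequential multi-wave estimation
    with informative prior carry-over, and a synthetic panel generator
    with known ground truth for end-to-end validation. Inference uses an
    in-package adaptive Metropolis-within-Gibbs sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    stats,
    utils
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
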