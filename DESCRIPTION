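Package: facestates
Title: Latent Behavioural States from Pre-Stimulus Facial Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers latent behavioural states from facial features measured
    before stimulus onset, using Markov-switching linear regression (MSLR)
    fitted by expectation-maximisation with sticky Dirichlet transition
    priors. Includes trajectory-based reaction-time extraction by
    sliding-window regression, per-trial facial-feature construction from
    pose-keypoint tracks, time-blocked cross-validation with data-driven
    state-number selection, and downstream state characterisation: dwell
    times, transition structure, Kullback-Leibler state certainty,
    Vargha-Delaney stochastic superiority, Jensen-Shannon clustering of
    state emission distributions, outcome decoding, facial template
    matching, and an autoregressive trial-history baseline. A synthetic-data
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
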