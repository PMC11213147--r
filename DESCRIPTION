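Package: hybridwe
Title: Hybrid Expert and Learned-CV Weighted-Ensemble Rare-Event Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted-ensemble (WE) rare-event sampling whose bins are built
    jointly from expert collective variables (CVs) and from low-dimensional
    CVs learned on the fly by a State Predictive Information Bottleneck
    (SPIB). Provides a deterministic Brownian-dynamics engine on analytic 2D
    toy potentials with brute-force rate oracles, a weight-conserving
    split/merge resampler over pluggable bin mappers, a variational
    encoder/decoder SPIB that discovers metastable states at a lag time, the
    hybrid binning rule that routes walkers to expert bins only in
    undersampled regions, the iterative WE/SPIB retraining protocol with
    checkpointing, and downstream analysis: weighted free-energy surfaces,
    history-labelled flux rate constants with run-to-run errors, Bayesian
    bootstrap credible intervals, and the metastable state-flux network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
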