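Package: ratchet
Title: Bayesian Inference and Comparison of Stochastic Transcription
    Elongation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-dependent Brownian-ratchet models of transcription
    elongation by RNA polymerase.  Implements nearest-neighbour
    thermodynamics of the transcription elongation complex, a hierarchical
    family of twelve kinetic models with partial equilibrium
    approximations for translocation and NTP binding, force-dependent
    translocation rates from transition-state theory, exact (Gillespie)
    stochastic simulation of full-template transcription with a
    master-equation first-passage oracle, and joint Bayesian inference of
    the model indicator and kinetic parameters from single-molecule
    force-velocity-[NTP] data by MCMC approximate Bayesian computation.
    Includes convergence diagnostics (effective sample size, R-hat,
    highest-posterior-density intervals, geometric medians) and a
    synthetic-data generator emulating published optical-trapping
    experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    seqinr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
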