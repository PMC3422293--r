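Package: jsmc
Title: Human Jejunal Smooth Muscle Cell Electrophysiology Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysically based single-cell model of human jejunal smooth
    muscle electrophysiology. Eight membrane currents (Hodgkin-Huxley T-type
    Ca2+ and Kv channels; Markov-state L-type Ca2+, BK and Nav1.5 channels;
    ten Tusscher-style NaK pump and Na+/Ca2+ exchanger; a non-selective leak)
    are coupled to a phenomenological interstitial-cell-of-Cajal (ICC) slow
    wave stimulus through a constant gap-junction conductance. Intracellular
    Na+, K+ and total Ca2+ are tracked with calmodulin/calreticulin Ca2+
    buffering. The integrator combines forward Euler for the membrane
    potential, gates and ion concentrations with backward Euler for Markov
    occupancies. Protocol engines reproduce free-running slow waves, voltage
    clamp with I-V extraction, calcium-free and 2-APB perturbations, and
    conductance/kinetics sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
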