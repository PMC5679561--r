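Package: glottofit
Title: Inverse Biomechanical Fitting of a Two-Mass Vocal-Fold Model to
    High-Speed Videoendoscopy Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the self-oscillating two-mass lumped-element model of
    the vocal folds (eight coupled ordinary differential equations with
    collision forces and Bernoulli subglottal driving pressure) and fits its
    per-side mass/stiffness scaling factors (Ql, Qr) and subglottal pressure
    (Ps) to mid-membranous vocal-fold edge trajectories extracted from
    laryngeal high-speed videoendoscopy. Fitting runs three derivative-free
    optimizers (Nelder-Mead, particle swarm, bee colony) against three cost
    functions (frequency-domain, time-domain, normalized frequency-domain)
    and selects the best parameter set by a normalized Euclidean distance.
    Includes trajectory preprocessing (pixel-to-metric conversion, rest
    geometry), spectral and cycle analysis, success criteria, left-right
    symmetry quotients, group summaries, and a synthetic-subject generator
    with jitter, shimmer, noise and pixel quantization for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
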