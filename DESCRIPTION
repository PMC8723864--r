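Package: pbcsync
Title: Synchronization Analysis of Delay-Coupled Pre-Botzinger Complex
    Bursting Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conductance-based model of a pre-Botzinger complex (PBC)
    inspiratory neuron with persistent-sodium and calcium-activated
    nonspecific cation (CAN) currents, in which the dendritic calcium
    oscillation is replaced by a prescribed elliptic path in the
    (calcium, IP3-fraction) plane.  Provides fixed-step integrators for
    the single neuron and for an electrically coupled two-neuron network
    with transmission delays (method of steps with cubic Hermite history
    interpolation), spike/burst/interspike-interval extraction and
    bifurcation scans, a full set of pairwise synchronization measures
    (correlation coefficient, maximum synchronization difference,
    Poincare-section phase difference, similarity function and lag
    recovery, synchronization classification), equilibrium and Hopf
    analysis of the somatic subsystem including the first Lyapunov
    coefficient, Benettin estimation of the maximal Lyapunov exponent,
    parameter-sweep experiments, and a surrogate-trace generator with
    known ground-truth synchronization structure for validating every
    metric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
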