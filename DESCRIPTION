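Package: lddm
Title: Disinhibition-Gated Decision Circuit Dynamics, Stability Analysis and Behavioral Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for a local-disinhibition
    decision circuit, a rate model in which option-specific excitatory units
    interact through divisive gain control while a gated disinhibitory loop
    switches the network between normalized value coding and winner-take-all
    selection.  Provides Runge-Kutta integration of the circuit with
    Ornstein-Uhlenbeck noise, nullcline and Jacobian stability analysis with
    regime classification over the recurrence/disinhibition plane, persistent
    activity (line versus point attractor) analysis, task protocols for
    reaction-time, fixed-duration and delayed-response paradigms, quantile
    maximum likelihood fitting of choice and reaction-time data, equilibrium
    firing-rate fitting for trinary value-representation designs, and
    comparison models (dynamic normalization, reduced recurrent network, and
    leaky competing accumulator).  Includes synthetic data generators so the
    full pipeline can be exercised without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
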