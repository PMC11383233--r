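Package: pumpburst
Title: Pump-Mediated Slow Bursting in Class I Neurons with Extracellular
    Potassium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and slow-fast analysis of a minimal conductance-based
    neuron model in which Wang-Buzsaki spike-generating currents couple to a
    slow extracellular potassium concentration through an electrogenic
    Na+/K+-ATPase. Provides fixed-step RK4 integration of the fast and
    complete systems, spike detection and burst statistics, regime
    classification (rest, tonic, bursting, depolarization block),
    equilibrium and limit-cycle continuation of the fast subsystem with
    detection of saddle-node, Hopf, homoclinic and fold-of-limit-cycle
    bifurcations, localization of the saddle-node-loop and
    homoclinic-inflection organizing points, averaging-based reduction of
    the slow potassium dynamics into hysteresis-loop diagrams, and
    (I_max, I_app) regime maps. Results are returned as tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
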