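Package: switchbeads
Title: Stochastic-Switching Bead Models of Condensin-Mediated Chromatin Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and asymptotic analysis of chromatin bead models in
    which transient condensin-like crosslinks switch on and off as a
    continuous-time Markov chain with position-dependent binding rates.
    Provides a hybrid Euler-Maruyama/Markov-switching integrator for the
    overdamped Langevin dynamics, enumeration of binding states and their
    generator matrix, the time-averaged drift field and its fixed points,
    most-probable transition paths by the string method, effective-potential
    and quasipotential barrier heights with Arrhenius-law lifetime
    predictions, Monte-Carlo escape-time experiments, and cluster-regime
    metrics (mixing coefficient, nearby-bead counts, unbound fractions,
    cluster persistence) for many-bead trajectories.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    minpack.lm,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
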