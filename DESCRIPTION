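Package: motorcycle
Title: Chemomechanical Cycle Analysis for Processive Kinesin Motors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for dissecting the chemomechanical cycle of processive
    kinesin motors such as the kinesin-3 KIF1A. Provides the deterministic
    algebra of the stepping cycle (kinetic-race processivity, cycle time
    budgets, off-rate hyperbolae, derived motility quantities), a
    continuous-time Markov chain (Gillespie) simulator of the canonical
    stepping cycle on finite microtubules, maximum-likelihood estimation of
    mean run length under end-of-track censoring with asymptotic and
    bootstrap uncertainty, fitting routines for stopped-flow transients,
    pseudo-first-order rate series, saturation curves and dwell-time
    distributions, and seeded synthetic-data generators that emulate the
    single-molecule and stopped-flow assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    minpack.lm,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
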