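Package: crossfeedr
Title: Minimal Metabolic Change Required for Cross-Feeding to Evolve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of how much metabolic rerouting a
    glucose-limited ancestral bacterium needs to give rise to producer and
    consumer strains of a cross-fed metabolite. Implements flux balance
    analysis (FBA), parsimonious FBA, regulatory on/off minimization (ROOM)
    as a mixed-integer program, a heterogeneous-ancestor variant that finds
    ancestral and evolved flux distributions jointly, minimization of
    metabolic adjustment (MoMA), flux-change classification, gene/operon/
    regulon mapping of changed reactions, metabolite ranking by total
    metabolic distance, and a glucose-consumption sweep. Ships a
    bounded-variable simplex and branch-and-bound core, deterministic toy
    network generators, and brute-force oracles so the whole pipeline is
    testable on small fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    quadprog,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Depends:
    R (>= 4.1)
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
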