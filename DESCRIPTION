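Package: kidscape
Title: Discovery and Characterization of Kinase Insert Domains in Plant
    Receptor-Like Cytoplasmic Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and characterizing the
    kinase insert domain (KID) of receptor-like cytoplasmic kinase
    subfamily XI: profile hidden Markov model homology search with Gumbel
    E-value calibration, kinase subdomain anchoring and KID delineation
    between the DFG and APE tripeptides, intrinsic-disorder propensity
    profiling, single-occurrence (OOPS) EM motif discovery with a
    twelve-position motif-architecture matrix, nuclear localization signal
    scanning with motif overlap, and full-length versus KID-only
    neighbor-joining phylogenies with bootstrap support.  Includes a
    synthetic kinase-proteome generator with planted ground truth so every
    stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    Rcpp,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
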