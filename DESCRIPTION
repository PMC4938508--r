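Package: memidr
Title: Intrinsic Disorder Analysis of Transmembrane Proteomes
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study intrinsically disordered regions (IDRs) in
    membrane proteins at proteome scale. Implements sliding-window
    disorder scoring (a charge/hydropathy FoldIndex-style score and the
    TOP-IDP propensity scale), ingestion of external per-residue score
    tracks and their consensus, IDR calling with the 30-residue rule,
    membrane-topology models built from TRANSMEM/TOPO_DOM annotations,
    side localization and occupancy statistics, predictor-overlap
    (inclusion) tables, amino-acid enrichment, phosphosite and
    protein-interaction density statistics, and a disorder-guided
    orientation predictor for multi-pass membrane proteins based on the
    positive-inside rule. A synthetic membrane-proteome generator with
    planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
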