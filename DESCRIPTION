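Package: frmotif
Title: Functional Response Motif Discovery in Bipartite Component-Target Networks
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A network-pharmacology toolkit for bipartite component-target
    (C-T) networks. Screens compounds for drug-likeness (Lipinski's Rule of
    Five plus bioavailability and gastrointestinal-absorption filters),
    detects network modules by minimizing the two-level map-equation
    codelength of a random walk, filters modules by permutation significance
    against a degree-preserving bipartite null, selects functional response
    motifs (FRMs) with a genetic-algorithm 0/1 knapsack optimizer backed by
    an exact dynamic-programming oracle, validates motifs with
    hypergeometric pathway enrichment (Benjamini-Hochberg corrected) and
    disease-gene relevance summaries, and ranks components by an
    information-gain Q score. Ships a synthetic-data generator with planted
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
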