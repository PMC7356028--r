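Package: ppiface
Title: Pairwise Protein-Protein Interface Prediction from Sequence
Version: 0.1.0
Authors@R:
    person("ppiface", "developers", email = "ppiface@example.com",
           role = c("aut", "cre"))
Description: Predicts inter-protein interface residue pairs for eukaryotic
    heterodimers from sequence-derived information. Combines a
    perturbation-based conditional-mutual-information co-evolution statistic
    computed on species-matched concatenated multiple sequence alignments,
    physicochemical and contact-potential pairwise feature matrices with
    convolution-derived residue-environment counterparts, a Random Forest
    residue-pair classifier, and a network-analysis post-filter that removes
    buried residues and intra-protein co-evolution signal before scoring
    clustered predictions with a unitary-kernel window sum. Ships a
    synthetic-complex generator (toy coordinates, annotations, and
    alignments with planted covariation) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
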