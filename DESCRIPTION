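Package: fuzzyPCM
Title: Fuzzy Proteochemometric Prediction of Protein-Ligand Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Predicts protein-ligand interaction for new ligands, new
    targets, and simultaneously new protein-ligand pairs by combining
    ungapped segment-based protein sequence similarity scoring with
    per-protein interaction coefficients.  Coefficients are either binary
    (from curated affinity data) or fuzzy probabilities (Pa, Pi) produced
    by a naive-Bayes classifier over multilevel-neighborhood-of-atoms
    (MNA) structural descriptors of the ligands.  Includes affinity-record
    curation (cutoff-based interaction indices, structure filters,
    eligibility fixpoint), leave-one-out ROC evaluation for the three
    prediction scenarios, and a synthetic benchmark generator with
    planted sequence motifs and ligand substructures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
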