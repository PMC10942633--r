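Package: tcrpred
Title: Sequence-Based Prediction of T-Cell Receptor Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the specificity of paired-chain T-cell
    receptors (TCRs) towards MHC class I presented peptides from the six
    complementarity-determining region (CDR) sequences. Implements data
    curation for paired-chain repertoires (CDR3 nomenclature normalisation,
    Hobohm-1 redundancy reduction, cross-validation partitioning, generation
    of swapped negatives and negative controls), a BLOSUM62 k-mer kernel
    nearest-binder similarity baseline, compact max-pooled convolutional
    neural network classifiers over BLOSUM50-encoded CDRs (pan-specific,
    peptide-specific and two-block pre-trained variants with block freezing
    and fine-tuning), model-driven outlier flagging, and an evaluation
    battery (per-peptide AUC and partial AUC, bootstrap model comparison,
    similarity-rescaled ensembles, percentile ranks against negative
    controls, and a peptide-identification rank test). A synthetic repertoire
    generator with planted CDR3 motifs supports desk-scale benchmarking of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Biostrings
Config/testthat/edition: 3
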