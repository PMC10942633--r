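#' Bundled curation summary tables
#'
#' Per-peptide observation counts shipped with the package as plain TSV:
#' * `"reference"`: curation summary of the curated public paired-chain
#'   dataset the default pipeline emulates (26 MHC class I epitopes):
#'   pre-reduction counts, records removed by each redundancy-reduction
#'   step, post-reduction counts, and how many observations derive from
#'   single-cell (10x) screens.
#' * `"immrep_train"` / `"immrep_test"`: redundancy overview of the IMMREP
#'   2022 benchmark training and test sets at the 95% kernel similarity
#'   threshold (pre/post counts and percent redundant).
#'
#' These are inputs for consistency checks of the curation arithmetic (the
#' two-step reduction bookkeeping and the swapped-negative ratio fallback),
#' not outputs of this package.
#'
#' @param name `"reference"`, `"immrep_train"` or `"immrep_test"`.
#' @return A data.frame.
#' @export
curation_summary <- function(name = c("reference", "immrep_train",
                                      "immrep_test")) {
  name <- match.arg(name)
  file <- switch(name,
                 reference = "reference_curation_counts.tsv",
                 immrep_train = "immrep_train_redundancy.tsv",
                 immrep_test = "immrep_test_redundancy.tsv")
  utils::read.delim(system.file("extdata", file, package = "tcrpred"),
                    check.names = TRUE, stringsAsFactors = FALSE)
}
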