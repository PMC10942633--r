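#' Parameters for the BLOSUM k-mer string kernel
#'
#' The kernel compares two CDR sequences by summing, over every k-mer length
#' from `kmin` to `kmax` and every pair of k-mers (one from each sequence),
#' the product of per-position base similarities. The base similarity is a
#' strictly positive multiplicative BLOSUM62 transform,
#' `b(x,y) = 2^(0.1139 * BLOSUM62(x,y))`, normalized per residue pair as
#' `b(x,y) / sqrt(b(x,x) b(y,y))`. The whole kernel is then normalized as
#' `K(a,b) / sqrt(K(a,a) K(b,b))`, giving a symmetric similarity on `[0,1]`
#' with self-similarity exactly 1. The base transform is a replaceable
#' strategy: pass any strictly positive 20 x 20 `base_matrix` to swap it.
#'
#' @param kmin,kmax Smallest and largest k-mer length (defaults 1 and 30;
#'   k-mers longer than a sequence contribute nothing, so `kmax` is
#'   effectively `min(kmax, length)`).
#' @param sm `substitution_matrix` used to derive the base similarity
#'   (BLOSUM62 raw by default).
#' @param cdr_weights Six nonnegative weights for (cdr1a, cdr2a, cdr3a,
#'   cdr1b, cdr2b, cdr3b) in the six-CDR weighted score; default
#'   `c(1,1,3,1,1,3)`.
#' @param base_matrix Optional strictly positive 20 x 20 matrix overriding
#'   the default base-similarity transform.
#' @return A `kernel_params` list with the precomputed normalized base
#'   matrix `mhat`.
#' @export
kernel_params <- function(kmin = 1L, kmax = 30L,
                          sm = load_substitution_matrix("BLOSUM62"),
                          cdr_weights = c(1, 1, 3, 1, 1, 3),
                          base_matrix = NULL) {
  stopifnot(kmin >= 1L, kmax >= kmin,
            length(cdr_weights) == 6L, all(cdr_weights >= 0),
            any(cdr_weights > 0))
  if (is.null(base_matrix)) base_matrix <- 2^(0.1139 * sm$scores)
  stopifnot(is.matrix(base_matrix), all(dim(base_matrix) == 20L),
            all(base_matrix > 0))
  d <- sqrt(diag(base_matrix))
  mhat <- base_matrix / outer(d, d)
  dimnames(mhat) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(kmin = as.integer(kmin), kmax = as.integer(kmax),
                 mhat = mhat,
                 cdr_weights = stats::setNames(cdr_weights,
                                               CDR_FEATURES[-1L])),
            class = "kernel_params")
}

#' Normalized k-mer kernel similarity between two sequences
#'
#' @param a,b Non-empty amino-acid strings.
#' @param params A [kernel_params()] object.
#' @return Similarity in `[0,1]`; symmetric; `kmer_kernel(s, s) == 1`.
#' @export
kmer_kernel <- function(a, b, params = kernel_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  drop(kmer_kernel_matrix(a, b, params))
}

#' Normalized k-mer kernel similarity matrix between two sequence sets
#'
#' @param a_seqs,b_seqs Character vectors of non-empty amino-acid strings.
#' @param params A [kernel_params()] object.
#' @return `length(a_seqs)` x `length(b_seqs)` similarity matrix.
#' @export
kmer_kernel_matrix <- function(a_seqs, b_seqs, params = kernel_params()) {
  if (any(!nzchar(a_seqs)) || any(!nzchar(b_seqs)))
    stop("empty sequence", call. = FALSE)
  .kernel_cross_cpp(lapply(a_seqs, aa_encode), lapply(b_seqs, aa_encode),
                    params$mhat, params$kmin, params$kmax)
}

#' Summed CDR3 similarity between two TCRs
#'
#' Mean of the alpha- and beta-chain CDR3 kernel similarities, so the value
#' lives on `[0,1]` and the 0.95 redundancy threshold is directly applicable.
#'
#' @param r1,r2 One-row `tcr_dataset`s (or lists with `cdr3a`, `cdr3b`).
#' @param params A [kernel_params()] object.
#' @return Similarity in `[0,1]`.
#' @export
summed_cdr3_similarity <- function(r1, r2, params = kernel_params()) {
  (kmer_kernel(r1$cdr3a[[1L]], r2$cdr3a[[1L]], params) +
   kmer_kernel(r1$cdr3b[[1L]], r2$cdr3b[[1L]], params)) / 2
}

# Pairwise summed-CDR3 similarity matrix between two datasets.
summed_cdr3_matrix <- function(ds1, ds2, params = kernel_params()) {
  (kmer_kernel_matrix(ds1$cdr3a, ds2$cdr3a, params) +
   kmer_kernel_matrix(ds1$cdr3b, ds2$cdr3b, params)) / 2
}

# Weighted six-CDR similarity matrix: rows = queries, cols = database.
weighted_cdr_matrix <- function(queries, database, params = kernel_params()) {
  w <- params$cdr_weights
  acc <- 0
  for (f in names(w)) {
    if (w[[f]] == 0) next
    acc <- acc + w[[f]] * kmer_kernel_matrix(queries[[f]], database[[f]], params)
  }
  acc / sum(w)
}

#' Similarity of one TCR to a positive database (nearest binder)
#'
#' Scores a query TCR against every TCR in a single-peptide positive
#' database as the weighted mean of the six per-CDR kernel similarities, and
#' aggregates over the database. The default aggregation is the maximum
#' (nearest binder), under which a query identical to any database entry is
#' guaranteed a score of 1. If the query's `record_id` is present in the
#' database it is excluded (identity exclusion).
#'
#' @param query One-row `tcr_dataset`.
#' @param positives `tcr_dataset` of positives for a single peptide.
#' @param params A [kernel_params()] object.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return Similarity score in `[0,1]`.
#' @export
tcrbase_score <- function(query, positives, params = kernel_params(),
                          aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(positives) == 0L) stop("empty positive database", call. = FALSE)
  if (length(unique(positives$peptide)) != 1L)
    stop("positive database spans multiple peptides", call. = FALSE)
  if (any(positives$binder != 1))
    stop("positive database contains non-binders", call. = FALSE)
  db <- positives[positives$record_id != query$record_id[[1L]], , drop = FALSE]
  if (nrow(db) == 0L) stop("empty positive database after identity exclusion",
                           call. = FALSE)
  sims <- weighted_cdr_matrix(query, db, params)
  if (aggregate == "max") max(sims) else mean(sims)
}

#' Score queries against per-peptide positive databases
#'
#' The k-mer kernel similarity baseline: each query is scored against the
#' positive database of its own `peptide` label. For cross-validation use,
#' pass `exclude_test_partition = TRUE` so that a query's own partition is
#' removed from its positive database (no query is compared against
#' positives of its own test fold). Queries whose peptide has no database
#' are skipped with a warning.
#'
#' @param queries `tcr_dataset` of query TCRs (any labels).
#' @param positives `tcr_dataset` of positives (one or more peptides), or a
#'   named list of per-peptide `tcr_dataset`s.
#' @param params A [kernel_params()] object.
#' @param aggregate `"max"` or `"mean"` database aggregation.
#' @param exclude_test_partition Remove database entries whose partition
#'   equals the query's partition.
#' @return data.frame with `record_id`, `peptide`, `binder`, `partition`,
#'   `tcrbase_score`; one row per scored query, input order preserved.
#' @export
tcrbase_predict <- function(queries, positives, params = kernel_params(),
                            aggregate = c("max", "mean"),
                            exclude_test_partition = FALSE) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(positives))
    positives <- split_dataset(positives[positives$binder == 1, , drop = FALSE],
                               positives$peptide[positives$binder == 1])
  out <- data.frame(record_id = queries$record_id, peptide = queries$peptide,
                    binder = queries$binder, partition = queries$partition,
                    tcrbase_score = rep(NA_real_, nrow(queries)),
                    stringsAsFactors = FALSE)
  if (nrow(queries) == 0L) return(out)
  agg_fun <- if (aggregate == "max") max else mean
  for (pep in unique(queries$peptide)) {
    qi <- which(queries$peptide == pep)
    db <- positives[[pep]]
    if (is.null(db) || nrow(db) == 0L) {
      warning("no positive database for peptide ", pep, "; rows skipped")
      next
    }
    if (!exclude_test_partition) {
      sims <- weighted_cdr_matrix(queries[qi, , drop = FALSE], db, params)
      self <- outer(queries$record_id[qi], db$record_id, "==")
      sims[self] <- NA
      out$tcrbase_score[qi] <- apply(sims, 1L, function(r)
        agg_fun(r[!is.na(r)]))
    } else {
      for (part in unique(queries$partition[qi])) {
        qij <- qi[which(queries$partition[qi] %in% part)]
        dbp <- db[is.na(db$partition) | is.na(part) | db$partition != part, ,
                  drop = FALSE]
        if (nrow(dbp) == 0L) {
          warning("empty training database for peptide ", pep,
                  " at partition ", part)
          next
        }
        sims <- weighted_cdr_matrix(queries[qij, , drop = FALSE], dbp, params)
        self <- outer(queries$record_id[qij], dbp$record_id, "==")
        sims[self] <- NA
        out$tcrbase_score[qij] <- apply(sims, 1L, function(r)
          agg_fun(r[!is.na(r)]))
      }
    }
  }
  out
}

# split() that preserves the tcr_dataset class on the pieces.
split_dataset <- function(ds, f) {
  lapply(split(seq_len(nrow(ds)), f), function(i) {
    out <- ds[i, , drop = FALSE]
    class(out) <- c("tcr_dataset", "data.frame")
    out
  })
}
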