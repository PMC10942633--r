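#' Encode one sequence feature as a fixed-shape BLOSUM matrix
#'
#' Each residue row is the substitution-matrix column of that residue divided
#' by the matrix divisor; rows beyond the sequence are right-padding, the
#' constant vector of twenty -1 values. Longer-than-cap input is an error,
#' never a truncation.
#'
#' @param seq Amino-acid string (may be empty for an all-padding matrix).
#' @param max_len Number of rows of the output.
#' @param sm A `substitution_matrix`; the model contract uses BLOSUM50 with
#'   divisor 5.
#' @return A numeric `max_len` x 20 matrix.
#' @export
encode_feature <- function(seq, max_len, sm = blosum50_embedding()) {
  stopifnot(inherits(sm, "substitution_matrix"))
  n <- nchar(seq)
  if (n > max_len)
    stop("sequence '", seq, "' has length ", n,
         " exceeding feature max length ", max_len, call. = FALSE)
  out <- matrix(-1, nrow = max_len, ncol = 20L)
  if (n > 0L) {
    idx <- aa_encode(seq)
    out[seq_len(n), ] <- sm$scores[idx, , drop = FALSE] / sm$divisor
  }
  out
}

# Cached BLOSUM50/5 embedding matrix (the CNN input convention).
blosum50_embedding <- local({
  sm <- NULL
  function() {
    if (is.null(sm)) sm <<- load_substitution_matrix("BLOSUM50", divisor = 5)
    sm
  }
})

#' Encode one TCR record into the seven model input matrices
#'
#' @param record One-row `tcr_dataset` (or a list with the seven sequence
#'   fields).
#' @return Named list of seven matrices with shapes (12,20), (7,20), (8,20),
#'   (22,20), (6,20), (7,20), (23,20) for peptide, cdr1a, cdr2a, cdr3a,
#'   cdr1b, cdr2b, cdr3b.
#' @export
encode_example <- function(record) {
  sm <- blosum50_embedding()
  stats::setNames(lapply(CDR_FEATURES, function(f)
    encode_feature(record[[f]][[1L]], CDR_MAX_LEN[[f]], sm)), CDR_FEATURES)
}

# Encode a whole dataset as one numeric array per feature
# (n_records x max_len x 20), the layout the CNN training loop consumes.
encode_dataset <- function(ds, features = CDR_FEATURES) {
  sm <- blosum50_embedding()
  stats::setNames(lapply(features, function(f) {
    L <- CDR_MAX_LEN[[f]]
    arr <- array(-1, dim = c(nrow(ds), L, 20L))
    seqs <- ds[[f]]
    for (i in seq_len(nrow(ds))) {
      n <- nchar(seqs[[i]])
      if (n > L)
        stop(f, " '", seqs[[i]], "' exceeds max length ", L, call. = FALSE)
      if (n > 0L)
        arr[i, seq_len(n), ] <- sm$scores[aa_encode(seqs[[i]]), ] / sm$divisor
    }
    arr
  }), features)
}
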