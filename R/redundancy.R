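#' Hobohm-1 redundancy reduction
#'
#' Greedy single pass in input order: a record is kept iff its similarity to
#' every already-kept record is below the threshold; otherwise it is removed
#' with the first offending kept record as its representative.
#'
#' @param ds A `tcr_dataset` (any ordering; the scan respects input order).
#' @param threshold Similarity threshold in `(0, 1]` (default 0.95).
#' @param params [kernel_params()] for the summed CDR3 similarity used as
#'   the pairwise measure.
#' @param sim_matrix Optional precomputed symmetric similarity matrix
#'   (rows/cols in `ds` order) overriding the kernel computation.
#' @param step_label Free-text label recorded in the result.
#' @return A `reduction_result` list: `kept` (`tcr_dataset`), `removed`
#'   (`tcr_dataset` of discarded records), `representative` (character
#'   vector, `removed$record_id` -> `record_id` of the kept representative),
#'   `threshold`, `step_label`.
#' @export
hobohm1 <- function(ds, threshold = 0.95, params = kernel_params(),
                    sim_matrix = NULL, step_label = "") {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(ds)
  if (n == 0L)
    return(structure(list(kept = ds, removed = ds,
                          representative = character(0),
                          threshold = threshold, step_label = step_label),
                     class = "reduction_result"))
  if (is.null(sim_matrix))
    sim_matrix <- summed_cdr3_matrix(ds, ds, params)
  kept_idx <- integer(0)
  rep_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- kept_idx[sim_matrix[i, kept_idx] >= threshold]
    if (length(hit) == 0L) kept_idx <- c(kept_idx, i)
    else rep_of[i] <- hit[[1L]]
  }
  removed_idx <- which(!is.na(rep_of))
  keep_class <- function(x) { class(x) <- c("tcr_dataset", "data.frame"); x }
  structure(list(
    kept = keep_class(ds[kept_idx, , drop = FALSE]),
    removed = keep_class(ds[removed_idx, , drop = FALSE]),
    representative = stats::setNames(ds$record_id[rep_of[removed_idx]],
                                     ds$record_id[removed_idx]),
    threshold = threshold, step_label = step_label),
    class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result%s> kept %d, removed %d (threshold %.3g)\n",
              if (nzchar(x$step_label)) paste0(" ", x$step_label) else "",
              nrow(x$kept), nrow(x$removed), x$threshold))
  invisible(x)
}

#' Two-step redundancy reduction protocol
#'
#' Step 1 runs Hobohm-1 independently within each peptide at the given
#' threshold (scan order = input order); peptides retaining fewer than
#' `min_count` unique TCRs after this step are dropped entirely. Step 2 runs
#' Hobohm-1 across all surviving records, ordered by ascending per-peptide
#' survivor count (ties broken lexicographically by peptide, then input
#' order) so that rare peptides keep their copies of cross-peptide
#' near-duplicates.
#'
#' @param ds `tcr_dataset` of positives only.
#' @param threshold Kernel similarity threshold (default 0.95).
#' @param min_count Minimum unique TCRs per peptide after step 1
#'   (default 30).
#' @param params [kernel_params()] for the summed CDR3 similarity.
#' @return List with `dataset` (the reduced `tcr_dataset`), `step1`
#'   (per-peptide `reduction_result`s plus `dropped_peptides`), `step2`
#'   (the cross-peptide `reduction_result`).
#' @export
two_step_reduction <- function(ds, threshold = 0.95, min_count = 30,
                               params = kernel_params()) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  if (any(ds$binder != 1))
    stop("redundancy reduction applies to positives only", call. = FALSE)
  by_pep <- split_dataset(ds, ds$peptide)
  step1 <- lapply(by_pep, hobohm1, threshold = threshold, params = params,
                  step_label = "within-peptide")
  survivors <- vapply(step1, function(r) nrow(r$kept), integer(1))
  dropped <- names(survivors)[survivors < min_count]
  kept_peps <- setdiff(names(survivors), dropped)
  if (length(kept_peps) == 0L)
    stop("no peptide retains ", min_count, " unique TCRs", call. = FALSE)
  # order peptides by ascending survivor count, ties lexicographic
  ord_peps <- kept_peps[order(survivors[kept_peps], kept_peps)]
  pooled <- do.call(rbind, lapply(ord_peps, function(p)
    as.data.frame(step1[[p]]$kept)))
  class(pooled) <- c("tcr_dataset", "data.frame")
  step2 <- hobohm1(pooled, threshold = threshold, params = params,
                   step_label = "cross-peptide")
  list(dataset = step2$kept,
       step1 = list(results = step1, dropped_peptides = dropped),
       step2 = step2)
}

#' Re-insert redundant positives into their representative's partition
#'
#' Builds the "redundant" training dataset: records removed by a reduction
#' step re-enter with the cross-validation partition of the record they were
#' redundant to. Only positives are re-added; evaluation should remain on
#' the original reduced records.
#'
#' @param reduced `tcr_dataset` with partitions assigned.
#' @param reduction A `reduction_result` whose representatives exist in
#'   `reduced`.
#' @return `tcr_dataset` of `reduced` plus the re-added positives.
#' @export
reassign_redundant <- function(reduced, reduction) {
  stopifnot(inherits(reduction, "reduction_result"))
  removed <- reduction$removed
  removed <- removed[removed$binder == 1, , drop = FALSE]
  if (nrow(removed) == 0L) return(reduced)
  rep_ids <- reduction$representative[removed$record_id]
  pos <- match(rep_ids, reduced$record_id)
  if (anyNA(pos))
    stop("representative record(s) missing from reduced dataset: ",
         paste(utils::head(rep_ids[is.na(pos)], 5L), collapse = ", "),
         call. = FALSE)
  if (anyNA(reduced$partition[pos]))
    stop("representative record(s) lack a partition assignment",
         call. = FALSE)
  removed$partition <- reduced$partition[pos]
  out <- rbind(as.data.frame(reduced), as.data.frame(removed))
  class(out) <- c("tcr_dataset", "data.frame")
  validate_tcr_dataset(out)
  out
}
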