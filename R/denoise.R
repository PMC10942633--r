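#' Flag potential outliers from validation prediction scores
#'
#' A positive observation is flagged when, for each of the four
#' cross-validation models that did not train on its partition, its
#' validation score falls below the n-th percentile of that model's
#' negative scores for the same peptide. Symmetrically, a negative is
#' flagged when its score exceeds the (100 - n)-th percentile of the
#' positive scores under all four models. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param val_preds Validation predictions in long format as returned by
#'   [train_nested_cv()]: columns `record_id`, `peptide`, `binder`,
#'   `partition`, `test_fold`, `score`, with one row per record per
#'   validating model.
#' @param n Percentile threshold in (0, 100); the reference protocol tested
#'   50, 60, 70, 80, 85, 90 and 95.
#' @return data.frame `record_id`, `peptide`, `binder`, `flagged`, `side`
#'   (`"positive_low"`, `"negative_high"` or `NA`).
#' @export
flag_outliers <- function(val_preds, n = 70) {
  stopifnot(n > 0, n < 100)
  need <- c("record_id", "peptide", "binder", "partition", "test_fold",
            "score")
  if (!all(need %in% names(val_preds)))
    stop("val_preds must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- table(val_preds$record_id)
  n_models <- max(counts)
  if (any(counts < n_models))
    stop("missing model scores for record(s): ",
         paste(utils::head(names(counts)[counts < n_models], 5L),
               collapse = ", "), call. = FALSE)
  flags <- list()
  for (pep in unique(val_preds$peptide)) {
    sub <- val_preds[val_preds$peptide == pep, , drop = FALSE]
    for (rid in unique(sub$record_id)) {
      rows <- sub[sub$record_id == rid, , drop = FALSE]
      is_pos <- rows$binder[[1L]] == 1
      part <- rows$partition[[1L]]
      hit <- logical(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        fold <- rows$test_fold[[i]]
        # scores of the contrary class under the same model: the model is
        # identified by (test fold, validation partition)
        ref <- sub[sub$test_fold == fold & sub$partition == part &
                     sub$binder == (if (is_pos) 0 else 1), "score"]
        if (length(ref) == 0L) { hit[i] <- FALSE; next }
        hit[i] <- if (is_pos)
          rows$score[[i]] < stats::quantile(ref, n / 100, type = 7,
                                            names = FALSE)
        else
          rows$score[[i]] > stats::quantile(ref, (100 - n) / 100, type = 7,
                                            names = FALSE)
      }
      flags[[length(flags) + 1L]] <- data.frame(
        record_id = rid, peptide = pep, binder = rows$binder[[1L]],
        flagged = all(hit),
        side = if (all(hit)) (if (is_pos) "positive_low" else "negative_high")
               else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, flags)
}

#' Remove flagged outliers from a training dataset
#'
#' Flagged records are excluded from training and validation use; model
#' evaluation should remain on the full dataset.
#'
#' @param ds The `tcr_dataset` the flags were computed on.
#' @param flags Output of [flag_outliers()].
#' @return `tcr_dataset` without the flagged records.
#' @export
build_limited_dataset <- function(ds, flags) {
  unknown <- setdiff(flags$record_id, ds$record_id)
  if (length(unknown) > 0L)
    stop("flags refer to unknown record(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  drop_ids <- flags$record_id[flags$flagged]
  out <- ds[!(ds$record_id %in% drop_ids), , drop = FALSE]
  class(out) <- c("tcr_dataset", "data.frame")
  out
}
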