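#' Area under the ROC curve
#'
#' Midrank (Mann-Whitney) convention: ties contribute half a concordant
#' pair.
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Standardized partial AUC at low false-positive rates
#'
#' Area under the piecewise-linear ROC curve restricted to
#' `FPR <= fpr_max` (default 0.1), with ties grouped so tied scores produce
#' diagonal segments. By default the partial area is McClish-standardized
#' so a random classifier scores 0.5 and a perfect one 1.0; set
#' `standardized = FALSE` for the raw area.
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores.
#' @param fpr_max Upper false-positive-rate bound (default 0.1).
#' @param standardized Apply the chance-0.5 standardization.
#' @return Partial AUC.
#' @export
roc_auc01 <- function(labels, scores, fpr_max = 0.1, standardized = TRUE) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: only one class present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (!standardized) return(area)
  min_a <- fpr_max^2 / 2
  max_a <- fpr_max
  0.5 * (1 + (area - min_a) / (max_a - min_a))
}

#' Aggregate per-peptide metrics into weighted and unweighted means
#'
#' The unweighted mean averages the per-peptide metric over peptides; the
#' weighted mean weights each peptide by its number of positive
#' observations.
#'
#' @param metrics Numeric vector of per-peptide metric values.
#' @param counts Positive observation counts per peptide (same order).
#' @return List with `unweighted`, `weighted`, `per_peptide` (named if
#'   `metrics` is) and `counts`.
#' @export
aggregate_metrics <- function(metrics, counts) {
  if (length(metrics) == 0L) stop("no per-peptide metrics", call. = FALSE)
  stopifnot(length(metrics) == length(counts), all(counts > 0))
  list(unweighted = mean(metrics),
       weighted = sum(metrics * counts) / sum(counts),
       per_peptide = metrics, counts = counts)
}

#' Per-peptide evaluation report
#'
#' Computes AUC and partial AUC (FPR <= 0.1) per peptide from a prediction
#' table and aggregates them.
#'
#' @param preds data.frame with `peptide`, `binder` and a score column.
#' @param score_col Name of the score column (default `"score"`).
#' @return An `eval_report`: data.frame `per_peptide` (peptide, n_pos, auc,
#'   auc01) plus `auc` and `auc01` aggregate lists.
#' @export
evaluate_predictions <- function(preds, score_col = "score") {
  stopifnot(all(c("peptide", "binder", score_col) %in% names(preds)))
  per <- lapply(split(preds, preds$peptide), function(sub) {
    if (length(unique(sub$binder)) < 2L) return(NULL)
    data.frame(peptide = sub$peptide[[1L]], n_pos = sum(sub$binder == 1),
               auc = roc_auc(sub$binder, sub[[score_col]]),
               auc01 = roc_auc01(sub$binder, sub[[score_col]]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per)) stop("no peptide with both classes", call. = FALSE)
  structure(list(per_peptide = per,
                 auc = aggregate_metrics(stats::setNames(per$auc, per$peptide),
                                         per$n_pos),
                 auc01 = aggregate_metrics(stats::setNames(per$auc01,
                                                           per$peptide),
                                           per$n_pos)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d peptides | AUC %.4f (unw) %.4f (w) | AUC0.1 %.4f (unw) %.4f (w)\n",
              nrow(x$per_peptide), x$auc$unweighted, x$auc$weighted,
              x$auc01$unweighted, x$auc01$weighted))
  invisible(x)
}

#' Bootstrap comparison of two prediction sets
#'
#' Resamples records with replacement `n` times (the same resample indices
#' applied to both models) and reports the fraction of resamples in which
#' the first model strictly outperforms the second under the given metric.
#'
#' @param predsA,predsB Prediction data.frames over identical records (same
#'   `record_id` order) with `peptide`, `binder` and `score`.
#' @param metric_fn Function mapping such a data.frame to one number;
#'   defaults to the unweighted mean per-peptide AUC. Resamples where the
#'   metric is undefined (e.g. a single-class draw) are skipped for both
#'   models.
#' @param n Number of resamples (default 10000).
#' @param seed Integer seed for the shared resample indices.
#' @return A `bootstrap_result` list with `p` (fraction A > B), `p_reverse`
#'   (fraction B > A), `ties`, `n_effective`, `n`, `seed`.
#' @export
bootstrap_compare <- function(predsA, predsB,
                              metric_fn = function(df)
                                evaluate_predictions(df)$auc$unweighted,
                              n = 10000L, seed = 1L) {
  if (!identical(predsA$record_id, predsB$record_id))
    stop("prediction sets are not aligned on identical records",
         call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  nr <- nrow(predsA)
  wins_a <- 0L; wins_b <- 0L; ties <- 0L; used <- 0L
  for (i in seq_len(n)) {
    idx <- sample.int(nr, nr, replace = TRUE)
    ma <- tryCatch(metric_fn(predsA[idx, , drop = FALSE]),
                   error = function(e) NA_real_)
    mb <- tryCatch(metric_fn(predsB[idx, , drop = FALSE]),
                   error = function(e) NA_real_)
    if (is.na(ma) || is.na(mb)) next
    used <- used + 1L
    if (ma > mb) wins_a <- wins_a + 1L
    else if (mb > ma) wins_b <- wins_b + 1L
    else ties <- ties + 1L
  }
  structure(list(p = wins_a / n, p_reverse = wins_b / n, ties = ties / n,
                 n_effective = used, n = n, seed = seed),
            class = "bootstrap_result")
}

#' Similarity-rescaled ensemble score
#'
#' Multiplies a CNN probability by the nearest-binder kernel similarity
#' raised to a power: `p_cnn * p_sim^alpha`. Larger `alpha` penalizes TCRs
#' with low similarity to known binders more harshly; `alpha = 0` returns
#' the CNN score unchanged.
#'
#' @param p_cnn CNN score(s) in (0, 1).
#' @param p_tcrbase Kernel similarity score(s) in `[0, 1]`.
#' @param alpha Nonnegative scaling exponent (default 10).
#' @return Ensemble score(s).
#' @export
ensemble_score <- function(p_cnn, p_tcrbase, alpha = 10) {
  stopifnot(alpha >= 0)
  p_cnn * p_tcrbase^alpha
}

#' Percentile rank against negative controls
#'
#' The percentage of negative-control scores strictly above the query
#' score; lower is better. Ties therefore lower (improve) the rank.
#'
#' @param score Query score(s).
#' @param control_scores Non-empty numeric vector of negative-control
#'   scores for the same peptide.
#' @return Percentile rank(s) in `[0, 100]`.
#' @export
percentile_rank <- function(score, control_scores) {
  if (length(control_scores) == 0L)
    stop("empty negative-control score set", call. = FALSE)
  vapply(score, function(s) 100 * mean(control_scores > s), numeric(1))
}

#' Peptide-identification rank test
#'
#' Given a full scoring grid (every TCR paired with every candidate
#' peptide), computes per peptide the fraction of its positive TCRs whose
#' true pairing attains the best score (maximum for direct scores, minimum
#' for percentile ranks). Best-score ties count as misses unless the true
#' peptide is the unique argmax.
#'
#' @param grid data.frame with `record_id`, `true_peptide`,
#'   `candidate_peptide`, and the score column; one row per (TCR,
#'   candidate) pair over a complete grid.
#' @param score_col Column scored (default `"score"`).
#' @param higher_better `TRUE` for direct scores, `FALSE` for percentile
#'   ranks.
#' @param exclude_peptides Candidate peptides to drop before ranking.
#' @return data.frame `peptide`, `n`, `top1` (fraction correctly
#'   identified).
#' @export
specificity_rank_test <- function(grid, score_col = "score",
                                  higher_better = TRUE,
                                  exclude_peptides = character(0)) {
  need <- c("record_id", "true_peptide", "candidate_peptide", score_col)
  stopifnot(all(need %in% names(grid)))
  grid <- grid[!(grid$candidate_peptide %in% exclude_peptides) &
                 !(grid$true_peptide %in% exclude_peptides), , drop = FALSE]
  cands <- sort(unique(grid$candidate_peptide))
  per_tcr <- split(grid, grid$record_id)
  bad <- names(per_tcr)[vapply(per_tcr, function(g)
    !setequal(g$candidate_peptide, cands), logical(1))]
  if (length(bad) > 0L)
    stop("incomplete pairing grid for record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  hits <- vapply(per_tcr, function(g) {
    s <- g[[score_col]]
    best <- if (higher_better) which(s == max(s)) else which(s == min(s))
    length(best) == 1L && g$candidate_peptide[best] == g$true_peptide[[1L]]
  }, logical(1))
  true_pep <- vapply(per_tcr, function(g) g$true_peptide[[1L]], character(1))
  agg <- tapply(hits, true_pep, mean)
  cnt <- tapply(hits, true_pep, length)
  data.frame(peptide = names(agg), n = as.integer(cnt),
             top1 = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3, nonzero variance).
#' @return List with `r` and `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
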