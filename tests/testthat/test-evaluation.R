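test_that("AUC follows the midrank convention", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(17)
  for (i in 1:10) {
    labels <- c(rep(1, 3), rep(0, 3))
    scores <- sample(round(stats::runif(6), 1))  # rounding provokes ties
    expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")
})

test_that("partial AUC is standardized to a chance level of 0.5", {
  expect_equal(roc_auc01(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc01(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(19)
  for (i in 1:10) {
    labels <- c(rep(1, 8), rep(0, 12))
    scores <- round(stats::runif(20), 1)
    expect_equal(roc_auc01(labels, scores), oracle_auc01(labels, scores),
                 tolerance = 1e-12)
  }
  # raw partial area stays on the [0, fpr_max] scale
  raw <- roc_auc01(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9),
                   standardized = FALSE)
  expect_equal(raw, 0.1)
})

test_that("auc metrics agree with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- c(rep(1, 30), rep(0, 70))
  scores <- c(stats::rnorm(30, 1), stats::rnorm(70))
  expect_equal(roc_auc(labels, scores),
               as.numeric(pROC::auc(labels, scores, quiet = TRUE)))
  expect_equal(roc_auc01(labels, scores),
               as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                                    partial.auc = c(1, 0.9),
                                    partial.auc.focus = "specificity",
                                    partial.auc.correct = TRUE)),
               tolerance = 1e-9)
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(29)
  labels <- rep(c(1, 0), each = 25)
  scores <- stats::runif(50)
  for (f in list(function(x) 10 * x - 3, function(x) x^3,
                 function(x) exp(x))) {
    expect_equal(roc_auc(labels, f(scores)), roc_auc(labels, scores))
    expect_equal(roc_auc01(labels, f(scores)), roc_auc01(labels, scores))
  }
})

test_that("aggregate metrics weight peptides by positive counts", {
  agg <- aggregate_metrics(c(0.8, 0.6), c(100, 300))
  expect_equal(agg$unweighted, 0.7)
  expect_equal(agg$weighted, 0.65)
  one <- aggregate_metrics(0.91, 42)
  expect_equal(one$unweighted, 0.91)
  expect_equal(one$weighted, 0.91)
  flat <- aggregate_metrics(rep(0.77, 26), sample(1:500, 26))
  expect_equal(flat$unweighted, 0.77)
  expect_equal(flat$weighted, 0.77)
  # aggregates always lie between the per-peptide extremes
  set.seed(31)
  m <- stats::runif(10)
  n <- sample(1:100, 10)
  agg2 <- aggregate_metrics(m, n)
  expect_gte(agg2$unweighted, min(m))
  expect_lte(agg2$unweighted, max(m))
  expect_gte(agg2$weighted, min(m))
  expect_lte(agg2$weighted, max(m))
  expect_error(aggregate_metrics(numeric(0), numeric(0)), "no per-peptide")
})

test_that("bootstrap comparison counts strict wins under shared indices", {
  set.seed(37)
  n <- 60
  preds <- data.frame(record_id = sprintf("r%02d", 1:n),
                      peptide = rep(c("A", "B"), each = n / 2),
                      binder = rep(c(1, 0), n / 2),
                      score = stats::runif(n))
  # identical predictions: A never strictly outperforms B
  res <- bootstrap_compare(preds, preds, n = 200, seed = 3)
  expect_equal(res$p, 0)
  expect_equal(res$ties, 1)
  # A strictly dominates B on every record
  better <- preds
  better$score <- ifelse(preds$binder == 1, 0.9, 0.1)
  res2 <- bootstrap_compare(better, preds, n = 200, seed = 3)
  expect_equal(res2$p, 1)
  # shares of wins, losses and ties partition the resamples
  noisy <- preds
  noisy$score <- preds$score + stats::rnorm(n, sd = 0.1)
  res3 <- bootstrap_compare(noisy, preds, n = 300, seed = 5)
  expect_equal(res3$p + res3$p_reverse + res3$ties,
               res3$n_effective / res3$n)
  # Monte-Carlo self-consistency across seeds (3 standard errors)
  res4 <- bootstrap_compare(noisy, preds, n = 300, seed = 11)
  se <- sqrt(res3$p * (1 - res3$p) / 300 + res4$p * (1 - res4$p) / 300)
  expect_lt(abs(res3$p - res4$p), 3 * max(se, 1e-3))
  expect_error(bootstrap_compare(preds, preds[n:1, ]), "aligned")
})

test_that("ensemble rescaling multiplies by powered similarity", {
  expect_equal(ensemble_score(0.7, 0.4, 0), 0.7)
  expect_equal(ensemble_score(0.7, 1, 25), 0.7)
  expect_equal(ensemble_score(0.9, 0.5, 1), 0.45)
  # monotone nonincreasing in alpha when similarity < 1
  alphas <- seq(0, 20, by = 2.5)
  vals <- ensemble_score(0.8, 0.9, alphas)
  expect_true(all(diff(vals) < 0))
})

test_that("percentile rank counts strictly higher controls", {
  controls <- seq(0.1, 1, by = 0.1)
  expect_equal(percentile_rank(2, controls), 0)
  expect_equal(percentile_rank(0.01, controls), 100)
  expect_equal(percentile_rank(0.55, controls), 50)
  # score equal to every control: strict "above" gives rank 0
  expect_equal(percentile_rank(0.3, rep(0.3, 8)), 0)
  # nonincreasing step function of the score
  grid <- seq(0, 1.05, by = 0.01)
  ranks <- percentile_rank(grid, controls)
  expect_true(all(diff(ranks) <= 0))
  expect_error(percentile_rank(0.5, numeric(0)), "empty")
})

test_that("the specificity rank test counts unique top-1 hits", {
  peps <- c("A", "B", "C")
  grid <- expand.grid(record_id = sprintf("t%d", 1:9),
                      candidate_peptide = peps,
                      stringsAsFactors = FALSE)
  grid$true_peptide <- rep(peps, each = 3)[match(grid$record_id,
                                                 sprintf("t%d", 1:9))]
  # oracle scorer: 1 for the true pair, 0 otherwise
  grid$score <- as.numeric(grid$candidate_peptide == grid$true_peptide)
  res <- specificity_rank_test(grid)
  expect_equal(res$top1, rep(1, 3))
  # hand-filled grid: t1 correct, t2 wrong, t3 tied (counts as a miss)
  small <- grid[grid$record_id %in% c("t1", "t2", "t3"), ]
  small$score[small$record_id == "t2"] <-
    c(0.2, 0.9, 0.1)[match(small$candidate_peptide[small$record_id == "t2"],
                           peps)]
  small$score[small$record_id == "t3"] <-
    c(0.5, 0.1, 0.5)[match(small$candidate_peptide[small$record_id == "t3"],
                           peps)]
  res2 <- specificity_rank_test(small)
  expect_equal(res2$top1[res2$peptide == "A"], 1 / 3)
  # percentile-rank mode: the minimum wins
  small$rank <- 100 * (1 - small$score)
  res3 <- specificity_rank_test(small, score_col = "rank",
                                higher_better = FALSE)
  expect_equal(res3, res2)
  # excluded peptides leave the grid entirely
  res4 <- specificity_rank_test(grid, exclude_peptides = "C")
  expect_setequal(res4$peptide, c("A", "B"))
  # incomplete grids are rejected
  expect_error(specificity_rank_test(grid[-1, ]), "incomplete")
})

test_that("pearson correlation matches the covariance formula", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.9, 10.4)
  y <- 2 * x + 1
  expect_equal(pearson_corr(x, y)$r, 1)
  set.seed(41)
  y2 <- stats::rnorm(10)
  manual <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  got <- pearson_corr(x, y2)
  expect_equal(got$r, manual)
  expect_equal(got$p, stats::cor.test(x, y2)$p.value)
  expect_error(pearson_corr(x, rep(1, 10)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})
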