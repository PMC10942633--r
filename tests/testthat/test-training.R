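test_that("sample weights follow the log2 abundance formula", {
  ds <- toy_dataset(8)  # two peptides, 4 records each
  w <- compute_sample_weights(ds, c = 3.8, mode = "pan")
  expect_equal(w, rep(log2(8 / 4) / 3.8, 8))
  expect_equal(compute_sample_weights(ds, mode = "peptide"), rep(1, 8))
  # worked case: N_total 1000, N_peptide 250 -> 2 / 3.8
  dsl <- toy_dataset(1000, peptides = c(rep("KVLEWGSNA", 1), rep("RQFTDYSMP", 3)))
  w2 <- compute_sample_weights(dsl, c = 3.8, mode = "pan")
  expect_equal(unique(w2[dsl$peptide == "KVLEWGSNA"]), 2 / 3.8)
  # degenerate single-peptide pan dataset: zero weights with a warning
  one <- toy_dataset(4, peptides = "KVLEWGSNA")
  expect_warning(w3 <- compute_sample_weights(one, mode = "pan"),
                 "single-peptide")
  expect_equal(w3, rep(0, 4))
})

test_that("pan-mode weighting keeps the overall loss near the unweighted one", {
  # a peptide panel with the breadth and imbalance the weighting constant
  # was calibrated for: a dozen peptides spanning a 20x abundance range
  set.seed(2)
  peps <- random_aa(12, 9)
  counts <- c(200, 150, 100, 80, 60, 40, 30, 20, 15, 12, 10, 10)
  ds <- toy_dataset(sum(counts), peptides = rep(peps, counts))
  w <- compute_sample_weights(ds, c = 3.8, mode = "pan")
  p <- stats::runif(nrow(ds), 0.2, 0.8)
  lw <- mean(w * -log(p))
  lu <- mean(-log(p))
  expect_lt(lw / lu, 2)
  expect_gt(lw / lu, 0.5)
})

test_that("adaptive batch size never leaves a runt final batch", {
  expect_equal(adaptive_batch_size(128), 64L)
  expect_equal(adaptive_batch_size(100), 64L)
  expect_equal(adaptive_batch_size(20), 20L)
  # n = 95: every b in 64..94 leaves a final batch < 32 (exhaustive scan),
  # so the whole set trains as a single batch
  scan <- vapply(64:94, function(b) { r <- 95 %% b; r == 0 || r >= 32 },
                 logical(1))
  expect_false(any(scan))
  expect_equal(adaptive_batch_size(95), 95L)
  for (n in c(33, 64, 65, 96, 127, 200, 321)) {
    b <- adaptive_batch_size(n)
    r <- n %% b
    expect_true(r == 0 || r >= 32 || n < 64)
  }
})

test_that("the combined stopping metric trades partial AUC against loss", {
  expect_equal(custom_cm(0.8, 0.5), 0.75)
  expect_equal(custom_cm(0.62, 0), 0.62)
  expect_equal(custom_cm(0.5, 2.0), 0.3)
})

test_that("cross-validation slots never leak the test partition", {
  slots <- tcrpred:::cv_slots(5)
  expect_length(slots, 20)
  for (sl in slots) {
    expect_false(sl$test %in% sl$train)
    expect_false(sl$test == sl$val)
    expect_false(sl$val %in% sl$train)
    expect_setequal(c(sl$test, sl$val, sl$train), 1:5)
  }
})

test_that("nested cross-validation predicts each record from unseen models", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(15, 2),
                                        seed = 6))
  ds <- partition_dataset(sim$dataset, k = 5, seed = 2)
  ds <- generate_swapped_negatives(ds, negative_config(seed = 3))
  cfg <- train_config(mode = "peptide", seed = 7, max_epochs = 3,
                      patience = 2)
  fit <- train_nested_cv(ds, model_spec("pep22"), cfg)
  preds <- fit$predictions
  expect_equal(nrow(preds), nrow(ds))
  expect_equal(preds$n_models, rep(4L, nrow(ds)))
  expect_true(all(preds$score > 0 & preds$score < 1))
  # each model slot excludes its test partition from training and validation
  for (m in fit$models) {
    expect_false(m$slot$test %in% m$slot$train)
    expect_false(m$slot$test == m$slot$val)
  }
  # validation table: 4 scores per record, one per foreign test fold
  vp <- fit$val_predictions
  per_rec <- table(vp$record_id)
  expect_true(all(per_rec == 4))
  folds_seen <- tapply(vp$test_fold, vp$record_id, function(x)
    length(unique(x)))
  expect_true(all(folds_seen == 4))
  expect_true(all(vp$test_fold != vp$partition))
  # determinism: identical configuration reproduces scores exactly
  fit2 <- train_nested_cv(ds, model_spec("pep22"), cfg)
  expect_identical(fit$predictions$score, fit2$predictions$score)
})

test_that("early stopping restores the best checkpoint", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(20, 2),
                                        seed = 9))
  ds <- partition_dataset(sim$dataset, k = 5, seed = 2)
  ds <- generate_swapped_negatives(ds, negative_config(seed = 3))
  enc <- tcrpred:::encode_dataset(ds, setdiff(tcrpred:::CDR_FEATURES,
                                              "peptide"))
  tr <- which(ds$partition <= 3)
  va <- which(ds$partition == 4)
  cfg <- train_config(mode = "peptide", seed = 5, max_epochs = 12,
                      patience = 4)
  m <- build_model(model_spec("pep22"), seed = 5)
  m <- tcrpred:::train_model(m, tcrpred:::enc_subset(enc, tr),
                             ds$binder[tr], rep(1, length(tr)),
                             tcrpred:::enc_subset(enc, va), ds$binder[va],
                             cfg)
  trace <- m$log[, "metric"]
  expect_equal(m$best_metric, max(trace, na.rm = TRUE))
  expect_equal(m$best_epoch, which.max(trace))
  # the restored weights reproduce the best epoch's validation metric
  p_val <- tcrpred:::cnn_forward(m, tcrpred:::enc_subset(enc, va))
  expect_equal(roc_auc01(ds$binder[va], p_val), m$best_metric,
               tolerance = 1e-12)
})

test_that("fine-tuning filters donor negatives and honors epoch zero", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(15, 3),
                                        seed = 14))
  ds <- partition_dataset(sim$dataset, k = 5, seed = 4)
  ds <- generate_swapped_negatives(ds, negative_config(seed = 5))
  newp <- "AYHIPCGKE"
  base <- ds[ds$peptide != newp, ]
  class(base) <- c("tcr_dataset", "data.frame")
  newd <- ds[ds$peptide == newp, ]
  class(newd) <- c("tcr_dataset", "data.frame")
  # base still contains swapped negatives donated by the new peptide
  donated <- base$negative_kind == "swapped" & base$source_peptide == newp
  expect_gt(sum(donated), 0)
  cfg <- train_config(mode = "pretrained", seed = 2, max_epochs = 2,
                      patience = 2)
  fit <- train_pretrained(base, cfg, slots = list(list(test = 1, val = 2,
                                                       train = 3:5)))
  r1 <- fit$models[[1]]$round1
  pan_keys <- grep("^pan/", names(r1$par), value = TRUE)
  ft_cfg <- train_config(mode = "finetune", seed = 3, max_epochs = 4,
                         patience = 2)
  # epochs = 0 leaves the pan block untouched
  ft0 <- finetune_pan_block(r1, newd, base, epochs = 0, cfg = ft_cfg)
  expect_identical(ft0$par[pan_keys], r1$par[pan_keys])
  ft1 <- finetune_pan_block(r1, newd, base, epochs = 1, cfg = ft_cfg)
  expect_false(identical(ft1$par[pan_keys], r1$par[pan_keys]))
  # leakage guard: the new peptide must be absent from base positives
  expect_error(finetune_pan_block(r1, newd, ds, epochs = 0, cfg = ft_cfg),
               "leakage")
})
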