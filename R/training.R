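#' Training configuration
#'
#' All values default to the framework's standard constants: Adam with
#' learning rate 0.001, binary cross-entropy loss, early stopping on
#' validation partial AUC (FPR <= 0.1), patience 100 for pan-specific and
#' pre-training rounds and 200 for peptide-specific training, batch size 64
#' (peptide-specific batches adapt so no batch falls below 32), and loss
#' scaling constant c = 3.8 for the pan-specific sample weights.
#'
#' @param mode `"pan"`, `"peptide"`, `"pretrained"` or `"finetune"`.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs; defaults to 200 for
#'   peptide mode and 100 otherwise.
#' @param max_epochs Epoch cap; defaults to 200 for pretrained rounds and
#'   1000 otherwise (patience governs in practice).
#' @param stop_metric `"val_auc01"` (maximized), `"val_loss"` (minimized)
#'   or `"custom_cm"` (validation AUC 0.1 minus 0.1 times validation loss,
#'   maximized).
#' @param batch_default,batch_min_last Batch policy; see
#'   [adaptive_batch_size()].
#' @param weight_constant_c Divisor of the log2 abundance weights in pan
#'   mode.
#' @param seed Integer master seed; shuffling, initialization and dropout
#'   draw from seeds derived from it.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("pan", "peptide", "pretrained", "finetune"),
                         learning_rate = 0.001,
                         patience = NULL,
                         max_epochs = NULL,
                         stop_metric = c("val_auc01", "val_loss", "custom_cm"),
                         batch_default = 64L,
                         batch_min_last = 32L,
                         weight_constant_c = 3.8,
                         seed = 1L,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  stop_metric <- match.arg(stop_metric)
  if (is.null(patience))
    patience <- if (mode == "peptide") 200L else 100L
  if (is.null(max_epochs))
    max_epochs <- if (mode == "pretrained") 200L else 1000L
  stopifnot(patience >= 1L, learning_rate > 0)
  structure(list(mode = mode, learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 stop_metric = stop_metric,
                 batch_default = as.integer(batch_default),
                 batch_min_last = as.integer(batch_min_last),
                 weight_constant_c = weight_constant_c,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Per-record loss weights
#'
#' Pan-specific training weights each observation by
#' `log2(N_total / N_peptide) / c`, where the counts run over all
#' observations (positives and their peptide-labeled negatives) in the
#' training split, steering the loss towards less abundant peptides.
#' Peptide-specific training uses weight 1 for all samples.
#'
#' @param ds Training-split `tcr_dataset`.
#' @param c Scaling constant (default 3.8).
#' @param mode `"pan"` or `"peptide"`.
#' @return Numeric weight per record.
#' @export
compute_sample_weights <- function(ds, c = 3.8, mode = c("pan", "peptide")) {
  mode <- match.arg(mode)
  if (mode == "peptide") return(rep(1, nrow(ds)))
  counts <- table(ds$peptide)
  if (any(counts == 0)) stop("zero-count peptide", call. = FALSE)
  if (length(counts) == 1L)
    warning("single-peptide dataset in pan mode: all weights are 0; ",
            "use peptide mode instead")
  n_total <- nrow(ds)
  as.numeric(log2(n_total / counts[ds$peptide]) / c)
}

#' Adaptive batch size
#'
#' Smallest batch size `b >= default` such that the final batch holds at
#' least `min_last` observations (or divides evenly); datasets smaller than
#' `default` train as a single batch.
#'
#' @param n Number of training observations.
#' @param default Default batch size (64; 32 in the low-data fine-tuning
#'   setup).
#' @param min_last Minimum size of the final batch (32).
#' @return Integer batch size.
#' @export
adaptive_batch_size <- function(n, default = 64L, min_last = 32L) {
  stopifnot(n >= 1L)
  if (n < default) return(as.integer(n))
  for (b in default:n) {
    r <- n %% b
    if (r == 0L || r >= min_last) return(as.integer(b))
  }
  as.integer(n)
}

#' Combined validation metric for low-data early stopping
#'
#' `AUC0.1 - 0.1 * loss`, maximized; balances ranking quality against
#' calibration when validation sets are tiny.
#'
#' @param auc01_val Validation partial AUC.
#' @param loss_val Validation binary cross-entropy.
#' @return Numeric metric value.
#' @export
custom_cm <- function(auc01_val, loss_val) auc01_val - 0.1 * loss_val

# All 20 (test, validation) cross-validation slots for k outer folds.
cv_slots <- function(k = 5L) {
  out <- list()
  for (t in seq_len(k))
    for (v in setdiff(seq_len(k), t))
      out[[length(out) + 1L]] <- list(test = t, val = v,
                                      train = setdiff(seq_len(k), c(t, v)))
  out
}

# Subset an encoded feature list by record index.
enc_subset <- function(enc, idx) {
  lapply(enc, function(a) a[idx, , , drop = FALSE])
}

# Core training loop: batched Adam on weighted BCE with early stopping and
# best-checkpoint restoration. Returns the model plus a per-epoch log.
train_model <- function(model, enc_train, y, w, enc_val, y_val, cfg,
                        fixed_epochs = NULL) {
  n <- length(y)
  bsz <- if (cfg$mode == "pan") cfg$batch_default
         else adaptive_batch_size(n, cfg$batch_default, cfg$batch_min_last)
  state <- adam_init(model$par)
  minimize <- cfg$stop_metric == "val_loss"
  best <- if (minimize) Inf else -Inf
  best_par <- model$par
  best_epoch <- 0L
  log <- list()
  rate <- model$spec$dropout
  max_epochs <- if (!is.null(fixed_epochs)) fixed_epochs else cfg$max_epochs
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bsz)
    for (s in starts) {
      idx <- ord[s:min(s + bsz - 1L, n)]
      encb <- enc_subset(enc_train, idx)
      mask <- NULL
      if (rate > 0) {
        mask <- lapply(model$spec$blocks, function(blk)
          matrix(stats::rbinom(length(idx) * blk$width, 1L, 1 - rate) /
                   (1 - rate), length(idx), blk$width))
        names(mask) <- names(model$spec$blocks)
      }
      cache <- cnn_forward(model, encb, keep = TRUE, dropout_mask = mask)
      grad <- cnn_backward(model, encb, cache, y[idx], w[idx])
      upd <- adam_step(model$par, grad, state, lr = cfg$learning_rate)
      model$par <- upd$par
      state <- upd$state
    }
    if (!is.null(fixed_epochs)) next
    p_val <- cnn_forward(model, enc_val, keep = FALSE)
    vloss <- bce_loss(y_val, p_val)
    vauc01 <- if (length(unique(y_val)) > 1L) roc_auc01(y_val, p_val) else NA
    metric <- switch(cfg$stop_metric,
                     val_loss = vloss,
                     val_auc01 = vauc01,
                     custom_cm = custom_cm(vauc01, vloss))
    log[[epoch]] <- c(epoch = epoch, val_loss = vloss, val_auc01 = vauc01,
                      metric = metric)
    improved <- if (minimize) metric < best else metric > best
    if (!is.na(metric) && improved) {
      best <- metric
      best_par <- model$par
      best_epoch <- epoch
    }
    if (cfg$verbose)
      message(sprintf("epoch %d loss %.4f auc01 %.4f", epoch, vloss, vauc01))
    if (epoch - best_epoch >= cfg$patience) break
  }
  if (is.null(fixed_epochs)) model$par <- best_par
  model$log <- do.call(rbind, log)
  model$best_epoch <- best_epoch
  model$best_metric <- best
  model
}

#' Train CNN models under nested cross-validation
#'
#' Five outer folds by four inner folds: for each outer test partition,
#' four models are trained (three partitions training, one validation) with
#' early stopping, and each test record's score is the mean of its four
#' inner-model scores. Peptide-specific variants (`pep22`) are trained
#' separately per peptide on that peptide's observations.
#'
#' @param ds Partitioned `tcr_dataset` including negatives.
#' @param spec A [model_spec()] (`pan21`, `pan22` or `pep22`; for the
#'   two-block variant see [train_pretrained()]).
#' @param cfg A [train_config()].
#' @param slots Optional subset of cross-validation slots (as returned by
#'   the internal planner; each a list with `test`, `val`, `train`) to
#'   restrict the run. Test scores then average over the available models.
#' @return List with `models` (one per slot, or per peptide x slot),
#'   `predictions` (test scores: `record_id`, `peptide`, `binder`,
#'   `partition`, `score`, `n_models`) and `val_predictions` (long format:
#'   one row per record x validating model with `test_fold` and `score`).
#' @export
train_nested_cv <- function(ds, spec, cfg = train_config(), slots = NULL) {
  if (anyNA(ds$partition)) stop("partitions must be assigned", call. = FALSE)
  parts <- sort(unique(ds$partition))
  if (is.null(slots)) slots <- cv_slots(length(parts))
  peptide_mode <- spec$variant == "pep22" || cfg$mode == "peptide"
  groups <- if (peptide_mode) split_dataset(ds, ds$peptide) else
    list(all = ds)
  feats <- model_features(spec)
  models <- list()
  test_scores <- list()
  val_scores <- list()
  for (gn in names(groups)) {
    sub <- groups[[gn]]
    enc <- encode_dataset(sub, feats)
    for (si in seq_along(slots)) {
      sl <- slots[[si]]
      tr <- which(sub$partition %in% sl$train)
      w_tr <- compute_sample_weights(sub[tr, , drop = FALSE],
                                     cfg$weight_constant_c,
                                     if (peptide_mode) "peptide" else "pan")
      va <- which(sub$partition == sl$val)
      if (length(va) == 0L) stop("empty validation partition ", sl$val,
                                 call. = FALSE)
      te <- which(sub$partition == sl$test)
      seed_i <- cfg$seed + 1000L * si + match(gn, names(groups))
      model <- build_model(spec, seed = seed_i)
      cfg_i <- cfg
      cfg_i$seed <- seed_i + 1L
      model <- train_model(model, enc_subset(enc, tr), sub$binder[tr],
                           w_tr, enc_subset(enc, va), sub$binder[va],
                           cfg_i)
      model$slot <- sl
      models[[sprintf("%s/t%d_v%d", gn, sl$test, sl$val)]] <- model
      if (length(te) > 0L)
        test_scores[[length(test_scores) + 1L]] <- data.frame(
          record_id = sub$record_id[te],
          score = cnn_forward(model, enc_subset(enc, te)),
          stringsAsFactors = FALSE)
      val_scores[[length(val_scores) + 1L]] <- data.frame(
        record_id = sub$record_id[va], test_fold = sl$test,
        score = cnn_forward(model, enc_subset(enc, va)),
        stringsAsFactors = FALSE)
    }
  }
  list(models = models,
       predictions = summarise_scores(ds, do.call(rbind, test_scores)),
       val_predictions = merge_record_info(ds, do.call(rbind, val_scores)))
}

summarise_scores <- function(ds, long) {
  agg <- stats::aggregate(score ~ record_id, data = long, FUN = mean)
  nmod <- stats::aggregate(score ~ record_id, data = long, FUN = length)
  out <- data.frame(record_id = ds$record_id, peptide = ds$peptide,
                    binder = ds$binder, partition = ds$partition,
                    stringsAsFactors = FALSE)
  out$score <- agg$score[match(out$record_id, agg$record_id)]
  out$n_models <- nmod$score[match(out$record_id, nmod$record_id)]
  out
}

merge_record_info <- function(ds, long) {
  info <- data.frame(record_id = ds$record_id, peptide = ds$peptide,
                     binder = ds$binder, partition = ds$partition,
                     stringsAsFactors = FALSE)
  merge(long, info, by = "record_id", sort = FALSE)
}

#' Train the two-block pre-trained models
#'
#' Round 1 trains the pan-specific block across all peptides with the
#' peptide-specific block frozen (patience 100, at most 200 epochs). Round
#' 2 starts from the round-1 weights per peptide, freezes the pan block,
#' unfreezes the peptide block, and trains on that peptide's observations
#' only. The shared dense head stays trainable in both rounds. Test scores
#' for each record come from its peptide's round-2 model.
#'
#' @param ds Partitioned `tcr_dataset` including negatives.
#' @param cfg A [train_config()] (`mode` is handled internally; `seed`,
#'   `patience`/`max_epochs` overrides and `stop_metric` are honored).
#' @param slots Optional slot subset, as in [train_nested_cv()].
#' @return List with `models` (per slot: `round1` model and per-peptide
#'   round-2 models), `predictions` and `val_predictions` as in
#'   [train_nested_cv()].
#' @export
train_pretrained <- function(ds, cfg = train_config(mode = "pretrained"),
                             slots = NULL) {
  if (anyNA(ds$partition)) stop("partitions must be assigned", call. = FALSE)
  parts <- sort(unique(ds$partition))
  if (is.null(slots)) slots <- cv_slots(length(parts))
  spec <- model_spec("pretrained")
  enc <- encode_dataset(ds, CDR_FEATURES)
  models <- list()
  test_scores <- list()
  val_scores <- list()
  for (si in seq_along(slots)) {
    sl <- slots[[si]]
    tr <- which(ds$partition %in% sl$train)
    va <- which(ds$partition == sl$val)
    te <- which(ds$partition == sl$test)
    seed_i <- cfg$seed + 1000L * si
    base <- build_model(spec, seed = seed_i)
    base <- set_block_trainable(base, "peptide_block", FALSE)
    cfg1 <- cfg
    cfg1$mode <- "pan"
    cfg1$patience <- 100L
    cfg1$max_epochs <- min(cfg$max_epochs, 200L)
    cfg1$seed <- seed_i + 1L
    w_tr <- compute_sample_weights(ds[tr, , drop = FALSE],
                                   cfg$weight_constant_c, "pan")
    base <- train_model(base, enc_subset(enc, tr), ds$binder[tr], w_tr,
                        enc_subset(enc, va), ds$binder[va], cfg1)
    base$slot <- sl
    slot_models <- list(round1 = base)
    for (pep in unique(ds$peptide)) {
      pi_tr <- tr[ds$peptide[tr] == pep]
      pi_va <- va[ds$peptide[va] == pep]
      pi_te <- te[ds$peptide[te] == pep]
      if (length(pi_tr) == 0L || length(pi_va) == 0L) next
      m <- set_block_trainable(base, "pan_block", FALSE)
      m <- set_block_trainable(m, "peptide_block", TRUE)
      cfg2 <- cfg
      cfg2$mode <- "peptide"
      cfg2$patience <- 100L
      cfg2$max_epochs <- min(cfg$max_epochs, 200L)
      cfg2$seed <- seed_i + 2L + match(pep, unique(ds$peptide))
      m <- train_model(m, enc_subset(enc, pi_tr), ds$binder[pi_tr],
                       rep(1, length(pi_tr)), enc_subset(enc, pi_va),
                       ds$binder[pi_va], cfg2)
      m$slot <- sl
      slot_models[[pep]] <- m
      if (length(pi_te) > 0L)
        test_scores[[length(test_scores) + 1L]] <- data.frame(
          record_id = ds$record_id[pi_te],
          score = cnn_forward(m, enc_subset(enc, pi_te)),
          stringsAsFactors = FALSE)
      val_scores[[length(val_scores) + 1L]] <- data.frame(
        record_id = ds$record_id[pi_va], test_fold = sl$test,
        score = cnn_forward(m, enc_subset(enc, pi_va)),
        stringsAsFactors = FALSE)
    }
    models[[sprintf("t%d_v%d", sl$test, sl$val)]] <- slot_models
  }
  list(models = models,
       predictions = summarise_scores(ds, do.call(rbind, test_scores)),
       val_predictions = merge_record_info(ds, do.call(rbind, val_scores)))
}

#' Fine-tune a pre-trained model towards a new peptide
#'
#' Starting from a round-1 (pan-trained) two-block model whose training
#' data did not include the new peptide, the pan block is unfrozen and
#' trained for exactly `epochs` epochs on the union of the base data and
#' the new peptide's observations, with loss weights `w_new` for the new
#' peptide's rows and `w_old` for the rest. Swapped negatives in the base
#' data whose donor TCR originated from the new peptide are removed first.
#' The pan block is then frozen and the peptide-specific block trained on
#' the new peptide's observations (batch default 32, combined
#' AUC0.1/loss stopping, patience 100).
#'
#' @param model A round-1 trained `"pretrained"` `tcr_cnn` with a `slot`
#'   (test/validation fold assignment).
#' @param new_data Partitioned `tcr_dataset` of the new peptide
#'   (positives and their negatives).
#' @param base_data Partitioned `tcr_dataset` used for round-1 training
#'   (must not contain the new peptide as a positive).
#' @param epochs Pan fine-tuning epochs (default 30; 0 leaves the pan
#'   block untouched).
#' @param w_new,w_old Sample weights for new-peptide and base rows.
#' @param cfg A [train_config()] supplying seeds and learning rate.
#' @return The fine-tuned `tcr_cnn`.
#' @export
finetune_pan_block <- function(model, new_data, base_data, epochs = 30L,
                               w_new = 1.0, w_old = 0.1,
                               cfg = train_config(mode = "finetune")) {
  stopifnot(inherits(model, "tcr_cnn"), model$spec$variant == "pretrained",
            !is.null(model$slot))
  new_pep <- unique(new_data$peptide[new_data$binder == 1])
  stopifnot(length(new_pep) == 1L)
  if (any(base_data$peptide == new_pep & base_data$binder == 1))
    stop("leakage: new peptide present as positive in base data",
         call. = FALSE)
  # drop swapped negatives donated by the new peptide's TCRs
  keep <- !(base_data$negative_kind == "swapped" &
              base_data$source_peptide == new_pep)
  base_data <- base_data[keep, , drop = FALSE]
  combined <- rbind(as.data.frame(base_data), as.data.frame(new_data))
  class(combined) <- c("tcr_dataset", "data.frame")
  sl <- model$slot
  tr <- which(combined$partition %in% sl$train)
  w <- ifelse(combined$peptide == new_pep, w_new, w_old)
  enc <- encode_dataset(combined, CDR_FEATURES)
  if (epochs > 0L) {
    m <- set_block_trainable(model, "pan_block", TRUE)
    m <- set_block_trainable(m, "peptide_block", FALSE)
    cfgA <- cfg
    cfgA$mode <- "pan"
    cfgA$seed <- cfg$seed + 7L
    m <- train_model(m, enc_subset(enc, tr), combined$binder[tr], w[tr],
                     enc_val = NULL, y_val = NULL, cfg = cfgA,
                     fixed_epochs = epochs)
  } else m <- model
  m <- set_block_trainable(m, "pan_block", FALSE)
  m <- set_block_trainable(m, "peptide_block", TRUE)
  ntr <- which(new_data$partition %in% sl$train)
  nva <- which(new_data$partition == sl$val)
  enc_new <- encode_dataset(new_data, CDR_FEATURES)
  cfgB <- cfg
  cfgB$mode <- "peptide"
  cfgB$stop_metric <- "custom_cm"
  cfgB$batch_default <- 32L
  cfgB$patience <- min(cfg$patience, 100L)
  cfgB$seed <- cfg$seed + 11L
  m <- train_model(m, enc_subset(enc_new, ntr), new_data$binder[ntr],
                   rep(1, length(ntr)), enc_subset(enc_new, nva),
                   new_data$binder[nva], cfgB)
  m$slot <- sl
  m
}
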