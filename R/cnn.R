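# Compact max-pooled CNN classifiers over BLOSUM-encoded CDR sequences.
#
# The networks are small enough (< 300k parameters) that the forward and
# backward passes are implemented directly on base-R matrix operations
# (BLAS): per input feature one 1-D convolution per kernel size, global max
# pooling with an activation applied to the pooled value, concatenation,
# dropout, and a small sigmoid dense head. Convolutions use same-padding
# along the length axis; the padding value is the encoding's pad vector
# (-1), so windows beyond a sequence see exactly what genuine padding rows
# contain and extending the padding never changes the pooled output.

KERNEL_SIZES <- c(1L, 3L, 5L, 7L, 9L)

#' Architecture specification for the CNN variants
#'
#' Four variants are supported:
#' * `"pan21"`: pan-specific baseline; 16 filters per kernel size, sigmoid
#'   pooling activation, no dropout, 32-unit dense layer. Consumes all seven
#'   features (peptide + six CDRs).
#' * `"pan22"`: updated pan-specific model; ReLU pooling activation,
#'   dropout 0.6 on the pooled concatenation, 64-unit dense layer.
#' * `"pep22"`: peptide-specific variant of `"pan22"`; consumes the six CDR
#'   features only (the peptide input is constant within one peptide's
#'   training set and is dropped).
#' * `"pretrained"`: two-block model: a pan-specific block (32 filters per
#'   size, seven features) and a peptide-specific block (16 filters per
#'   size, six features). Each block's pooled concatenation passes its own
#'   dropout layer and a 64-unit sigmoid dense layer; the two 64-unit
#'   outputs are concatenated (width 128) and fed to a shared 32-unit
#'   sigmoid dense layer and the sigmoid output unit. Blocks can be frozen
#'   independently; the shared head stays trainable in both training
#'   rounds.
#'
#' All variants end in a single sigmoid output unit, so scores lie in
#' (0, 1).
#'
#' @param variant One of `"pan21"`, `"pan22"`, `"pep22"`, `"pretrained"`.
#' @return A `model_spec` list describing blocks, filters, activations and
#'   dense sizes.
#' @export
model_spec <- function(variant = c("pan22", "pep22", "pan21", "pretrained")) {
  variant <- match.arg(variant)
  seven <- CDR_FEATURES
  six <- setdiff(CDR_FEATURES, "peptide")
  spec <- switch(variant,
    pan21 = list(blocks = list(main = list(features = seven, filters = 16L)),
                 pool_activation = "sigmoid", dropout = 0,
                 dense_units = 32L, block_dense = FALSE),
    pan22 = list(blocks = list(main = list(features = seven, filters = 16L)),
                 pool_activation = "relu", dropout = 0.6,
                 dense_units = 64L, block_dense = FALSE),
    pep22 = list(blocks = list(main = list(features = six, filters = 16L)),
                 pool_activation = "relu", dropout = 0.6,
                 dense_units = 64L, block_dense = FALSE),
    pretrained = list(blocks = list(pan = list(features = seven, filters = 32L),
                                    pep = list(features = six, filters = 16L)),
                      pool_activation = "relu", dropout = 0.6,
                      dense_units = 32L, block_dense = TRUE,
                      block_dense_units = 64L))
  spec$variant <- variant
  spec$kernel_sizes <- KERNEL_SIZES
  for (b in names(spec$blocks))
    spec$blocks[[b]]$width <- length(spec$blocks[[b]]$features) *
      length(KERNEL_SIZES) * spec$blocks[[b]]$filters
  structure(spec, class = "model_spec")
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a CNN model with freshly initialized weights
#'
#' Weights use Glorot-uniform initialization under the given seed; biases
#' start at zero. The returned handle carries the weights as a flat named
#' list (keys like `pan/conv/cdr3b/k5/W`), per-block trainability flags and
#' the architecture specification it was built from.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `tcr_cnn`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  rng <- local_rng(seed)
  on.exit(rng())
  par <- list()
  for (bn in names(spec$blocks)) {
    blk <- spec$blocks[[bn]]
    for (f in blk$features) {
      for (k in spec$kernel_sizes) {
        key <- sprintf("%s/conv/%s/k%d/", bn, f, k)
        par[[paste0(key, "W")]] <- glorot_uniform(k * 20L, blk$filters,
                                                  k * 20L, k * blk$filters)
        par[[paste0(key, "b")]] <- numeric(blk$filters)
      }
    }
    if (isTRUE(spec$block_dense)) {
      u <- spec$block_dense_units
      par[[sprintf("%s/dense/W", bn)]] <-
        glorot_uniform(blk$width, u, blk$width, u)
      par[[sprintf("%s/dense/b", bn)]] <- numeric(u)
    }
  }
  head_in <- if (isTRUE(spec$block_dense))
    length(spec$blocks) * spec$block_dense_units
  else spec$blocks$main$width
  par[["shared/dense/W"]] <- glorot_uniform(head_in, spec$dense_units,
                                            head_in, spec$dense_units)
  par[["shared/dense/b"]] <- numeric(spec$dense_units)
  par[["shared/out/W"]] <- glorot_uniform(spec$dense_units, 1L,
                                          spec$dense_units, 1L)
  par[["shared/out/b"]] <- numeric(1L)
  structure(list(spec = spec, par = par,
                 trainable = stats::setNames(rep(TRUE, length(spec$blocks)),
                                             names(spec$blocks)),
                 seed = as.integer(seed)),
            class = "tcr_cnn")
}

#' Total and per-variant trainable parameter count
#'
#' @param model A `tcr_cnn` (or a [model_spec()], which is built with
#'   throwaway weights first).
#' @return Integer: number of scalar parameters.
#' @export
count_params <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = 0L)
  sum(vapply(model$par, length, integer(1)))
}

#' Toggle trainability of a model block
#'
#' For the two-block pre-trained variant, freezes or unfreezes exactly the
#' named block's convolution and per-block dense weights. The shared dense
#' head and output layer are always trainable.
#'
#' @param model A `tcr_cnn` of the `"pretrained"` variant.
#' @param block `"pan_block"` or `"peptide_block"`.
#' @param trainable Logical.
#' @return The updated model.
#' @export
set_block_trainable <- function(model, block, trainable) {
  stopifnot(inherits(model, "tcr_cnn"))
  if (model$spec$variant != "pretrained")
    stop("block freezing applies to the pretrained variant only",
         call. = FALSE)
  bn <- switch(block, pan_block = "pan", peptide_block = "pep",
               stop("invalid block name: ", block, call. = FALSE))
  model$trainable[[bn]] <- isTRUE(trainable)
  model
}

# Build the im2col matrix for one feature batch: X is (B, L, 20); returns
# (B*L, k*20) with row index b + (p-1)*B and same-padding with the pad
# value -1.
im2col <- function(X, k) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  if (k == 1L) return(matrix(X, B * L, 20L))
  half <- (k - 1L) %/% 2L
  Xp <- array(-1, dim = c(B, L + k - 1L, 20L))
  Xp[, half + seq_len(L), ] <- X
  out <- matrix(0, B * L, k * 20L)
  for (t in seq_len(k))
    out[, (t - 1L) * 20L + 1:20] <- matrix(Xp[, (t - 1L) + seq_len(L), ,
                                              drop = FALSE], B * L, 20L)
  out
}

relu <- function(x) (x > 0) * x
sigm <- function(x) 1 / (1 + exp(-x))

# Forward pass. enc: named list of (B, L_f, 20) arrays covering all block
# features. Returns scores and, if keep = TRUE, the intermediates needed
# for backprop. dropout_mask: NULL (inference) or list per block of (B,
# width) masks.
cnn_forward <- function(model, enc, keep = FALSE, dropout_mask = NULL) {
  spec <- model$spec
  par <- model$par
  act <- spec$pool_activation
  cache <- list(blocks = list())
  block_out <- list()
  for (bn in names(spec$blocks)) {
    blk <- spec$blocks[[bn]]
    B <- dim(enc[[blk$features[[1L]]]])[1L]
    pooled_pre <- matrix(0, B, blk$width)
    amax <- matrix(1L, B, blk$width)
    cols <- list()
    off <- 0L
    for (f in blk$features) {
      X <- enc[[f]]
      L <- dim(X)[2L]
      for (k in spec$kernel_sizes) {
        key <- sprintf("%s/conv/%s/k%d/", bn, f, k)
        Y <- im2col(X, k)
        Z <- Y %*% par[[paste0(key, "W")]]
        Z <- sweep(Z, 2L, par[[paste0(key, "b")]], "+")
        Fl <- blk$filters
        # max over positions with argmax bookkeeping
        mx <- Z[seq_len(B), , drop = FALSE]
        am <- matrix(1L, B, Fl)
        if (L > 1L) for (p in 2:L) {
          Zp <- Z[(p - 1L) * B + seq_len(B), , drop = FALSE]
          upd <- Zp > mx
          mx[upd] <- Zp[upd]
          am[upd] <- p
        }
        idx <- off + seq_len(Fl)
        pooled_pre[, idx] <- mx
        amax[, idx] <- am
        if (keep) cols[[key]] <- Y
        off <- off + Fl
      }
    }
    H <- if (act == "relu") relu(pooled_pre) else sigm(pooled_pre)
    mask <- if (!is.null(dropout_mask)) dropout_mask[[bn]] else NULL
    Hd <- if (!is.null(mask)) H * mask else H
    if (isTRUE(spec$block_dense)) {
      Dpre <- sweep(Hd %*% par[[sprintf("%s/dense/W", bn)]], 2L,
                    par[[sprintf("%s/dense/b", bn)]], "+")
      D <- sigm(Dpre)
      block_out[[bn]] <- D
      if (keep) cache$blocks[[bn]] <- list(pooled_pre = pooled_pre,
                                           amax = amax, H = H, Hd = Hd,
                                           mask = mask, D = D, cols = cols)
    } else {
      block_out[[bn]] <- Hd
      if (keep) cache$blocks[[bn]] <- list(pooled_pre = pooled_pre,
                                           amax = amax, H = H, Hd = Hd,
                                           mask = mask, cols = cols)
    }
  }
  Hcat <- do.call(cbind, block_out[names(spec$blocks)])
  Apre <- sweep(Hcat %*% par[["shared/dense/W"]], 2L,
                par[["shared/dense/b"]], "+")
  A <- sigm(Apre)
  out <- drop(sigm(sweep(A %*% par[["shared/out/W"]], 2L,
                         par[["shared/out/b"]], "+")))
  if (!keep) return(out)
  cache$Hcat <- Hcat
  cache$A <- A
  cache$score <- out
  cache
}

# Backward pass for weighted binary cross-entropy. Returns the gradient as
# a flat list parallel to model$par (frozen blocks get NULL gradients).
cnn_backward <- function(model, enc, cache, y, w) {
  spec <- model$spec
  par <- model$par
  B <- length(cache$score)
  g <- list()
  # d loss / d out_pre (sigmoid + BCE), mean over batch with sample weights
  dz_out <- matrix((cache$score - y) * w / B, ncol = 1L)
  g[["shared/out/W"]] <- crossprod(cache$A, dz_out)
  g[["shared/out/b"]] <- colSums(dz_out)
  dA <- dz_out %*% t(par[["shared/out/W"]])
  dApre <- dA * cache$A * (1 - cache$A)
  g[["shared/dense/W"]] <- crossprod(cache$Hcat, dApre)
  g[["shared/dense/b"]] <- colSums(dApre)
  dHcat <- dApre %*% t(par[["shared/dense/W"]])
  off <- 0L
  for (bn in names(spec$blocks)) {
    blk <- spec$blocks[[bn]]
    bc <- cache$blocks[[bn]]
    width_out <- if (isTRUE(spec$block_dense)) spec$block_dense_units
                 else blk$width
    dBlock <- dHcat[, off + seq_len(width_out), drop = FALSE]
    off <- off + width_out
    if (!model$trainable[[bn]] && !isTRUE(spec$block_dense)) next
    if (isTRUE(spec$block_dense)) {
      dDpre <- dBlock * bc$D * (1 - bc$D)
      if (model$trainable[[bn]]) {
        g[[sprintf("%s/dense/W", bn)]] <- crossprod(bc$Hd, dDpre)
        g[[sprintf("%s/dense/b", bn)]] <- colSums(dDpre)
      }
      dHd <- dDpre %*% t(par[[sprintf("%s/dense/W", bn)]])
    } else dHd <- dBlock
    if (!model$trainable[[bn]]) next
    dH <- if (!is.null(bc$mask)) dHd * bc$mask else dHd
    dPre <- if (spec$pool_activation == "relu") dH * (bc$pooled_pre > 0)
            else { s <- sigm(bc$pooled_pre); dH * s * (1 - s) }
    colp <- 0L
    for (f in blk$features) {
      L <- dim(enc[[f]])[2L]
      for (k in spec$kernel_sizes) {
        key <- sprintf("%s/conv/%s/k%d/", bn, f, k)
        Fl <- blk$filters
        idx <- colp + seq_len(Fl)
        dmx <- dPre[, idx, drop = FALSE]
        am <- bc$amax[, idx, drop = FALSE]
        dZ <- matrix(0, B * L, Fl)
        rows <- rep(seq_len(B), Fl) + (as.vector(am) - 1L) * B
        dZ[cbind(rows, rep(seq_len(Fl), each = B))] <- as.vector(dmx)
        g[[paste0(key, "W")]] <- crossprod(bc$cols[[key]], dZ)
        g[[paste0(key, "b")]] <- colSums(dZ)
        colp <- colp + Fl
      }
    }
  }
  g
}

# Adam optimizer state and one update step over a flat gradient list.
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grad)) {
    if (is.null(grad[[nm]])) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(par = par, state = state)
}

#' Predict binding scores with a CNN model
#'
#' Deterministic forward pass (dropout disabled).
#'
#' @param object A `tcr_cnn`.
#' @param newdata A `tcr_dataset` or a pre-encoded feature list (named
#'   arrays `(n, L, 20)`).
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict.tcr_cnn <- function(object, newdata, ...) {
  enc <- if (is.data.frame(newdata))
    encode_dataset(newdata, model_features(object$spec)) else newdata
  cnn_forward(object, enc, keep = FALSE)
}

model_features <- function(spec) {
  unique(unlist(lapply(spec$blocks, `[[`, "features")))
}

#' @export
print.tcr_cnn <- function(x, ...) {
  cat(sprintf("<tcr_cnn> variant %s, %d parameters (trainable blocks: %s)\n",
              x$spec$variant, count_params(x),
              paste(names(x$trainable)[x$trainable], collapse = ", ")))
  invisible(x)
}

# Weighted binary cross-entropy (numerically clipped).
bce_loss <- function(y, p, w = 1) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}
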