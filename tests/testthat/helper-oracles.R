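# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# k-mer kernel by explicit enumeration of every k-mer pair.
oracle_kernel <- function(a, b, params) {
  mh <- params$mhat
  raw <- function(x, y) {
    x <- strsplit(x, "")[[1]]
    y <- strsplit(y, "")[[1]]
    total <- 0
    for (k in params$kmin:min(params$kmax, length(x), length(y))) {
      for (i in 1:(length(x) - k + 1)) {
        for (j in 1:(length(y) - k + 1)) {
          p <- 1
          for (t in 0:(k - 1)) p <- p * mh[x[i + t], y[j + t]]
          total <- total + p
        }
      }
    }
    total
  }
  raw(a, b) / sqrt(raw(a, a) * raw(b, b))
}

# AUC by exhaustive pair counting (concordant + half ties).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Partial AUC by explicit ROC enumeration over score thresholds and
# trapezoid integration clipped at fpr_max, then the chance-0.5 rescaling.
oracle_auc01 <- function(labels, scores, fpr_max = 0.1) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t), 0))
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t), 0))
  area <- 0
  for (i in seq_len(length(th))) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]; y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  0.5 * (1 + (area - fpr_max^2 / 2) / (fpr_max - fpr_max^2 / 2))
}

# Greedy Hobohm-1 scan, coded independently over an explicit matrix.
oracle_hobohm <- function(sim, threshold) {
  kept <- integer(0)
  rep_of <- rep(NA_integer_, nrow(sim))
  for (i in seq_len(nrow(sim))) {
    offender <- NA_integer_
    for (j in kept) if (sim[i, j] >= threshold) { offender <- j; break }
    if (is.na(offender)) kept <- c(kept, i) else rep_of[i] <- offender
  }
  list(kept = kept, rep_of = rep_of)
}

# Random amino-acid strings; len is recycled over n.
random_aa <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(tcrpred:::AA_ALPHABET, len[i], replace = TRUE),
          collapse = ""),
    character(1))
}

# Minimal well-formed dataset builder for plumbing tests.
toy_dataset <- function(n = 6, peptides = c("KVLEWGSNA", "RQFTDYSMP")) {
  set.seed(99)
  df <- data.frame(
    peptide = rep_len(peptides, n),
    cdr1a = random_aa(n, 6), cdr2a = random_aa(n, 6),
    cdr3a = paste0("C", random_aa(n, 10), "F"),
    cdr1b = random_aa(n, 5), cdr2b = random_aa(n, 6),
    cdr3b = paste0("C", random_aa(n, 11), "F"),
    binder = 1, stringsAsFactors = FALSE)
  tcr_dataset(df)
}
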