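#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertion, deletion, substitution),
#' computed with `utils::adist`.
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(utils::adist(a[i], b[i])),
         integer(1))
}

#' Configuration for negative generation
#'
#' @param swapped_ratio Target swapped negatives per positive (default 5).
#' @param control_ratio Target negative controls per positive (default 0;
#'   the IMMREP-style setup uses 2 together with `swapped_ratio = 3`).
#' @param min_peptide_distance Minimum Levenshtein distance between a
#'   peptide and the source peptide of its swapped negatives. The default 4
#'   enforces a distance strictly greater than 3; the IMMREP-style setup
#'   uses 3 ("at least three").
#' @param within_partition Sample donors only from the same partition
#'   (default `TRUE`, limiting leakage across folds).
#' @param seed Integer seed for the sampling.
#' @return A `negative_config` list.
#' @export
negative_config <- function(swapped_ratio = 5, control_ratio = 0,
                            min_peptide_distance = 4L,
                            within_partition = TRUE, seed = 1L) {
  stopifnot(is.finite(swapped_ratio), swapped_ratio >= 0,
            is.finite(control_ratio), control_ratio >= 0,
            min_peptide_distance >= 0)
  structure(list(swapped_ratio = swapped_ratio, control_ratio = control_ratio,
                 min_peptide_distance = as.integer(min_peptide_distance),
                 within_partition = isTRUE(within_partition),
                 seed = as.integer(seed)),
            class = "negative_config")
}

#' Randomly partition a dataset for cross-validation
#'
#' Records are assigned to `k` partitions of near-equal size (sizes differ
#' by at most one) by a seeded random permutation.
#'
#' @param ds `tcr_dataset` (positives, at this stage of the pipeline).
#' @param k Number of partitions (default 5).
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return The dataset with `partition` filled in.
#' @export
partition_dataset <- function(ds, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  n <- nrow(ds)
  if (n < k) stop("fewer records (", n, ") than partitions (", k, ")",
                  call. = FALSE)
  parts <- rep_len(seq_len(k), n)
  rng <- local_rng(seed)
  ds$partition <- as.integer(parts[sample.int(n)])
  rng()
  ds
}

# Seeded RNG scope: sets the seed, returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Generate swapped negatives
#'
#' For each peptide `p`, TCRs observed binding sufficiently distant peptides
#' (`levenshtein(p, q) >= min_peptide_distance`) are relabeled as
#' non-binders of `p`. Donors are sampled uniformly without replacement from
#' the pooled eligible TCRs per (peptide, partition); when the pool is
#' smaller than `swapped_ratio` times the positives, the entire pool is used
#' once (so abundant peptides can end below the target ratio). A TCR may
#' serve as a negative for several peptides but never twice for the same
#' one. Positive records are never mutated.
#'
#' @param ds Partitioned `tcr_dataset` of positives (at least two peptides).
#' @param cfg A [negative_config()].
#' @return `tcr_dataset` of the input positives plus generated swapped
#'   negatives (`binder = 0`, `negative_kind = "swapped"`, `source_peptide`
#'   = the donor's peptide).
#' @export
generate_swapped_negatives <- function(ds, cfg = negative_config()) {
  stopifnot(inherits(cfg, "negative_config"))
  if (any(ds$binder != 1))
    stop("swapped negatives are generated from positives only", call. = FALSE)
  peps <- unique(ds$peptide)
  if (length(peps) < 2L) stop("need at least two peptides", call. = FALSE)
  if (cfg$within_partition && anyNA(ds$partition))
    stop("partitions must be assigned before negative generation",
         call. = FALSE)
  dist <- utils::adist(peps, peps)
  dimnames(dist) <- list(peps, peps)
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  neg <- list()
  for (p in peps) {
    donors_pep <- peps[dist[p, ] >= cfg$min_peptide_distance & peps != p]
    if (length(donors_pep) == 0L) {
      warning("no eligible donor peptides for ", p,
              " at minimum distance ", cfg$min_peptide_distance)
      next
    }
    groups <- if (cfg$within_partition)
      split(seq_len(nrow(ds)), ds$partition) else list(all = seq_len(nrow(ds)))
    for (g in groups) {
      n_pos <- sum(ds$peptide[g] == p)
      if (n_pos == 0L) next
      pool <- g[ds$peptide[g] %in% donors_pep]
      want <- ceiling(cfg$swapped_ratio * n_pos)
      take <- if (length(pool) <= want) pool
              else pool[sample.int(length(pool), want)]
      if (length(take) == 0L) next
      nd <- as.data.frame(ds[take, , drop = FALSE])
      nd$source_peptide <- nd$peptide
      nd$peptide <- p
      nd$binder <- 0
      nd$negative_kind <- "swapped"
      nd$record_id <- paste0(nd$record_id, "_sw_", p)
      neg[[length(neg) + 1L]] <- nd
    }
  }
  out <- rbind(as.data.frame(ds), do.call(rbind, neg))
  rownames(out) <- NULL
  class(out) <- c("tcr_dataset", "data.frame")
  validate_tcr_dataset(out)
  out
}

#' Sample negative controls per peptide and partition
#'
#' Background-repertoire TCRs (assumed non-binding) are sampled without
#' replacement for each (peptide, partition) cell at `control_ratio`
#' controls per positive. The control table is expected to be redundancy
#' reduced at the working threshold and partitioned before sampling. If a
#' partition holds fewer controls than required, all are used with a
#' warning.
#'
#' @param controls Partitioned `tcr_dataset` of background TCRs.
#' @param positives Partitioned `tcr_dataset` of positives.
#' @param cfg A [negative_config()] with `control_ratio > 0`.
#' @return `tcr_dataset` of sampled controls labeled `binder = 0`,
#'   `negative_kind = "control"`, one block per (peptide, partition).
#' @export
sample_negative_controls <- function(controls, positives,
                                     cfg = negative_config(control_ratio = 2)) {
  stopifnot(inherits(cfg, "negative_config"))
  empty <- tcr_dataset(as.data.frame(positives)[0, , drop = FALSE])
  if (cfg$control_ratio == 0) return(empty)
  rng <- local_rng(cfg$seed + 1L)
  on.exit(rng())
  out <- list()
  for (p in unique(positives$peptide[positives$binder == 1])) {
    for (part in unique(positives$partition)) {
      n_pos <- sum(positives$peptide == p & positives$binder == 1 &
                     positives$partition %in% part)
      if (n_pos == 0L) next
      pool <- which(controls$partition %in% part)
      want <- ceiling(cfg$control_ratio * n_pos)
      if (length(pool) < want) {
        warning("only ", length(pool), " controls available in partition ",
                part, " for peptide ", p, " (wanted ", want, ")")
        take <- pool
      } else take <- pool[sample.int(length(pool), want)]
      if (length(take) == 0L) next
      cd <- as.data.frame(controls[take, , drop = FALSE])
      cd$source_peptide <- cd$peptide
      cd$peptide <- p
      cd$binder <- 0
      cd$negative_kind <- "control"
      cd$record_id <- paste0(cd$record_id, "_ctl_", p)
      out[[length(out) + 1L]] <- cd
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tcr_dataset", "data.frame")
  validate_tcr_dataset(res)
  res
}
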