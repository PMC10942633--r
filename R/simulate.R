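# Synthetic peptide-specific TCR repertoires with planted CDR3 motifs.
#
# Each peptide is associated with a short sequence motif planted at a fixed
# offset of the CDR3beta loop of its binders; all other positions and loops
# are background residues drawn i.i.d. from a configurable alphabet
# distribution. The generator supports controlled label noise (positives
# secretly carrying another peptide's motif) and planted near-duplicates,
# with a ground-truth table for both, so curation, denoising and training
# are all testable without external data.

#' Default synthetic peptide panel
#'
#' Three invented 9-mer peptides (pairwise Levenshtein distance >= 4, so
#' swapped-negative generation is unconstrained at the default distance
#' threshold) with distinct 5-residue CDR3beta motifs.
#'
#' @param n_pos Positive TCRs per peptide (recycled).
#' @param n_peptides Number of peptides from the panel (2 or 3).
#' @return data.frame with `peptide`, `n_pos`, `motif`.
#' @export
default_peptide_panel <- function(n_pos = 100L, n_peptides = 3L) {
  stopifnot(n_peptides >= 2L, n_peptides <= 3L)
  panel <- data.frame(
    peptide = c("KVLEWGSNA", "RQFTDYSMP", "AYHIPCGKE")[seq_len(n_peptides)],
    motif = c("SWGEQ", "RDNYK", "PHLFM")[seq_len(n_peptides)],
    stringsAsFactors = FALSE)
  panel$n_pos <- rep_len(as.integer(n_pos), n_peptides)
  panel
}

#' Simulation configuration
#'
#' @param peptides data.frame with columns `peptide`, `n_pos`, `motif`
#'   (motifs may contain `.` wildcards, instantiated per TCR). Peptide
#'   sequences should be pairwise Levenshtein >= 4 unless a test wants the
#'   distance constraint to bite.
#' @param background Residue sampling weights over the 20-letter alphabet
#'   (default uniform).
#' @param noise_rate Fraction of positives per peptide whose CDR loops are
#'   secretly generated from a different peptide's motif (label noise;
#'   default 0).
#' @param dup_rate Fraction of records duplicated as near-copies (identical
#'   CDR3 loops, at most one substitution in a CDR1/CDR2 loop, so each
#'   duplicate has summed CDR3 similarity 1 to its source; default 0).
#' @param motif_offset 1-based CDR3beta position at which the motif starts
#'   (default 4: after the leading cysteine and two background residues).
#' @param paired_motifs Also plant a (reversed) motif in CDR3alpha.
#' @param len_ranges Named list of `c(min, max)` sequence-length ranges
#'   within the global caps.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(peptides = default_peptide_panel(),
                       background = rep(1, 20),
                       noise_rate = 0, dup_rate = 0,
                       motif_offset = 4L, paired_motifs = FALSE,
                       len_ranges = list(cdr1a = c(5L, 7L), cdr2a = c(5L, 8L),
                                         cdr3a = c(12L, 16L),
                                         cdr1b = c(4L, 6L), cdr2b = c(5L, 7L),
                                         cdr3b = c(13L, 17L)),
                       seed = 42L) {
  stopifnot(is.data.frame(peptides),
            all(c("peptide", "n_pos", "motif") %in% names(peptides)),
            all(peptides$n_pos >= 1L),
            noise_rate >= 0, noise_rate <= 1, dup_rate >= 0, dup_rate <= 1,
            length(background) == 20L, all(background >= 0))
  for (m in peptides$motif)
    if (nchar(m) + motif_offset + 1L > CDR_MAX_LEN[["cdr3b"]])
      stop("motif '", m, "' does not fit the CDR3beta length cap",
           call. = FALSE)
  structure(list(peptides = peptides, background = background / sum(background),
                 noise_rate = noise_rate, dup_rate = dup_rate,
                 motif_offset = as.integer(motif_offset),
                 paired_motifs = isTRUE(paired_motifs),
                 len_ranges = len_ranges, seed = as.integer(seed)),
            class = "sim_config")
}

# sample() treats a scalar first argument as 1:x; this helper never does.
sample1 <- function(v) v[sample.int(length(v), 1L)]

rand_residues <- function(n, freqs) {
  if (n <= 0L) return("")
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = freqs), collapse = "")
}

instantiate_motif <- function(motif, freqs) {
  ch <- strsplit(motif, "")[[1L]]
  wild <- ch == "."
  if (any(wild))
    ch[wild] <- sample(AA_ALPHABET, sum(wild), replace = TRUE, prob = freqs)
  paste(ch, collapse = "")
}

# CDR3 with the motif planted at a fixed offset: C + background + motif +
# background + F, total length drawn from the configured range.
make_cdr3 <- function(motif, offset, len_range, freqs) {
  min_len <- max(len_range[1L], offset + nchar(motif) + 1L)
  len <- sample1(seq(min_len, max(len_range[2L], min_len)))
  pre <- rand_residues(offset - 2L, freqs)
  post <- rand_residues(len - offset - nchar(motif), freqs)
  paste0("C", pre, instantiate_motif(motif, freqs), post, "F")
}

make_background_cdr3 <- function(len_range, freqs) {
  len <- sample1(seq(len_range[1L], len_range[2L]))
  paste0("C", rand_residues(len - 2L, freqs), "F")
}

rand_len_seq <- function(len_range, freqs) {
  rand_residues(sample1(seq(len_range[1L], len_range[2L])), freqs)
}

#' Simulate a motif-structured peptide-specific repertoire
#'
#' Generates positive TCR records per peptide whose CDR3beta carries the
#' peptide's motif; other loops are background. A `noise_rate` fraction of
#' each peptide's positives is secretly generated from another peptide's
#' motif (the truth table records the true source peptide); a `dup_rate`
#' fraction of records is duplicated as near-copies (recorded with their
#' source id).
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a `tcr_dataset` of positives) and `truth`
#'   (list of data.frames `flips` (`record_id`, `labeled_peptide`,
#'   `true_motif_peptide`) and `dups` (`record_id`, `source_id`)).
#' @export
simulate_repertoire <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  fr <- cfg$background
  lr <- cfg$len_ranges
  rows <- list()
  flips <- list()
  peps <- cfg$peptides
  for (pi in seq_len(nrow(peps))) {
    p <- peps$peptide[[pi]]
    n_flip <- round(cfg$noise_rate * peps$n_pos[[pi]])
    for (j in seq_len(peps$n_pos[[pi]])) {
      rid <- sprintf("p%d_%04d", pi, j)
      motif_from <- pi
      if (j <= n_flip && nrow(peps) > 1L) {
        motif_from <- sample1(setdiff(seq_len(nrow(peps)), pi))
        flips[[length(flips) + 1L]] <- data.frame(
          record_id = rid, labeled_peptide = p,
          true_motif_peptide = peps$peptide[[motif_from]],
          stringsAsFactors = FALSE)
      }
      motif <- peps$motif[[motif_from]]
      cdr3a <- if (cfg$paired_motifs)
        make_cdr3(paste(rev(strsplit(motif, "")[[1L]]), collapse = ""),
                  cfg$motif_offset, lr$cdr3a, fr)
      else make_background_cdr3(lr$cdr3a, fr)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, peptide = p,
        cdr1a = rand_len_seq(lr$cdr1a, fr), cdr2a = rand_len_seq(lr$cdr2a, fr),
        cdr3a = cdr3a,
        cdr1b = rand_len_seq(lr$cdr1b, fr), cdr2b = rand_len_seq(lr$cdr2b, fr),
        cdr3b = make_cdr3(motif, cfg$motif_offset, lr$cdr3b, fr),
        binder = 1, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  dups <- list()
  if (cfg$dup_rate > 0) {
    n_dup <- round(cfg$dup_rate * nrow(df))
    src <- sample.int(nrow(df), n_dup)
    for (s in src) {
      d <- df[s, , drop = FALSE]
      d$record_id <- paste0(d$record_id, "_dup")
      # one substitution in CDR2beta: the CDR3 loops stay identical, so the
      # duplicate sits at summed CDR3 similarity 1 to its source
      ch <- strsplit(d$cdr2b, "")[[1L]]
      pos <- sample.int(length(ch), 1L)
      ch[pos] <- sample1(setdiff(AA_ALPHABET, ch[pos]))
      d$cdr2b <- paste(ch, collapse = "")
      dups[[length(dups) + 1L]] <- data.frame(record_id = d$record_id,
                                              source_id = df$record_id[[s]],
                                              stringsAsFactors = FALSE)
      df <- rbind(df, d)
    }
  }
  rownames(df) <- NULL
  list(dataset = tcr_dataset(df),
       truth = list(
         flips = if (length(flips)) do.call(rbind, flips) else
           data.frame(record_id = character(0), labeled_peptide = character(0),
                      true_motif_peptide = character(0)),
         dups = if (length(dups)) do.call(rbind, dups) else
           data.frame(record_id = character(0), source_id = character(0))))
}

#' Write a ready-made synthetic benchmark suite
#'
#' Produces fixture tables for every pipeline stage: a separable 2-peptide
#' training benchmark, a redundancy fixture with planted near-duplicates, a
#' denoising fixture with planted label flips, and a 3-peptide table large
#' enough for leave-most-out subsampling. Truth tables are written
#' alongside.
#'
#' @param scale `"tiny"` (fast unit-test scale) or `"desk"` (benchmark
#'   scale).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
make_benchmark_suite <- function(scale = c("tiny", "desk"), seed = 42L,
                                 out_dir = tempfile("benchmark")) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- switch(scale, tiny = 30L, desk = 100L)
  paths <- list()
  emit <- function(sim, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_tcr_table(sim$dataset, p)
    paths[[name]] <<- p
    for (tt in names(sim$truth)) {
      if (nrow(sim$truth[[tt]]) == 0L) next
      tp <- file.path(out_dir, paste0(name, "_", tt, ".tsv"))
      utils::write.table(sim$truth[[tt]], tp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0(name, "_", tt)]] <<- tp
    }
  }
  emit(simulate_repertoire(sim_config(default_peptide_panel(n, 2L),
                                      seed = seed)), "separable")
  emit(simulate_repertoire(sim_config(default_peptide_panel(n, 2L),
                                      dup_rate = 0.25, seed = seed + 1L)),
       "redundancy")
  emit(simulate_repertoire(sim_config(default_peptide_panel(n, 2L),
                                      noise_rate = 0.10, seed = seed + 2L)),
       "denoise")
  emit(simulate_repertoire(sim_config(default_peptide_panel(
    switch(scale, tiny = 60L, desk = 130L), 3L), seed = seed + 3L)), "lmo")
  paths
}
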