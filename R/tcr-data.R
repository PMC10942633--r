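# Canonical column order and per-feature maximum lengths. The caps are the
# dataset-wide maxima of the curated reference data and are frozen constants
# of the model contract: the CNN input shapes depend on them.
CDR_FEATURES <- c("peptide", "cdr1a", "cdr2a", "cdr3a", "cdr1b", "cdr2b", "cdr3b")
CDR_MAX_LEN <- c(peptide = 12L, cdr1a = 7L, cdr2a = 8L, cdr3a = 22L,
                 cdr1b = 6L, cdr2b = 7L, cdr3b = 23L)

TCR_COLUMNS <- c("record_id", CDR_FEATURES, "binder", "partition",
                 "negative_kind", "source_peptide", "origin", "mhc")

#' Construct and validate a TCR dataset
#'
#' A TCR dataset is a `data.frame` with one row per paired-chain TCR
#' observation and the canonical columns `record_id`, `peptide`,
#' `cdr1a`..`cdr3b`, `binder` (1 binder / 0 non-binder), `partition`
#' (integer cross-validation partition, `NA` = unassigned), `negative_kind`
#' (`"none"`, `"swapped"` or `"control"`), `source_peptide` (the peptide the
#' TCR was originally observed binding; equals `peptide` for positives),
#' `origin` and `mhc` metadata. MHC is carried as metadata only; no model in
#' the package consumes it.
#'
#' Validation enforces the 20-letter uppercase alphabet on all sequence
#' fields, the per-feature length caps (12, 7, 8, 22, 6, 7, 23), unique
#' record ids, and label consistency (`binder == 0` iff `negative_kind` is
#' not `"none"`).
#'
#' @param df A data.frame carrying at least the sequence columns and
#'   `binder`; missing optional columns are defaulted.
#' @return The validated data.frame with class `tcr_dataset`.
#' @export
tcr_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (f in CDR_FEATURES)
    if (is.null(df[[f]])) stop("missing column: ", f, call. = FALSE)
  if (is.null(df$binder)) stop("missing column: binder", call. = FALSE)
  if (is.null(df$record_id))
    df$record_id <- sprintf("tcr%06d", seq_len(nrow(df)))
  if (is.null(df$partition)) df$partition <- NA_integer_
  df$partition <- as.integer(df$partition)
  if (is.null(df$negative_kind))
    df$negative_kind <- ifelse(df$binder == 1, "none", "swapped")
  if (is.null(df$source_peptide)) {
    df$source_peptide <- df$peptide
  } else {
    miss <- is.na(df$source_peptide) | !nzchar(df$source_peptide)
    df$source_peptide[miss] <- df$peptide[miss]
  }
  if (is.null(df$origin)) df$origin <- "synthetic"
  if (is.null(df$mhc)) df$mhc <- NA_character_
  df$mhc[!is.na(df$mhc) & !nzchar(df$mhc)] <- NA_character_
  df <- df[, TCR_COLUMNS]
  validate_tcr_dataset(df)
  class(df) <- c("tcr_dataset", "data.frame")
  df
}

validate_tcr_dataset <- function(df) {
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id values", call. = FALSE)
  if (!all(df$binder %in% c(0, 1)))
    stop("binder must be 0 or 1", call. = FALSE)
  bad_kind <- !(df$negative_kind %in% c("none", "swapped", "control"))
  if (any(bad_kind))
    stop("invalid negative_kind: ",
         paste(unique(df$negative_kind[bad_kind]), collapse = ", "),
         call. = FALSE)
  mism <- (df$binder == 1 & df$negative_kind != "none") |
          (df$binder == 0 & df$negative_kind == "none")
  if (any(mism))
    stop("label/negative_kind mismatch at row(s) ",
         paste(utils::head(which(mism), 5L), collapse = ", "), call. = FALSE)
  pat <- sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = ""))
  for (f in CDR_FEATURES) {
    v <- df[[f]]
    bad <- !grepl(pat, v)
    if (any(bad))
      stop("row ", which(bad)[1L], ": ", f, " '", v[bad][1L],
           "' contains characters outside the standard amino-acid alphabet",
           call. = FALSE)
    over <- nchar(v) > CDR_MAX_LEN[[f]]
    if (any(over))
      stop("row ", which(over)[1L], ": ", f, " length ", nchar(v[over][1L]),
           " exceeds cap ", CDR_MAX_LEN[[f]], call. = FALSE)
  }
  invisible(df)
}

#' Per-peptide positive counts
#'
#' Counts are always recomputed from the records, never cached, so they are
#' consistent after any mutation.
#'
#' @param ds A `tcr_dataset`.
#' @return Named integer vector, peptide -> number of positive records.
#' @export
peptide_counts <- function(ds) {
  pos <- ds[ds$binder == 1, , drop = FALSE]
  if (nrow(pos) == 0L) return(integer(0))
  tab <- table(pos$peptide)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.tcr_dataset <- function(x, ...) {
  cat(sprintf("<tcr_dataset> %d records, %d positives, %d peptides\n",
              nrow(x), sum(x$binder == 1), length(unique(x$peptide))))
  NextMethod()
}

# Column maps for the two supported table dialects. "paired" is the
# A1..B3/peptide/binder layout common for paired-chain specificity tables;
# "immrep" is the IMMREP 2022 benchmark layout where negatives carry
# binder = -1 (remapped to 0 on read).
dialect_map <- function(dialect = c("paired", "immrep")) {
  dialect <- match.arg(dialect)
  list(dialect = dialect,
       columns = c(A1 = "cdr1a", A2 = "cdr2a", A3 = "cdr3a",
                   B1 = "cdr1b", B2 = "cdr2b", B3 = "cdr3b",
                   peptide = "peptide", binder = "binder"))
}

#' Read a TCR table
#'
#' Parses a delimited paired-chain TCR table into a [tcr_dataset()]. Two
#' dialects are supported: `"paired"` (columns
#' `A1,A2,A3,B1,B2,B3,peptide,binder` plus optional `partition`,
#' `negative_kind`, `source_peptide`, `origin`, `mhc`, `record_id`) and
#' `"immrep"` (same columns, negatives labeled `-1`, remapped to 0).
#' Empty `partition` cells parse as unassigned.
#'
#' @param path File path.
#' @param dialect `"paired"` or `"immrep"`.
#' @param sep Field delimiter; `NULL` auto-detects tab vs comma from the
#'   header line.
#' @return A `tcr_dataset`; row order preserved.
#' @export
read_tcr_table <- function(path, dialect = c("paired", "immrep"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  map <- dialect_map(dialect)$columns
  missing_cols <- setdiff(names(map), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- stats::setNames(raw[names(map)], unname(map))
  df$binder <- as.numeric(df$binder)
  if (dialect == "immrep") df$binder[df$binder == -1] <- 0
  for (opt in c("record_id", "negative_kind", "source_peptide", "origin", "mhc"))
    if (opt %in% names(raw)) df[[opt]] <- raw[[opt]]
  if ("partition" %in% names(raw)) {
    p <- raw[["partition"]]
    p[!nzchar(trimws(p))] <- NA
    df$partition <- as.integer(p)
  }
  empty <- !nzchar(df$peptide) | Reduce(`|`, lapply(CDR_FEATURES,
                                                    function(f) !nzchar(df[[f]])))
  if (any(empty))
    stop("row ", which(empty)[1L], ": empty sequence field", call. = FALSE)
  tcr_dataset(df)
}

#' Write a TCR table
#'
#' Inverse of [read_tcr_table()]: `read_tcr_table(write_tcr_table(ds))`
#' reproduces all typed fields. Unassigned partitions are written as empty
#' cells; in the `"immrep"` dialect negative labels are written as `-1`.
#'
#' @param ds A `tcr_dataset`.
#' @param path Output path.
#' @param dialect `"paired"` or `"immrep"`.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_tcr_table <- function(ds, path, dialect = c("paired", "immrep"),
                            sep = "\t") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "tcr_dataset"))
  map <- dialect_map(dialect)$columns
  out <- stats::setNames(as.data.frame(ds)[unname(map)], names(map))
  if (dialect == "immrep") out$binder[out$binder == 0] <- -1
  out$partition <- ifelse(is.na(ds$partition), "", as.character(ds$partition))
  for (opt in c("negative_kind", "source_peptide", "origin", "mhc", "record_id"))
    out[[opt]] <- ds[[opt]]
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Normalize CDR3 nomenclature
#'
#' IMGT-style CDR3 junctions begin with a cysteine and end with phenylalanine
#' or tryptophan. This prepends `C` when missing and appends `F` when the
#' sequence ends in neither `F` nor `W`. Idempotent; the interior is never
#' modified.
#'
#' @param seq Character vector of amino-acid strings.
#' @return Character vector of normalized sequences.
#' @examples
#' fix_cdr3_nomenclature("ASSLRSYEQY")   # -> "CASSLRSYEQYF"
#' fix_cdr3_nomenclature("CASSLGW")      # unchanged, W accepted
#' @export
fix_cdr3_nomenclature <- function(seq) {
  if (any(!nzchar(seq) | is.na(seq)))
    stop("empty sequence", call. = FALSE)
  out <- ifelse(substr(seq, 1L, 1L) == "C", seq, paste0("C", seq))
  last <- substr(out, nchar(out), nchar(out))
  ifelse(last %in% c("F", "W"), out, paste0(out, "F"))
}
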