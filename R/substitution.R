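#' @useDynLib tcrpred, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# The 20 standard residues, in the NCBI matrix ordering used by the bundled
# tables. All encoding and kernel code indexes residues through this vector.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a bundled substitution matrix
#'
#' Reads one of the two canonical substitution matrices shipped with the
#' package (standard NCBI text layout, restricted to the 20 standard amino
#' acids) and attaches a normalization divisor used when the matrix serves as
#' a residue embedding.
#'
#' @param name `"BLOSUM50"` or `"BLOSUM62"`.
#' @param divisor Positive real; score lookups through [sm_score()] with
#'   `normalized = TRUE` return `score / divisor`. The CDR embedding uses
#'   BLOSUM50 with divisor 5; the k-mer kernel uses BLOSUM62 raw
#'   (divisor 1).
#' @return An object of class `substitution_matrix`: a list with `name`,
#'   `scores` (20 x 20 integer matrix, residue dimnames) and `divisor`.
#' @examples
#' b62 <- load_substitution_matrix("BLOSUM62")
#' sm_score(b62, "A", "A")
#' @export
load_substitution_matrix <- function(name = c("BLOSUM50", "BLOSUM62"),
                                     divisor = 1) {
  name <- match.arg(name)
  if (!is.numeric(divisor) || length(divisor) != 1L || divisor <= 0)
    stop("`divisor` must be a single positive number", call. = FALSE)
  path <- system.file("extdata", paste0(name, ".txt"), package = "tcrpred")
  if (path == "")
    stop("bundled matrix not found: ", name, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  stopifnot(identical(header, AA_ALPHABET))
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  scores <- t(vapply(rows, function(r) as.integer(r[-1L]),
                     integer(length(AA_ALPHABET))))
  dimnames(scores) <- list(AA_ALPHABET, AA_ALPHABET)
  stopifnot(identical(vapply(rows, `[[`, "", 1L), AA_ALPHABET),
            isTRUE(all.equal(scores, t(scores))))
  structure(list(name = name, scores = scores, divisor = divisor),
            class = "substitution_matrix")
}

#' Look up a substitution score
#'
#' @param sm A `substitution_matrix`.
#' @param a,b Single residues (uppercase, standard alphabet).
#' @param normalized If `TRUE`, divide by the matrix divisor.
#' @return Numeric score.
#' @export
sm_score <- function(sm, a, b, normalized = FALSE) {
  stopifnot(inherits(sm, "substitution_matrix"))
  if (!(a %in% AA_ALPHABET) || !(b %in% AA_ALPHABET))
    stop("non-standard residue in lookup: ",
         paste(setdiff(c(a, b), AA_ALPHABET), collapse = ", "), call. = FALSE)
  s <- sm$scores[a, b]
  if (normalized) s / sm$divisor else as.numeric(s)
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("<substitution_matrix> %s (divisor %g)\n", x$name, x$divisor))
  invisible(x)
}

# Integer-encode an AA string (1-based indices into AA_ALPHABET).
# Errors on any non-standard character.
aa_encode <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx))
    stop("non-amino-acid character(s) in sequence '", seq, "': ",
         paste(unique(ch[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}
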