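#' @useDynLib plastcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table modifyList head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# All user-facing tables are written 1-based inclusive.

IUPAC_CHARS <- c("A", "C", "G", "T", "N")

#' Reverse complement of a nucleotide string
#'
#' @param x single nucleotide string over A/C/G/T/N (case-insensitive).
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# fast path for char vectors (already split, uppercase)
revcomp_chars <- function(v) {
  rev(chartr("ACGTN", "TGCAN", v))
}

seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1L]]

chars_seq <- function(v) paste0(v, collapse = "")

#' GC content over unambiguous bases
#'
#' Fraction of G+C among A/C/G/T (N and other ambiguity codes are excluded
#' from numerator and denominator).
#'
#' @param seq nucleotide string.
#' @return numeric in \[0, 1\]; NaN for a sequence with no unambiguous base.
#' @export
gc_content <- function(seq) {
  v <- seq_chars(seq)
  acgt <- v %in% c("A", "C", "G", "T")
  sum(v[acgt] %in% c("G", "C")) / sum(acgt)
}

validate_nucleotides <- function(seq, what = "sequence") {
  v <- seq_chars(seq)
  bad <- setdiff(unique(v), IUPAC_CHARS)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC symbol(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(chars_seq(v))
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# six non-strand-specific substitution classes, e.g. "A/G" == "G/A" == "T/C"
snp_pair_class <- function(ref, alt) {
  p <- vapply(seq_along(ref), function(i) {
    paste(sort(c(ref[i], alt[i])), collapse = "/")
  }, character(1))
  p
}

gc_class_of <- function(ref, alt) {
  ifelse(ref %in% c("A", "T") & alt %in% c("A", "T"), "AT<->TA",
    ifelse(ref %in% c("C", "G") & alt %in% c("C", "G"), "CG<->GC",
      "GC-changing"))
}

fmt_pi <- function(x) sprintf("%.5f", x)
fmt_pct <- function(x) sprintf("%.2f", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
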