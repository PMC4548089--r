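# Pairwise / three-way alignment ingestion, internal global aligner, and
# column <-> genome coordinate maps.

#' Construct a validated alignment object
#'
#' @param rows named character vector of equal-length gapped sequences over
#'   A/C/G/T/N/-; all-gap columns are removed (count reported via message).
#' @param reference_index which row plays the reference role (default 1).
#' @return object of class `pairwise_alignment` (also used for 3-row
#'   alignments): list with `names`, `rows`, `mat` (character matrix,
#'   rows x columns), `reference_index`, `ncol`.
#' @export
pairwise_alignment <- function(rows, reference_index = 1L) {
  if (length(rows) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L) {
    stop(sprintf("ragged alignment: row lengths %s",
                 paste(nchar(rows), collapse = ", ")), call. = FALSE)
  }
  nms <- names(rows) %||% paste0("seq", seq_along(rows))
  mat <- do.call(rbind, lapply(toupper(rows), function(r) {
    strsplit(r, "", fixed = TRUE)[[1L]]
  }))
  bad <- setdiff(unique(as.vector(mat)), c(IUPAC_CHARS, "-"))
  if (length(bad)) {
    stop("non-IUPAC symbol(s) in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  allgap <- colSums(mat == "-") == nrow(mat)
  if (any(allgap)) {
    message(sprintf("removed %d all-gap column(s)", sum(allgap)))
    mat <- mat[, !allgap, drop = FALSE]
  }
  rownames(mat) <- nms
  structure(list(names = nms,
                 rows = apply(mat, 1L, paste0, collapse = ""),
                 mat = mat,
                 reference_index = as.integer(reference_index),
                 ncol = ncol(mat)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns (reference: %s)\n",
              nrow(x$mat), x$ncol, x$names[x$reference_index]))
  invisible(x)
}

#' Ungapped sequence of one alignment row
#' @param aln alignment.
#' @param i row index.
#' @return nucleotide string without gaps.
#' @export
ungap <- function(aln, i) gsub("-", "", aln$rows[[i]], fixed = TRUE)

#' Read an alignment from aligned FASTA or Clustal
#'
#' @param path input file.
#' @param format "fasta" or "clustal".
#' @param reference_index reference row (default 1).
#' @return [pairwise_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference_index = 1L) {
  format <- match.arg(format)
  rows <- if (format == "fasta") {
    ss <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("alignment FASTA parse error: ",
                                            conditionMessage(e), call. = FALSE))
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    read_clustal(path)
  }
  if (length(rows) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  pairwise_alignment(rows, reference_index)
}

# Clustal format: header line, then blocks of "name  SEQ" lines with an
# optional conservation line (leading whitespace) per block.
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("CLUSTAL|MUSCLE", lines[1L], ignore.case = TRUE)) {
    stop("not a Clustal file (missing header)", call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[!grepl("^\\s*$", body)]
  body <- body[grepl("^\\S", body)]  # drop conservation lines
  parts <- list()
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 2L) next
    nm <- toks[1L]
    parts[[nm]] <- paste0(parts[[nm]] %||% "", toks[2L])
  }
  unlist(parts)
}

#' Write an alignment as aligned FASTA
#' @param aln alignment.
#' @param path output file.
#' @export
write_aligned_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(unname(aln$rows), aln$names))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Globally align two sequences
#'
#' Affine-gap Needleman-Wunsch with deterministic tie-breaking (substitution
#' preferred over gap, gap in `b` over gap in `a`). A gap of length k scores
#' `gap_open + (k-1) * gap_extend`. For long, closely related sequences a
#' diagonal band keeps time and memory linear in sequence length; the default
#' band is exhaustive below 2 kb and `2|n-m| + 400` columns above, wide
#' enough for the indel load of congeneric plastomes.
#'
#' @param a,b nucleotide strings (a is the reference row).
#' @param scoring list with match, mismatch, gap_open, gap_extend
#'   (defaults 1, -2, -5, -2).
#' @param names labels for the two rows.
#' @param band band half-width in columns, or NULL for the default.
#' @return [pairwise_alignment()] with attribute `score`.
#' @export
align_pair <- function(a, b, scoring = NULL, names = c("a", "b"), band = NULL) {
  a <- validate_nucleotides(a, "sequence a")
  b <- validate_nucleotides(b, "sequence b")
  sc <- modifyList(list(match = 1, mismatch = -2, gap_open = -5,
                        gap_extend = -2), scoring %||% list())
  n <- nchar(a); m <- nchar(b)
  if (is.null(band)) {
    band <- if (max(n, m) <= 2000L) max(n, m) else 2L * abs(n - m) + 400L
  }
  res <- .nw_affine(a, b, sc$match, sc$mismatch, sc$gap_open, sc$gap_extend,
                    as.integer(band))
  aln <- pairwise_alignment(setNames(c(res$a, res$b), names),
                            reference_index = 1L)
  attr(aln, "score") <- res$score
  aln
}

#' Column/position coordinate maps for every alignment row
#'
#' @param aln alignment.
#' @return list of class `alignment_map`: per row, `col2pos` (0-based
#'   sequence position per column, NA at gaps) and `pos2col` (0-based column
#'   per sequence position); maps are mutually inverse on non-gap columns.
#' @export
build_map <- function(aln) {
  maps <- lapply(seq_len(nrow(aln$mat)), function(i) {
    nongap <- aln$mat[i, ] != "-"
    col2pos <- rep(NA_integer_, aln$ncol)
    col2pos[nongap] <- seq_len(sum(nongap)) - 1L
    pos2col <- which(nongap) - 1L
    list(col2pos = col2pos, pos2col = pos2col)
  })
  names(maps) <- aln$names
  structure(maps, class = "alignment_map")
}

#' Merge a third sequence into a pairwise alignment via the reference row
#'
#' Aligns `c_seq` to the ungapped reference of `aln` and threads the two gap
#' patterns together (reference-anchored merge). Columns where both the
#' existing alignment and the new pairwise alignment gap the reference are
#' interleaved deterministically (existing columns first).
#'
#' @param aln 2-row alignment whose reference row anchors the merge.
#' @param c_seq third sequence.
#' @param name label for the new row.
#' @param scoring,band passed to [align_pair()].
#' @return 3-row [pairwise_alignment()].
#' @export
merge_third_row <- function(aln, c_seq, name = "c", scoring = NULL, band = NULL) {
  ri <- aln$reference_index
  refseq <- ungap(aln, ri)
  ac <- align_pair(refseq, c_seq, scoring = scoring, band = band,
                   names = c("ref", name))
  # walk both alignments over reference positions
  m1 <- aln$mat; m2 <- ac$mat
  i1 <- 1L; i2 <- 1L
  out <- vector("list", 0L)
  oth <- setdiff(seq_len(nrow(m1)), ri)
  n1 <- ncol(m1); n2 <- ncol(m2)
  while (i1 <= n1 || i2 <= n2) {
    g1 <- i1 <= n1 && m1[ri, i1] == "-"
    g2 <- i2 <= n2 && m2[1L, i2] == "-"
    if (g1) {
      out[[length(out) + 1L]] <- c(m1[ri, i1], m1[oth, i1], "-")
      i1 <- i1 + 1L
    } else if (g2) {
      out[[length(out) + 1L]] <- c("-", rep("-", length(oth)), m2[2L, i2])
      i2 <- i2 + 1L
    } else {
      stopifnot(i1 <= n1, i2 <= n2, m1[ri, i1] == m2[1L, i2])
      out[[length(out) + 1L]] <- c(m1[ri, i1], m1[oth, i1], m2[2L, i2])
      i1 <- i1 + 1L; i2 <- i2 + 1L
    }
  }
  mat <- do.call(cbind, out)
  rows <- apply(mat, 1L, paste0, collapse = "")
  names(rows) <- c(aln$names[ri], aln$names[oth], name)
  pairwise_alignment(rows, reference_index = 1L)
}
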