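# Microsatellite (SSR) detection: maximal mono- and di-nucleotide tandem
# repeats at configurable unit-count thresholds.

#' Find microsatellites in a genome
#'
#' Scans one strand for maximal exact tandem repeats of 1-bp and 2-bp motifs.
#' A mononucleotide run is reported at `mono_min` units or more, a
#' dinucleotide repeat at `di_min` units or more; a dinucleotide motif that is
#' itself a homopolymer ("AA") is counted as a mononucleotide run. Di spans
#' are trimmed to whole units (left-anchored), so span length is always
#' motif length x unit count and neither one-unit extension keeps the repeat
#' exact. Where a qualifying mono run and a qualifying di repeat overlap, the
#' longer span wins (ties go to the mono run).
#'
#' @param genome [annotated_genome()] or plain nucleotide string.
#' @param mono_min minimum units for 1-bp motifs (>= 2).
#' @param di_min minimum units for 2-bp motifs (>= 2).
#' @param with_context add region/compartment/label columns via [locate()]
#'   (requires an annotated genome).
#' @return data.frame: motif, units, start, end (0-based half-open), length,
#'   and optionally region, compartment, label; sorted by start.
#' @export
find_ssrs <- function(genome, mono_min = 8L, di_min = 4L, with_context = FALSE) {
  stopifnot(mono_min >= 2L, di_min >= 2L)
  seq <- if (inherits(genome, "annotated_genome")) genome$seq else
    validate_nucleotides(genome, "sequence")
  v <- seq_chars(seq)
  n <- length(v)
  empty <- data.frame(motif = character(), units = integer(), start = integer(),
                      end = integer(), length = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  # mono runs via rle
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based
  keep <- r$lengths >= mono_min & r$values %in% c("A", "C", "G", "T")
  mono <- data.frame(motif = r$values[keep],
                     units = r$lengths[keep],
                     start = starts[keep],
                     end = ends[keep],
                     stringsAsFactors = FALSE)

  # di repeats: maximal stretches with period 2 (v[i] == v[i+2]), motif not a
  # homopolymer, trimmed to whole units
  di <- empty[, c("motif", "units", "start", "end")]
  if (n >= 4L) {
    p2 <- c(v[seq_len(n - 2L)] == v[seq_len(n - 2L) + 2L] &
              v[seq_len(n - 2L)] != "N", FALSE, FALSE)
    rr <- rle(p2)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths
    hit <- which(rr$values)
    rows <- list()
    for (h in hit) {
      span <- rr$lengths[h] + 2L          # bases in the period-2 stretch
      s0 <- rs[h]                         # 0-based start
      units <- span %/% 2L
      if (units < di_min) next
      motif <- paste0(v[s0 + 1L], v[s0 + 2L])
      if (substr(motif, 1L, 1L) == substr(motif, 2L, 2L)) next  # homopolymer
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, units = units, start = s0, end = s0 + 2L * units,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) di <- do.call(rbind, rows)
  }

  out <- rbind(mono, di)
  if (nrow(out) == 0L) return(empty)
  out$length <- out$end - out$start
  # overlap resolution: longer span wins, ties to mono (motif length 1)
  out <- out[order(-out$length, nchar(out$motif), out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- (i + 1L):nrow(out)
      ov <- out$start[later] < out$end[i] & out$end[later] > out$start[i]
      keep[later][ov] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL

  if (with_context) {
    if (!inherits(genome, "annotated_genome")) {
      stop("with_context requires an annotated genome", call. = FALSE)
    }
    ctx <- lapply(out$start, function(p) locate(genome, p))
    out$region <- vapply(ctx, function(x) x$region %||% NA_character_, "")
    out$compartment <- vapply(ctx, `[[`, "", "compartment")
    out$label <- vapply(ctx, function(x) x$label %||% NA_character_, "")
  }
  out
}

#' Write an SSR table as TSV (1-based inclusive coordinates)
#' @param ssrs data.frame from [find_ssrs()].
#' @param genome_id label written in the first column.
#' @param path output file.
#' @export
write_ssr_tsv <- function(ssrs, genome_id, path) {
  out <- data.frame(genome = rep(genome_id, nrow(ssrs)),
                    motif = ssrs$motif, units = ssrs$units,
                    start = ssrs$start + 1L, end = ssrs$end,
                    region = ssrs$region %||% NA,
                    compartment = ssrs$compartment %||% NA,
                    label = ssrs$label %||% NA)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
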