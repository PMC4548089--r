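# Sliding-window nucleotide diversity (Pi) over alignment columns and
# divergence-hotspot calling.

# per-pair column vectors: valid (both non-gap, non-N) and diff
pair_site_vectors <- function(aln) {
  nr <- nrow(aln$mat)
  pairs <- utils::combn(nr, 2L)
  lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    a <- aln$mat[i, ]; b <- aln$mat[j, ]
    valid <- a != "-" & b != "-" & a != "N" & b != "N"
    list(valid = valid, diff = valid & a != b)
  })
}

#' Sliding-window nucleotide diversity
#'
#' Windows slide over alignment columns. Within a window, Pi is the average
#' over all row pairs of (differing sites / valid sites), a valid site being
#' a column where both rows of the pair carry an unambiguous base. Pairs with
#' zero valid sites in a window contribute 0; a window with no valid site in
#' any pair gets pi = 0 and `no_valid = TRUE`. A trailing partial window
#' shorter than `window_len` is dropped.
#'
#' @param aln alignment (2 or more rows).
#' @param window_len window length in alignment columns (default 600).
#' @param step step size in columns (default 200).
#' @param map optional [build_map()] used to report reference-coordinate
#'   midpoints.
#' @return data.frame of class `diversity_profile`: start_col, end_col
#'   (0-based half-open), mid_col, mid_ref (reference coordinate of the
#'   midpoint, NA at reference gaps), valid_sites (summed over pairs),
#'   pi, no_valid.
#' @export
window_pi <- function(aln, window_len = 600L, step = 200L, map = NULL) {
  if (window_len < 1L || step < 1L) {
    stop("window_len and step must be >= 1", call. = FALSE)
  }
  nc <- aln$ncol
  if (nc < window_len) {
    stop("alignment shorter than one window", call. = FALSE)
  }
  pv <- pair_site_vectors(aln)
  starts <- seq.int(0L, nc - window_len, by = step)
  cs <- lapply(pv, function(p) {
    list(valid = c(0, cumsum(p$valid)), diff = c(0, cumsum(p$diff)))
  })
  pi <- numeric(length(starts)); vs <- numeric(length(starts))
  novalid <- logical(length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]; e <- s + window_len
    num <- 0; npairs_valid <- 0L; tot_valid <- 0
    for (p in cs) {
      v <- p$valid[e + 1L] - p$valid[s + 1L]
      d <- p$diff[e + 1L] - p$diff[s + 1L]
      tot_valid <- tot_valid + v
      if (v > 0) {
        num <- num + d / v
        npairs_valid <- npairs_valid + 1L
      }
    }
    pi[w] <- if (npairs_valid > 0L) num / length(cs) else 0
    vs[w] <- tot_valid
    novalid[w] <- npairs_valid == 0L
  }
  mid <- starts + window_len %/% 2L
  mid_ref <- rep(NA_integer_, length(starts))
  if (!is.null(map)) {
    ri <- aln$reference_index
    mid_ref <- map[[ri]]$col2pos[mid + 1L]
  }
  out <- data.frame(start_col = starts, end_col = starts + window_len,
                    mid_col = mid, mid_ref = mid_ref, valid_sites = vs,
                    pi = pi, no_valid = novalid)
  class(out) <- c("diversity_profile", "data.frame")
  attr(out, "window_len") <- window_len
  attr(out, "step") <- step
  attr(out, "n_rows") <- nrow(aln$mat)
  out
}

#' Overall (per-site) nucleotide diversity of an alignment
#'
#' The per-site alternative to the per-window mean: average over row pairs of
#' total differing sites / total valid sites.
#'
#' @param aln alignment.
#' @return single numeric.
#' @export
pi_overall <- function(aln) {
  pv <- pair_site_vectors(aln)
  mean(vapply(pv, function(p) {
    v <- sum(p$valid)
    if (v == 0) 0 else sum(p$diff) / v
  }, numeric(1)))
}

#' Call divergence hotspots from a diversity profile
#'
#' Runs of consecutive windows with pi strictly above `threshold` are merged
#' into one hotspot each and labelled with the loci (genes, introns, spacers)
#' the merged span overlaps on the reference annotation.
#'
#' @param profile [window_pi()] output.
#' @param threshold Pi cutoff (0.008 is a typical within-genus setting,
#'   0.015 between genera).
#' @param ref_genome optional annotated genome for labels.
#' @param map optional alignment map (required with `ref_genome` to convert
#'   columns to reference coordinates).
#' @param reference_index row mapped to reference coordinates (default 1).
#' @return data.frame: start_col, end_col (merged, 0-based half-open),
#'   n_windows, max_pi, start_ref, end_ref, labels (";"-joined locus names).
#' @export
call_hotspots <- function(profile, threshold, ref_genome = NULL, map = NULL,
                          reference_index = 1L) {
  stopifnot(threshold > 0)
  hot <- profile$pi > threshold
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      n_windows = integer(), max_pi = numeric(),
                      start_ref = integer(), end_ref = integer(),
                      labels = character(), stringsAsFactors = FALSE)
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    sc <- profile$start_col[idx[1L]]
    ec <- profile$end_col[idx[length(idx)]]
    sr <- er <- NA_integer_
    labels <- NA_character_
    if (!is.null(map)) {
      c2p <- map[[reference_index]]$col2pos
      span <- c2p[(sc + 1L):ec]
      span <- span[!is.na(span)]
      if (length(span)) { sr <- min(span); er <- max(span) + 1L }
    }
    if (!is.null(ref_genome) && !is.na(sr)) {
      labels <- paste(unique(vapply(
        seq.int(sr, er - 1L, by = max(1L, (er - sr) %/% 50L)),
        function(p) {
          ctx <- locate(ref_genome, p)
          if (ctx$compartment == "intergenic") ctx$label %||% "NA"
          else ctx$label
        }, "")), collapse = ";")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start_col = sc, end_col = ec, n_windows = length(idx),
      max_pi = max(profile$pi[idx]), start_ref = sr, end_ref = er,
      labels = labels, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a diversity profile as TSV (Pi at 5 decimals)
#' @param profile [window_pi()] output.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- data.frame(mid_col = profile$mid_col + 1L,
                    mid_ref = ifelse(is.na(profile$mid_ref), NA,
                                     profile$mid_ref + 1L),
                    valid_sites = profile$valid_sites,
                    pi = fmt_pi(profile$pi))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hotspots as BED (reference coordinates, 0-based half-open)
#' @param hotspots [call_hotspots()] output.
#' @param genome_id chrom name.
#' @param path output file.
#' @export
write_hotspot_bed <- function(hotspots, genome_id, path) {
  df <- data.frame(chrom = rep(genome_id, nrow(hotspots)),
                   start = hotspots$start_ref, end = hotspots$end_ref,
                   name = hotspots$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
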