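# Mutation-event calling between aligned genomes: micro-inversions first,
# then indels (maximal gap runs, SSR vs non-SSR), then per-column SNPs
# (Ts/Tv, base-pair class), with locus context and region/compartment
# summaries. The first alignment row is the reference: a gap in the
# reference row is an insertion (sequence present in the other genome), a
# gap in the other row a deletion.

match_states <- function(aln) {
  ri <- aln$reference_index
  oi <- setdiff(seq_len(nrow(aln$mat)), ri)[1L]
  a <- aln$mat[ri, ]; b <- aln$mat[oi, ]
  gap <- a == "-" | b == "-"
  anyN <- a == "N" | b == "N"
  mism <- !gap & !anyN & a != b
  list(ri = ri, oi = oi, a = a, b = b, gap = gap, anyN = anyN, mism = mism)
}

#' Detect micro-inversions in a pairwise alignment
#'
#' Scans maximal runs of mismatching, gap-free columns. A run is reported as
#' an inversion when the non-reference segment equals the reverse complement
#' of the reference segment, contains at least `min_mismatches` mismatching
#' columns, and spans at most `max_inv_len` columns. A run that is not itself
#' a reverse-complement pair is grown symmetrically into its flanking match
#' columns (smallest window first) in case the inverted segment has
#' palindromically matching columns inside. Consumed columns are returned so
#' SNP and indel calling can skip them; a single mismatching column is never
#' an inversion (it is a SNP).
#'
#' @param aln pairwise alignment (row 1 = reference unless set otherwise).
#' @param min_inv_len minimum segment length in bp.
#' @param max_inv_len maximum segment length in bp.
#' @param min_mismatches minimum mismatching columns inside the segment.
#' @return list with `events` (data.frame: start_col, end_col 0-based
#'   half-open, length, ref_segment, alt_segment) and `consumed` (logical
#'   per column).
#' @export
detect_inversions <- function(aln, min_inv_len = 3L, max_inv_len = 50L,
                              min_mismatches = 2L) {
  st <- match_states(aln)
  nc <- aln$ncol
  consumed <- rep(FALSE, nc)
  events <- list()
  # prefix sums over columns: mismatches and disallowed (gap or N) columns
  cmis <- c(0L, cumsum(st$mism))
  cbad <- c(0L, cumsum(st$gap | st$anyN))
  in_win <- function(v, ws, we) v[we + 1L] - v[ws]
  r <- rle(st$mism)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  for (k in runs) {
    s <- starts[k]; e <- ends[k]          # 1-based inclusive columns
    if (any(consumed[s:e])) next
    nmis <- e - s + 1L
    found <- NULL
    # grow the window outwards over gap-free columns, smallest span first;
    # internal match columns are allowed (palindromic positions of an
    # inverted segment can coincide), the window just needs enough
    # mismatches in total
    max_ext <- max_inv_len - nmis
    for (ext in 0:max(0L, max_ext)) {
      for (aa in 0:ext) {
        bb <- ext - aa
        ws <- s - aa; we <- e + bb
        if (ws < 1L || we > nc) next
        L <- we - ws + 1L
        if (L < min_inv_len || L > max_inv_len) next
        if (in_win(cbad, ws, we) > 0L) next
        if (in_win(cmis, ws, we) < min_mismatches) next
        refseg_c <- st$a[ws:we]
        if (!all(st$b[ws:we] == revcomp_chars(refseg_c))) next
        refseg <- chars_seq(refseg_c)
        altseg <- chars_seq(st$b[ws:we])
        if (refseg == altseg) next
        found <- list(ws = ws, we = we, refseg = refseg, altseg = altseg)
        break
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      consumed[found$ws:found$we] <- TRUE
      events[[length(events) + 1L]] <- data.frame(
        start_col = found$ws - 1L, end_col = found$we,
        length = found$we - found$ws + 1L,
        ref_segment = found$refseg, alt_segment = found$altseg,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(start_col = integer(), end_col = integer(), length = integer(),
               ref_segment = character(), alt_segment = character(),
               stringsAsFactors = FALSE)
  list(events = ev, consumed = consumed)
}

#' Call SNPs from a pairwise alignment
#'
#' One SNP per column where both rows carry unequal, non-gap, non-N bases and
#' the column is not consumed by a detected inversion. Each SNP is classified
#' as transition/transversion, into the three GC classes (AT<->TA, CG<->GC,
#' GC-changing) and the six non-strand-specific base-pair classes, and
#' localized on the reference genome when one is supplied.
#'
#' @param aln pairwise alignment.
#' @param map [build_map()] of `aln` (built internally if NULL).
#' @param ref_genome optional [annotated_genome()] for locus context.
#' @param consumed logical per column from [detect_inversions()] (optional).
#' @return data.frame: column (0-based), ref_pos, alt_pos (0-based), ref_base,
#'   alt_base, kind (Ts/Tv), pair_class, gc_class, region, compartment, label.
#' @export
call_snps <- function(aln, map = NULL, ref_genome = NULL, consumed = NULL) {
  st <- match_states(aln)
  map <- map %||% build_map(aln)
  consumed <- consumed %||% rep(FALSE, aln$ncol)
  cols <- which(st$mism & !consumed)
  ref <- st$a[cols]; alt <- st$b[cols]
  ref_pos <- map[[st$ri]]$col2pos[cols]
  alt_pos <- map[[st$oi]]$col2pos[cols]
  out <- data.frame(column = cols - 1L, ref_pos = ref_pos, alt_pos = alt_pos,
                    ref_base = ref, alt_base = alt,
                    kind = ifelse(is_transition(ref, alt), "Ts", "Tv"),
                    pair_class = snp_pair_class(ref, alt),
                    gc_class = gc_class_of(ref, alt),
                    stringsAsFactors = FALSE)
  add_context(out, ref_genome, out$ref_pos)
}

add_context <- function(df, ref_genome, positions) {
  if (is.null(ref_genome) || nrow(df) == 0L) {
    df$region <- rep(NA_character_, nrow(df))
    df$compartment <- rep(NA_character_, nrow(df))
    df$label <- rep(NA_character_, nrow(df))
    return(df)
  }
  ctx <- lapply(positions, function(p) locate(ref_genome, p))
  df$region <- vapply(ctx, function(x) x$region %||% NA_character_, "")
  df$compartment <- vapply(ctx, `[[`, "", "compartment")
  df$label <- vapply(ctx, function(x) x$label %||% NA_character_, "")
  df
}

#' Call indels from a pairwise alignment
#'
#' Each maximal gap run in either row is one event. A gap in the reference
#' row is an insertion (the other genome carries the bases); a gap in the
#' other row is a deletion. An event is an SSR (slippage) indel when its
#' motif is a whole number of units of a microsatellite locus that overlaps
#' or abuts the event site in either genome and the longer allele meets the
#' SSR threshold; otherwise it is non-SSR. Indel positions are left-
#' normalized (shifted left while the preceding reference base equals the
#' last base of the motif) so homopolymer gaps report a canonical position.
#'
#' @param aln pairwise alignment.
#' @param map [build_map()] of `aln` (built internally if NULL).
#' @param ssr_ref,ssr_alt SSR tables of the two ungapped genomes
#'   ([find_ssrs()]); computed from the alignment rows if NULL.
#' @param ref_genome optional annotated genome for locus context.
#' @param consumed logical per column from [detect_inversions()] (optional).
#' @param mono_min,di_min SSR thresholds used for the slippage rule.
#' @return data.frame: start_col (0-based), polarity (insertion/deletion),
#'   motif, size, ref_flank_pos (0-based reference position of the base
#'   left of the event after normalization), ssr_type (SSR/non-SSR),
#'   ssr_motif, region, compartment, label.
#' @export
call_indels <- function(aln, map = NULL, ssr_ref = NULL, ssr_alt = NULL,
                        ref_genome = NULL, consumed = NULL,
                        mono_min = 8L, di_min = 4L) {
  st <- match_states(aln)
  map <- map %||% build_map(aln)
  consumed <- consumed %||% rep(FALSE, aln$ncol)
  refseq <- seq_chars(ungap(aln, st$ri))
  altseq <- seq_chars(ungap(aln, st$oi))
  if (is.null(ssr_ref)) ssr_ref <- find_ssrs(chars_seq(refseq), mono_min, di_min)
  if (is.null(ssr_alt)) ssr_alt <- find_ssrs(chars_seq(altseq), mono_min, di_min)

  events <- list()
  for (side in c("ref", "alt")) {
    row <- if (side == "ref") st$a else st$b
    other <- if (side == "ref") st$b else st$a
    gap <- row == "-" & !consumed
    r <- rle(gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      motif <- chars_seq(other[s:e])
      if (grepl("N", motif, fixed = TRUE)) next
      size <- e - s + 1L
      polarity <- if (side == "ref") "insertion" else "deletion"
      # positions of the base to the left of the gap in each genome
      ref_left <- last_nongap_pos(map[[st$ri]]$col2pos, s - 1L)
      alt_left <- last_nongap_pos(map[[st$oi]]$col2pos, s - 1L)
      # left-normalize against the sequence that carries the extra bases
      carrier <- if (side == "ref") altseq else refseq
      carrier_left <- if (side == "ref") alt_left else ref_left
      norm <- left_normalize(carrier, carrier_left, motif)
      shift <- carrier_left - norm$left
      motif <- norm$motif
      ref_left <- ref_left - shift
      alt_left <- alt_left - shift
      cls <- classify_ssr_indel(motif, size,
                                ref_left, refseq, ssr_ref,
                                alt_left, altseq, ssr_alt,
                                mono_min, di_min)
      events[[length(events) + 1L]] <- data.frame(
        start_col = s - 1L, polarity = polarity, motif = tolower(motif),
        size = size, ref_flank_pos = ref_left,
        ssr_type = cls$type, ssr_motif = cls$motif,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(start_col = integer(), polarity = character(),
               motif = character(), size = integer(), ref_flank_pos = integer(),
               ssr_type = character(), ssr_motif = character(),
               stringsAsFactors = FALSE)
  ev <- ev[order(ev$start_col), , drop = FALSE]
  rownames(ev) <- NULL
  # context at the first reference base at/right of the event
  ctx_pos <- pmin(pmax(ev$ref_flank_pos + 1L, 0L),
                  max(length(refseq) - 1L, 0L))
  add_context(ev, ref_genome, ctx_pos)
}

last_nongap_pos <- function(col2pos, col) {
  # 0-based position of the last non-gap base at column <= col; -1 if none
  if (col < 1L) return(-1L)
  p <- col2pos[seq_len(col)]
  p <- p[!is.na(p)]
  if (length(p) == 0L) -1L else p[length(p)]
}

left_normalize <- function(carrier, left, motif) {
  # carrier: char vector of the genome containing the indel bases; the indel
  # occupies positions (left+1-based indexing) ... shift left while the base
  # before the indel equals the last base of the motif (rotating the motif)
  m <- seq_chars(motif)
  while (left >= 0L && carrier[left + 1L] == m[length(m)]) {
    m <- c(m[length(m)], m[-length(m)])
    left <- left - 1L
  }
  list(left = left, motif = chars_seq(m))
}

classify_ssr_indel <- function(motif, size, ref_left, refseq, ssr_ref,
                               alt_left, altseq, ssr_alt, mono_min, di_min) {
  for (ml in c(1L, 2L)) {
    if (size %% ml != 0L) next
    units_changed <- size %/% ml
    # candidate motif from the indel itself
    m <- substr(motif, 1L, ml)
    if (ml == 2L && substr(m, 1L, 1L) == substr(m, 2L, 2L)) next
    if (!is_tandem_of(motif, m)) next
    thresh <- if (ml == 1L) mono_min else di_min
    # the locus must overlap/abut the event site in either genome
    for (g in list(list(tab = ssr_ref, left = ref_left),
                   list(tab = ssr_alt, left = alt_left))) {
      t <- g$tab
      if (nrow(t) == 0L) next
      hit <- nchar(t$motif) == ml &
        t$start <= g$left + 1L + size & t$end >= g$left + 1L
      hit <- hit & vapply(t$motif, function(x) same_cycle(x, m), TRUE)
      if (!any(hit)) next
      longer_units <- max(t$units[hit])
      # the longer allele: the locus in the carrier genome already includes
      # the extra units on one side; require it to meet the threshold
      if (max(longer_units, longer_units + units_changed) >= thresh) {
        return(list(type = "SSR", motif = t$motif[hit][which.max(t$units[hit])]))
      }
    }
  }
  list(type = "non-SSR", motif = NA_character_)
}

is_tandem_of <- function(s, unit) {
  k <- nchar(unit)
  n <- nchar(s)
  if (n %% k != 0L) return(FALSE)
  identical(s, strrep(unit, n %/% k))
}

same_cycle <- function(a, b) {
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

#' Call every mutation event between two aligned genomes
#'
#' Runs the detection cascade in the documented order (inversions, then
#' indels, then SNPs) so that a micro-inversion is not double-counted as a
#' stack of SNPs.
#'
#' @param aln pairwise alignment (row 1 = reference).
#' @param ref_genome optional annotated genome for locus context.
#' @param mono_min,di_min SSR thresholds for the slippage rule.
#' @param min_inv_len,max_inv_len,min_mismatches inversion parameters.
#' @return list with `snps`, `indels`, `inversions` data.frames and the
#'   alignment `map`.
#' @export
call_events <- function(aln, ref_genome = NULL, mono_min = 8L, di_min = 4L,
                        min_inv_len = 3L, max_inv_len = 50L,
                        min_mismatches = 2L) {
  map <- build_map(aln)
  inv <- detect_inversions(aln, min_inv_len, max_inv_len, min_mismatches)
  indels <- call_indels(aln, map, ref_genome = ref_genome,
                        consumed = inv$consumed,
                        mono_min = mono_min, di_min = di_min)
  snps <- call_snps(aln, map, ref_genome = ref_genome, consumed = inv$consumed)
  inversions <- inv$events
  if (nrow(inversions) > 0L) {
    st <- match_states(aln)
    pos <- vapply(inversions$start_col, function(c0) {
      p <- map[[st$ri]]$col2pos[c0 + 1L]
      if (is.na(p)) -1L else p
    }, integer(1))
    inversions$ref_pos <- pos
    inversions <- add_context(inversions, ref_genome, pos)
  } else {
    inversions$ref_pos <- integer(0)
    inversions <- add_context(inversions, ref_genome, integer(0))
  }
  list(snps = snps, indels = indels, inversions = inversions, map = map)
}

#' Summarize called events by type, compartment and plastome region
#'
#' IRa and IRb are pooled into a single "IR" class, matching single-IR
#' accounting of duplicated events. Percentages are reported at 2-decimal
#' precision and sum to 100 within rounding.
#'
#' @param events list from [call_events()].
#' @return list with `counts` (snp, indel, inversion, total, ts, tv,
#'   ssr_indel, nonssr_indel), `indel_by_compartment`,
#'   `snp_by_compartment`, `region_pct_all`, `region_pct_snp`,
#'   `region_pct_indel`.
#' @export
summarize_events <- function(events) {
  snps <- events$snps; indels <- events$indels; invs <- events$inversions
  counts <- list(
    snp = nrow(snps), indel = nrow(indels), inversion = nrow(invs),
    total = nrow(snps) + nrow(indels) + nrow(invs),
    ts = sum(snps$kind == "Ts"), tv = sum(snps$kind == "Tv"),
    ssr_indel = sum(indels$ssr_type == "SSR"),
    nonssr_indel = sum(indels$ssr_type == "non-SSR"))
  comp_tab <- function(x) {
    lv <- c("intergenic", "intron", "exon")
    tab <- table(factor(x$compartment, levels = lv))
    as.list(setNames(as.integer(tab), lv))
  }
  region_pct <- function(regions) {
    regions <- regions[!is.na(regions)]
    pooled <- ifelse(regions %in% c("IRa", "IRb"), "IR", regions)
    lv <- c("LSC", "IR", "SSC")
    tab <- table(factor(pooled, levels = lv))
    n <- sum(tab)
    if (n == 0L) {
      message("no localized events; region percentages reported as 0")
      return(as.list(setNames(rep(0, length(lv)), lv)))
    }
    as.list(setNames(round(100 * as.integer(tab) / n, 2), lv))
  }
  all_regions <- c(snps$region, indels$region, invs$region)
  list(counts = counts,
       indel_by_compartment = comp_tab(indels),
       snp_by_compartment = comp_tab(snps),
       region_pct_all = region_pct(all_regions),
       region_pct_snp = region_pct(snps$region),
       region_pct_indel = region_pct(indels$region))
}

# ---- writers -----------------------------------------------------------

#' Write SNPs as a minimal VCF 4.2
#' @param snps data.frame from [call_snps()].
#' @param ref_genome annotated reference genome (CHROM and POS refer to it).
#' @param path output file.
#' @export
write_snp_vcf <- function(snps, ref_genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", ref_genome$id,
                       ref_genome$length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tTSTV=%s", ref_genome$id,
                       snps$ref_pos + 1L, snps$ref_base, snps$alt_base,
                       snps$kind), con)
  }
  invisible(path)
}

#' Write indels and inversions as a Table-3-style TSV
#' @param indels,inversions data.frames from [call_events()].
#' @param path output file.
#' @export
write_indel_tsv <- function(indels, inversions, path) {
  a <- data.frame(location = indels$label, region = indels$region,
                  compartment = indels$compartment, motif = indels$motif,
                  size = indels$size, direction = indels$polarity,
                  class = indels$ssr_type)
  b <- if (nrow(inversions) > 0L) {
    data.frame(location = inversions$label, region = inversions$region,
               compartment = inversions$compartment,
               motif = tolower(inversions$ref_segment),
               size = inversions$length, direction = "inversion",
               class = "inversion")
  } else NULL
  write.table(rbind(a, b), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
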