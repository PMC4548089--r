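# Genome input/output, quadripartite structure, locus context.

#' Construct an annotated genome object
#'
#' The container used throughout the pipeline: a nucleotide sequence plus a
#' feature table and (optionally) the quadripartite partition. Coordinates in
#' the feature table are 0-based half-open; the exported table writers convert
#' to 1-based inclusive.
#'
#' @param id accession or label.
#' @param seq nucleotide string over A/C/G/T/N.
#' @param features data.frame with columns `name`, `type`
#'   (gene/exon/intron), `biotype` (protein/tRNA/rRNA), `strand` (+/-),
#'   `start`, `end` (0-based half-open), or NULL for a feature-less genome.
#' @param circular logical; plastomes are circular molecules kept in their
#'   deposited linear order.
#' @param partition optional partition as returned by [detect_partition()].
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, seq, features = NULL, circular = TRUE,
                             partition = NULL) {
  seq <- validate_nucleotides(seq, sprintf("genome '%s'", id))
  if (is.null(features)) {
    features <- data.frame(name = character(), type = character(),
                           biotype = character(), strand = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  }
  n <- nchar(seq)
  if (nrow(features) > 0L) {
    if (any(features$start < 0L | features$end > n | features$start >= features$end)) {
      stop("feature coordinates outside [0, genome length) or empty interval",
           call. = FALSE)
    }
  }
  structure(list(id = id, seq = seq, length = n, circular = circular,
                 features = features, partition = partition),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d feature rows%s\n", x$id,
              format(x$length, big.mark = ","), nrow(x$features),
              if (!is.null(x$partition)) ", partitioned" else ""))
  invisible(x)
}

# ---- readers -----------------------------------------------------------

#' Read a genome from GenBank or FASTA
#'
#' GenBank flat files supply both sequence and annotation (gene, CDS, tRNA,
#' rRNA features; `join()` and `complement()` location syntax). A FASTA file
#' yields a feature-less genome unless an annotation table is supplied
#' (TSV with columns gene, kind, strand, start, end; 1-based inclusive).
#' Introns are synthesized as the gaps between consecutive exons of the same
#' gene.
#'
#' @param path input file.
#' @param format "genbank" or "fasta".
#' @param annotation_table optional TSV path used with FASTA input.
#' @param id label override; default is taken from the file.
#' @return [annotated_genome()].
#' @export
read_genome <- function(path, format = c("genbank", "fasta"),
                        annotation_table = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "genbank") {
    gb <- parse_genbank(path)
    feats <- features_from_records(gb$records, gb$length)
    annotated_genome(id %||% gb$id, gb$seq, feats)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) < 1L) stop("FASTA file contains no sequence", call. = FALSE)
    seq <- as.character(ss[[1L]])
    lab <- id %||% sub("\\s.*$", "", names(ss)[1L])
    feats <- NULL
    if (!is.null(annotation_table)) {
      tab <- read.table(annotation_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      need <- c("gene", "kind", "strand", "start", "end")
      if (!all(need %in% names(tab))) {
        stop("annotation table must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
      }
      recs <- lapply(split(tab, tab$gene), function(g) {
        list(name = g$gene[1L],
             kind = g$kind[1L],
             strand = g$strand[1L],
             intervals = cbind(g$start - 1L, g$end))  # to 0-based half-open
      })
      feats <- features_from_records(unname(recs), nchar(seq))
    }
    annotated_genome(lab, seq, feats)
  }
}

# Minimal GenBank flat-file parser: LOCUS, FEATURES (gene/CDS/tRNA/rRNA with
# join/complement locations and /gene qualifiers), ORIGIN sequence block.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines)
  if (length(loc) == 0L) stop("malformed GenBank file (no LOCUS line): line 1",
                              call. = FALSE)
  toks <- strsplit(trimws(lines[loc[1L]]), "\\s+")[[1L]]
  id <- toks[2L]
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) {
    stop(sprintf("malformed GenBank file (no ORIGIN): line %d", length(lines)),
         call. = FALSE)
  }
  # sequence
  sl <- lines[(ostart[1L] + 1L):length(lines)]
  sl <- sl[!grepl("^//", sl)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(sl, collapse = "")))

  records <- list()
  if (length(fstart) > 0L) {
    fl <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    # unfold: a new feature starts at column 6 with a key; qualifiers at col 22
    keyline <- grepl("^ {5}\\S", fl)
    idx <- cumsum(keyline)
    for (k in seq_len(max(idx, 0))) {
      block <- fl[idx == k]
      key <- strsplit(trimws(block[1L]), "\\s+")[[1L]][1L]
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      # location string may wrap before qualifiers begin
      qual_at <- grep("^\\s+/", block)
      locend <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
      locstr <- paste0(trimws(sub("^\\s*\\S+\\s*", "", block[1L])),
                       paste0(trimws(block[seq_len(locend)[-1L]]), collapse = ""))
      gene <- NA_character_
      gq <- grep("/gene=", block, value = TRUE)
      if (length(gq)) gene <- gsub('.*?/gene="?([^"]+)"?.*', "\\1", gq[1L])
      parsedloc <- parse_gb_location(locstr)
      records[[length(records) + 1L]] <-
        list(name = gene, kind = key, strand = parsedloc$strand,
             intervals = parsedloc$intervals)
    }
  }
  list(id = id, seq = seq, length = nchar(seq), records = records)
}

parse_gb_location <- function(s) {
  strand <- "+"
  s <- gsub("\\s", "", s)
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) s <- sub("^join\\((.*)\\)$", "\\1", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    c(ab[1L] - 1L, ab[2L])  # 1-based inclusive -> 0-based half-open
  }, numeric(2)))
  dimnames(iv) <- NULL
  list(strand = strand, intervals = iv)
}

# Build the feature data.frame (gene/exon/intron rows) from parsed records.
# CDS/tRNA/rRNA records carry the exon structure; bare gene records of
# protein genes supply the span. Genes duplicated in the IR keep both copies
# as rows; gene_count() collapses duplicates by name.
features_from_records <- function(records, genome_len) {
  rows <- list()
  add <- function(name, type, biotype, strand, start, end) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, biotype = biotype, strand = strand,
      start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
  }
  kinds <- vapply(records, `[[`, "", "kind")
  names_ <- vapply(records, function(r) r$name %||% NA_character_, "")
  # prefer structured records (CDS/tRNA/rRNA); fall back to gene records for
  # genes lacking one (e.g. annotation-table input where kind == "gene")
  handled <- character()
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (r$kind == "gene") next
    nm <- r$name %||% sprintf("feat%03d", i)
    biotype <- switch(r$kind, CDS = "protein", tRNA = "tRNA", rRNA = "rRNA",
                      protein = "protein", "protein")
    iv <- r$intervals[order(r$intervals[, 1L]), , drop = FALSE]
    key <- sprintf("%s@%d", nm, iv[1L, 1L])
    if (key %in% handled) next
    handled <- c(handled, key)
    add(nm, "gene", biotype, r$strand, iv[1L, 1L], iv[nrow(iv), 2L])
    for (j in seq_len(nrow(iv))) add(nm, "exon", biotype, r$strand,
                                     iv[j, 1L], iv[j, 2L])
    if (nrow(iv) > 1L) {
      for (j in seq_len(nrow(iv) - 1L)) {
        add(nm, "intron", biotype, r$strand, iv[j, 2L], iv[j + 1L, 1L])
      }
    }
  }
  # bare gene records whose name got no structured record at all
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (r$kind != "gene") next
    nm <- r$name
    if (is.null(nm) || is.na(nm)) next
    if (nm %in% vapply(rows, function(x) x$name[1L], "")) next
    iv <- r$intervals[order(r$intervals[, 1L]), , drop = FALSE]
    add(nm, "gene", "protein", r$strand, iv[1L, 1L], iv[nrow(iv), 2L])
    for (j in seq_len(nrow(iv))) add(nm, "exon", "protein", r$strand,
                                     iv[j, 1L], iv[j, 2L])
    if (nrow(iv) > 1L) {
      for (j in seq_len(nrow(iv) - 1L)) {
        add(nm, "intron", "protein", r$strand, iv[j, 2L], iv[j + 1L, 1L])
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  if (any(out$end > genome_len)) {
    stop("feature outside sequence bounds", call. = FALSE)
  }
  out[order(out$start, out$name, out$type), , drop = FALSE]
}

#' Count distinct genes by biotype
#'
#' Genes duplicated in the inverted repeat count once.
#'
#' @param genome [annotated_genome()].
#' @return named integer vector (protein, tRNA, rRNA, total).
#' @export
gene_count <- function(genome) {
  g <- genome$features[genome$features$type == "gene", , drop = FALSE]
  g <- g[!duplicated(g$name), , drop = FALSE]
  n <- table(factor(g$biotype, levels = c("protein", "tRNA", "rRNA")))
  c(protein = unname(n["protein"]), tRNA = unname(n["tRNA"]),
    rRNA = unname(n["rRNA"]), total = nrow(g))
}

# ---- quadripartite structure -------------------------------------------

#' Detect the quadripartite plastome structure
#'
#' Finds the maximal pair of disjoint, exactly reverse-complementary segments
#' of at least `min_ir_len` bp. The longer arc between the two repeats is
#' labelled LSC, the shorter SSC. The genome must be in the standard deposited
#' orientation in which the second repeat copy ends at the sequence end
#' (LSC-IRb-SSC-IRa order or its SSC-first rotation); an origin-spanning
#' repeat raises the "no quadripartite structure" error with advice to rotate.
#'
#' @param genome [annotated_genome()].
#' @param min_ir_len minimum repeat length in bp.
#' @return list of class `plastome_partition` with elements `lsc`, `irb`,
#'   `ssc`, `ira`, each `c(start, end)` 0-based half-open, plus `ir_len`.
#' @export
detect_partition <- function(genome, min_ir_len = 1000L) {
  n <- genome$length
  if (n < 4L * min_ir_len) {
    stop("genome shorter than 4 * min_ir_len", call. = FALSE)
  }
  hit <- longest_inverted_pair(genome$seq, min_ir_len)
  if (is.null(hit)) {
    stop(sprintf("no quadripartite structure: no inverted repeat pair >= %d bp",
                 min_ir_len), call. = FALSE)
  }
  s1 <- hit$start1; e1 <- hit$start1 + hit$len
  s2 <- hit$start2; e2 <- hit$start2 + hit$len
  # In the standard deposited orientation one repeat copy reaches a sequence
  # end. A short residual outside the exactly matching pair (a repeat flank
  # broken by recent mutations) is absorbed into the adjacent repeat
  # interval so the four regions still tile the genome; for a pristine
  # genome the residuals are zero and the repeat intervals are exact.
  if (s1 > 0L && e2 < n) {
    if (min(s1, n - e2) >= hit$len) {
      stop(paste0("no quadripartite structure: inverted repeat pair does ",
                  "not flank the sequence ends; rotate the genome so one ",
                  "repeat copy ends at the sequence end"), call. = FALSE)
    }
    if (s1 <= n - e2) s1 <- 0L else e2 <- n
  }
  # arcs between the copies
  arc_mid <- c(e1, s2)              # between IR1 and IR2
  arc_out <- if (s1 == 0L) c(e2, n) else c(0L, s1)
  len_mid <- arc_mid[2L] - arc_mid[1L]
  len_out <- arc_out[2L] - arc_out[1L]
  if (len_out >= len_mid) {
    lsc <- arc_out; ssc <- arc_mid
    irb <- c(s1, e1); ira <- c(s2, e2)   # IRb follows the LSC in genome order
  } else {
    lsc <- arc_mid; ssc <- arc_out
    ira <- c(s1, e1); irb <- c(s2, e2)
  }
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 ir_len = hit$len, genome_length = n),
            class = "plastome_partition")
}

#' @export
print.plastome_partition <- function(x, ...) {
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("%-4s %9d..%9d  (%d bp)\n", toupper(r), x[[r]][1L] + 1L,
                x[[r]][2L], x[[r]][2L] - x[[r]][1L]))
  }
  invisible(x)
}

# Seed-and-extend search for the longest pair of disjoint segments S[a..] and
# S[b..] with S[b..b+L] == revcomp(S[a..a+L]). Seeds of length k are matched
# between the sequence and its reverse complement, collapsed per diagonal, and
# each diagonal's maximal run is measured exactly.
longest_inverted_pair <- function(seq, min_len, k = 24L) {
  v <- seq_chars(seq)
  n <- length(v)
  if (n < 2L * min_len) return(NULL)
  rc <- revcomp_chars(v)
  step <- max(1L, min_len - k)     # sampling stride still hits every run >= min_len
  pos_f <- seq.int(1L, n - k + 1L)
  pos_r <- seq.int(1L, n - k + 1L, by = step)
  # hash forward k-mers
  keys_f <- substring(chars_seq(v), pos_f, pos_f + k - 1L)
  env <- split(pos_f, keys_f)
  best <- NULL
  seen_diag <- character()
  rstr <- chars_seq(rc)
  for (j in pos_r) {
    km <- substr(rstr, j, j + k - 1L)
    hits <- env[[km]]
    if (is.null(hits)) next
    for (i in hits) {
      # rc position j corresponds to forward position (n - j - k + 2) of the
      # revcomp'd copy; extend the match in both directions
      ext <- extend_rc_match(v, rc, i, j, k, n)
      a1 <- ext$fstart; L <- ext$len
      b_rc <- ext$rstart
      # segment in original coordinates matched via rc: rc[b..b+L-1] maps to
      # forward interval [n - (b+L-1), n - b + 1] 1-based
      b1 <- n - (b_rc + L - 1L) + 1L
      if (L < min_len) next
      # require disjoint copies
      lo <- min(a1, b1); hi <- max(a1, b1)
      if (lo + L > hi) next
      key <- sprintf("%d:%d:%d", lo, hi, L)
      if (key %in% seen_diag) next
      seen_diag <- c(seen_diag, key)
      if (is.null(best) || L > best$len) {
        best <- list(start1 = lo - 1L, start2 = hi - 1L, len = L)
      }
    }
  }
  best
}

# extend an exact seed match between v (forward) and rc (revcomp copy)
extend_rc_match <- function(v, rc, i, j, k, n) {
  a <- i; b <- j
  while (a > 1L && b > 1L && v[a - 1L] == rc[b - 1L] && v[a - 1L] != "N") {
    a <- a - 1L; b <- b - 1L
  }
  ae <- i + k - 1L; be <- j + k - 1L
  while (ae < n && be < n && v[ae + 1L] == rc[be + 1L] && v[ae + 1L] != "N") {
    ae <- ae + 1L; be <- be + 1L
  }
  list(fstart = a, rstart = b, len = ae - a + 1L)
}

#' Project a partition onto another genome through an alignment
#'
#' Maps the region boundaries of a (reference) partition through the column
#' maps of a pairwise alignment onto a second genome. Used when the second
#' genome's own repeats are too mutation-fragmented for exact detection to
#' place the boundaries unambiguously: homology, not exact repetition, then
#' defines its regions.
#'
#' @param partition reference [detect_partition()] result.
#' @param map [build_map()] of the alignment containing both genomes.
#' @param from,to row indices of the reference and target genomes.
#' @param to_length target genome length.
#' @return `plastome_partition` for the target genome.
#' @export
project_partition <- function(partition, map, from, to, to_length) {
  c2p <- map[[to]]$col2pos
  proj <- function(pos) {
    if (pos >= length(map[[from]]$pos2col)) return(to_length)
    j <- map[[from]]$pos2col[pos + 1L] + 1L      # 1-based column
    while (j <= length(c2p) && is.na(c2p[j])) j <- j + 1L
    if (j > length(c2p)) to_length else c2p[j]
  }
  regs <- c("lsc", "irb", "ssc", "ira")
  starts <- vapply(regs, function(r) partition[[r]][1L], numeric(1))
  ord <- order(starts)
  new_starts <- c(0L, vapply(starts[ord][-1L], proj, numeric(1)))
  new_ends <- c(new_starts[-1L], to_length)
  out <- list()
  for (k in seq_along(ord)) {
    out[[regs[ord[k]]]] <- as.integer(c(new_starts[k], new_ends[k]))
  }
  out$ir_len <- out$irb[2L] - out$irb[1L]
  out$genome_length <- as.integer(to_length)
  structure(out[c(regs, "ir_len", "genome_length")],
            class = "plastome_partition")
}

#' Region of a position under a partition
#'
#' @param partition [detect_partition()] result.
#' @param position 0-based position.
#' @return one of "LSC", "IRb", "SSC", "IRa".
#' @export
region_of <- function(partition, position) {
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- partition[[r]]
    if (position >= iv[1L] && position < iv[2L]) {
      return(c(lsc = "LSC", irb = "IRb", ssc = "SSC", ira = "IRa")[[r]])
    }
  }
  stop("position outside genome", call. = FALSE)
}

#' GC content per plastome region
#'
#' @param genome partitioned [annotated_genome()].
#' @return named numeric vector: total, LSC, IR, SSC (fractions).
#' @export
region_gc <- function(genome) {
  p <- genome$partition
  if (is.null(p)) stop("genome has no partition", call. = FALSE)
  sub <- function(iv) substr(genome$seq, iv[1L] + 1L, iv[2L])
  c(total = gc_content(genome$seq),
    LSC = gc_content(sub(p$lsc)),
    IR = gc_content(paste0(sub(p$irb), sub(p$ira))),
    SSC = gc_content(sub(p$ssc)))
}

# ---- locus context -----------------------------------------------------

#' Resolve a genome position to its locus context
#'
#' @param genome annotated genome; partition used for the region label when
#'   present.
#' @param position 0-based genome position.
#' @return list with `region` (LSC/IRb/SSC/IRa or NA), `compartment`
#'   (exon/intron/intergenic) and `label` (gene, "gene(intron)", or
#'   "geneA-geneB" spacer using the flanking genes in genome order).
#' @export
locate <- function(genome, position) {
  if (position < 0L || position >= genome$length) {
    stop(sprintf("position %d out of range [0, %d)", position, genome$length),
         call. = FALSE)
  }
  region <- if (!is.null(genome$partition)) {
    region_of(genome$partition, position)
  } else NA_character_
  f <- genome$features
  if (nrow(f) == 0L) {
    return(list(region = region, compartment = "intergenic", label = NA_character_))
  }
  inside <- f$start <= position & position < f$end
  ex <- f[inside & f$type == "exon", , drop = FALSE]
  if (nrow(ex) > 0L) {
    return(list(region = region, compartment = "exon", label = ex$name[1L]))
  }
  gn <- f[inside & f$type == "gene", , drop = FALSE]
  if (nrow(gn) > 0L) {
    return(list(region = region, compartment = "intron",
                label = sprintf("%s(intron)", gn$name[1L])))
  }
  # intergenic: flanking gene-level rows in genome order (circular)
  g <- f[f$type == "gene", , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  before <- g[g$end <= position, , drop = FALSE]
  after <- g[g$start > position, , drop = FALSE]
  up <- if (nrow(before)) before$name[which.max(before$end)] else
    if (genome$circular && nrow(g)) g$name[nrow(g)] else NA_character_
  down <- if (nrow(after)) after$name[which.min(after$start)] else
    if (genome$circular && nrow(g)) g$name[1L] else NA_character_
  list(region = region, compartment = "intergenic",
       label = paste0(up, "-", down))
}

# ---- writers -----------------------------------------------------------

#' Write a partition as BED (0-based half-open)
#' @param partition partition object.
#' @param genome_id chrom name.
#' @param path output file.
#' @export
write_partition_bed <- function(partition, genome_id, path) {
  nm <- c(lsc = "LSC", irb = "IRb", ssc = "SSC", ira = "IRa")
  df <- do.call(rbind, lapply(names(nm), function(r) {
    data.frame(chrom = genome_id, start = partition[[r]][1L],
               end = partition[[r]][2L], name = nm[[r]])
  }))
  df <- df[order(df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA (with 70-column wrapping)
#' @param genome annotated genome.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write the annotation as a TSV table (1-based inclusive, gene-level rows
#' expanded to one row per exon)
#' @param genome annotated genome.
#' @param path output file.
#' @export
write_annotation_tsv <- function(genome, path) {
  f <- genome$features[genome$features$type == "exon", , drop = FALSE]
  out <- data.frame(gene = f$name, kind = f$biotype, strand = f$strand,
                    start = f$start + 1L, end = f$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
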