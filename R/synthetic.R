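# Synthetic plastome pairs with a known mutation ledger. The generator
# emulates the quadripartite layout at reduced scale (LSC 20 kb, IR 4 kb x2,
# SSC 5 kb by default), genes with introns on both strands, planted
# microsatellite tracts, and a divergence spectrum of SSR-slippage indels,
# non-SSR indels, substitutions with a controllable Ts fraction, and short
# micro-inversions. Events are spaced so that pairwise alignment recovers
# each one as its own atomic feature, which makes exact ledger recovery a
# fair test of the calling cascade.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

random_cds <- function(n_codons) {
  # start codon, non-stop internal codons, one stop
  all_codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sense <- setdiff(all_codons, STOPS)
  paste0("ATG", paste0(sample(sense, n_codons - 2L, replace = TRUE),
                       collapse = ""), "TAA")
}

#' Generate a synthetic annotated plastome
#'
#' Builds a genome with exact inverted repeats (IRa = reverse complement of
#' IRb), protein/tRNA/rRNA genes (some two-exon, some minus strand, with
#' frame-consistent CDSs opened by ATG and closed by a stop) in the
#' single-copy regions, and planted mono-/di-nucleotide SSR tracts whose
#' coordinates are recorded in `$ssr_tracts`. Two calls with the same seed
#' are identical.
#'
#' @param seed integer RNG seed.
#' @param lsc,ir,ssc region lengths in bp (each >= 1 kb).
#' @param n_genes total genes placed in the single-copy regions.
#' @param ssr_density planted SSR tracts per single-copy bp (default 6e-4,
#'   about 15 tracts at the default scale).
#' @param id genome label.
#' @return [annotated_genome()] with `$partition` set and a `$ssr_tracts`
#'   data.frame (motif, units, start, end, 0-based half-open).
#' @export
make_genome <- function(seed, lsc = 20000L, ir = 4000L, ssc = 5000L,
                        n_genes = 40L, ssr_density = 6e-4, id = "synthetic") {
  stopifnot(lsc >= 1000L, ir >= 1000L, ssc >= 1000L, n_genes >= 1L)
  with_seed(seed, {
    sc_len <- lsc + ssc
    n_lsc_genes <- max(1L, round(n_genes * lsc / sc_len))
    n_ssc_genes <- n_genes - n_lsc_genes
    n_tracts <- max(0L, round(ssr_density * sc_len))
    n_tr_lsc <- round(n_tracts * lsc / sc_len)

    lsc_blk <- build_sc_region(lsc, n_lsc_genes, n_tr_lsc, prefix = "g")
    ssc_blk <- build_sc_region(ssc, n_ssc_genes, n_tracts - n_tr_lsc,
                               prefix = "h")
    irb_seq <- chars_seq(random_bases(ir))
    ira_seq <- chars_seq(revcomp_chars(seq_chars(irb_seq)))

    seq <- paste0(lsc_blk$seq, irb_seq, ssc_blk$seq, ira_seq)
    off_ssc <- lsc + ir
    feats <- rbind(lsc_blk$features,
                   shift_intervals(ssc_blk$features, off_ssc))
    tracts <- rbind(lsc_blk$tracts, shift_intervals(ssc_blk$tracts, off_ssc))
    g <- annotated_genome(id, seq, feats)
    g$partition <- structure(
      list(lsc = c(0L, lsc), irb = c(lsc, lsc + ir),
           ssc = c(lsc + ir, lsc + ir + ssc),
           ira = c(lsc + ir + ssc, lsc + 2L * ir + ssc),
           ir_len = ir, genome_length = g$length),
      class = "plastome_partition")
    g$ssr_tracts <- tracts
    g
  })
}

shift_intervals <- function(df, off) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df$start <- df$start + off
  df$end <- df$end + off
  df
}

# one single-copy region: random filler with carved gene and SSR slots
build_sc_region <- function(len, n_genes, n_tracts, prefix) {
  v <- random_bases(len)
  occupied <- matrix(numeric(0), ncol = 2L)   # [start, end) 0-based, w/ margin
  claim <- function(start, end, margin = 30L) {
    s <- max(0L, start - margin); e <- min(len, end + margin)
    if (nrow(occupied) > 0L &&
        any(occupied[, 1L] < e & occupied[, 2L] > s)) return(FALSE)
    occupied <<- rbind(occupied, c(s, e))
    TRUE
  }
  feats <- list()
  # genes: ~70% protein (25% of those two-exon), ~20% tRNA, ~10% rRNA
  n_protein <- max(1L, round(0.7 * n_genes))
  n_trna <- round(0.2 * n_genes)
  n_rrna <- n_genes - n_protein - n_trna
  mk_name <- function(kind, i) sprintf("%s%s%02d", prefix, kind, i)
  for (i in seq_len(n_genes)) {
    biotype <- if (i <= n_protein) "protein" else
      if (i <= n_protein + n_trna) "tRNA" else "rRNA"
    nm <- mk_name(switch(biotype, protein = "", tRNA = "trn", rRNA = "rrn"), i)
    strand <- sample(c("+", "-"), 1L, prob = c(0.6, 0.4))
    if (biotype == "protein") {
      n_codons <- sample(40:140, 1L)
      cds <- random_cds(n_codons)
      two_exon <- runif(1) < 0.25
      if (two_exon) {
        k <- 3L * sample(10L:(n_codons - 10L), 1L)
        intron <- chars_seq(random_bases(sample(80:200, 1L)))
        if (strand == "+") {
          e1 <- substr(cds, 1L, k); e2 <- substr(cds, k + 1L, nchar(cds))
          block <- paste0(e1, intron, e2)
          ex_len <- c(nchar(e1), nchar(e2))
        } else {
          rc <- revcomp(cds)
          e1 <- substr(rc, 1L, nchar(cds) - k)
          e2 <- substr(rc, nchar(cds) - k + 1L, nchar(cds))
          block <- paste0(e1, intron, e2)
          ex_len <- c(nchar(e1), nchar(e2))
        }
        glen <- nchar(block)
        slot <- find_slot(len, glen, claim)
        if (is.na(slot)) next
        v[(slot + 1L):(slot + glen)] <- seq_chars(block)
        iv1 <- c(slot, slot + ex_len[1L])
        iv2 <- c(slot + ex_len[1L] + length(intron_chars <- seq_chars(intron)),
                 slot + glen)
        feats[[length(feats) + 1L]] <- data.frame(
          name = nm, type = c("gene", "exon", "intron", "exon"),
          biotype = biotype, strand = strand,
          start = c(slot, iv1[1L], iv1[2L], iv2[1L]),
          end = c(slot + glen, iv1[2L], iv2[1L], iv2[2L]),
          stringsAsFactors = FALSE)
      } else {
        block <- if (strand == "+") cds else revcomp(cds)
        glen <- nchar(block)
        slot <- find_slot(len, glen, claim)
        if (is.na(slot)) next
        v[(slot + 1L):(slot + glen)] <- seq_chars(block)
        feats[[length(feats) + 1L]] <- data.frame(
          name = nm, type = c("gene", "exon"), biotype = biotype,
          strand = strand, start = slot, end = slot + glen,
          stringsAsFactors = FALSE)
      }
    } else {
      glen <- if (biotype == "tRNA") sample(70:90, 1L) else sample(110:160, 1L)
      slot <- find_slot(len, glen, claim)
      if (is.na(slot)) next
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, type = c("gene", "exon"), biotype = biotype,
        strand = strand, start = slot, end = slot + glen,
        stringsAsFactors = FALSE)
    }
  }
  # SSR tracts in the remaining free space
  tracts <- list()
  for (i in seq_len(n_tracts)) {
    mono <- runif(1) < 0.8
    if (mono) {
      base <- sample(BASES, 1L)
      units <- sample(8:15, 1L)
      tract <- strrep(base, units)
      first <- base; last <- base
    } else {
      motif <- sample(c("AT", "TA", "AG", "GA", "CT", "TC", "AC", "CA"), 1L)
      units <- sample(4:8, 1L)
      tract <- strrep(motif, units)
      first <- substr(motif, 1L, 1L); last <- substr(motif, 2L, 2L)
    }
    tlen <- nchar(tract)
    slot <- find_slot(len, tlen + 2L, claim)
    if (is.na(slot)) next
    # write flanking breaker bases so the planted tract is maximal
    v[slot + 1L] <- sample(setdiff(BASES, last), 1L)
    v[(slot + 2L):(slot + 1L + tlen)] <- seq_chars(tract)
    v[slot + 2L + tlen] <- sample(setdiff(BASES, first), 1L)
    tracts[[length(tracts) + 1L]] <- data.frame(
      motif = if (mono) base else motif, units = units,
      start = slot + 1L, end = slot + 1L + tlen, stringsAsFactors = FALSE)
  }
  feats_df <- if (length(feats)) do.call(rbind, feats) else NULL
  tracts_df <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(motif = character(), units = integer(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  list(seq = chars_seq(v), features = feats_df, tracts = tracts_df)
}

find_slot <- function(len, width, claim, tries = 500L) {
  for (t in seq_len(tries)) {
    s <- sample.int(len - width - 60L, 1L) + 30L
    if (claim(s, s + width)) return(s)
  }
  stop("infeasible packing: could not place a block of width ", width,
       call. = FALSE)
}

#' Mutation spectrum for the synthetic generator
#'
#' The default spectrum is the package's study condition for recovery
#' experiments: 50 substitutions with Ts fraction 0.5, 10 SSR-slippage
#' indels, 10 non-SSR indels with a size distribution that mirrors the
#' observed plastome indel spectrum (mostly 1-7 bp with rare 21/22/94 bp
#' events), and one 5-bp micro-inversion, all separated by at least 20 bp.
#'
#' @param n_snps,n_ssr_indels,n_nonssr_indels,n_inversions event counts.
#' @param ts_fraction probability that a substitution is a transition.
#' @param nonssr_size_dist data.frame(size, weight); weights are normalized.
#' @param inversion_len inversion segment length in bp.
#' @param min_spacing minimum distance between event footprints in bp.
#' @param ir_event_fraction fraction of events allowed to fall in the
#'   inverted repeats (default 0.03, reflecting how strongly conserved the
#'   IRs are relative to the single-copy regions); the remainder is placed
#'   in LSC/SSC.
#' @param seed RNG seed driving all randomness of [mutate_genome()].
#' @return list of class `mutation_spectrum`.
#' @export
make_spectrum <- function(n_snps = 50L, ts_fraction = 0.5,
                          n_ssr_indels = 10L, n_nonssr_indels = 10L,
                          nonssr_size_dist = NULL, n_inversions = 1L,
                          inversion_len = 5L, min_spacing = 20L,
                          ir_event_fraction = 0.03, seed = 1L) {
  stopifnot(n_snps >= 0L, n_ssr_indels >= 0L, n_nonssr_indels >= 0L,
            n_inversions >= 0L, ts_fraction >= 0, ts_fraction <= 1)
  if (is.null(nonssr_size_dist)) {
    nonssr_size_dist <- data.frame(
      size = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 21L, 22L, 94L),
      weight = c(12, 3, 1, 1, 3, 3, 1, 1, 1, 1))
  }
  nonssr_size_dist$weight <- nonssr_size_dist$weight /
    sum(nonssr_size_dist$weight)
  structure(list(n_snps = as.integer(n_snps), ts_fraction = ts_fraction,
                 n_ssr_indels = as.integer(n_ssr_indels),
                 n_nonssr_indels = as.integer(n_nonssr_indels),
                 nonssr_size_dist = nonssr_size_dist,
                 n_inversions = as.integer(n_inversions),
                 inversion_len = as.integer(inversion_len),
                 min_spacing = as.integer(min_spacing),
                 ir_event_fraction = ir_event_fraction,
                 seed = as.integer(seed)),
            class = "mutation_spectrum")
}

#' Apply a mutation spectrum to a genome
#'
#' Derives a second genome differing from the input by exactly the events in
#' the returned ledger: substitutions (transition with probability
#' `ts_fraction`), SSR indels that change planted tract lengths by one or
#' two units, non-SSR indels of novel motifs, and micro-inversions of
#' non-palindromic segments in which every base differs from its
#' reverse-complement counterpart. Event footprints are pairwise separated
#' by at least `min_spacing` bp and avoid planted SSR tracts (other than
#' the tracts being expanded/contracted), so that alignment recovers each
#' event atomically. Annotation coordinates are lifted over exactly.
#'
#' @param genome genome from [make_genome()] (needs `$ssr_tracts` for SSR
#'   indels).
#' @param spectrum [make_spectrum()].
#' @return list: `genome` (derived [annotated_genome()]) and `ledger`
#'   (data.frame: type, pos, size, motif, polarity, snp_kind, ssr_type,
#'   ref_base, alt_base; `pos` is the 0-based reference position — the SNP
#'   site, the left-normalized flank of an indel, or the inversion start).
#' @export
mutate_genome <- function(genome, spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  with_seed(spectrum$seed, {
    v <- seq_chars(genome$seq)
    n <- length(v)
    sp <- spectrum$min_spacing
    tracts <- genome$ssr_tracts %||%
      data.frame(motif = character(), units = integer(), start = integer(),
                 end = integer())
    # blocked intervals [s, e) incl. spacing margin; all planted tracts are
    # blocked for non-SSR events
    blocked <- if (nrow(tracts)) cbind(tracts$start - sp, tracts$end + sp)
    else matrix(numeric(0), ncol = 2L)
    exon_iv <- {
      f <- genome$features
      ex <- f[f$type == "exon", , drop = FALSE]
      if (nrow(ex)) cbind(ex$start, ex$end) else matrix(numeric(0), ncol = 2L)
    }
    clash <- function(s, e) {
      nrow(blocked) > 0L && any(blocked[, 1L] < e + sp & blocked[, 2L] > s - sp)
    }
    in_exon <- function(s, e) {
      nrow(exon_iv) > 0L && any(exon_iv[, 1L] < e & exon_iv[, 2L] > s)
    }
    block <- function(s, e) blocked <<- rbind(blocked, c(s, e))
    ledger <- list()
    events <- list()   # applied later, high positions first
    add_event <- function(ev) events[[length(events) + 1L]] <<- ev
    add_ledger <- function(type, pos, size, motif, polarity = NA_character_,
                           snp_kind = NA_character_, ssr_type = NA_character_,
                           ref_base = NA_character_, alt_base = NA_character_) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        type = type, pos = as.integer(pos), size = as.integer(size),
        motif = motif, polarity = polarity, snp_kind = snp_kind,
        ssr_type = ssr_type, ref_base = ref_base, alt_base = alt_base,
        stringsAsFactors = FALSE)
    }

    # 1. SSR indels on planted tracts
    if (spectrum$n_ssr_indels > 0L) {
      if (nrow(tracts) < spectrum$n_ssr_indels) {
        stop(sprintf(paste0("cannot place %d SSR indels: only %d planted ",
                            "tracts; lower n_ssr_indels or raise ssr_density"),
                     spectrum$n_ssr_indels, nrow(tracts)), call. = FALSE)
      }
      pick <- sample.int(nrow(tracts), spectrum$n_ssr_indels)
      for (ti in pick) {
        tr <- tracts[ti, ]
        ml <- nchar(tr$motif)
        delta <- sample(c(-2L, -1L, 1L, 2L), 1L)
        if (tr$units + delta < max(2L, ceiling(3 / ml))) delta <- abs(delta)
        k <- abs(delta) * ml
        add_event(list(kind = "ssr_indel", pos = tr$start, delta = delta,
                       motif = tr$motif, k = k))
        add_ledger("indel", tr$start - 1L, k,
                   tolower(strrep(tr$motif, abs(delta))),
                   polarity = if (delta > 0L) "insertion" else "deletion",
                   ssr_type = "SSR")
      }
    }

    # IR event budget: the repeats are strongly conserved, so only a small,
    # fixed number of events may land there (also keeps the derived genome's
    # maximal exact repeat pair detectable at reduced scale)
    n_total <- spectrum$n_snps + spectrum$n_ssr_indels +
      spectrum$n_nonssr_indels + spectrum$n_inversions
    ir_budget <- round(spectrum$ir_event_fraction %||% 0.03 * n_total)
    ir_iv <- if (!is.null(genome$partition)) {
      rbind(genome$partition$irb, genome$partition$ira)
    } else matrix(numeric(0), ncol = 2L)
    in_ir <- function(s, e) {
      nrow(ir_iv) > 0L && any(ir_iv[, 1L] < e & ir_iv[, 2L] > s)
    }
    sample_site <- function(width, avoid_exons = FALSE, tries = 2000L) {
      for (t in seq_len(tries)) {
        s <- sample.int(n - width - 200L, 1L) + 100L
        if (clash(s, s + width)) next
        if (avoid_exons && in_exon(s, s + width)) next
        if (in_ir(s, s + width)) {
          if (ir_budget < 1L) next
          ir_budget <<- ir_budget - 1L
        }
        return(s)
      }
      stop("cannot place events with min_spacing; use fewer events",
           call. = FALSE)
    }

    # 2. micro-inversions: segment where every base mismatches its
    # reverse-complement counterpart (seg[i] != comp(seg[L+1-i])) and the
    # reverse complement is not a short rotation of the segment (otherwise
    # the optimal alignment explains the event as two small indels instead
    # of a run of substitutions, and the event is genuinely ambiguous)
    L <- spectrum$inversion_len
    for (i in seq_len(spectrum$n_inversions)) {
      repeat {
        s <- sample_site(L, avoid_exons = TRUE)
        seg <- v[(s + 1L):(s + L)]
        if (ok_inversion_segment(seg)) break
      }
      block(s, s + L)
      add_event(list(kind = "inversion", pos = s, len = L))
      add_ledger("inversion", s, L, chars_seq(seg))
    }

    # 3. non-SSR indels
    sizes <- spectrum$nonssr_size_dist
    for (i in seq_len(spectrum$n_nonssr_indels)) {
      size <- sample(sizes$size, 1L, prob = sizes$weight)
      ins <- runif(1) < 0.5
      if (ins) {
        repeat {
          s <- sample_site(1L, avoid_exons = TRUE)   # insert after ref pos s
          left <- v[s + 1L]; right <- v[s + 2L]
          motif <- novel_motif(size, left, right)
          if (!is.null(motif)) break
        }
        block(s, s + 1L)
        add_event(list(kind = "insertion", pos = s, motif = motif))
        # ledger positions are left-normalized with the same rule the
        # caller applies, so homologous placements compare equal
        norm <- left_normalize(v, s, chars_seq(motif))
        add_ledger("indel", norm$left, size, tolower(norm$motif),
                   polarity = "insertion", ssr_type = "non-SSR")
      } else {
        repeat {
          s <- sample_site(size + 2L, avoid_exons = TRUE)
          seg <- v[(s + 2L):(s + 1L + size)]        # delete ref [s+1, s+size]
          before <- v[s + 1L]; after <- v[s + 2L + size]
          if (before != seg[length(seg)] && after != seg[1L] &&
              !is_low_complexity(seg) && !any(seg == "N")) break
        }
        block(s, s + size + 1L)
        add_event(list(kind = "deletion", pos = s, size = size))
        norm <- left_normalize(v, s, chars_seq(seg))
        add_ledger("indel", norm$left, size, tolower(norm$motif),
                   polarity = "deletion", ssr_type = "non-SSR")
      }
    }

    # 4. SNPs
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in seq_len(spectrum$n_snps)) {
      s <- sample_site(1L)
      ref <- v[s + 1L]
      if (ref == "N") next
      is_ts <- runif(1) < spectrum$ts_fraction
      alt <- if (is_ts) ts_map[[ref]] else {
        tv_opts <- setdiff(BASES, c(ref, ts_map[[ref]]))
        sample(tv_opts, 1L)
      }
      block(s, s + 1L)
      add_event(list(kind = "snp", pos = s, alt = alt))
      add_ledger("snp", s, 1L, NA_character_,
                 snp_kind = if (is_ts) "Ts" else "Tv",
                 ref_base = ref, alt_base = alt)
    }

    # apply events right to left so reference coordinates stay valid
    events <- events[order(-vapply(events, function(e) as.numeric(e$pos),
                                   numeric(1)))]
    w <- v
    shifts <- list()  # (ref_pos_after_which, delta) for liftover
    for (ev in events) {
      if (ev$kind == "snp") {
        w[ev$pos + 1L] <- ev$alt
      } else if (ev$kind == "inversion") {
        w[(ev$pos + 1L):(ev$pos + ev$len)] <-
          revcomp_chars(w[(ev$pos + 1L):(ev$pos + ev$len)])
      } else if (ev$kind == "insertion") {
        w <- append(w, seq_chars(ev$motif), after = ev$pos + 1L)
        shifts[[length(shifts) + 1L]] <- c(ev$pos, nchar(ev$motif))
      } else if (ev$kind == "deletion") {
        w <- w[-((ev$pos + 2L):(ev$pos + 1L + ev$size))]
        shifts[[length(shifts) + 1L]] <- c(ev$pos, -ev$size)
      } else if (ev$kind == "ssr_indel") {
        ml <- nchar(ev$motif)
        if (ev$delta > 0L) {
          w <- append(w, rep(seq_chars(ev$motif), ev$delta), after = ev$pos)
          shifts[[length(shifts) + 1L]] <- c(ev$pos - 1L, ev$k)
        } else {
          w <- w[-((ev$pos + 1L):(ev$pos + ev$k))]
          shifts[[length(shifts) + 1L]] <- c(ev$pos - 1L, -ev$k)
        }
      }
    }
    # exact liftover of feature coordinates (events never straddle exons)
    lift <- function(x) {
      for (sft in shifts) {
        if (x > sft[1L]) x <- x + sft[2L]
      }
      x
    }
    feats <- genome$features
    if (nrow(feats) > 0L) {
      feats$start <- as.integer(vapply(feats$start, lift, numeric(1)))
      feats$end <- as.integer(vapply(feats$end, lift, numeric(1)))
    }
    led <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(type = character(), pos = integer(), size = integer(),
                 motif = character(), polarity = character(),
                 snp_kind = character(), ssr_type = character(),
                 ref_base = character(), alt_base = character(),
                 stringsAsFactors = FALSE)
    led <- led[order(led$pos), , drop = FALSE]
    rownames(led) <- NULL
    derived <- annotated_genome(paste0(genome$id, "_derived"), chars_seq(w),
                                feats, circular = genome$circular)
    list(genome = derived, ledger = led)
  })
}

# liftover of int coordinates; vapply over shifts — defined once for clarity
novel_motif <- function(size, left, right, tries = 50L) {
  for (t in seq_len(tries)) {
    m <- random_bases(size)
    if (m[1L] == left || m[length(m)] == right) next
    if (size >= 2L && m[1L] == m[length(m)]) next
    if (is_low_complexity(m)) next
    return(chars_seq(m))
  }
  NULL
}

# A planted inversion must beat every gapped explanation under the default
# scoring (match 1, mismatch -2, gap -5/-2): every column mismatches, and at
# shift d the overlap between segment and reverse complement has too few
# matches for a two-gap alignment to score higher (3 * matches < 8 + 2d).
ok_inversion_segment <- function(seg) {
  L <- length(seg)
  if (any(seg == "N")) return(FALSE)
  r <- revcomp_chars(seg)
  if (any(seg == r)) return(FALSE)
  for (d in seq_len(min(3L, L - 1L))) {
    m1 <- sum(seg[(1L + d):L] == r[1L:(L - d)])
    m2 <- sum(seg[1L:(L - d)] == r[(1L + d):L])
    if (3L * max(m1, m2) >= 8L + 2L * d) return(FALSE)
  }
  TRUE
}

is_low_complexity <- function(chars) {
  n <- length(chars)
  if (n == 1L) return(FALSE)
  if (length(unique(chars)) == 1L) return(TRUE)
  # period-2 tandem
  if (n >= 4L && n %% 2L == 0L) {
    if (all(chars[seq(1L, n - 2L)] == chars[seq(3L, n)])) return(TRUE)
  }
  FALSE
}

#' Score called events against a ground-truth ledger
#'
#' Events are matched within each type by position with a tolerance of
#' +/- 2 bp (greedy nearest-neighbour matching on sorted positions).
#'
#' @param called list from [call_events()].
#' @param ledger ledger data.frame from [mutate_genome()].
#' @param tol positional tolerance in bp.
#' @return data.frame: type, n_true, n_called, n_matched, precision, recall,
#'   no_calls flag. With no calls of a type, precision is reported as 1
#'   with `no_calls = TRUE`.
#' @export
score_recovery <- function(called, ledger, tol = 2L) {
  pull <- function(type) {
    switch(type,
      snp = called$snps$ref_pos,
      indel = called$indels$ref_flank_pos,
      inversion = called$inversions$ref_pos)
  }
  rows <- lapply(c("snp", "indel", "inversion"), function(type) {
    truth <- sort(ledger$pos[ledger$type == type])
    calls <- sort(pull(type) %||% integer(0))
    matched <- 0L
    ti <- 1L
    for (cp in calls) {
      while (ti <= length(truth) && truth[ti] < cp - tol) ti <- ti + 1L
      if (ti <= length(truth) && abs(truth[ti] - cp) <= tol) {
        matched <- matched + 1L
        ti <- ti + 1L
      }
    }
    data.frame(type = type, n_true = length(truth), n_called = length(calls),
               n_matched = matched,
               precision = if (length(calls) == 0L) 1 else matched / length(calls),
               recall = if (length(truth) == 0L) 1 else matched / length(truth),
               no_calls = length(calls) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
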