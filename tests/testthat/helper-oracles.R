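# Independent oracles used to compute expected values. Each one is a
# deliberately naive implementation kept separate from the package's code
# paths: plain recursion over all alignments, an O(n^2) scan-all-substrings
# SSR search, whole-protein translation via seqinr, and a column walker that
# counts maximal difference features in an alignment.

# ---- alignment ----------------------------------------------------------

# exhaustive enumeration: every alignment is a path of column operations
# (substitution, gap-in-b, gap-in-a); gap runs score open + (k-1) * extend.
oracle_align_exhaustive <- function(a, b, match = 1, mismatch = -2,
                                    gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == "N" || bv[j] == "N") 0 else
        if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {  # gap in b
      g <- if (prev == "x") gap_extend else gap_open
      best <- max(best, g + rec(i + 1, j, "x"))
    }
    if (j <= length(bv)) {  # gap in a
      g <- if (prev == "y") gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# plain full-matrix affine DP (Gotoh), no band, scores only
oracle_align_dp <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == "N" || bv[j - 1] == "N") 0 else
        if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- SSR ---------------------------------------------------------------

# O(n^2): at every start and motif length, extend the exact tandem repeat as
# far as it goes; keep maximal qualifying repeats; collapse phase-shifted
# views of the same dinucleotide stretch to the leftmost; resolve mono/di
# overlaps by the longer span (ties to mono).
oracle_ssr_naive <- function(seq, mono_min = 8, di_min = 4) {
  v <- strsplit(toupper(seq), "")[[1]]
  n <- length(v)
  hits <- list()
  for (ml in 1:2) {
    thr <- if (ml == 1) mono_min else di_min
    for (s in seq_len(n - ml * thr + 1)) {
      motif <- v[s:(s + ml - 1)]
      if (any(motif == "N")) next
      if (ml == 2 && motif[1] == motif[2]) next
      # count units
      u <- 1
      while (s + (u + 1) * ml - 1 <= n &&
             all(v[(s + u * ml):(s + (u + 1) * ml - 1)] == motif)) u <- u + 1
      if (u < thr) next
      # maximal: cannot extend one unit left
      if (s - ml >= 1 && all(v[(s - ml):(s - 1)] == motif)) next
      hits[[length(hits) + 1]] <- data.frame(
        motif = paste(motif, collapse = ""), units = u, start = s - 1,
        end = s - 1 + u * ml, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), units = integer(),
                      start = integer(), end = integer()))
  }
  out <- do.call(rbind, hits)
  out$len <- out$end - out$start
  # collapse overlapping di repeats that are phases of one stretch: keep the
  # leftmost (which also has the most units after trimming)
  keep <- rep(TRUE, nrow(out))
  o <- order(nchar(out$motif), out$start)
  out <- out[o, ]
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[j]) next
      if (nchar(out$motif[i]) != 2 || nchar(out$motif[j]) != 2) next
      if (out$start[j] > out$start[i] && out$start[j] <= out$start[i] + 1 &&
          out$end[j] <= out$end[i] + 1) keep[j] <- FALSE
    }
  }
  out <- out[keep, ]
  # mono/di overlap: longer span wins, ties to mono
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i] || !keep[j]) next
      ov <- out$start[j] < out$end[i] & out$end[j] > out$start[i]
      if (!ov) next
      ij <- c(out$len[i], out$len[j])
      drop <- if (ij[1] != ij[2]) which.min(ij) else
        which.max(c(nchar(out$motif[i]), nchar(out$motif[j])))
      keep[c(i, j)[drop]] <- FALSE
    }
  }
  out <- out[keep, c("motif", "units", "start", "end")]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# ---- coding ------------------------------------------------------------

# whole-protein oracle: substitute the base in the genome, splice both
# versions, translate with seqinr (bacterial/plastid code), compare proteins
oracle_effect <- function(genome, gene, pos, alt_base) {
  v <- strsplit(genome$seq, "")[[1]]
  v[pos + 1] <- alt_base
  g2 <- genome
  g2$seq <- paste(v, collapse = "")
  cds1 <- suppressWarnings(splice_cds(genome, gene))
  cds2 <- suppressWarnings(splice_cds(g2, gene))
  p1 <- seqinr::translate(strsplit(cds1, "")[[1]], numcode = 11)
  p2 <- seqinr::translate(strsplit(cds2, "")[[1]], numcode = 11)
  if (identical(p1, p2)) "S" else "N"
}

# ---- events ------------------------------------------------------------

# brute-force column walker: number of maximal difference features in a
# gapped 2-row alignment = maximal gap runs (each row) + mismatch columns
oracle_feature_count <- function(row_a, row_b) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  gaps_a <- rle(a == "-")
  gaps_b <- rle(b == "-")
  n_gap_runs <- sum(gaps_a$values) + sum(gaps_b$values)
  mism <- sum(a != "-" & b != "-" & a != "N" & b != "N" & a != b)
  n_gap_runs + mism
}
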