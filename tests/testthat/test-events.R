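test_that("SNP columns are classified by transition/transversion and pair class", {
  ev <- call_snps(aln_of("ACGT", "ACGA"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_base, "T")
  expect_equal(ev$alt_base, "A")
  expect_equal(ev$kind, "Tv")
  expect_equal(ev$gc_class, "AT<->TA")

  ev2 <- call_snps(aln_of("AG", "GG"))
  expect_equal(ev2$kind, "Ts")
  expect_equal(ev2$gc_class, "GC-changing")
  expect_equal(ev2$pair_class, "A/G")

  # N-containing and gap columns are excluded
  ev3 <- call_snps(aln_of("ANG-T", "ATGCT"))
  expect_equal(nrow(ev3), 0L)
})

test_that("every SNP is exactly one of Ts/Tv and one gc class", {
  set.seed(301)
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r)) {
    ev <- call_snps(aln_of(paste0("GG", r, "GG"), paste0("GG", a, "GG")))
    expect_equal(nrow(ev), 1L)
    expect_true(ev$kind %in% c("Ts", "Tv"))
    is_ts <- all(c(r, a) %in% c("A", "G")) || all(c(r, a) %in% c("C", "T"))
    expect_equal(ev$kind, if (is_ts) "Ts" else "Tv")
    expect_true(ev$gc_class %in% c("AT<->TA", "CG<->GC", "GC-changing"))
  }
})

test_that("a reverse-complemented segment is one inversion, not five SNPs", {
  # revcomp(ACCTG) = CAGGT; hand-verified: A<->T? col-by-col all five differ
  left <- "GATTACA"; right <- "TTGCAGA"
  aln <- aln_of(paste0(left, "ACCTG", right), paste0(left, "CAGGT", right))
  inv <- detect_inversions(aln)
  expect_equal(nrow(inv$events), 1L)
  expect_equal(inv$events$length, 5L)
  expect_equal(inv$events$ref_segment, "ACCTG")
  expect_equal(inv$events$alt_segment, "CAGGT")
  snps <- call_snps(aln, consumed = inv$consumed)
  expect_equal(nrow(snps), 0L)
  ev <- call_events(aln)
  expect_equal(nrow(ev$inversions), 1L)
  expect_equal(nrow(ev$snps), 0L)
  expect_equal(nrow(ev$indels), 0L)
})

test_that("a palindromic identical segment is no event at all", {
  s <- paste0("GATTACA", "ACGCGT", "TTGCAGA")  # ACGCGT is its own revcomp
  aln <- aln_of(s, s)
  expect_equal(nrow(detect_inversions(aln)$events), 0L)
  expect_equal(nrow(call_snps(aln)), 0L)
})

test_that("a single mismatch is a SNP even if a 1-bp inversion would explain it", {
  aln <- aln_of("GGATGG", "GGTTGG")  # A->T: revcomp(A) = T
  inv <- detect_inversions(aln)
  expect_equal(nrow(inv$events), 0L)
  expect_equal(nrow(call_snps(aln, consumed = inv$consumed)), 1L)
})

test_that("an inversion with palindromic internal matches is still recovered", {
  # segment ATTAA -> revcomp TTAAT: column 2 matches (T/T), so the mismatch
  # run is split; the window search must reassemble the full segment
  left <- "GGCGCGC"; right <- "CGCGCGG"
  aln <- aln_of(paste0(left, "ATTAA", right), paste0(left, "TTAAT", right))
  inv <- detect_inversions(aln)
  expect_equal(nrow(inv$events), 1L)
  expect_equal(inv$events$length, 5L)
})

test_that("slippage in a homopolymer is one SSR insertion", {
  ref <- paste0("GCGT", strrep("A", 10), "TCGC")
  alt <- paste0("GCGT", strrep("A", 12), "TCGC")
  aln <- align_pair(ref, alt)
  ind <- call_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$polarity, "insertion")
  expect_equal(ind$size, 2L)
  expect_equal(ind$motif, "aa")
  expect_equal(ind$ssr_type, "SSR")
  # left-normalized: flank is the base before the run (0-based position 3)
  expect_equal(ind$ref_flank_pos, 3L)
})

test_that("a novel hexamer is one non-SSR insertion", {
  set.seed(302)
  left <- rand_seq(60); right <- rand_seq(60)
  ref <- paste0(left, right)
  alt <- paste0(left, "TTCGAA", right)
  ind <- call_indels(align_pair(ref, alt))
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$size, 6L)
  expect_equal(ind$polarity, "insertion")
  expect_equal(ind$ssr_type, "non-SSR")
})

test_that("swapping the reference swaps insertion and deletion labels only", {
  set.seed(303)
  left <- rand_seq(50); mid <- rand_seq(50); right <- rand_seq(50)
  ref <- paste0(left, mid, right)
  alt <- paste0(left, "CCTTGG", mid, substr(right, 4, 50))
  aln <- align_pair(ref, alt)
  fwd <- call_indels(aln)
  swapped <- aln
  swapped$reference_index <- 2L
  rev <- call_indels(swapped)
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- fwd[order(fwd$start_col), ]; rev <- rev[order(rev$start_col), ]
  expect_equal(fwd$size, rev$size)
  expect_equal(fwd$motif, rev$motif)
  expect_equal(fwd$ssr_type, rev$ssr_type)
  flip <- c(insertion = "deletion", deletion = "insertion")
  expect_equal(unname(flip[fwd$polarity]), rev$polarity)
})

test_that("event count equals the brute-force feature count of the alignment", {
  # conservation: no column double-counted, none dropped (inversions off)
  for (seed in 304:308) {
    g <- make_genome(seed = seed, lsc = 3000, ir = 1000, ssc = 1000,
                     n_genes = 6)
    mut <- mutate_genome(g, make_spectrum(n_snps = 12, n_ssr_indels = 2,
                                          n_nonssr_indels = 4,
                                          n_inversions = 0, seed = seed))
    aln <- align_pair(g$seq, mut$genome$seq)
    ev <- call_events(aln, min_mismatches = 10000L)
    expect_equal(nrow(ev$snps) + nrow(ev$indels),
                 oracle_feature_count(aln$rows[[1]], aln$rows[[2]]),
                 info = paste("seed", seed))
  }
})

test_that("summaries pool the IRs and report exact percentages", {
  g <- make_genome(seed = 310)
  mut <- mutate_genome(g, make_spectrum(seed = 310))
  aln <- align_pair(g$seq, mut$genome$seq)
  ev <- call_events(aln, ref_genome = g)
  s <- summarize_events(ev)
  expect_equal(s$counts$total, s$counts$snp + s$counts$indel + s$counts$inversion)
  expect_equal(s$counts$ts + s$counts$tv, s$counts$snp)
  expect_equal(s$counts$ssr_indel + s$counts$nonssr_indel, s$counts$indel)
  expect_equal(sum(unlist(s$region_pct_all)), 100, tolerance = 0.011)
  comp <- unlist(s$indel_by_compartment)
  expect_equal(sum(comp), s$counts$indel)

  # empty event list: zero counts, percentages reported as zero with a note
  empty <- call_events(aln_of("ACGTACGTAC", "ACGTACGTAC"))
  expect_message(s0 <- summarize_events(empty), "no localized")
  expect_equal(s0$counts$total, 0L)
})

test_that("SNP VCF output is minimal 4.2 with 1-based positions", {
  g <- toy_annotated()
  ref50 <- substr(g$seq, 50, 50)
  alt50 <- setdiff(c("A", "C", "G", "T"), ref50)[1]
  aln <- align_pair(g$seq, paste0(substr(g$seq, 1, 49), alt50,
                                  substr(g$seq, 51, g$length)))
  snps <- call_snps(aln, ref_genome = g)
  expect_equal(nrow(snps), 1L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(snps, g, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(as.integer(strsplit(body[1], "\t")[[1]][2]), 50L)
})
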