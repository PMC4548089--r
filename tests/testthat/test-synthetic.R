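test_that("generation is deterministic per seed", {
  g1 <- make_genome(seed = 601)
  g2 <- make_genome(seed = 601)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$features, g2$features)
  expect_identical(g1$ssr_tracts, g2$ssr_tracts)
  g3 <- make_genome(seed = 602)
  expect_false(identical(g1$seq, g3$seq))
})

test_that("the constructed partition is recovered exactly by detection", {
  g <- make_genome(seed = 603)
  p <- detect_partition(g)
  expect_equal(p$lsc, g$partition$lsc)
  expect_equal(p$irb, g$partition$irb)
  expect_equal(p$ssc, g$partition$ssc)
  expect_equal(p$ira, g$partition$ira)
  expect_equal(p$ir_len, 4000L)
})

test_that("generated genes are frame-consistent coding sequences", {
  g <- make_genome(seed = 604)
  genes <- unique(g$features$name[g$features$biotype == "protein" &
                                    g$features$type == "gene"])
  for (gene in genes) {
    cds <- splice_cds(g, gene)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    # no internal stop
    codons <- substring(cds, seq(1, nchar(cds) - 3, 3),
                        seq(3, nchar(cds) - 3, 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("all planted SSR tracts are found by the scanner", {
  g <- make_genome(seed = 605)
  expect_gt(nrow(g$ssr_tracts), 0L)
  found <- find_ssrs(g, mono_min = 8, di_min = 4)
  for (i in seq_len(nrow(g$ssr_tracts))) {
    tr <- g$ssr_tracts[i, ]
    hit <- found[found$start == tr$start & found$end == tr$end, ]
    expect_equal(nrow(hit), 1L,
                 info = sprintf("tract %s x%d at %d", tr$motif, tr$units,
                                tr$start))
  }
})

test_that("an all-zero spectrum returns an identical genome and empty ledger", {
  g <- make_genome(seed = 606)
  mut <- mutate_genome(g, make_spectrum(n_snps = 0, n_ssr_indels = 0,
                                        n_nonssr_indels = 0,
                                        n_inversions = 0, seed = 1))
  expect_identical(mut$genome$seq, g$seq)
  expect_equal(nrow(mut$ledger), 0L)
})

test_that("mutation is deterministic per spectrum seed", {
  g <- make_genome(seed = 607)
  m1 <- mutate_genome(g, make_spectrum(seed = 9))
  m2 <- mutate_genome(g, make_spectrum(seed = 9))
  expect_identical(m1$genome$seq, m2$genome$seq)
  expect_identical(m1$ledger, m2$ledger)
})

test_that("SNP counts and Ts draw recover the spectrum", {
  g <- make_genome(seed = 608)
  mut <- mutate_genome(g, make_spectrum(n_snps = 50, ts_fraction = 0.5,
                                        n_ssr_indels = 0,
                                        n_nonssr_indels = 0,
                                        n_inversions = 0, seed = 7))
  aln <- align_pair(g$seq, mut$genome$seq)
  ev <- call_events(aln, ref_genome = g)
  expect_equal(nrow(ev$snps), 50L)
  # Ts count within the central 99% binomial band of Bin(50, 0.5)
  ts <- sum(ev$snps$kind == "Ts")
  expect_gte(ts, qbinom(0.005, 50, 0.5))
  expect_lte(ts, qbinom(0.995, 50, 0.5))
  # called Ts/Tv equal the ledger's draws exactly
  expect_equal(ts, sum(mut$ledger$snp_kind == "Ts"))
})

test_that("a planted 5-bp inversion is recovered at the ledger position", {
  g <- make_genome(seed = 609)
  mut <- mutate_genome(g, make_spectrum(n_snps = 0, n_ssr_indels = 0,
                                        n_nonssr_indels = 0,
                                        n_inversions = 1, inversion_len = 5,
                                        seed = 11))
  aln <- align_pair(g$seq, mut$genome$seq)
  inv <- call_events(aln, ref_genome = g)$inversions
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$length, 5L)
  expect_equal(inv$ref_pos, mut$ledger$pos[mut$ledger$type == "inversion"])
  expect_identical(revcomp(inv$ref_segment), inv$alt_segment)
})

test_that("annotation liftover keeps gene sequences intact after mutation", {
  g <- make_genome(seed = 610)
  mut <- mutate_genome(g, make_spectrum(seed = 12))
  d <- mut$genome
  # every gene whose span contains no planted event must splice identically
  ev_pos <- mut$ledger$pos
  genes <- g$features[g$features$type == "gene" &
                        g$features$biotype == "protein", ]
  n_checked <- 0L
  for (i in seq_len(nrow(genes))) {
    hit <- any(ev_pos >= genes$start[i] - 100 & ev_pos <= genes$end[i] + 100)
    if (hit) next
    expect_identical(splice_cds(d, genes$name[i]),
                     splice_cds(g, genes$name[i]))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 0L)
})

test_that("recovery scoring arithmetic and conventions are exact", {
  g <- make_genome(seed = 611)
  mut <- mutate_genome(g, make_spectrum(seed = 13))
  aln <- align_pair(g$seq, mut$genome$seq)
  ev <- call_events(aln, ref_genome = g)
  sc <- score_recovery(ev, mut$ledger)
  expect_true(all(sc$precision == 1))
  expect_true(all(sc$recall == 1))
  # drop one called SNP out of 50 -> recall 49/50
  ev2 <- ev
  ev2$snps <- ev2$snps[-1, ]
  sc2 <- score_recovery(ev2, mut$ledger)
  expect_equal(sc2$recall[sc2$type == "snp"], 0.98)
  # empty call set: recall 0, precision reported as 1 with the no-calls flag
  ev3 <- ev
  ev3$snps <- ev3$snps[0, ]
  sc3 <- score_recovery(ev3, mut$ledger)
  expect_equal(sc3$recall[sc3$type == "snp"], 0)
  expect_equal(sc3$precision[sc3$type == "snp"], 1)
  expect_true(sc3$no_calls[sc3$type == "snp"])
})

test_that("too many events for the spacing raise a placement error", {
  g <- make_genome(seed = 612, lsc = 1000, ir = 1000, ssc = 1000, n_genes = 2)
  expect_error(
    mutate_genome(g, make_spectrum(n_snps = 500, n_ssr_indels = 0,
                                   n_nonssr_indels = 0, n_inversions = 0,
                                   seed = 1)),
    "min_spacing|fewer events")
})

test_that("SSR indels require enough planted tracts", {
  g <- make_genome(seed = 613, ssr_density = 0)
  expect_error(mutate_genome(g, make_spectrum(n_ssr_indels = 10, seed = 1)),
               "planted tracts")
})
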