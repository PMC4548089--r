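snp_row <- function(pos, ref, alt) {
  data.frame(ref_pos = pos, ref_base = ref, alt_base = alt,
             kind = ifelse(all(c(ref, alt) %in% c("A", "G")) ||
                             all(c(ref, alt) %in% c("C", "T")), "Ts", "Tv"),
             stringsAsFactors = FALSE)
}

test_that("CDS splicing honours exon order, strand and introns", {
  # plus strand, single exon
  g1 <- annotated_genome("p", "ATGAAATAACC", data.frame(
    name = "x", type = c("gene", "exon"), biotype = "protein", strand = "+",
    start = 0L, end = 9L))
  expect_equal(splice_cds(g1, "x"), "ATGAAATAA")
  # minus strand: genomic TTTCAT reads ATGAAA on the coding strand
  g2 <- annotated_genome("m", "GGTTTCATGG", data.frame(
    name = "y", type = c("gene", "exon"), biotype = "protein", strand = "-",
    start = 2L, end = 8L))
  expect_equal(splice_cds(g2, "y"), "ATGAAA")
  # two exons with a spliced-out intron
  intron <- strrep("C", 100)
  g3 <- annotated_genome("s", paste0("ATG", intron, "TAA"), data.frame(
    name = "z", type = c("gene", "exon", "intron", "exon"),
    biotype = "protein", strand = "+",
    start = c(0L, 0L, 3L, 103L), end = c(106L, 3L, 103L, 106L)))
  expect_equal(splice_cds(g3, "z"), "ATGTAA")
  # non-multiple-of-3 warns and truncates
  g4 <- annotated_genome("t", "ATGAAAT", data.frame(
    name = "w", type = c("gene", "exon"), biotype = "protein", strand = "+",
    start = 0L, end = 7L))
  expect_warning(cds <- splice_cds(g4, "w"), "truncating")
  expect_equal(cds, "ATGAAA")
})

test_that("single-SNP effects follow the genetic code", {
  g <- annotated_genome("c", "ATGGCTTAA", data.frame(
    name = "x", type = c("gene", "exon"), biotype = "protein", strand = "+",
    start = 0L, end = 9L))
  # GCT -> GCC: Ala -> Ala, synonymous
  e1 <- effect_of(snp_row(5L, "T", "C"), g, "x")
  expect_equal(e1$effect, "S")
  expect_equal(e1$ref_codon, "GCT")
  expect_equal(e1$alt_codon, "GCC")
  # ATG -> ATA: Met -> Ile, non-synonymous
  e2 <- effect_of(snp_row(2L, "G", "A"), g, "x")
  expect_equal(e2$effect, "N")
  expect_equal(e2$ref_aa, "M")
  expect_equal(e2$alt_aa, "I")
  expect_error(effect_of(snp_row(100L, "A", "C"), g, "x"), "not in exons")
})

test_that("effects agree with the whole-protein translation oracle", {
  # 1000 random coding SNPs on a synthetic genome, each checked against
  # translating the full spliced CDS before/after the substitution
  g <- make_genome(seed = 401)
  ex <- g$features[g$features$type == "exon" &
                     g$features$biotype == "protein", ]
  set.seed(402)
  n_checked <- 0L
  while (n_checked < 1000L) {
    i <- sample(nrow(ex), 1L)
    pos <- sample(ex$start[i]:(ex$end[i] - 1L), 1L)
    ref <- substr(g$seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    got <- effect_of(snp_row(pos, ref, alt), g, ex$name[i])$effect
    want <- oracle_effect(g, ex$name[i], pos, alt)
    expect_equal(got, want,
                 info = sprintf("gene %s pos %d %s>%s", ex$name[i], pos,
                                ref, alt))
    n_checked <- n_checked + 1L
  }
})

test_that("S/N calls are invariant under reverse-complementing the genome", {
  g <- make_genome(seed = 403, lsc = 4000, ir = 1000, ssc = 2000,
                   n_genes = 10)
  # mirror the genome: revcomp sequence, reflect coordinates, flip strands
  L <- g$length
  f <- g$features
  f2 <- f
  f2$start <- L - f$end
  f2$end <- L - f$start
  f2$strand <- ifelse(f$strand == "+", "-", "+")
  gm <- annotated_genome("mirror", revcomp(g$seq), f2)
  ex <- f[f$type == "exon" & f$biotype == "protein", ]
  set.seed(404)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:50) {
    i <- sample(nrow(ex), 1L)
    pos <- sample(ex$start[i]:(ex$end[i] - 1L), 1L)
    ref <- substr(g$seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    e_fwd <- effect_of(snp_row(pos, ref, alt), g, ex$name[i])$effect
    e_rev <- effect_of(snp_row(L - 1L - pos, comp[[ref]], comp[[alt]]),
                       gm, ex$name[i])$effect
    expect_equal(e_fwd, e_rev)
  }
})

test_that("gene tables balance Ts+Tv against S+N per gene and in total", {
  g <- make_genome(seed = 405)
  mut <- mutate_genome(g, make_spectrum(n_snps = 60, seed = 406))
  aln <- align_pair(g$seq, mut$genome$seq)
  ev <- call_events(aln, ref_genome = g)
  eff <- coding_effects(ev$snps, g)
  cm <- setNames(rep("other", length(unique(eff$gene))), unique(eff$gene))
  tab <- gene_table(eff, cm)
  genes <- tab[!tab$gene %in% c("(subtotal)", "(total)"), ]
  expect_true(all(genes$ts + genes$tv == genes$s + genes$n))
  tot <- tab[tab$gene == "(total)", ]
  with_sn <- eff[!is.na(eff$effect), ]
  expect_equal(tot$s + tot$n, nrow(with_sn))
  expect_equal(attr(eff, "n_coding") + attr(eff, "n_noncoding"),
               nrow(ev$snps))
})

test_that("tRNA/rRNA exon SNPs are coding only under the RNA switch", {
  g <- make_genome(seed = 407)
  rna_ex <- g$features[g$features$type == "exon" &
                         g$features$biotype != "protein", ]
  pos <- rna_ex$start[1L]
  ref <- substr(g$seq, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  snps <- snp_row(pos, ref, alt)
  e_protein_only <- coding_effects(snps, g, include_rna = FALSE)
  e_with_rna <- coding_effects(snps, g, include_rna = TRUE)
  expect_equal(attr(e_protein_only, "n_coding"), 0L)
  expect_equal(attr(e_with_rna, "n_coding"), 1L)
  expect_true(is.na(e_with_rna$effect[1L]))   # RNA genes get no S/N call
})

test_that("a small two-gene table sums categories correctly", {
  eff <- data.frame(gene = c("ga", "gb", "gb"),
                    ref_pos = c(1L, 2L, 3L),
                    kind = c("Ts", "Tv", "Tv"),
                    effect = c("S", "N", "N"),
                    stringsAsFactors = FALSE)
  tab <- gene_table(eff, c(ga = "other", gb = "other"))
  tot <- tab[tab$gene == "(total)", ]
  expect_equal(tot$s, 1L)
  expect_equal(tot$n, 2L)
  # empty effects: zero totals
  empty <- gene_table(eff[0, ], c())
  expect_equal(empty[empty$gene == "(total)", ]$s, 0L)
  # unmapped gene warns and lands in "other"
  expect_warning(t2 <- gene_table(eff, c(ga = "other")), "category map")
  expect_true("gb" %in% t2$gene)
})
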