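# Small fixtures built in code.

seq_chars_test <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# quadripartite toy built from explicit blocks
toy_quadripartite <- function(lsc = 5000, irb = 1500, ssc = 1200, seed = 11) {
  set.seed(seed)
  lsc_s <- rand_seq(lsc)
  irb_s <- rand_seq(irb)
  ssc_s <- rand_seq(ssc)
  ira_s <- revcomp(irb_s)
  annotated_genome("toy", paste0(lsc_s, irb_s, ssc_s, ira_s))
}

# genome with two adjacent genes and one 2-exon gene for locate()/splicing
toy_annotated <- function() {
  set.seed(21)
  # layout: 0-99 spacer | gene a (100-279, 2 exons 100-160 / 220-280,
  # intron 160-220) | spacer | gene b (400-520, minus strand) | spacer
  filler <- function(n) rand_seq(n)
  cds_a <- paste0("ATG", strrep("GCT", 38), "TAA")       # 120 bp
  e1 <- substr(cds_a, 1, 60); e2 <- substr(cds_a, 61, 120)
  cds_b <- paste0("ATG", strrep("AAA", 38), "TAA")
  seq <- paste0(filler(100), e1, filler(60), e2, filler(120),
                revcomp(cds_b), filler(80))
  feats <- data.frame(
    name = c("a", "a", "a", "a", "b", "b"),
    type = c("gene", "exon", "intron", "exon", "gene", "exon"),
    biotype = "protein",
    strand = c("+", "+", "+", "+", "-", "-"),
    start = c(100L, 100L, 160L, 220L, 400L, 400L),
    end = c(280L, 160L, 220L, 280L, 520L, 520L),
    stringsAsFactors = FALSE)
  annotated_genome("toy2", seq, feats)
}

# GenBank flat-file text for a 240-bp record with one 2-exon gene
write_toy_genbank <- function(path) {
  set.seed(31)
  seq <- tolower(paste0(rand_seq(40),
                        "atggct", rand_seq(30), "gcttaa",
                        rand_seq(158)))
  # exons at 41..46 and 77..82 (1-based), intron between
  lines <- c(
    "LOCUS       TOY0001                  240 bp    DNA     circular PLN 01-JAN-2020",
    "DEFINITION  toy chloroplast record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..240",
    "     gene            41..82",
    '                     /gene="tgn"',
    "     CDS             join(41..46,77..82)",
    '                     /gene="tgn"',
    "ORIGIN",
    paste0("        1 ", gsub("(.{10})", "\\1 ",
                              substr(seq, 1, 60))),
    paste0("       61 ", gsub("(.{10})", "\\1 ",
                              substr(seq, 61, 120))),
    paste0("      121 ", gsub("(.{10})", "\\1 ",
                              substr(seq, 121, 180))),
    paste0("      181 ", gsub("(.{10})", "\\1 ",
                              substr(seq, 181, 240))),
    "//")
  writeLines(lines, path)
  invisible(toupper(seq))
}

# build an alignment object directly from gapped strings
aln_of <- function(a, b, ...) pairwise_alignment(c(a = a, b = b), ...)
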