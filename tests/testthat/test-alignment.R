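test_that("identical sequences align without gaps at full match score", {
  aln <- align_pair("ACGT", "ACGT")
  expect_equal(attr(aln, "score"), 4)
  expect_equal(unname(aln$rows), c("ACGT", "ACGT"))
})

test_that("a single deletion aligns as one gap at the optimal score", {
  # exhaustive enumeration over all alignments of these strings fixes the
  # optimum at 3 matches + one opened gap
  expect_equal(oracle_align_exhaustive("ACGT", "AGT"), -2)
  aln <- align_pair("ACGT", "AGT")
  expect_equal(attr(aln, "score"), -2)
  gaps <- gregexpr("-+", aln$rows[[2]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 1L)
  expect_false(grepl("-", aln$rows[[1]]))
})

test_that("aligner equals the exhaustive-search optimum on short pairs", {
  set.seed(101)
  for (k in 1:25) {
    a <- rand_seq(sample(1:8, 1))
    b <- rand_seq(sample(1:8, 1))
    expect_equal(attr(align_pair(a, b), "score"),
                 oracle_align_exhaustive(a, b),
                 info = paste(a, b))
  }
})

test_that("aligner equals an independent plain-DP oracle on 200-bp pairs", {
  set.seed(102)
  for (k in 1:5) {
    a <- rand_seq(200)
    # derive b by light mutation so the pair is alignable
    v <- strsplit(a, "")[[1]]
    idx <- sample(200, 8)
    v[idx] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    b <- paste(v[-sample(200, 2)], collapse = "")
    expect_equal(attr(align_pair(a, b), "score"), oracle_align_dp(a, b))
  }
})

test_that("aligner agrees with Biostrings pairwiseAlignment on random pairs", {
  # cross-check against the reference implementation: our gap convention
  # open + (k-1)*extend corresponds to gapOpening = 3, gapExtension = 2
  set.seed(103)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (k in 1:3) {
    a <- rand_seq(100)
    v <- strsplit(a, "")[[1]]
    v[sample(100, 5)] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    b <- paste(v[-sample(100, 3)], collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = mat, gapOpening = 3, gapExtension = 2,
      type = "global")
    expect_equal(attr(align_pair(a, b), "score"), Biostrings::score(ref))
  }
})

test_that("ungapping each aligned row reproduces the input sequence", {
  set.seed(104)
  for (k in 1:5) {
    a <- rand_seq(300)
    v <- strsplit(a, "")[[1]]
    v[sample(300, 10)] <- sample(c("A", "C", "G", "T"), 10, replace = TRUE)
    b <- paste(append(v[-sample(300, 4)], c("T", "T", "C"), after = 100),
               collapse = "")
    aln <- align_pair(a, b)
    expect_identical(ungap(aln, 1), a)
    expect_identical(ungap(aln, 2), b)
  }
})

test_that("aligned FASTA and Clustal readers agree and validate input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC-GT", ">s2", "ACAGT"), fa)
  a1 <- read_alignment(fa, "fasta")
  expect_equal(a1$ncol, 5L)
  expect_equal(unname(a1$rows), c("AC-GT", "ACAGT"))

  clu <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "s1      AC-GT", "s2      ACAGT", "        ** **"), clu)
  a2 <- read_alignment(clu, "clustal")
  expect_equal(unname(a2$rows), unname(a1$rows))

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTA", ">s2", "ACGTAC"), ragged)
  expect_error(read_alignment(ragged, "fasta"), "ragged")
})

test_that("all-gap columns are removed with a message", {
  expect_message(a <- pairwise_alignment(c(x = "A-C", y = "A-G")),
                 "all-gap")
  expect_equal(a$ncol, 2L)
})

test_that("coordinate maps are mutually inverse and row-independent", {
  a <- pairwise_alignment(c(r = "A-CG-T", s = "AACGTT", t = "-ACG-T"))
  m <- build_map(a)
  expect_equal(m[["r"]]$col2pos, c(0L, NA, 1L, 2L, NA, 3L))
  expect_length(m, 3L)
  for (i in 1:3) {
    p2c <- m[[i]]$pos2col
    expect_equal(m[[i]]$col2pos[p2c + 1L], seq_along(p2c) - 1L)
  }
})

test_that("reference-anchored third-row merge preserves all three sequences", {
  set.seed(105)
  a <- rand_seq(400)
  v <- strsplit(a, "")[[1]]
  v[sample(400, 6)] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
  b <- paste(v[-sample(400, 3)], collapse = "")
  w <- strsplit(a, "")[[1]]
  w[sample(400, 9)] <- sample(c("A", "C", "G", "T"), 9, replace = TRUE)
  cc <- paste(append(w, c("G", "G"), after = 200), collapse = "")
  m3 <- merge_third_row(align_pair(a, b), cc, name = "c")
  expect_equal(nrow(m3$mat), 3L)
  expect_identical(ungap(m3, 1), a)
  expect_identical(ungap(m3, 2), b)
  expect_identical(ungap(m3, 3), cc)
})
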