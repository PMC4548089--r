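test_that("identical rows give zero diversity everywhere", {
  s <- rand_seq(2000, seed = 501)
  p <- window_pi(pairwise_alignment(c(a = s, b = s)))
  expect_true(all(p$pi == 0))
  expect_true(all(!p$no_valid))
})

test_that("six mismatches in one 600-column window give pi = 0.01", {
  set.seed(502)
  a <- rand_seq(600)
  v <- strsplit(a, "")[[1]]
  idx <- sample(600, 6)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  v[idx] <- flip[v[idx]]
  p <- window_pi(pairwise_alignment(c(a = a, b = paste(v, collapse = ""))),
                 window_len = 600, step = 600)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pi, 6 / 600)
})

test_that("windows advance by step and drop the trailing partial window", {
  s <- rand_seq(1500, seed = 503)
  p <- window_pi(pairwise_alignment(c(a = s, b = s)), 600, 200)
  expect_equal(p$start_col, seq(0L, 900L, by = 200L))
  expect_true(all(p$end_col - p$start_col == 600L))
  expect_error(window_pi(pairwise_alignment(c(a = s, b = s)), 0, 200),
               "window_len")
})

test_that("whole-alignment window equals the direct pairwise count", {
  g <- make_genome(seed = 504, lsc = 3000, ir = 1000, ssc = 1000, n_genes = 5,
                   ssr_density = 2e-3)
  mut <- mutate_genome(g, make_spectrum(n_snps = 25, n_ssr_indels = 3,
                                        n_nonssr_indels = 3, seed = 505))
  aln <- align_pair(g$seq, mut$genome$seq)
  p <- window_pi(aln, window_len = aln$ncol, step = aln$ncol)
  a <- aln$mat[1, ]; b <- aln$mat[2, ]
  valid <- a != "-" & b != "-" & a != "N" & b != "N"
  expect_equal(nrow(p), 1L)
  expect_equal(p$pi, sum(valid & a != b) / sum(valid))
  expect_equal(pi_overall(aln), p$pi)
})

test_that("an added substitution strictly increases its window's pi", {
  s <- rand_seq(600, seed = 506)
  v <- strsplit(s, "")[[1]]
  v[300] <- setdiff(c("A", "C", "G", "T"), v[300])[1]
  p0 <- window_pi(pairwise_alignment(c(a = s, b = s)), 600, 600)
  p1 <- window_pi(pairwise_alignment(c(a = s, b = paste(v, collapse = ""))),
                  600, 600)
  expect_gt(p1$pi, p0$pi)
})

test_that("three-row diversity averages all pairs (A = B case)", {
  set.seed(507)
  a <- rand_seq(600)
  v <- strsplit(a, "")[[1]]
  idx <- sample(600, 9)
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  v[idx] <- flip[v[idx]]
  cc <- paste(v, collapse = "")
  pi_ac <- window_pi(pairwise_alignment(c(a = a, c = cc)), 600, 600)$pi
  p3 <- window_pi(pairwise_alignment(c(a = a, b = a, c = cc)), 600, 600)
  expect_equal(p3$pi, (2 / 3) * pi_ac)
  expect_equal(attr(p3, "n_rows"), 3L)
})

test_that("gap-containing pair-sites are excluded from both counts", {
  # 600 columns; one row gaps 10 columns that hold 2 of the differences
  set.seed(508)
  a <- rand_seq(600)
  v <- strsplit(a, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  v[c(50, 55, 300)] <- flip[v[c(50, 55, 300)]]
  v[46:55] <- "-"
  b <- paste(v, collapse = "")
  p <- window_pi(pairwise_alignment(c(a = a, b = b)), 600, 600)
  expect_equal(p$valid_sites, 590)
  expect_equal(p$pi, 1 / 590)
})

test_that("hotspots merge adjacent qualifying windows and label loci", {
  # no qualifying window -> empty
  s <- rand_seq(2000, seed = 509)
  p0 <- window_pi(pairwise_alignment(c(a = s, b = s)))
  expect_equal(nrow(call_hotspots(p0, 0.008)), 0L)

  # mutations concentrated in one tract -> exactly one merged hotspot
  g <- make_genome(seed = 510)
  v <- seq_chars_test(g$seq)
  set.seed(511)
  tract <- 8000:9000
  idx <- sample(tract, 40)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  v[idx] <- flip[v[idx]]
  aln <- pairwise_alignment(c(ref = g$seq, alt = paste(v, collapse = "")))
  map <- build_map(aln)
  prof <- window_pi(aln, map = map)
  hs <- call_hotspots(prof, 0.008, ref_genome = g, map = map)
  expect_equal(nrow(hs), 1L)
  expect_lte(hs$start_ref, 8000)
  expect_gte(hs$end_ref, 9000)
  expect_true(nchar(hs$labels) > 0)
})

test_that("profile TSV prints Pi at five decimals", {
  s <- rand_seq(1200, seed = 512)
  p <- window_pi(pairwise_alignment(c(a = s, b = s)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(pi = "character"))
  expect_true(all(grepl("^\\d\\.\\d{5}$", tab$pi)))
})
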