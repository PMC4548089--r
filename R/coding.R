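# Synonymous / non-synonymous classification of coding SNPs and per-gene
# mutation tables grouped by functional category.

#' Spliced coding sequence of a gene
#'
#' Exons concatenated in strand order, reverse-complemented for minus-strand
#' genes. A spliced length that is not a multiple of 3 triggers a warning and
#' trailing-base truncation.
#'
#' @param genome annotated genome.
#' @param gene gene name.
#' @return coding-strand nucleotide string.
#' @export
splice_cds <- function(genome, gene) {
  ex <- genome$features[genome$features$name == gene &
                          genome$features$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop(sprintf("gene '%s' has no exons", gene), call. = FALSE)
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- paste0(vapply(seq_len(nrow(ex)), function(j) {
    substr(genome$seq, ex$start[j] + 1L, ex$end[j])
  }, ""), collapse = "")
  if (ex$strand[1L] == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L) {
    warning(sprintf("CDS of '%s' not a multiple of 3; truncating %d base(s)",
                    gene, nchar(cds) %% 3L), call. = FALSE)
    cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  }
  cds
}

# plastid (bacterial) genetic code; amino-acid assignments as table 11
plastid_code <- function() Biostrings::getGeneticCode("11")

translate_codon <- function(codon, code = plastid_code()) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(code[[codon]])
}

#' Coding effect of a single SNP
#'
#' Maps a reference-genome SNP position into the spliced CDS of `gene`,
#' substitutes only this SNP's base (other nearby variants held at the
#' reference state) and compares amino acids under the plastid genetic code.
#' Start codons get no special casing: the call is by amino-acid identity.
#'
#' @param snp one row of the [call_snps()] table (needs ref_pos, ref_base,
#'   alt_base).
#' @param genome reference annotated genome.
#' @param gene gene whose exons contain the SNP.
#' @return list of class `coding_effect`: gene, cds_pos (0-based),
#'   codon_index, codon_pos (0-2), ref_codon, alt_codon, ref_aa, alt_aa,
#'   effect ("S"/"N").
#' @export
effect_of <- function(snp, genome, gene) {
  ex <- genome$features[genome$features$name == gene &
                          genome$features$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop(sprintf("gene '%s' has no exons", gene), call. = FALSE)
  ex <- ex[order(ex$start), , drop = FALSE]
  pos <- snp$ref_pos
  hit <- which(ex$start <= pos & pos < ex$end)
  if (length(hit) == 0L) {
    stop(sprintf("position %d not in exons of '%s'", pos, gene), call. = FALSE)
  }
  # offset within the plus-strand concatenation
  prior <- if (hit[1L] > 1L) sum(ex$end[seq_len(hit[1L] - 1L)] -
                                   ex$start[seq_len(hit[1L] - 1L)]) else 0L
  off_plus <- prior + (pos - ex$start[hit[1L]])
  cds_len <- sum(ex$end - ex$start)
  minus <- ex$strand[1L] == "-"
  cds_pos <- if (minus) cds_len - 1L - off_plus else off_plus
  ref_base <- toupper(snp$ref_base)
  alt_base <- toupper(snp$alt_base)
  if (minus) {
    ref_base <- chartr("ACGTN", "TGCAN", ref_base)
    alt_base <- chartr("ACGTN", "TGCAN", alt_base)
  }
  cds <- splice_cds_quiet(genome, gene)
  if (cds_pos >= nchar(cds)) {
    stop(sprintf("position %d beyond truncated CDS of '%s'", pos, gene),
         call. = FALSE)
  }
  if (substr(cds, cds_pos + 1L, cds_pos + 1L) != ref_base) {
    stop(sprintf("reference base mismatch at %d in '%s'", pos, gene),
         call. = FALSE)
  }
  ci <- cds_pos %/% 3L
  cp <- cds_pos %% 3L
  ref_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, cp + 1L, cp + 1L) <- alt_base
  code <- plastid_code()
  ref_aa <- translate_codon(ref_codon, code)
  alt_aa <- translate_codon(alt_codon, code)
  structure(list(gene = gene, cds_pos = cds_pos, codon_index = ci,
                 codon_pos = cp, ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 effect = if (identical(ref_aa, alt_aa)) "S" else "N"),
            class = "coding_effect")
}

splice_cds_quiet <- function(genome, gene) {
  suppressWarnings(splice_cds(genome, gene))
}

#' Classify all coding SNPs of a call set
#'
#' Finds, for each SNP, the protein gene whose exon contains it on the
#' reference genome and computes the S/N effect. SNPs in tRNA/rRNA exons are
#' counted as coding when `include_rna` is TRUE but never receive an S/N
#' call; by default coding means protein-gene exons.
#'
#' @param snps [call_snps()] table.
#' @param genome reference annotated genome.
#' @param include_rna whether tRNA/rRNA exons count as coding.
#' @return data.frame: snps rows that are coding, with gene, effect, kind;
#'   attribute `n_noncoding` gives the complementary count.
#' @export
coding_effects <- function(snps, genome, include_rna = FALSE) {
  f <- genome$features
  ex <- f[f$type == "exon", , drop = FALSE]
  rows <- list()
  n_coding <- 0L
  for (i in seq_len(nrow(snps))) {
    pos <- snps$ref_pos[i]
    hit <- ex[ex$start <= pos & pos < ex$end, , drop = FALSE]
    if (nrow(hit) == 0L) next
    protein <- hit[hit$biotype == "protein", , drop = FALSE]
    if (nrow(protein) == 0L && !include_rna) next
    n_coding <- n_coding + 1L
    if (nrow(protein) > 0L) {
      eff <- effect_of(snps[i, ], genome, protein$name[1L])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = protein$name[1L], ref_pos = pos, kind = snps$kind[i],
        effect = eff$effect, ref_aa = eff$ref_aa, alt_aa = eff$alt_aa,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = hit$name[1L], ref_pos = pos, kind = snps$kind[i],
        effect = NA_character_, ref_aa = NA_character_,
        alt_aa = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), ref_pos = integer(), kind = character(),
               effect = character(), ref_aa = character(),
               alt_aa = character(), stringsAsFactors = FALSE)
  attr(out, "n_coding") <- n_coding
  attr(out, "n_noncoding") <- nrow(snps) - n_coding
  out
}

#' Per-gene mutation table with functional-category subtotals
#'
#' One row per gene with Ts, Tv, S and N counts (per gene ts+tv == s+n:
#' every protein-coding SNP receives both classifications), grouped by a
#' functional category map, with subtotal rows per category and a grand
#' total. Genes missing from the map go to "other" with a warning.
#'
#' @param effects [coding_effects()] table (rows with S/N calls).
#' @param category_map named character vector or list gene -> category, or a
#'   YAML path; default ships the standard four plastid groups
#'   (photosynthetic apparatus / photosynthetic metabolism / gene
#'   expression / other).
#' @return data.frame: category, gene, ts, tv, s, n; subtotal rows carry
#'   gene == "(subtotal)" and the grand total gene == "(total)".
#' @export
gene_table <- function(effects, category_map = NULL) {
  cm <- load_category_map(category_map)
  eff <- effects[!is.na(effects$effect), , drop = FALSE]
  genes <- unique(eff$gene)
  cat_of <- vapply(genes, function(g) {
    if (!is.null(cm[[g]])) cm[[g]] else {
      warning(sprintf("gene '%s' not in category map; assigned 'other'", g),
              call. = FALSE)
      "other"
    }
  }, "")
  rows <- lapply(seq_along(genes), function(i) {
    e <- eff[eff$gene == genes[i], , drop = FALSE]
    data.frame(category = cat_of[i], gene = genes[i],
               ts = sum(e$kind == "Ts"), tv = sum(e$kind == "Tv"),
               s = sum(e$effect == "S"), n = sum(e$effect == "N"),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), gene = character(), ts = integer(),
               tv = integer(), s = integer(), n = integer(),
               stringsAsFactors = FALSE)
  cat_order <- c("photosynthetic apparatus", "photosynthetic metabolism",
                 "gene expression", "other")
  tab$category <- factor(tab$category,
                         levels = union(cat_order, unique(tab$category)))
  tab <- tab[order(tab$category, tab$gene), , drop = FALSE]
  out <- list()
  for (cc in levels(droplevels(tab$category))) {
    sub <- tab[tab$category == cc, , drop = FALSE]
    out[[length(out) + 1L]] <- sub
    out[[length(out) + 1L]] <- data.frame(
      category = cc, gene = "(subtotal)", ts = sum(sub$ts), tv = sum(sub$tv),
      s = sum(sub$s), n = sum(sub$n), stringsAsFactors = FALSE)
  }
  total <- data.frame(category = "all", gene = "(total)", ts = sum(tab$ts),
                      tv = sum(tab$tv), s = sum(tab$s), n = sum(tab$n),
                      stringsAsFactors = FALSE)
  res <- rbind(do.call(rbind, lapply(out, function(x) {
    x$category <- as.character(x$category); x
  })), total)
  rownames(res) <- NULL
  res
}

load_category_map <- function(category_map) {
  if (is.null(category_map)) {
    path <- system.file("extdata", "gene_categories.yaml",
                        package = "plastcomp")
    return(yaml::read_yaml(path))
  }
  if (is.character(category_map) && length(category_map) == 1L &&
      file.exists(category_map)) {
    return(yaml::read_yaml(category_map))
  }
  as.list(category_map)
}

#' Write a gene table as TSV
#' @param tab [gene_table()] output.
#' @param path output file.
#' @export
write_gene_table_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
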