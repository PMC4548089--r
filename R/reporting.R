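# End-to-end orchestration: configuration, the compare and simulate runs,
# and the report bundle writers. Output formatting is fixed (Pi at 5
# decimals, percentages at 2) so identical inputs give byte-identical files.

#' Build a run configuration
#'
#' @param genomes list of [annotated_genome()] objects or file paths
#'   (GenBank or FASTA; FASTA entries may be `list(path =, annotation =)`).
#' @param reference index of the reference genome (default 1).
#' @param external_alignment optional aligned FASTA/Clustal path used instead
#'   of the internal aligner.
#' @param mono_min,di_min SSR unit-count thresholds.
#' @param window_len,step sliding-window parameters in alignment columns.
#' @param hotspot_threshold Pi cutoff for hotspot calls (0.008 within a
#'   genus; 0.015 is the usual between-genus setting).
#' @param min_inv_len,max_inv_len,min_mismatches inversion parameters.
#' @param scoring,band aligner parameters (see [align_pair()]).
#' @param category_map optional YAML path or named list for [gene_table()].
#' @param coding_includes_rna whether tRNA/rRNA exons count as coding.
#' @param min_ir_len partition detection threshold.
#' @param out_dir output directory (created), or NULL to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(genomes, reference = 1L, external_alignment = NULL,
                       mono_min = 8L, di_min = 4L, window_len = 600L,
                       step = 200L, hotspot_threshold = 0.008,
                       min_inv_len = 3L, max_inv_len = 50L,
                       min_mismatches = 2L, scoring = NULL, band = NULL,
                       category_map = NULL, coding_includes_rna = FALSE,
                       min_ir_len = 1000L, out_dir = NULL) {
  stopifnot(length(genomes) >= 2L, reference >= 1L,
            reference <= length(genomes),
            mono_min >= 2L, di_min >= 2L, window_len >= 1L, step >= 1L,
            hotspot_threshold > 0)
  structure(as.list(environment()), class = "run_config")
}

load_config_genome <- function(g) {
  if (inherits(g, "annotated_genome")) return(g)
  if (is.list(g)) {
    return(read_genome(g$path, format = "fasta",
                       annotation_table = g$annotation))
  }
  fmt <- if (grepl("\\.(gb|gbk|genbank)$", g, ignore.case = TRUE))
    "genbank" else "fasta"
  read_genome(g, format = fmt)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full comparative analysis
#'
#' Reads the genomes, detects partitions, scans SSRs, aligns the reference to
#' the second genome (and threads in a third for the diversity profile when
#' given), calls and classifies all mutation events, classifies coding SNPs,
#' computes the sliding-window Pi profile and hotspots, and (optionally)
#' writes the report bundle: summary JSON, SSR TSVs, indel/inversion TSV,
#' per-gene S/N TSV, SNP VCF, diversity TSV, hotspot BED, aligned FASTA and
#' partition BEDs.
#'
#' @param config [run_config()].
#' @return list of class `compare_report`: genomes, partitions, ssr tables,
#'   alignment, events, summary, coding effects and gene table, diversity
#'   profile and hotspots, plus the genome-level summary list.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genomes <- stage("io", lapply(config$genomes, load_config_genome))
  # reference first
  ord <- c(config$reference, setdiff(seq_along(genomes), config$reference))
  genomes <- genomes[ord]
  # the reference must partition exactly; a non-reference genome whose
  # repeat pair is detectable but mutation-fragmented (ambiguous flanks)
  # gets its regions by homology, projected from the reference after
  # alignment
  genomes[[1L]]$partition <- stage("partition",
                                   detect_partition(genomes[[1L]],
                                                    config$min_ir_len))
  deferred <- logical(length(genomes))
  for (i in seq_along(genomes)[-1L]) {
    genomes[[i]]$partition <- stage("partition", tryCatch(
      detect_partition(genomes[[i]], config$min_ir_len),
      error = function(e) {
        if (grepl("does not flank", conditionMessage(e))) NULL else stop(e)
      }))
    deferred[i] <- is.null(genomes[[i]]$partition)
  }
  ref <- genomes[[1L]]
  ssrs <- stage("ssr", lapply(genomes, function(g) {
    find_ssrs(g, config$mono_min, config$di_min,
              with_context = nrow(g$features) > 0L)
  }))
  aln <- stage("alignment", {
    if (!is.null(config$external_alignment)) {
      fmt <- if (grepl("\\.(aln|clustal|clu)$", config$external_alignment,
                       ignore.case = TRUE)) "clustal" else "fasta"
      read_alignment(config$external_alignment, fmt)
    } else {
      a2 <- align_pair(genomes[[1L]]$seq, genomes[[2L]]$seq,
                       scoring = config$scoring, band = config$band,
                       names = c(genomes[[1L]]$id, genomes[[2L]]$id))
      if (length(genomes) >= 3L) {
        merge_third_row(a2, genomes[[3L]]$seq, name = genomes[[3L]]$id,
                        scoring = config$scoring, band = config$band)
      } else a2
    }
  })
  if (any(deferred)) {
    pmap <- build_map(aln)
    for (i in which(deferred)) {
      message(sprintf(paste0("partition of '%s' projected from the ",
                             "reference through the alignment"),
                      genomes[[i]]$id))
      genomes[[i]]$partition <- project_partition(
        ref$partition, pmap, from = 1L, to = i,
        to_length = genomes[[i]]$length)
    }
  }
  events <- stage("events", call_events(
    aln, ref_genome = ref, mono_min = config$mono_min, di_min = config$di_min,
    min_inv_len = config$min_inv_len, max_inv_len = config$max_inv_len,
    min_mismatches = config$min_mismatches))
  summ <- stage("summary", summarize_events(events))
  effects <- stage("coding", coding_effects(events$snps, ref,
                                            config$coding_includes_rna))
  gtab <- stage("coding", gene_table(effects, config$category_map))
  map <- events$map
  profile <- stage("diversity", window_pi(aln, config$window_len,
                                          config$step, map = map))
  hotspots <- stage("diversity", call_hotspots(
    profile, config$hotspot_threshold, ref_genome = ref, map = map))
  genome_summary <- lapply(genomes, function(g) {
    gc <- region_gc(g)
    p <- g$partition
    cnt <- gene_count(g)
    list(id = g$id, length = g$length,
         lsc_len = p$lsc[2L] - p$lsc[1L], ir_len = p$ir_len,
         ssc_len = p$ssc[2L] - p$ssc[1L],
         gc_total = as.numeric(fmt_pct(100 * gc[["total"]])),
         gc_lsc = as.numeric(fmt_pct(100 * gc[["LSC"]])),
         gc_ir = as.numeric(fmt_pct(100 * gc[["IR"]])),
         gc_ssc = as.numeric(fmt_pct(100 * gc[["SSC"]])),
         genes_protein = cnt[["protein"]], genes_trna = cnt[["tRNA"]],
         genes_rrna = cnt[["rRNA"]], genes_total = cnt[["total"]])
  })
  report <- structure(
    list(genomes = genomes, ssrs = ssrs, alignment = aln, events = events,
         summary = summ, coding_effects = effects, gene_table = gtab,
         profile = profile, hotspots = hotspots,
         genome_summary = genome_summary,
         snp_coding = attr(effects, "n_coding"),
         snp_noncoding = attr(effects, "n_noncoding"),
         pi_mean = mean(profile$pi), pi_max = max(profile$pi)),
    class = "compare_report")
  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

#' @export
print.compare_report <- function(x, ...) {
  s <- x$summary$counts
  cat(sprintf("<compare_report> %s vs %s\n", x$genomes[[1L]]$id,
              x$genomes[[2L]]$id))
  cat(sprintf("  events: %d total = %d SNP + %d indel + %d inversion\n",
              s$total, s$snp, s$indel, s$inversion))
  cat(sprintf("  SNPs: %d Ts / %d Tv; coding %d, non-coding %d\n", s$ts, s$tv,
              x$snp_coding, x$snp_noncoding))
  cat(sprintf("  indels: %d SSR / %d non-SSR\n", s$ssr_indel, s$nonssr_indel))
  cat(sprintf("  Pi: mean %s, max %s over %d windows\n", fmt_pi(x$pi_mean),
              fmt_pi(x$pi_max), nrow(x$profile)))
  invisible(x)
}

write_report <- function(report, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(list.files(out, full.names = TRUE)))
  ref <- report$genomes[[1L]]
  summary_json <- list(
    genomes = report$genome_summary,
    events = report$summary$counts,
    indel_by_compartment = report$summary$indel_by_compartment,
    snp_by_compartment = report$summary$snp_by_compartment,
    region_pct_all = report$summary$region_pct_all,
    region_pct_snp = report$summary$region_pct_snp,
    region_pct_indel = report$summary$region_pct_indel,
    snp_coding = report$snp_coding, snp_noncoding = report$snp_noncoding,
    pi_mean = as.numeric(fmt_pi(report$pi_mean)),
    pi_max = as.numeric(fmt_pi(report$pi_max)),
    parameters = list(mono_min = config$mono_min, di_min = config$di_min,
                      window_len = config$window_len, step = config$step,
                      hotspot_threshold = config$hotspot_threshold))
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (i in seq_along(report$genomes)) {
    g <- report$genomes[[i]]
    write_ssr_tsv(report$ssrs[[i]], g$id,
                  file.path(out, sprintf("ssr_%s.tsv", g$id)))
    write_partition_bed(g$partition, g$id,
                        file.path(out, sprintf("partition_%s.bed", g$id)))
  }
  write_indel_tsv(report$events$indels, report$events$inversions,
                  file.path(out, "indels.tsv"))
  write_snp_vcf(report$events$snps, ref, file.path(out, "snps.vcf"))
  write_gene_table_tsv(report$gene_table, file.path(out, "gene_sn.tsv"))
  write_profile_tsv(report$profile, file.path(out, "diversity.tsv"))
  write_hotspot_bed(report$hotspots, ref$id, file.path(out, "hotspots.bed"))
  write_aligned_fasta(report$alignment, file.path(out, "alignment.fasta"))
  ok <- TRUE
  invisible(out)
}

#' Simulate a plastome pair and write the bundle
#'
#' Deterministic per seed: the pair (FASTA), annotation tables (TSV) and the
#' ground-truth ledger (JSON) are byte-identical across runs with the same
#' configuration.
#'
#' @param spectrum [make_spectrum()]; its seed drives genome construction
#'   and mutation placement.
#' @param out_dir output directory, or NULL to skip writing.
#' @param ... passed to [make_genome()] (lsc, ir, ssc, n_genes, ...).
#' @return list: `reference`, `derived` (annotated genomes), `ledger`.
#' @export
run_simulate <- function(spectrum = make_spectrum(), out_dir = NULL, ...) {
  ref <- make_genome(seed = spectrum$seed, ...)
  mut <- mutate_genome(ref, spectrum)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref, file.path(out_dir, "reference.fasta"))
    write_fasta(mut$genome, file.path(out_dir, "derived.fasta"))
    write_annotation_tsv(ref, file.path(out_dir, "reference_annotation.tsv"))
    write_annotation_tsv(mut$genome, file.path(out_dir, "derived_annotation.tsv"))
    jsonlite::write_json(mut$ledger, file.path(out_dir, "ledger.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)
  }
  list(reference = ref, derived = mut$genome, ledger = mut$ledger)
}
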