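# plastcomp

Comparative mutation analysis of chloroplast genomes (plastomes) in R.

Congeneric plant species differ across their ~150 kb plastomes by only a few
hundred characters — single-nucleotide substitutions, short indels,
microsatellite length changes, and the occasional micro-inversion — and
those characters are exactly what species identification and low-level
phylogenetics need. `plastcomp` implements the full comparative workflow for
two (or three) annotated plastomes:

* **Structure** — detection of the quadripartite organisation
  (LSC / IRb / SSC / IRa, the two IRs being exact reverse complements),
  per-region lengths and GC content, gene inventories.
* **Microsatellites (SSRs)** — maximal mono- and di-nucleotide tandem
  repeats at the conventional thresholds (≥ 8 units mono, ≥ 4 units di).
* **Mutation events** — called from a global alignment in a fixed cascade:
  micro-inversions (a segment whose counterpart equals its reverse
  complement), then indels (one event per maximal gap run, classified
  SSR-slippage vs non-SSR, insertion vs deletion relative to the reference),
  then SNPs (transition/transversion, base-pair class, GC class), each
  localized to exon / intron / intergenic spacer ("geneA-geneB") and region.
* **Coding effects** — synonymous/non-synonymous classification under the
  plastid genetic code (NCBI table 11), with per-gene tables grouped into
  functional categories.
* **Nucleotide diversity** — sliding-window Pi (600-bp windows, 200-bp
  step over alignment columns) with divergence-hotspot calling at
  configurable thresholds (0.008 within a genus, 0.015 between genera).
* **Synthetic data** — a generator that builds reduced-scale annotated
  plastome pairs with a ground-truth mutation ledger, so every stage above
  is testable end-to-end with no downloads.

Alignments can be ingested from aligned FASTA/Clustal (for externally or
manually curated alignments) or produced by the built-in banded affine-gap
Needleman–Wunsch aligner (C++, deterministic tie-breaking).

## Worked example

Simulate a congeneric pair under the study spectrum (50 substitutions, 10
SSR-slippage indels, 10 non-SSR indels, one 5-bp micro-inversion, events
spaced ≥ 20 bp) and run the full comparison:

```r
library(plastcomp)

sim <- run_simulate(make_spectrum(seed = 2026))
cfg <- run_config(genomes = list(sim$reference, sim$derived))
rep <- run_compare(cfg)
rep
#> <compare_report> synthetic vs synthetic_derived
#>   events: 71 total = 50 SNP + 20 indel + 1 inversion
#>   SNPs: 20 Ts / 30 Tv; coding 17, non-coding 33
#>   indels: 10 SSR / 10 non-SSR
#>   Pi: mean 0.00169, max 0.01333 over 163 windows

score_recovery(rep$events, sim$ledger)
#>        type n_true n_called n_matched precision recall no_calls
#> 1       snp     50       50        50         1      1    FALSE
#> 2     indel     20       20        20         1      1    FALSE
#> 3 inversion      1        1         1         1      1    FALSE
```

Reading it: the pipeline called 71 events on the 33-kb pair — every planted
substitution, indel and the single micro-inversion, with the correct
SSR/non-SSR split — and recovered the ground-truth ledger with precision and
recall 1.0 for every event type. The window profile behaves like a real
congeneric comparison: mean Pi 0.00169, a maximum of 0.01333 where events
happen to cluster.

With `out_dir` set, `run_compare()` writes the full report bundle: a summary
JSON (lengths, GC, partition, gene counts, event totals, region
percentages), SSR tables, an indel/inversion table, a per-gene S/N table, a
SNP VCF, the diversity profile TSV, hotspot BED and the aligned FASTA.
Identical inputs give byte-identical outputs.

Real data enter the same way: `read_genome("KT348516.gb", "genbank")` parses
a GenBank flat file (sequence + gene/CDS/tRNA/rRNA features), or FASTA plus
a TSV annotation table; `run_config(genomes = list(...),
external_alignment = "pair.aln")` substitutes a curated alignment for the
internal aligner.

## The analysis workflow

The `analysis/` scripts run the study end-to-end on generated data and
leave their tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | builds the study pair + ground-truth ledger |
| `analysis/02_compare.R`  | full comparison, report tables, ledger check |
| `analysis/03_diversity.R` | Pi profiles (2- and 3-row) + hotspot plot |
| `analysis/04_recovery.R` | 20-seed recovery experiment |

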