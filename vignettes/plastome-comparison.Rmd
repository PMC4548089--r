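---
title: "Comparative mutation analysis of plastomes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mutation analysis of plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

## The problem

Chloroplast genomes of closely related plant species are extremely similar:
between congeners, most of the ~150 kb molecule is identical, and the few
hundred differences that do exist — single-nucleotide substitutions, short
insertions/deletions, microsatellite length changes and the occasional
micro-inversion — are exactly the characters a systematist wants for species
identification and low-level phylogenetics. `plastcomp` implements the full
comparative workflow for a pair (or trio) of annotated plastomes: structural
partitioning, microsatellite scanning, mutation-event calling and
classification, and sliding-window nucleotide diversity with hotspot
detection. A first-class synthetic-pair generator with a ground-truth ledger
makes every stage testable without any external data.

## The quadripartite model

A plastome is circular with four canonical segments: a large single-copy
region (LSC), a small single-copy region (SSC) and two inverted repeats (IRb,
IRa) that are exact reverse complements of one another. `detect_partition()`
finds the maximal pair of disjoint, exactly reverse-complementary segments of
at least `min_ir_len` bp (default 1000) by seed-and-extend matching between
the sequence and its reverse complement, then labels the longer arc LSC and
the shorter SSC.

Two deliberate choices here:

* **Exact matching.** The repeats of congeneric plastomes are typically
  length-identical and letter-perfect, so the detector demands exact reverse
  complementarity; a mismatch-tolerant mode is out of scope. When the second
  genome of a pair carries recent mutations inside a repeat, the *maximal
  exact* pair shrinks; a residual flank outside the matched pair (shorter
  than the detected repeat itself) is absorbed into the adjacent repeat
  interval so the four regions still tile the genome. For a pristine genome the residuals
  are zero and the repeat intervals are exact, which is what the test suite
  asserts.
* **Linear orientation.** Inputs are processed in their deposited linear
  order, in which one repeat copy reaches a sequence end. An inverted-repeat
  pair that spans the origin raises the documented "no quadripartite
  structure" error with advice to rotate; since both deposited plastomes and
  every genome this package generates follow the standard LSC-IRb-SSC-IRa
  convention, origin-spanning repeats are unreachable in practice, and
  silent rotation would complicate every downstream coordinate.

Coordinates are 0-based half-open internally; every written table is 1-based
inclusive (BED output stays 0-based half-open, as BED requires).

## Alignment

Events are read off a global pairwise alignment. The package accepts an
externally produced alignment (aligned FASTA or Clustal) — the route used
when reproducing published counts, which historically came from manually
adjusted alignments — or aligns internally with an affine-gap
Needleman-Wunsch (Gotoh three-state) aligner written in C++.

Scoring defaults are match `+1`, mismatch `-2`, gap `-5` to open and `-2`
per additional base (`gap(k) = -5 - 2(k-1)`). Affine penalties matter: a
94-bp deletion must align as a single gap run, not fragment into many small
ones. Tie-breaking is deterministic — substitution preferred over gap, gap
in the second sequence over gap in the first — so identical inputs always
give identical alignments. `N` scores 0 against anything and is excluded
from all downstream counting.

For two ~30 kb congeneric sequences a full dynamic-programming matrix is
wasteful, so the aligner runs inside a diagonal band (default: exhaustive
below 2 kb; `2|n-m| + 400` columns above). The band is far wider than the
cumulative indel offset of congeneric plastomes; the test suite checks the
banded result against an exhaustive enumeration oracle on short pairs and an
independent full-matrix implementation on longer ones, and against
`Biostrings::pairwiseAlignment` as an external reference.

## Microsatellites

`find_ssrs()` reports maximal exact tandem repeats of 1-bp motifs at
`mono_min = 8` units or more and 2-bp motifs at `di_min = 4` units or more,
on the given strand (an A-run and a T-run are distinct motifs). A "di"
repeat whose motif is a homopolymer is counted as a mono run. Dinucleotide
stretches of odd length are trimmed to whole units, left-anchored, so span =
motif length x unit count always holds; where a qualifying mono run and di
repeat overlap, the longer span is reported (ties to the mono run).
Compound or interrupted repeats are not merged, and 3-bp and longer motifs
are out of scope.

The thresholds are exposed rather than hard-coded because published SSR
tables for this kind of comparison sometimes include loci below the stated
floor in one genome of the pair (reported-if-either-qualifies conventions
vary); with the thresholds as parameters the caller can reproduce either
convention explicitly.

## Mutation events

Calling runs as a cascade — inversions first, then indels, then SNPs — so
that no alignment column is counted twice:

1. **Micro-inversions.** A run of mismatching, gap-free columns is grown
   outwards (smallest window first, up to `max_inv_len = 50`) and reported
   as an inversion when the second row equals the reverse complement of the
   first over the window and the window holds at least `min_mismatches = 2`
   mismatches. Internal matching columns are allowed — palindromic positions
   of an inverted segment coincide by construction. The two-mismatch floor
   means a single mismatching column is always a SNP, never a "1-bp
   inversion". Consumed columns are masked from the later stages.
2. **Indels.** Each maximal gap run in either row is one event: gap in the
   reference row = insertion (the other genome carries the bases), gap in
   the other row = deletion. Events are left-normalized (the gap slides left
   while the preceding base equals the last motif base, rotating the motif),
   giving canonical positions inside repeat tracts. An event is an
   SSR-slippage indel when its motif is a whole number of units of a
   microsatellite locus overlapping the site in either genome and the longer
   allele meets the SSR threshold; everything else is non-SSR.
3. **SNPs.** One event per remaining column where both rows carry unequal,
   unambiguous bases; classified as transition/transversion, into the six
   non-strand-specific base-pair classes, and the three GC classes
   (AT&harr;TA, CG&harr;GC, GC-changing).

Adjacent mismatch columns are separate SNPs (unless consumed by an
inversion): multi-nucleotide substitution events are not modelled, matching
the per-site counting convention of the comparative literature. Events
localized in the inverted repeats are counted once with IRa/IRb pooled into
a single "IR" class in the summaries.

## Coding effects

Protein-gene SNPs are classified synonymous/non-synonymous by splicing the
reference CDS (exons concatenated in strand order, reverse-complemented for
minus-strand genes), substituting *only the SNP under consideration* (other
nearby variants held at reference — the per-site convention again), and
comparing amino acids under the plastid/bacterial genetic code (NCBI table
11; the amino-acid map matches the standard code, and start codons get no
special casing). Multiple SNPs in one codon are therefore scored
independently against the reference codon.

"Coding" defaults to protein-gene exons; SNPs in tRNA/rRNA exons can be
included in the coding/non-coding split via `coding_includes_rna`, but never
receive an S/N call. Per-gene tables group genes into four functional
categories (photosynthetic apparatus, photosynthetic metabolism, gene
expression, other) via a YAML map; the shipped default covers the standard
plastid gene inventory, and unmapped genes fall into "other" with a warning.
For every gene, Ts+Tv must equal S+N — each coding SNP receives both
classifications — and the suite enforces this identity.

## Nucleotide diversity

`window_pi()` slides windows of `window_len = 600` columns at `step = 200`
over **alignment columns** (not reference coordinates), computing for each
window the mean over row pairs of differing sites / valid sites, where a
valid site has unambiguous bases in both rows of the pair. Gap-containing
pair-sites are excluded from numerator and denominator alike — the closest
well-defined analogue of the classic sliding-window diversity computation
when the gap handling of the original tooling is not specified. The trailing
partial window is dropped; window midpoints are reported both in columns and
(via the coordinate map) reference coordinates, so profiles can be drawn on
either axis.

The summary statistic is the **per-window mean** of Pi, matching the
sliding-window framing; a per-site alternative (`pi_overall()`) is exposed
for callers who prefer total-differences / total-valid-sites. With three
rows the same definition averages over the three pairs, and the documented
thresholds are `0.008` for within-genus hotspots and `0.015` for
between-genus ones. Hotspots are maximal runs of consecutive windows
strictly above threshold, merged and labelled with the genes, introns and
spacers they overlap on the reference annotation.

## The synthetic generator

`make_genome()` builds a reduced-scale plastome — LSC 20 kb, IR 4 kb x2,
SSC 5 kb, 40 genes, ~15 planted SSR tracts by default — with exact repeats,
frame-consistent CDSs (ATG start, stop end, no internal stops, ~25%
two-exon, ~40% minus-strand), tRNA/rRNA genes, and maximality-guaranteed
SSR tracts (flanking breaker bases prevent chance extension). The reduced
scale keeps a full alignment-plus-calling cycle around a second per pair
while preserving every structural feature the pipeline must handle.

`mutate_genome()` derives a second genome under a `make_spectrum()`
specification. The default spectrum is the package's study condition: 50
substitutions with transition fraction 0.5, 10 SSR-slippage indels (planted
tracts change by 1-2 units), 10 non-SSR indels with a size distribution
mirroring the observed plastome indel spectrum (mostly 1-7 bp, with rare
21/22/94-bp events), and one 5-bp micro-inversion, all footprints at least
`min_spacing = 20` bp apart. Placement constraints make exact recovery a
fair test rather than a lucky one:

* events avoid planted SSR tracts (other than the tracts being mutated), so
  slippage classification cannot be confounded;
* non-SSR indel motifs are constrained against their flanks and against
  1-/2-bp periodicity, so they cannot masquerade as slippage;
* inversion segments mismatch their reverse complement at every position
  *and* the reverse complement is not a 1-3 bp rotation of the segment —
  otherwise the optimal alignment explains the change as two small indels
  and the event is genuinely ambiguous rather than miscalled;
* only a small fixed share of events (`ir_event_fraction = 0.03`) may fall
  in the inverted repeats, reflecting how conserved the IRs are relative to
  the single-copy regions (and keeping the derived genome's maximal exact
  repeat pair detectable at reduced scale);
* ledger indel positions are left-normalized with the same rule the caller
  uses, so homologous placements compare equal under the ±2 bp matching
  tolerance of `score_recovery()`.

Annotation coordinates are lifted over exactly by interval arithmetic. All
randomness flows from the spectrum's single seed; two runs with the same
seed are byte-identical. A "hard mode" is available by simply lowering
`min_spacing`, but interacting events have no unambiguous ground truth and
are excluded from the recovery claims.

What the generator does **not** emulate: rate heterogeneity along the
molecule (real hotspots arise from locally elevated rates; the generator
places events uniformly), recombination, compound/interrupted
microsatellites, and base-composition skew. Passing the recovery suite
therefore demonstrates the correctness of the calling machinery on
well-separated events, not calling performance on clustered real-world
variation — which is why the published-accession reproduction is kept as a
separate, data-dependent check.

## Numerical and formatting choices

* Pi is written at 5 decimals and percentages at 2, so golden-file
  comparisons are stable and output matches the precision such studies
  print.
* Windows with no valid site get Pi = 0 plus a flag rather than NaN.
* Empty event sets summarize to zero counts with a logged note; the
  percentage denominators are never zero-divided.
* `score_recovery()` with no calls of a type reports precision 1 with a
  `no_calls` flag (a no-call set makes no false claims), and recall 0.
* Reported seeds must stay below 2^31; the acceptance script derives
  per-replicate seeds as `seed * 1000 + k`.

## Problem sizes used by the test and acceptance runs

The test suite and the acceptance script run entirely on generated data:
33-kb genome pairs under the study spectrum (20 independent seeds for the
round-trip experiment), 2-kb repeat-enriched sequences against the
quadratic SSR oracle, 1000 random coding SNPs against the whole-protein
translation oracle, and sub-10-bp sequence pairs against the exhaustive
alignment oracle. These sizes exercise every code path — multi-exon genes,
minus strands, both repeat classes, all event types — while a full suite
run stays in the tens of seconds.

## Known limitations

* The partition detector requires the standard linear orientation and
  reports approximate region boundaries for heavily IR-mutated inputs
  (exact for pristine ones).
* Reproduction of published event counts is alignment-sensitive: a manually
  adjusted alignment can shift indel/SNP counts by small amounts relative to
  any fully automatic alignment, which is why published-count checks carry a
  ±3 tolerance while structural lengths are exact.
* tRNA structure prediction, de-novo annotation and rearrangements beyond
  micro-inversions are out of scope.
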