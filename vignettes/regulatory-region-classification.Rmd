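---
title: "Methods: classifying distal regulatory regions and validating against planted truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying distal regulatory regions and validating against planted truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Plant genomes mark active transcription start sites and enhancers with
H3K27ac, while H3K4me1 tracks gene bodies. `distalreg` operationalizes the
resulting decision rule for a distal H3K27ac peak — one whose edge-to-edge
gap to the closest annotated gene is at least 2 kb:

1. **H3K4me1 proximity.** If an H3K4me1 peak lies within 1 kb of the peak
   (overlap counts, the gap is edge-to-edge), the region likely reflects an
   unannotated or misannotated gene: the 1 kb allowance covers the distance
   between a TSS and the H3K4me1-marked gene body downstream of it.
2. **Strand-resolved transcription.** Within the peak, each strand's
   coverage area divided by the read length estimates the number of reads
   produced from that strand. A strand is called expressed at `min_reads`
   estimated reads or more, and the two strand calls collapse to
   *bidirectional*, *unidirectional* or *none*. Bidirectional, capped,
   short transcripts are the signature of enhancer RNAs.

The cross of the two axes yields six classes. The collapse of
`plus_only`/`minus_only` into *unidirectional* is the only lossy step; raw
per-strand estimates stay on every record so the call can be re-thresholded.

## Assumptions

* Coverage tracks are non-negative, strand-split, and expressed on the same
  genome assembly as the peaks. Stranded coverage is stored run-length
  encoded per chromosome (`stranded_signal`), with the library's read
  length carried alongside for the area-to-reads conversion.
* All interval operations are strand-blind (peaks are unstranded).
* Internally every interval is a `GRanges` (1-based closed, the
  Bioconductor convention). BED-family inputs (0-based half-open) are
  converted at the parse/write boundary; GFF3 passes through natively.
  Using one internal convention eliminates off-by-one drift; all the
  half-open edge cases (e.g. BED `(0,10)` vs `(10,20)` do not overlap) are
  tested explicitly.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| distal threshold | 2000 | bp edge gap, inclusive | "at least 2 kb from the closest gene" applied to peak boundaries, not midpoints or summits |
| H3K4me1 window | 1000 | bp edge gap, overlap included | TSS-to-gene-body distance allowance |
| `min_reads` (RNA) | 5 | estimated reads per strand | transcription evidence is never quantified as a coverage threshold in the source datasets; an estimated-read count is depth-robust and explicit. Raising it is monotone: *none* never shrinks, *bidirectional* never grows |
| `min_reads` (RAMPAGE) | 2 | estimated reads per strand | cap-selected libraries are shallower than total RNA-seq |
| mappability `k` | 150 | bp | single-end read length of the tiling used to define mappable space |
| metaprofile flanks / bins | 5000 / 50 | bp | conventional metaplot scales; the exact bin geometry of published figures is not stated, so these defaults are documented rather than claimed to match |
| boundary `edge_bp` | 500 | bp | the scale of RdDM-targeted mCHH islands at enhancer borders |
| DEG threshold | FDR < 0.05, no fold-change floor | — | the upstream DE fits publish FDR; both knobs are exposed |

# Distances, overlaps, and their edge cases

Distance is the edge-to-edge gap; any overlap gives 0. `GenomicRanges::distance`
also returns 0 for book-ended intervals (gap of zero bases), so "distance
0" and "overlaps by at least 1 bp" coincide except on that measure-zero
case — the same semantics as `bedtools closest`. Queries on chromosomes
with no reference get `Inf`, a supported value, not an error. Multi-sample
intersection tables merge the union of peaks by single-linkage with a
minimum 1 bp overlap (book-ended peaks are *not* merged), and membership is
evaluated against the merged regions; this makes the upset counts
deterministic and order-invariant. Feature annotation is prioritized
gene > TE family > near-gene intergenic > distal intergenic, with TE ties
broken by largest overlap then lexicographic family name.

# Mappability and random controls

Aligner-based mappability is emulated by exact k-mer uniqueness: the genome
is tiled into non-overlapping 150 bp bins and a bin is mappable when its
sequence occurs exactly once in the genome considering both strands and
contains no N. This is deterministic and dependency-free; it is slightly
stricter than a mismatch-tolerant aligner (a bin whose duplicate carries
one mismatch is unique to an aligner at high MAPQ but also unique here, and
a bin equal to its own reverse complement counts twice and is masked).
Control regions are placed uniformly over every start position at which the
whole control fits inside a single mappable run, conserving the count and
length multiset exactly — the behaviour of shuffling with an include mask.
Controls may overlap each other (the upstream tool's default; a flag
forbids it via rejection sampling) and are not confined to their source
chromosome. Placement is deterministic given a seed.

# Metaprofiles and the boundary statistic

Scaled-region profiles rescale each interval body to a fixed number of bins
using cumulative-sum interpolation, which is exact under fractional-bp
weighting — intervals shorter than one bin are handled without special
cases. Flanks are binned at fixed width. Positions beyond a chromosome end
are missing values excluded from bin means, not zero-filled, avoiding
artificial boundary dips. The boundary-enrichment ratio compares mean
signal within `edge_bp` of each boundary (inside body bins, counted
per-row from that row's interval width, plus outside flank bins) to the
mean over the remaining interior body bins; a flat track gives exactly 1,
and an interior mean of zero yields `Inf` with a message.

# Statistics

Class-wise activity comparisons use the two-sided Welch *t* test
(`stats::t.test`, unequal variances); the test suite verifies the statistic
against the closed-form expression to 1e-10. Loop-linked gene expression is
compared on log2(RPKM + 0.1) against two seeded backgrounds: uniformly
random genes, and random genes overlapping any loop anchor; 100 repeated
draws of the linked-set size summarize the background as a median of draw
means. Degenerate cases are explicit: two identical distributions report
p = 1; a class with fewer than two members is excluded from pairwise tests;
empty classes report `NA` fractions rather than 0.

# What the synthetic generator emulates — and what it does not

`generate_dataset()` builds a genome of fixed-pitch 30 kb units on
10 chromosomes (600 units), each carrying one gene, and plants:

* six enhancer classes at 100 peaks each, all placed ≥ 2 kb from genes by
  construction, with H3K4me1 peaks 100–800 bp away for the K4me1+ classes;
* per-strand read counts of 15–30 on expressed strands, realized as
  idealized uniform coverage (count × read length / width), so calls are
  exact at the default threshold of 5;
* 24nt siRNA signal with class-specific boundary factors (3× for
  bidirectional, 2× unidirectional, 1× none) over 0.2 background —
  the RdDM-island contrast against shuffled controls;
* TFBS, capped-RNA, conserved-element evidence at class-specific rates,
  reporter activity at class-specific means (bidirectional > unidirectional
  > none);
* 300 chromatin loops wiring enhancers to their unit's gene, whose RPKM is
  shifted +1.5 log2 units in the loop tissue;
* pairwise DE tables over five tissues with exactly 150 pollen-specific
  up-regulated genes (and smaller planted sets), where non-planted genes
  receive at most three non-ns pairings so chance tissue-specificity is
  impossible;
* a conservation flow drawn per reference DEG from a 3-way multinomial
  (conserved 0.6 / homolog-not-DEG 0.3 / no-homolog 0.1) — drawn over all
  reference DEGs so the recovered percentage estimates 60% directly;
* 50 small-RNA clusters, 10 of them hairpin-like (3 kb span, 95% strand
  bias, 70% 22nt), over a genome-wide 21:22:24 = 1:3:6 read mixture
  realized exactly;
* 40 telomere repeat copies per chromosome end, with chance motif
  occurrences scrubbed from the terminal windows so the planted copy number
  is exact.

Counts are exact wherever the configuration states a count and sampled
wherever it states a probability. The whole bundle is deterministic in one
seed, and serializes to plain-text standard formats with its truth tables.

What it deliberately does **not** emulate: realistic TE sequence models
(the background is i.i.d. uniform ACGT, so 150-mer collisions are
negligible outside planted repeats and mappability truth is controllable);
read-level noise (coverage is an idealized pileup, not a read simulator);
biological correlation between evidence layers beyond the planted
class-conditional rates; genome-scale gene density. Passing tests on this
bundle therefore demonstrate the correctness of the operations and the
recoverability of planted structure, not performance on real, noisy,
repeat-rich data.

# Problem sizes

The bundled analyses run on a 18.2 Mb genome (10 × 1.82 Mb), 600 genes,
600 enhancers, 2,000 reference DEGs, ~25,000 small-RNA reads and 10,000
control placements; mappability cross-checks use 50 kb genomes with planted
300 bp duplications. These sizes keep every planted rate at least two
binomial standard errors away from its decision boundary while remaining
desk-scale. Replication-scale inputs (full maize peak sets, OCR/loop/
activity tracks from public accessions) flow through the same interfaces.

# Known limitations

* The k-mer mappability surrogate ignores mismatch-tolerant multi-mapping;
  masks from a real aligner can be supplied via `mask_from_intervals()`.
* Hairpin flagging is a heuristic on span, strand bias and 22nt fraction;
  it does not fold RNA and will not separate a true inverted repeat from a
  strand-biased cluster of the same composition.
* Telomere copy numbers are per-window, assembly-based counts and
  systematically underestimate true telomere length.
* "In a loop" means overlapping either anchor; records strictly between
  anchors are reported separately to disambiguate the looser usage.
* Whether peak–OCR style intersections should require more than 1 bp of
  overlap is exposed as `min_bp`; 1 bp is the default.
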