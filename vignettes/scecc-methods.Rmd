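---
title: "Methods: detecting and classifying eccDNA in single cells with scecc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying eccDNA in single cells with scecc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`scecc` implements a computational pipeline for single-cell
circle-enrichment sequencing of extrachromosomal circular DNA (eccDNA).
In this assay, linear DNA is digested with an exonuclease, the surviving
circular molecules are amplified by rolling-circle amplification (RCA),
and each cell is sequenced as a paired-end library. Computationally,
circles leave two signatures in the alignments: contiguous runs of
strongly enriched coverage over the circle's genomic template, and
chimeric reads that span the circle's closure point. This vignette
documents the statistical model, the notation, and the methodological
decisions behind each module.

## Coverage model and CPR detection

Per-cell alignments are deduplicated (same 5' unclipped positions of a
pair, highest total mapping quality kept) and binned into fixed windows
(`bin_size = 100` bp). A bin is *enriched* when its read count reaches

    max(min_cov, enrichment_factor * background),

where the background is the `background_quantile` (default 0.5) quantile
of the bin counts across the nuclear genome, **including empty bins**.
After digestion most of the genome carries essentially no reads, so this
quantile is near zero and the floor `min_cov = 5` does the work; in a
poorly digested, high-background library the quantile rises and the
`enrichment_factor = 4` scaling takes over. The quantile is deliberately
computed over all bins rather than nonzero bins only: when circles
occupy a sizable fraction of the genome, the nonzero bins are dominated
by the circles themselves and a nonzero-only quantile would estimate the
signal instead of the noise floor.

Maximal runs of enriched bins are merged across gaps of up to
`merge_gap = 1000` bp, and each region's borders are refined to the
outermost bin whose count is at least `edge_fraction = 0.1` of the
region's maximum. Regions shorter than `min_cpr_length = 200` bp are
dropped. The resulting intervals are *circle-producing regions* (CPRs).
The mitochondrial contig and spike-in contigs are excluded from nuclear
CPR calling but analyzed separately for normalization and QC.

## Chimeric reads and junctions

Reads supporting the circular topology are split into:

* **Split reads** — primary alignments carrying an `SA` tag; the clipped
  end of the primary and the facing clipped end of each supplementary
  alignment define a junction's two breakends.
* **Discordant pairs** — inter-chromosomal pairs, same-orientation
  (tandem) pairs, everted pairs (leftmost read on the reverse strand —
  the orientation produced by a pair straddling a circle junction), and
  pairs with insert size above 1 kb.

Read pairs in tandem orientation with read 2 mapped upstream of read 1
are a known library artifact of RCA chemistry and are dropped by
default (`drop_r2r1 = TRUE`); the filter is exposed as an option because
the artifact's prevalence is protocol dependent.

Raw junctions are canonicalized (breakends in genome order) and
clustered by single linkage: two raw junctions join the same cluster
when *both* breakends lie within `window = 500` bp of each other.
Clusters with fewer than `min_support = 2` reads are discarded. The
cluster representative is the support-weighted median of each breakend —
a robust choice for stray split positions; the mean would be pulled by
outliers. Junctions are assigned a span class relative to the CPR
catalog: `edge` (both breakends within 500 bp of one CPR's
extremities), `internal`, `distal_intra` (same chromosome, > 1 Mb
apart), or `inter`. A CPR is structurally `simple` when all of its
junctions are edge-joining and there are at most two of them (the two
strand representations of one closure), `complex` otherwise, and
`unclassified` with no junction evidence.

## Population classification model

Let a population have \(N_{tot}\) cells and let \(R\) be a pseudo-bulk
CPR called from the pooled alignments. The model scores \(R\) with:

* **Frequency of occurrence**
  \(f_{raw} = N_{pos} / N_{tot}\), where a cell is positive when at
  least one of its CPRs overlaps at least 10% of \(R\)'s length.
* **Uniformity (mean Jaccard)**
  \(J_{raw} = \frac{1}{N_{tot}} \sum_i J(R, C_i)\), where \(C_i\) is the
  union of cell \(i\)'s CPRs overlapping \(R\) (Jaccard 0 when none
  overlaps).
* **Mitochondrial normalization** — the mitochondrial genome is a bona
  fide circle present in every cell, so its frequency \(f_{mt}\) and
  Jaccard \(J_{mt}\) (whole contig vs per-cell detected regions) give a
  ceiling: \(f_{norm} = \min(1, f_{raw}/f_{mt})\),
  \(J_{norm} = \min(1, J_{raw}/J_{mt})\).
* **Uniformity score** \(U = f_{norm} \cdot J_{norm}\).

Quadrant labels use strict thresholds: high frequency iff
\(f_{norm} > 0.65\) and high uniformity iff \(U > 0.3\), giving HFHU,
HFLU, LFHU and LFLU. The normalized frequency (not the raw one) is used
in the quadrant rule by default (`use_normalized = TRUE`): the published
thresholds are calibrated against the mitochondrial ceiling, and using
\(f_{raw}\) would make labels depend on how completely the
mitochondrial circle itself is detected. The whole classification is
validated against an independent brute-force oracle that recomputes
every quantity by integer position-set arithmetic.

## QC metrics

Per cell: mapping rate; circular spike-in fraction (reads on the
circular spike-in contig over all spike-in reads — a measure of how
completely linear DNA was removed); number of CPRs; and a mappability
proxy (fraction of primary reads with mapping quality above 20, standing
in for external mappability tracks). Thresholds follow the published
rules: 0.90, 0.80, 100 CPRs and 0.70. The default combination rule fails
a cell on *any* violation; `rule = "all"` implements the lenient
reading in which only a cell violating every criterion fails. Both are
provided because printed protocol text joins the rules with "and",
which is ambiguous between the two readings; the strict rule is the
default and is logged in the QC reasons.

## Landscape statistics

The downstream statistics are deliberately simple, testable estimators:
coverage autocorrelation over genomic distance with a coordinate-shuffle
null; GC content of CPRs against length- and contig-matched background
intervals (rank-sum test); scaled-region meta-gene profiles; annotation
overlap with circle-read-weighted feature fractions; across-cell
co-occurrence (Pearson) against an anchor region; eccDNA-expression
correlation on log1p-transformed matrices; copy-number-stratified CPR
density per 100 kb of class territory; and Euclidean distances between
cells restricted to one quadrant class (e.g. daughter-cell HFHU
vectors). Group comparisons use the two-sided Wilcoxon rank-sum test
with Benjamini-Hochberg adjustment rather than count-model machinery:
the compared quantities are bounded fractions over few samples, where a
rank test's exactness matters more than shrinkage.

## Topic model

Cells are documents, fixed 2-kb genomic bins the vocabulary, circle
reads the tokens. A latent Dirichlet allocation model with symmetric
priors \(\alpha = 50/K\), \(\beta = 0.1\) is fitted by collapsed Gibbs
sampling (implemented in C++, driven by R's RNG so fits are
seed-reproducible). LDA was chosen over heavier topic frameworks because
the collapsed sampler is small enough to verify directly and has no
external model dependencies. The number of topics is selected on a grid
by the discrete second derivative of the final log-likelihood (the
elbow); a flat curve falls back to minimum perplexity. Recovery is
validated on planted partitions scored by the adjusted Rand index.

## Simulator

The bundled simulator emits alignments directly — no read aligner is
involved — so every record's CIGAR, `SA` tag, mate fields and flags are
exact consequences of the planted truth, and all validation is
deterministic given a seed. Reads are drawn uniformly on the circle
(positions modulo the circle length); a read crossing the closure point
becomes a soft-clipped primary plus supplementary records, and a pair
straddling it comes out everted. Per-circle RCA unevenness is modeled as
a lognormal depth multiplier. All planted segments are emitted on the
'+' strand: strand randomization would not change any quantity the
pipeline measures (coverage, breakend positions, pair orientation
classes are strand-symmetric), so it is left out of scope, as are
sequencing-error models beyond uniform substitutions and multi-sample
barcode structure. Default design parameters (20 cells, a 1-Mb nuclear
genome, 50 singleton circles per cell, 30x circle depth, 0.1x linear
background) describe a desk-scale population that exercises every code
path in minutes; they are the package's own choice of problem size, not
a claim about any particular dataset.

## Reproducibility

Every stochastic function takes an explicit seed; `simulate_population`
writes a manifest with md5 checksums and reruns are byte-identical. The
script `scripts/acceptance.R` regenerates the package's headline
simulation numbers from a single `--seed`.
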