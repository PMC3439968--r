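---
title: "Methods: crosslink calling, permutation FDR, motifs and RNA maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosslink calling, permutation FDR, motifs and RNA maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iclipr)
```

## The measurement model

iCLIP reads report protein–RNA contacts indirectly: reverse
transcription truncates at the crosslinked nucleotide, so a CLIP-tag
aligned at genomic interval `[start, end)` implies a crosslink at
`start − 1` on the `+` strand and at `end` on the `−` strand (the
strand mirror of the same rule; the package treats the half-open `end`
coordinate as "one base past the highest aligned base", so the `−`
crosslink is the base immediately 5' of the read start in read
orientation). Random barcodes (UMIs) embedded in the sequencing primer
identify unique cDNA molecules; deduplication keeps one event per
(contig, strand, crosslink position, barcode), deliberately collapsing
truncation-length variants of the same molecule, because an iCLIP event
is defined by its truncation position, not by the read span. Barcodes
containing `N` are kept distinct rather than fuzzily matched — a
conservative choice that never over-collapses.

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted on read and reproduced exactly on write, which
makes coordinate handling testable as a round trip.

## Permutation FDR for sites and clusters

The null model re-places every event of a *co-transcribed region*
independently and uniformly within it. Co-transcribed regions are
strand-specific unions of overlapping annotated gene spans: the
shuffling domain should be transcribed sequence, and merging overlapping
genes avoids arbitrarily splitting events between them. Events in
unannotated space have no region to shuffle within and are reported
unscored.

For each region and count height *k*,

> FDR(k) = mean over permutations of #{positions with randomized count ≥ k} / #{observed positions with count ≥ k},

clipped to [0, 1]. The raw ratio is not guaranteed monotone in *k*
(both numerator and denominator shrink), so it is made non-increasing
by a running maximum from the highest height downward — the
conservative direction: a taller pile never becomes *more* significant
than its raw estimate, a shorter one may become less. Significance is
strict (`fdr < threshold`, default 0.05).

Clusters merge significant sites with inter-site gaps ≤ 15 nt; the
cluster statistic is the **total member-site count** (not the member
count — an open choice documented here), tested with the same
permutation machinery: per permutation, positions reaching the region's
minimal significant height count as null significant sites and are
merged with the same gap rule. This is equivalent to literally re-running
site calling on each randomized dataset — a randomized region has the
same event count and length, hence the same height threshold — without
requiring nested permutation ensembles. The per-region FDR controls
per-region error; accordingly the package's null-calibration checks
measure the fraction of *regions* yielding a false positive.

Ties, degenerate inputs: a region of length 1 forces all events onto
one position (its FDR is then ≈ 1 since the null reproduces it);
`n_perm < 1` errors; permutations are reproducible given `seed`.

## Pentamer Z-scores and consensus

Each unique crosslink position (weight 1.0, regardless of tag count)
contributes the set of distinct pentamers whose full 5-nt span lies in
the windows [−30,−10] or [+10,+30] in transcript orientation — once per
site even if a pentamer occurs in both windows. The excluded core
(−9..+9) avoids the uracil run at the crosslink itself, which otherwise
dominates any enrichment statistic. Full-span containment is the
strictest consistent reading of the window endpoints; a `span =
"start"` flag implements the alternative (first base in window) for
sensitivity analysis.

The null re-places each site uniformly within its gene (the longest
containing same-strand gene, ties broken by gene id) 100 times;
`z = (observed − null mean) / null sd`, with `z = 0` when the null is
degenerate and matches the observation, `±Inf` flagged otherwise.
Internally, pentamers are mapped to integers via a precomputed
per-contig index (forward and reverse-complement), making 100 shuffles
of thousands of sites a few vector operations each. The consensus
stacks the top five pentamers unweighted into a 4 × 5 frequency matrix
(columns sum to 1) with an IUPAC string from the nonzero bases; motifs
are reported in the RNA alphabet.

## RNA maps

Raw positional histograms around splice sites confound binding with the
genome-wide length distribution of exons and introns: short features
make near-junction offsets look enriched. The normalizer counts, for
every offset, the number of junctions whose *relevant feature half*
(`floor(length/2)` nucleotides adjacent to the boundary) spans that
offset; density is `1000 × raw / normalizer` — crosslinks per 10³ nt.
Junctions with exons < 60 nt or introns < 200 nt are excluded; each
crosslink is assigned to its closest retained boundary, with
equidistant ties going to the downstream boundary in transcript
orientation (a deterministic convention; the data model is
genomic-contiguous, so exon–exon junction reads are not modelled).
Offsets run −300..+300, negative upstream.

Branch points come from an external candidate table (predictions with
SVM scores) — no predictor is implemented. Selection: drop introns
< 240 nt; drop candidates with negative scores or outside the last
intron half; take the best score, ties to the candidate closest to the
3' splice site; discard selections closer than 20 nt to it. The
branch-point profile normalizes over last-half footprints with the
branch point at offset 0.

Smoothing uses a discrete Gaussian kernel with support ±5 and
σ = half-width/2 (the stated "half-width" is read as the kernel
support; `sigma = half_width` switches to the σ reading). The kernel is
renormalized over defined neighbors at profile edges and across
normalizer gaps, so mass is conserved wherever no truncation occurs.
The per-offset denominator is the junction count; multiplying by 10³
makes it the "per 10³ nt" convention, and both `raw` and `normalizer`
columns are exposed so either convention can be recovered.

## RNA classes

Each event is assigned to exactly one class by a fixed priority —
scaRNA > snoRNA > lincRNA > other ncRNA > CDS exon > 5'UTR > 3'UTR >
intron > intergenic — strand-matched, so snoRNA/scaRNA genes nested in
host-gene introns are reported as ncRNA hits and antisense events fall
through to intergenic. Class lengths are computed on the same
priority-partitioned, merged intervals (no nucleotide counted twice);
fold enrichment is the class density relative to the genome-average
density, so classes that tile the genome average to 1.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with every draw seeded (independent streams per stage: genome, events,
tag emission). Defaults are sized for desk runs: 2 contigs × 1 Mb, 150
genes, ~2 × 10⁴ events (13 000 binding positions with geometric
multiplicity of mean 1.5). Gene models use log-normal exon (median
300 nt) and intron (median 1 kb) lengths, a Poisson exon count, 12%
ncRNA genes across subclasses and 10% intronless histone-like genes
(CDS with a short 3'UTR); per-gene expression weights are log-normal.
Every multi-exon intron ≥ 100 nt receives 1–3 fabricated branch-point
candidates with Normal(1, 1) scores in its last half, so the selection
filters are exercised, including negative scores.

Design choices worth recording:

* **Motif planting rewrites sequence locally** rather than rejection
  sampling, so the planted fraction is exact and every rewrite is in
  the truth set. The pentamer is written with two flanking bases per
  side drawn from its own base composition: binding motifs of SR-type
  proteins are degenerate composition-biased stretches (CU-rich or
  GA-rich), and without composition-matched flanks the pentamers
  straddling the planted motif's boundary would carry one
  uniform-random base, contaminating the top ranks with off-composition
  shift variants that no real CU-rich binding landscape would produce.
  Rewrites never overlap each other (placements are resampled with
  bounded retries), so a planting cannot corrupt an earlier one.
* **Tag emission is the exact inverse of crosslink calling**: the tag
  start is one nucleotide downstream of the crosslink on the event
  strand, insert lengths are uniform in [40, 100] clipped to the
  contig, and the barcodes of molecules sharing a position are drawn
  without replacement, so deduplication plus pileup reproduces the
  truth exactly for any PCR duplication rate — the central end-to-end
  test has no stochastic slack.
* **Positional enrichments are mixtures**: a configured fraction of
  events is placed uniformly at the enriched offsets (5' splice-site
  window, branch-point window, histone ORF 3' ends at 14–50 nt). This
  gives the same positional law as rate-multiplier rejection sampling
  with an exact planted fraction.

What the generator does *not* emulate: sequencing errors, mapping
ambiguity, crosslinking sequence bias beyond the planted motif,
isoform-level structure (one transcript per gene), or overlapping
genes. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under the stated generative model, not
robustness to alignment artefacts or annotation ambiguity in real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations scaled to the
statistics they check: null FDR calibration pools 20 simulations of
2 000 events over 40 genes; cluster recovery plants 200-event clusters
over 50-event backgrounds in 10-kb regions across 20 seeds; motif
recovery uses 5 000 sites with a 30% planted fraction and 100 shuffles
across 20 seeds; RNA-map flatness uses dense uniform occupancy
(4 × 10⁵ events over ~50 genes) so that per-offset binomial noise stays
below the asserted coefficient of variation of 0.2 at normalizer ≥ 20.
Profile densities are `NA` where the normalizer is 0; smoothing
preserves `NA`s and renormalizes around them. FDR monotonicity is
enforced exactly (running maximum), cluster BED scores are
`round(1000 × fdr)` capped at 1000, and all RNGs are plain R streams
seeded per stage.

## Known limitations

* The FDR recipe is a reconstruction of the cited iCLIP statistics
  (the original is specified only by reference); it is documented above
  precisely so results are interpretable.
* Replicate merging, control-library subtraction and GO enrichment are
  out of scope.
* Multi-transcript genes pool exons/introns with duplicates collapsed;
  junction geometry keeps the longest flanking features at a shared
  boundary.
* `anchored_profile` assigns an item to its closest anchor when
  transcript footprints overlap, which undercounts items genuinely
  shared between transcripts.
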