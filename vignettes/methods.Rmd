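---
title: "Co-location networks for longevity GWAS: models and design choices"
author: "ColocNet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Co-location networks for longevity GWAS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Genome-wide association studies of *Drosophila* lifespan produce two kinds
of summary statistics: per-SNP haplotype-frequency tables from
evolve-and-resequence designs (a "synthetic" population bred from a small
set of inbred founders, with allele frequencies compared between
long-surviving and control flies) and per-SNP association p-values from
inbred reference panels (DGRP-style).  Most hits land outside genes, and
single-locus significance misses loci that act jointly.  ColocNet follows a
co-location strategy: loci that sit close together in the
three-dimensional nucleus — as measured by Hi-C contact frequency — are
analysed together.  The pipeline has four stages:

1. **GWAS filtering.**  For haplotype data the divergence statistic
   \(D = 100\sqrt{\sum_{j=1}^{n}(h_{O,j}-h_{Y,j})^2/n}\) is computed per
   SNP over the \(n\) founder haplotypes (old group \(h_O\), young control
   \(h_Y\)); SNPs with \(D > 7.9\) are significant.  For p-value data the
   cut is Bonferroni: \(p < \alpha/m\) with \(\alpha = 0.05\) and \(m\)
   the number of genomic bins (1,503 at 80 kb; 11,839 at 10 kb in the
   reference fly Hi-C data).  Both cuts are strict inequalities.  SNPs
   recorded twice at one position have their two groups' frequency vectors
   concatenated and renormalised, with \(n\) updated.

2. **Network construction.**  The genome is partitioned into 80-kb bins
   indexed contiguously across chromosomes (2L is bins 1–287 in the
   default fly-like layout).  Bins harboring at least one significant SNP
   become nodes of the *original* network; edges join node pairs whose
   normalized Hi-C contact frequency strictly exceeds a top-1% threshold.
   Thresholds are computed per chromosome (arms pooled: 2L+2R as "2",
   3L+3R as "3") for intra-chromosomal contacts, plus one
   inter-chromosomal threshold, each as the smallest observed positive
   frequency with at most 1% of entries strictly above it; self-contacts
   are excluded.  The *extended* network adds every bin that interacts
   above threshold with an original node (one round, no transitive
   closure).  Degrees, connected components, ego subnetworks, shared-node
   accounting (14 shared 80-kb bins span 1.12 Mb) and seeded Louvain
   communities at resolution 0.1 summarise the result.

3. **TAD-border enrichment.**  Published TAD border intervals are flanked
   by 100 bp on each side; non-coding SNPs falling in these boundary
   regions are counted and compared against 100 matched random control
   sets (same chromosome, same core width, flanked identically, rejected
   if overlapping any real flanked border).  Fisher's exact test on the
   2-by-2 table of in/out counts (observed vs replicate-averaged control)
   tests overrepresentation.  Genes carrying lifespan phenotypes are
   classified by proximity to mutated (SNP-carrying) vs non-mutated
   borders, using a 30-kb window: the 10-kb bin containing the border plus
   one bin on each side.

4. **Target mapping and reporting.**  At 10-kb resolution, each
   non-coding-SNP-harboring bin is paired with its strongest
   intra-chromosomal interactor (ties broken toward smaller distance, then
   smaller bin ID).  Bins whose strongest partner is non-adjacent
   (distance ≥ 2 bins) are "long-range"; pairs are ranked by frequency and
   the top 30 retained, with genes in the target bin listed.  Gene sets of
   clusters and subnetworks are tested for GO term enrichment with a
   one-sided hypergeometric test.

## The synthetic-data generator

All inputs are emulated by seeded generators so every stage is testable
without downloads.  Each generator draws from its own RNG stream derived
from the master seed, so outputs are byte-identical under a fixed seed and
adding a generator never perturbs another.

**Genome layout.** Fly-like arm lengths (2L 22.96 Mb, 2R 21.12 Mb, 3L
24.56 Mb, 3R 27.92 Mb, 4 1.28 Mb, X 22.40 Mb) chosen so 80-kb binning
yields exactly 1,503 bins with the canonical arm boundaries.

**Contacts.** Expected intra-chromosomal frequency is
\(C(1+d)^{-\gamma}\) with bin distance \(d\), scale \(C = 600\) and decay
\(\gamma = 1\); inter-chromosomal pairs sit at a constant baseline 2.  All
entries carry multiplicative log-normal noise (sdlog 1 at 80 kb, 0.5 at
10 kb).  This is the simplest model that makes adjacent-bin contacts
strongest and gives the heavy upper tail that top-percentile thresholding
assumes; with these values the computed top-1% thresholds land in the same
range as published fly Hi-C cutoffs (hundreds intra, ~20 inter).  Planted
modules (by default four blocks of ten contiguous bins on different arms)
have within-module expectations boosted 20-fold; planted long-range 10-kb
pairs at 50 kb and 100 kb separations are boosted 80-fold.  Self-contacts
are generated but never enter thresholding.  The 10-kb matrix is
intra-chromosomal only and band-limited to 100 bins (1 Mb), which covers
every distance the target-mapping stage inspects.

**Haplotype frequencies.** Per SNP, a founder base vector
\(b \sim \mathrm{Dirichlet}(50 \cdot \mathbf{1}_8)\) (eight founders,
concentrated around balanced representation); old and young vectors are
\(b\) plus independent sum-zero Gaussian noise with sd 0.03, clipped to
\([0,1]\) and renormalised (clipping is rare at these settings and is
logged).  Under this null, \(\sum_j (h_{O,j}-h_{Y,j})^2\) is exactly
\(2\sigma^2\) times a \(\chi^2_{n-1}\) variable, giving a closed-form tail
rate for \(D\) that the tests check against simulation.  With sd 0.03 the
null yields a few hundred significant bins per million SNPs, matching the
scale of original networks built from real data.  In planted bins the old
vector is pulled toward one founder by effect size 0.5, putting expected
\(D\) near 16, comfortably beyond 7.9.

**P-values.** Uniform(0,1) off-plant; inside planted bins 30% of SNPs are
pushed below one tenth of the Bonferroni cut.

**Annotations.** 2,847 TAD borders with cores of 100–500 bp, allocated
proportionally to chromosome length and kept disjoint even after
flanking; 15,000 genes with log-normal lengths (median 2 kb), phenotype
flags (90% none, 3% each long-lived/short-lived/increased-mortality, 1%
lethal) and GO terms from a fixed 20-term vocabulary.  Genes carrying the
planted longevity term ("determination of adult lifespan") are 85%
concentrated inside planted module bins, giving cluster-level GO
enrichment a recoverable truth.  Border SNP enrichment is planted by
adding extra uniformly placed SNPs inside flanked borders; the default
rate multiplier for the p-value dataset is 1.3, matching the observed
obs/control ratio in published fly TAD-boundary counts, and 1.0 (none)
for the haplotype dataset.

**Sizes.** The default tables carry 10^6 haplotype-frequency SNPs and
2×10^6 p-value SNPs, the scale of the source datasets.  What the
generator does *not* emulate: linkage disequilibrium between SNPs,
read-level sampling noise, real gene coordinates, sequence content, or
domain-level TAD structure in the contact matrix.  Passing tests
therefore demonstrate that the pipeline recovers signal of the planted
form at realistic size and noise, not that it would make identical calls
on any particular real dataset.

## Numerical and design choices

* **Threshold definition.** The cutoff is an order statistic over
  *positive* entries only (zero-inflated Hi-C matrices make quantiles over
  all entries meaningless): the smallest observed value with at most
  \(1-q\) of entries strictly greater.  "Strong" is strictly greater than
  the cutoff.  Recomputation is bit-for-bit reproducible.
* **Cross-arm contacts** (2L–2R, 3L–3R) are classed as intra-chromosomal
  for thresholding by default, since thresholds are reported per numbered
  chromosome; `crossArm = "inter"` switches to the per-arm reading.
* **Extension edges.** The extended edge set keeps added–added edges when
  above threshold; this is required for extended networks to form the
  large single components observed in practice.  `starExtension = TRUE`
  restores the strict added-to-original-only reading.  Extension is one
  round only.
* **Degree is unweighted** (the number of connections); weights are kept
  on edges and used by Louvain.  Louvain runs are seeded; the seed is
  recorded in the partition object.
* **Intervals** live in `GRanges` (1-based closed) inside the package;
  files use BED-style 0-based half-open coordinates.  Gene intervals are
  treated as closed for coding classification ("between gene start and
  end" inclusive); SNP positions are 1-based points.
* **Fisher sidedness.** The enrichment test defaults to one-sided greater
  (the hypothesis is overrepresentation), with `"two.sided"` available;
  on published fly TAD-boundary counts the printed p-value is the one the
  two-sided test reproduces.  The replicate-averaged control count is
  rounded half-up before entering the exact test, which needs an integer
  table.
* **Control borders** preserve each real border's core width (the
  conservative superset of the literal point-plus-flanks reading, which
  `pointBorders = TRUE` restores), are placed on the matching chromosome,
  and are rejected while overlapping any real flanked border, with
  per-replicate RNG substreams.
* **"Long-range"** is operationalised as a strongest interactor at ≥ 2
  bins, contrasting with the adjacent-bin dominance of decaying contact
  matrices; the seed set defaults to every bin with at least one
  non-coding SNP (most top pairs in practice involve non-significant
  SNPs), and ranking is by frequency descending.  Recovery of planted
  pairs is evaluated on the top distinct unordered pairs, as many as were
  planted: both orientations of a planted pair appear in the per-bin
  ranking, and trailing noise pairs below them are genuine lower-frequency
  calls rather than errors.
* **GO universe** defaults to the genes residing in the active network's
  nodes — the background implied by asking which *network* genes share a
  function; `universe = "genome"` switches to all annotated genes.  Raw
  hypergeometric p-values are reported; Benjamini–Hochberg is optional and
  off by default.  GO terms are flat labels (no DAG propagation).
* **Duplicate combining** renormalises the concatenated frequency vectors
  to sum 1 per group; the statistic is scale-dependent, so keeping the
  sum-to-1 invariant is the only choice that leaves singleton records and
  combined records on the same scale.

## Problem sizes used by the tests and the acceptance script

Unit tests run on toy layouts (tens of bins).  The community-recovery
check uses the full 1,503-bin layout with 10^5 haplotype SNPs per seed
over 20 seeds (median adjusted Rand index against the planted module
labels).  TAD calibration uses 200 null datasets of 3,000 uniform SNPs on
a two-chromosome layout with 20 control replicates; power uses the default
2,847 borders with 2×10^5 SNPs and a doubled border rate over 10–20
datasets.  The end-to-end determinism check and the acceptance pipeline
run the full default conditions (10^6 + 2×10^6 SNPs).  These sizes are the
package's chosen study conditions; the generator and pipeline accept
larger values unchanged.

## Known limitations

* Reported GO p-values depend on the chosen universe; external enrichment
  services use their own backgrounds, so printed p-values are not
  comparable across tools.
* The contact model has no TAD-level block structure, so TAD borders and
  the contact matrix are statistically independent in the synthetic data.
* Louvain is a heuristic; different seeds can move boundary nodes between
  communities (planted modules are robust to this, background bins less
  so).
* At 10-kb resolution the reference bin count (11,839) reflects bins
  observed in real data; the synthetic 10-kb layout bins the whole genome
  (12,024 bins) and uses its own count for Bonferroni correction.
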