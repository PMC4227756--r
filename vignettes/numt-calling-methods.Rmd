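---
title: "Detecting, genotyping and dating polymorphic numt insertions"
author: "numtcaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, genotyping and dating polymorphic numt insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtcaller)
```

## The problem

Fragments of the mitochondrial genome occasionally integrate into nuclear
chromosomes (nuclear insertions of mitochondrial origin, NumtS). Hundreds of
such fragments are fixed in the human reference assembly, but integration is
an ongoing process: insertions still segregating in the population are absent
from the reference, invisible to reference-based annotation, and can
masquerade as mitochondrial heteroplasmy when nuclear reads carrying
numt-specific alleles are mistaken for minor mitochondrial variants.

`numtcaller` finds these non-reference insertions in paired-end whole-genome
alignments, genotypes them across a cohort, tests their positions for
co-location with genomic features, estimates when each insertion occurred,
and screens their private alleles against reported heteroplasmy positions. A
deterministic simulator generates aligned fixtures with implanted fragments
so that every stage is testable without external data.

## Discovery model

An insertion that is present in a sample but absent from the reference
produces a characteristic alignment signal at the integration locus:

1. **Mito-anchored pairs.** Read pairs straddling a junction have one end
   uniquely mapped to the nuclear flank and the mate placed on the
   mitochondrial contig (or on a known reference numt, when the aligner
   prefers the older homologous copy). Anchors with MAPQ < 10 are discarded;
   this removes ambiguous placements at the cost of blindness inside
   low-mappability repeats, which is accepted and documented behaviour.
2. **Clustering.** Anchors sharing a chromosome and orientation are merged
   by single linkage whenever consecutive positions are within
   $W_L = \hat\mu + 3\hat\sigma$ of each other, where $\hat\mu$ and
   $\hat\sigma$ are the mean and standard deviation of the sample's outer
   insert length. The insert model discards the extreme 0.5% tail on each
   side before taking moments; chimeric pairs otherwise inflate
   $\hat\sigma$ and with it every clustering window. Forward-strand anchors
   flank the insertion from the left, reverse-strand anchors from the
   right.
3. **Linking.** A forward cluster is linked to the nearest downstream
   reverse cluster whose start is within $2 W_L$ of its end. When several
   reverse clusters are in range the smallest gap wins (ties to the
   leftmost forward cluster) and each cluster joins at most one link; the
   linking problem is small enough that greedy nearest-pair assignment is
   adequate. Unlinked clusters are kept as one-sided candidates, flagged
   imprecise unless split reads localize them.
4. **Breakpoints.** Soft-clipped reads inside the linked gap (padded by
   $W_L$) vote for the position where their alignment breaks; the modal
   position wins, ties to the leftmost, and at least two identically
   clipped reads are required. The clipped tail (at least 20 bp) must
   realign to the mitochondrial sequence — an ungapped scan over the
   doubled, circularized genome on both strands at 90% identity — before a
   site is marked precise. Tails matching nothing leave the site imprecise
   with the cluster-bounded interval as its confidence region.

Internally all coordinates are 0-based half-open and a call's `pos` is the
first reference base after the insertion; in VCF output this same number is
the 1-based position of the last base before the insertion, which is the
usual convention for insertion records. Mitochondrial coordinates are
treated as circular throughout: fragments may span the origin, which matters
for D-loop-containing and near-full-length events.

## Genotype likelihood

Read evidence at a site is summarized by the genotype likelihood
$$ L(g) = \frac{1}{m^k} \prod_{j \in \text{ref}} \big[(m-g)(1-e_j) + g e_j\big]
  \prod_{j \in \text{alt}} \big[(m-g) e_j + g (1-e_j)\big], $$
with ploidy $m$ (2 by default), $k$ the total number of reads, and $e_j$ the
per-read mapping error $10^{-\mathrm{MAPQ}_j/10}$ capped into
$[10^{-6}, 0.5]$ so a single read can neither dominate nor be less
informative than a coin flip. Reference-spanning reads (aligned continuously
across the breakpoint with at least 20 bases on each side and no clip of 20
bp or more) are most likely under $g = 0$; insertion-supporting reads
(anchors and split reads) under $g = m$. The factor assignment is chosen so
that error-free reference evidence maximizes $L(0)$ — the self-consistent
reading of the underlying SNP-genotyping framework. A useful identity falls
out of the algebra: for $m = 2$ every factor at $g = 1$ equals 1, so
$L(1) = 2^{-k}$ exactly, which the test suite exploits as an oracle-free
invariant.

Discovery reports a **Phred insertion quality**,
$-10\log_{10} L(0) / \sum_g L(g)$ under a flat prior, capped at 99.99 —
confidence that at least one insertion allele is present. Calls pass when
quality ≥ 50, insertion-supporting reads ≥ 4 and breakpoint coverage ≥ 5;
every violated criterion is named in the FILTER field. The **genotype**
reported in cohort mode is instead the maximum-posterior $g$ under a
Hardy–Weinberg prior.

## Cohort genotyping and EM allele frequencies

Across a cohort the breakpoint is first refined by pooling soft-clips over
all samples (modal identical break whose longest clipped tail realigns to
the mitochondrion). Per-sample likelihoods at the refined position then
enter an EM loop: the E-step computes genotype posteriors under the current
Hardy–Weinberg prior, the M-step re-estimates the insertion allele frequency
as the posterior-weighted mean allele count over $mN$ chromosomes, clamped
away from 0 and 1 by a pseudocount of $1/(2N+2)$. Iteration stops when the
frequency moves by less than $10^{-4}$ or after 10 iterations. The procedure
is deterministic given the inputs and in practice converges in 2–4
iterations.

## Enrichment testing

Insertion positions are compared against feature tracks with a two-tailed
permutation test: each null replicate redraws one position per observed
position on the same chromosome, uniformly over non-gap bases (the matching
covariate is chromosome only — a stated choice, not an inference). The
p-value uses the add-one correction
$p = 2\,(\min(\#\{T \ge t\}, \#\{T \le t\}) + 1)/(n+1)$, capped at 1, so it
is never exactly zero. The default statistic is the count of positions whose
flank intersects the track; mean flank GC percent and AT/TA dinucleotide
density are available as continuous alternatives. The tie-inclusive
two-tailed p is intentionally conservative on heavily tied discrete counts;
exact 5% calibration is the theoretical expectation (and is verified in the
tests) only for continuous statistics. Null overlap counting runs through a
vectorized sorted-interval path that is verified against the plain
interval-tree path.

## Insertion dating

The age of an insertion is estimated from diagnostic positions — alignment
columns where the modern human mitochondrial sequence differs from an
inferred ancestral primate mitochondrial sequence by substitution (indel
columns are excluded; they carry alignment ambiguity rather than dating
signal). Within the region a numt covers, the fraction of diagnostic
positions at which the numt carries the modern allele places the insertion
along the human lineage:
$$ \mathrm{age} = \left(1 - \frac{\mathrm{pct}}{100}\right) \times 6\ \mathrm{MY}, $$
with the matching percentage rounded to the nearest integer **half to even**
before the multiplication — both choices recovered from the arithmetic of
the published per-numt tabulations, which include the two half-way cases
7/8 = 87.5 → 88 and 37/40 = 92.5 → 92 and are only reproduced under this
rounding order. A numt matching the modern allele everywhere is reported as
"<0.1" MYA rather than 0; one covering no diagnostic positions is
undatable (NA). Hypervariable D-loop sites are not excluded.

Numt sequences are aligned to the modern mitochondrion with an affine-gap
alignment, global in the numt and local in a doubled copy of the circular
genome so origin-spanning fragments stay contiguous; both strands are
tried and 90% identity is required — below that a sequence is rejected as
not of recent mitochondrial origin. The same alignment yields the SNP
profile (substitutions relative to the mitochondrial reference, 1-based
mitochondrial coordinates) used for heteroplasmy screening: a reported
heteroplasmy is flagged as potentially numt-confounded only when both its
position and its allele equal a numt substitution.

## The simulator

The simulator is the package's study-conditions generator, not a test
afterthought. It builds a random (or supplied) nuclear contig and circular
mitochondrial contig, implants fragments per a declarative spec (position,
circular mitochondrial interval, strand, genotype), draws fragment lengths
from Normal(300, 30) by default, covers the locus to a configurable depth
with 100 bp reads, and then plays the role of an idealized aligner: reads
wholly in nuclear flanks align normally at MAPQ 60, reads wholly inside the
implant align to the mitochondrial contig (modulo circularity, with strand
flips for minus-strand implants), and junction-spanning reads are
soft-clipped at the breakpoint with their tail bases preserved. A
`repeat_flank` option zeroes MAPQ over an interval to exercise the
unique-mapping filter. Output is a coordinate-sorted, indexed BAM plus a
truth table; everything is a pure function of the seed.

What it deliberately does not emulate: indel sequencing errors, base-quality
models beyond a flat substitution rate, target-site duplications,
post-insertion rearrangements of the insert, and real aligner mapping
ambiguity (every placement is either unique or explicitly repeat-masked).
Passing recovery tests on these fixtures therefore demonstrates the
correctness of the clustering/likelihood/EM machinery under the stated read
geometry, not robustness to every artifact of real data.

## Numerical and design choices

- **Insert model trimming.** 0.5% per tail, before moments; degenerate
  (zero-variance) inputs give $W_L$ equal to the mean.
- **Breakpoint ties.** Modal clip position, ties to the leftmost; at least
  2 identically clipped reads for precision (a single read cannot
  distinguish a junction from a chimeric artifact).
- **Depth definition.** DP at a site is the sum of reference-spanning and
  insertion-supporting reads (the AD components), matching the VCF
  convention for allele-depth-based DP.
- **Likelihood underflow.** Posteriors are recomputed in log space when the
  direct product underflows; log and direct paths agree to 1e-10 relative
  for read counts up to 30.
- **EM floor.** The pseudocount $1/(2N+2)$ keeps Hardy–Weinberg priors
  proper at monomorphic sites.
- **Problem sizes in tests.** Simulated fixtures use a 50 kb nuclear locus
  (1 kb implant, 10–20x coverage; 50-sample cohorts) — large enough that
  cluster geometry, breakpoint voting and EM behave as at genome scale,
  while a full run of the suite stays interactive.

## Known limitations

- Insertions inside low-MAPQ repeats are invisible by construction (the
  MAPQ ≥ 10 anchor filter).
- Nested, duplicated or multi-allelic insertion configurations at one locus
  are not modelled.
- The reported mitochondrial source interval for imprecise sites is the
  linear span of mate placements and may overstate wrapped (origin-spanning)
  fragments.
- Dating precision degrades for short fragments: with few diagnostic
  positions the matching ratio is coarse, and ages for fragments covering
  none are undefined.
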