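# numtcaller

Discovery, genotyping and dating of polymorphic nuclear insertions of
mitochondrial origin (NumtS) from paired-end whole-genome alignments.

Mitochondrial DNA keeps integrating into nuclear chromosomes. Insertions
that are still segregating in the population are absent from the reference
assembly, so reference-based numt annotation cannot see them — yet they
confound studies of mitochondrial heteroplasmy, where nuclear reads carrying
numt-private alleles look like minor mitochondrial variants. `numtcaller`
is for population and mitochondrial geneticists who want to find these
events in their own cohorts: it detects non-reference insertions from
discordant read pairs, localizes breakpoints with split reads, genotypes
sites across samples, tests insertion positions for feature enrichment,
estimates insertion ages, and screens numt alleles against reported
heteroplasmy positions.

## Method at a glance

- **Discovery.** Read pairs with one end uniquely mapped to a nuclear locus
  (MAPQ ≥ 10) and the mate on the mitochondrial contig (or a known
  reference numt) are clustered by orientation within the insert-size
  window *W<sub>L</sub>* = mean + 3·sd; forward clusters link to downstream
  reverse clusters within 2·*W<sub>L</sub>*; soft-clipped reads breaking at
  a common position whose clipped tails realign to the circular
  mitochondrial genome give precise breakpoints.
- **Scoring.** Genotype likelihood with per-read mapping errors
  *e<sub>j</sub>* = 10^(−MAPQ/10):

  L(g) = m^(−k) · ∏_ref [(m−g)(1−e_j) + g·e_j] · ∏_alt [(m−g)·e_j + g·(1−e_j)]

  Calls require Phred insertion quality ≥ 50, ≥ 4 supporting reads and
  ≥ 5× coverage at the insertion point.
- **Cohort genotyping.** Hardy–Weinberg priors with the insertion allele
  frequency re-estimated by EM (≤ 10 iterations).
- **Enrichment.** Two-tailed permutation test against BED feature tracks,
  resampling chromosome-matched random positions over non-gap bases, with
  add-one p-values.
- **Dating.** Diagnostic positions are alignment columns where the modern
  and inferred ancestral mitochondrial sequences differ; the fraction a
  numt matches on the modern side gives
  age = (1 − pct/100) × 6 MY (pct rounded half-to-even).
- **Simulation.** A seeded generator implants mitochondrial fragments into
  a synthetic diploid locus and emits idealized alignments (sorted indexed
  BAM + truth table) so the whole pipeline is testable offline.

## Worked example

Simulate a sample homozygous for a 1 kb insertion of mitochondrial
[2000, 3000) at chr1:25,000, then run discovery:

```r
library(numtcaller)

cfg <- sim_config(nuclear_length = 50000, coverage = 20,
                  numt_spec = list(list(nuclear_pos = 25000,
                                        mito_start = 2000, mito_end = 3000,
                                        strand = "+", genotype = 2)),
                  seed = 1)
sim <- simulate_sample(cfg)
res <- discover_numts(sim$bam, "chrM", sim$mito_seq, verbose = TRUE)
#> [numtcaller] insert-size: mean=299.8 sd=29.3 W_L=387.8
#> [numtcaller] extract: 29 mito-anchored pairs
#> [numtcaller] cluster: 2 clusters
#> [numtcaller] link: 1 candidates
#> [numtcaller] call: 1 calls (1 PASS)
res$calls[, c("chrom", "pos", "precise", "support", "depth",
              "quality", "filter", "gt")]
#>   chrom   pos precise support depth quality filter  gt
#> 1  chr1 25000    TRUE      38    38   99.99   PASS 1/1
```

The implanted breakpoint is recovered exactly (`pos` is the 0-based first
base after the insertion; the same number is the 1-based VCF POS of the
last base before it), marked precise by split-read confirmation, supported
by 38 reads with no reference-spanning reads (hence genotype 1/1), at the
quality cap of 99.99.

Dating a numt that matches the modern human mitochondrial allele at 50 of
68 diagnostic positions:

```r
estimate_age(68, 50)
#> $n_diagnostic   68
#> $n_match_modern 50
#> $pct_modern     74
#> $age_mya        1.56
#> $age_label      "1.56"
```

74% modern matching places the insertion at (1 − 0.74) × 6 = 1.56 million
years ago.

A command-line wrapper over the same functions is installed at
`inst/cli/numtcaller.R` with subcommands `simulate`, `discover`,
`genotype`, `enrich`, `date` and `screen-heteroplasmy`.

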