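# Collect per-sample read evidence for a known site: insertion-supporting
# anchors (mito-anchored pairs whose cluster window covers the breakpoint)
# plus identically clipped reads, and reference-spanning reads.
site_evidence <- function(bam, chrom, breakpoint, mito_name,
                          known_numts = NULL, mapq_min = 10, W_L = 400,
                          min_clip = 20) {
  pairs <- extract_candidate_pairs(bam, mito_name, known_numts, mapq_min)
  near <- pairs[pairs$chrom == chrom &
                  ((pairs$strand == "+" & pairs$end <= breakpoint + min_clip &
                      pairs$end >= breakpoint - W_L) |
                   (pairs$strand == "-" & pairs$pos >= breakpoint - min_clip &
                      pairs$pos <= breakpoint + W_L)), , drop = FALSE]
  clips <- collect_softclips(bam, chrom, breakpoint - W_L, breakpoint + W_L)
  clips <- clips[clips$boundary == breakpoint, , drop = FALSE]
  extra <- setdiff(clips$read_name, near$read_name)
  alt_mapq <- c(near$mapq, clips$mapq[match(extra, clips$read_name)])
  ref <- count_reference_spanning(bam, chrom, breakpoint, min_clip = min_clip)
  list(ref_err = mapq_to_error(ref$mapq), alt_err = mapq_to_error(alt_mapq),
       ref_count = ref$count,
       alt_count = length(unique(c(near$read_name, clips$read_name))))
}

#' Genotype a numt site across a cohort
#'
#' Gathers read evidence at a refined breakpoint in every sample and runs
#' EM-based genotyping with a Hardy-Weinberg population prior whose allele
#' frequency is re-estimated from the cohort.
#'
#' @param bams character vector of indexed BAM paths.
#' @param chrom,breakpoint site position (0-based first base after the
#'   insertion).
#' @param mito_name mitochondrial contig name.
#' @param known_numts optional known-numt \code{GRanges}.
#' @param mapq_min anchor mapping-quality threshold.
#' @param W_L clustering window from the insert-size model.
#' @param max_iter,tol EM controls.
#' @return list with per-sample \code{genotypes} (allele counts), \code{gt}
#'   strings, \code{GQ}, \code{allele_frequency}, \code{n_iter},
#'   \code{converged}, and the per-sample \code{evidence}.
#' @export
genotype_cohort <- function(bams, chrom, breakpoint, mito_name,
                            known_numts = NULL, mapq_min = 10, W_L = 400,
                            max_iter = 10, tol = 1e-4) {
  evidence <- lapply(bams, site_evidence, chrom = chrom,
                     breakpoint = breakpoint, mito_name = mito_name,
                     known_numts = known_numts, mapq_min = mapq_min,
                     W_L = W_L)
  em <- em_population_genotyping(evidence, max_iter = max_iter, tol = tol)
  m <- 2
  gq <- vapply(seq_along(bams), function(i) {
    p <- em$posteriors[i, ]
    min(-10 * log10(max(1 - p[em$genotypes[i] + 1L], 1e-10)), 99.99)
  }, 0)
  gt <- vapply(em$genotypes, function(g)
    paste(c(rep("0", m - g), rep("1", g)), collapse = "/"), "")
  list(genotypes = em$genotypes, gt = gt, GQ = gq,
       allele_frequency = em$allele_frequency, n_iter = em$n_iter,
       converged = em$converged, evidence = evidence,
       posteriors = em$posteriors)
}
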