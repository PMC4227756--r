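#' Run configuration for the numt calling pipeline
#'
#' Bundles input paths and thresholds. Defaults are the published operating
#' point: anchors require MAPQ >= 10, calls require Phred insertion quality
#' >= 50, >= 4 supporting reads and >= 5-fold coverage at the insertion
#' point; cohort EM runs at most 10 iterations; permutation tests use 1000
#' resamples.
#'
#' @param bam,bam_list input alignment file(s).
#' @param ref reference FASTA path.
#' @param mito_name mitochondrial contig name.
#' @param known_numts_bed optional BED of known reference numts.
#' @param mapq,min_quality,min_reads,min_depth,max_em_iter,n_resamples
#'   thresholds.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory.
#' @param verbose log per-stage counters.
#' @return a \code{numt_run_config} list.
#' @export
run_config <- function(bam = NULL, bam_list = NULL, ref = NULL,
                       mito_name = "chrM", known_numts_bed = NULL,
                       mapq = 10, min_quality = 50, min_reads = 4,
                       min_depth = 5, max_em_iter = 10, n_resamples = 1000,
                       seed = 1, out_dir = ".", verbose = TRUE) {
  structure(list(bam = bam, bam_list = bam_list, ref = ref,
                 mito_name = mito_name, known_numts_bed = known_numts_bed,
                 mapq = mapq, min_quality = min_quality,
                 min_reads = min_reads, min_depth = min_depth,
                 max_em_iter = max_em_iter, n_resamples = n_resamples,
                 seed = seed, out_dir = out_dir, verbose = verbose),
            class = "numt_run_config")
}

read_known_numts <- function(bed) {
  if (is.null(bed)) return(NULL)
  df <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) names(gr) <- df[[4]]
  gr
}

load_mito_seq <- function(ref, mito_name) {
  if (is.null(ref)) return(NULL)
  seqs <- Biostrings::readDNAStringSet(ref)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  if (!(mito_name %in% names(seqs))) {
    stop("mitochondrial contig '", mito_name, "' absent from reference ", ref)
  }
  seqs[[mito_name]]
}

#' Run discovery (and optionally cohort genotyping) end to end
#'
#' Discovers numt insertions in each input sample, writes a VCF per sample,
#' and when several samples are given genotypes every discovered PASS site
#' across the cohort with EM-estimated population priors, writing a
#' multi-sample VCF.
#'
#' @param config a \code{numt_run_config}.
#' @return list with \code{per_sample} discovery results, \code{sites}
#'   (merged PASS sites), \code{cohort} (genotyping results or \code{NULL})
#'   and \code{vcf} (output path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "numt_run_config"))
  set.seed(config$seed)
  bams <- c(config$bam, config$bam_list)
  if (length(bams) == 0) stop("no input alignment files")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- read_known_numts(config$known_numts_bed)
  mito_seq <- load_mito_seq(config$ref, config$mito_name)
  per_sample <- lapply(bams, function(b) {
    discover_numts(b, config$mito_name, mito_seq, known,
                   mapq_min = config$mapq, min_quality = config$min_quality,
                   min_reads = config$min_reads,
                   min_depth = config$min_depth, verbose = config$verbose)
  })
  names(per_sample) <- vapply(bams, function(b)
    sub("\\.bam$", "", basename(b)), "")
  all_calls <- do.call(rbind, lapply(per_sample, `[[`, "calls"))
  sites <- all_calls[all_calls$filter == "PASS", , drop = FALSE]
  # merge sites found in several samples: same chrom within one window
  if (nrow(sites) > 1) {
    w <- per_sample[[1]]$model$W_L
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)] |
                      diff(sites$pos) > w))
    sites <- sites[!duplicated(grp), , drop = FALSE]
  }
  contigs <- Rsamtools::scanBamHeader(bams[1])[[1]]$targets
  cohort <- NULL
  if (length(bams) > 1 && nrow(sites) > 0) {
    w <- per_sample[[1]]$model$W_L
    cohort <- lapply(seq_len(nrow(sites)), function(i) {
      genotype_cohort(bams, sites$chrom[i], sites$pos[i], config$mito_name,
                      known, mapq_min = config$mapq, W_L = w,
                      max_iter = config$max_em_iter)
    })
    fields <- t(vapply(seq_len(nrow(sites)), function(i) {
      co <- cohort[[i]]
      vapply(seq_along(bams), function(s) {
        ev <- co$evidence[[s]]
        sprintf("%s:%d:%d:%d,%d", co$gt[s], round(co$GQ[s]),
                ev$ref_count + ev$alt_count, ev$ref_count, ev$alt_count)
      }, "")
    }, character(length(bams))))
    if (nrow(sites) == 1) fields <- matrix(fields, nrow = 1)
    vcf <- file.path(config$out_dir, "cohort.vcf")
    write_numt_vcf(sites, vcf, contigs, sample_ids = names(per_sample),
                   sample_fields = fields,
                   mito_length = unname(contigs[config$mito_name]))
  } else {
    vcf <- file.path(config$out_dir, "calls.vcf")
    write_numt_vcf(sites, vcf, contigs,
                   sample_ids = names(per_sample)[1],
                   mito_length = unname(contigs[config$mito_name]))
  }
  list(per_sample = per_sample, sites = sites, cohort = cohort, vcf = vcf)
}
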