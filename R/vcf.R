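#' Write numt calls as a VCF 4.2 file
#'
#' Emits one record per site with the symbolic ALT \code{<INS:MT>}, the
#' mitochondrial source interval in INFO (MSTART/MEND 1-based, MLEN), the
#' IMPRECISE flag and CIPOS confidence interval for non-precise sites, and
#' per-sample GT:GQ:DP:AD fields. POS is the 1-based last reference base
#' before the insertion.
#'
#' @param calls data.frame of sites (columns as produced by
#'   \code{\link{call_sites}}: chrom, pos, ci_start, ci_end, precise,
#'   quality, filter, mito_start, mito_end).
#' @param path output path.
#' @param contigs named integer vector of contig lengths for the header.
#' @param sample_ids sample column names.
#' @param sample_fields character matrix (sites x samples) of
#'   \code{GT:GQ:DP:AD} strings; defaults to the single-sample fields in
#'   \code{calls}.
#' @param mito_length mitochondrial genome length for MLEN on wrapped
#'   intervals.
#' @return invisibly, the path.
#' @export
write_numt_vcf <- function(calls, path, contigs, sample_ids = NULL,
                           sample_fields = NULL, mito_length = 16569) {
  if (is.null(sample_ids)) {
    sample_ids <- if (nrow(calls) > 0) calls$sample_id[1] else "sample"
  }
  if (is.null(sample_fields) && nrow(calls) > 0) {
    sample_fields <- matrix(sprintf("%s:%d:%d:%d,%d", calls$gt,
                                    round(calls$GQ), calls$depth,
                                    calls$ref_count, calls$support),
                            ncol = 1)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=numtcaller",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##ALT=<ID=INS:MT,Description=\"Insertion of mitochondrial sequence\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variation\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=MSTART,Number=1,Type=Integer,Description=\"Mitochondrial start of inserted sequence (1-based)\">",
    "##INFO=<ID=MEND,Number=1,Type=Integer,Description=\"Mitochondrial end of inserted sequence (1-based)\">",
    "##INFO=<ID=MLEN,Number=1,Type=Integer,Description=\"Length of inserted mitochondrial sequence\">",
    "##FILTER=<ID=min-quality,Description=\"Phred insertion quality below threshold\">",
    "##FILTER=<ID=min-reads,Description=\"Fewer supporting reads than required\">",
    "##FILTER=<ID=min-depth,Description=\"Coverage at insertion point below threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at insertion point\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Reference and insertion supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      parts <- character(0)
      if (!calls$precise[i]) {
        parts <- c(parts, "IMPRECISE",
                   sprintf("CIPOS=%d,%d", calls$ci_start[i] - calls$pos[i],
                           calls$ci_end[i] - calls$pos[i]))
      }
      if (!is.na(calls$mito_start[i])) {
        mlen <- circular_length(calls$mito_start[i],
                                calls$mito_end[i] %% mito_length,
                                mito_length)
        parts <- c(parts, sprintf("MSTART=%d", calls$mito_start[i] + 1L),
                   sprintf("MEND=%d",
                           ifelse(calls$mito_end[i] == 0, mito_length,
                                  calls$mito_end[i])),
                   sprintf("MLEN=%d", mlen))
      }
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }, "")
    body <- sprintf("%s\t%d\tnumt_%d\tN\t<INS:MT>\t%d\t%s\t%s\tGT:GQ:DP:AD\t%s",
                    calls$chrom, pmax(calls$pos, 1L), seq_len(nrow(calls)),
                    round(calls$quality), calls$filter, info,
                    apply(sample_fields, 1, paste, collapse = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a numt VCF back into a calls table
#'
#' @param path VCF path.
#' @return data.frame with chrom, pos (0-based insertion point), filter,
#'   quality, precise, mito_start, mito_end (0-based half-open) and the
#'   per-sample GT strings as a matrix attribute \code{"gt"}.
#' @export
read_numt_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  imprecise <- if ("IMPRECISE" %in% names(info)) info$IMPRECISE else
    rep(FALSE, n)
  mstart <- if ("MSTART" %in% names(info)) unlist_or_na(info$MSTART, n) else
    rep(NA_integer_, n)
  mend <- if ("MEND" %in% names(info)) unlist_or_na(info$MEND, n) else
    rep(NA_integer_, n)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),   # POS (1-based last base) == 0-based point
    quality = rr$QUAL,
    filter = rr$FILTER,
    precise = !imprecise,
    mito_start = mstart - 1L,
    mito_end = mend,
    stringsAsFactors = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  attr(out, "gt") <- gt
  out
}

unlist_or_na <- function(x, n) {
  v <- suppressWarnings(as.integer(unlist(lapply(x, function(e)
    if (length(e) == 0) NA_integer_ else e[1]))))
  if (length(v) != n) rep(NA_integer_, n) else v
}
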