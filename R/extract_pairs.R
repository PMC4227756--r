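#' Extract mitochondria-anchored read pairs from an alignment file
#'
#' Scans a coordinate-sorted, indexed BAM for pairs whose nuclear end maps
#' uniquely (MAPQ at or above \code{mapq_min}, primary, non-duplicate) while
#' the mate maps to the mitochondrial contig or inside a known reference
#' numt interval. These anchors are the discovery signal for non-reference
#' numt insertions; each physical pair is emitted at most once.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param mito_name mitochondrial contig name (must exist in the header).
#' @param known_numts optional \code{GRanges} of known reference numts
#'   (names used as target ids).
#' @param mapq_min minimum nuclear-end mapping quality (reads below are
#'   discarded as not uniquely mapped).
#' @return data.frame of anchors: \code{read_name}, \code{chrom},
#'   \code{pos} (0-based leftmost), \code{end} (0-based exclusive),
#'   \code{strand}, \code{mapq}, \code{mate_target}, \code{mate_pos}
#'   (0-based).
#' @export
extract_candidate_pairs <- function(bam, mito_name, known_numts = NULL,
                                    mapq_min = 10) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(mito_name %in% names(hdr))) {
    stop("mitochondrial contig '", mito_name, "' absent from BAM header")
  }
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index (.bai) not found for ", bam)
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "rname", "strand", "pos", "qwidth", "mapq",
             "mrnm", "mpos"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  rname <- as.character(x$rname)
  mrnm <- as.character(x$mrnm)
  nuclear <- rname != mito_name & !is.na(x$mapq) & x$mapq >= mapq_min
  mate_target <- rep(NA_character_, length(rname))
  mate_target[mrnm == mito_name] <- mito_name
  if (!is.null(known_numts) && length(known_numts) > 0) {
    ids <- names(known_numts)
    if (is.null(ids)) ids <- paste0("ref_numt_", seq_along(known_numts))
    mate_gr <- GenomicRanges::GRanges(
      mrnm, IRanges::IRanges(x$mpos, width = pmax(x$qwidth, 1L)))
    hit <- GenomicRanges::findOverlaps(mate_gr, known_numts,
                                       ignore.strand = TRUE, select = "first")
    in_numt <- !is.na(hit) & mrnm != mito_name
    mate_target[in_numt] <- ids[hit[in_numt]]
  }
  keep <- nuclear & !is.na(mate_target)
  out <- data.frame(
    read_name = x$qname[keep], chrom = rname[keep],
    pos = x$pos[keep] - 1L, end = x$pos[keep] - 1L + x$qwidth[keep],
    strand = as.character(x$strand)[keep], mapq = x$mapq[keep],
    mate_target = mate_target[keep], mate_pos = x$mpos[keep] - 1L,
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$read_name), , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}
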