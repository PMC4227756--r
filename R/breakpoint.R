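# Parse a CIGAR string into leading/trailing soft-clip lengths and the
# reference span consumed by aligned operations.
cigar_parts <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  lead <- if (length(op) && op[1] == "S") len[1] else 0L
  trail <- if (length(op) > 1 && op[length(op)] == "S") len[length(op)] else 0L
  ref_span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  list(lead = lead, trail = trail, ref_span = ref_span)
}

# Soft-clipped reads in a region: one row per clipped read end, with the
# 0-based reference boundary where the clip begins and the clipped tail.
collect_softclips <- function(bam, chrom, region_start, region_end,
                              min_clip = 1) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  which <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(max(1, region_start + 1), max(1, region_end)))
  param <- Rsamtools::ScanBamParam(flag = flag, which = which,
    what = c("qname", "pos", "cigar", "seq", "mapq"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$pos)
  rows <- list()
  for (i in seq_len(n)) {
    cp <- cigar_parts(x$cigar[i])
    s <- as.character(x$seq[i])
    qlen <- nchar(s)
    if (cp$lead > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        read_name = x$qname[i], boundary = x$pos[i] - 1L, side = "left",
        clip_len = cp$lead, tail = substr(s, 1, cp$lead),
        mapq = x$mapq[i], stringsAsFactors = FALSE)
    }
    if (cp$trail > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        read_name = x$qname[i], boundary = x$pos[i] - 1L + cp$ref_span,
        side = "right", clip_len = cp$trail,
        tail = substr(s, qlen - cp$trail + 1, qlen),
        mapq = x$mapq[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_name = character(0), boundary = integer(0),
                      side = character(0), clip_len = integer(0),
                      tail = character(0), mapq = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$read_name, out$side)), , drop = FALSE]
  out[out$clip_len >= min_clip, , drop = FALSE]
}

#' Align a clipped tail to the circular mitochondrial genome
#'
#' Ungapped scan of the tail over the doubled (circularized) mitochondrial
#' sequence, both strands, requiring at least \code{min_identity} matching
#' bases.
#'
#' @param tail tail sequence (character or \code{DNAString}).
#' @param mito_seq mitochondrial \code{DNAString}.
#' @param min_identity minimum fraction of matching bases.
#' @return list with \code{hit} (logical), \code{mito_start}, \code{mito_end}
#'   (0-based half-open, start taken modulo the mito length), \code{strand}.
#' @export
align_tail_to_mito <- function(tail, mito_seq, min_identity = 0.9) {
  if (is.character(tail)) tail <- Biostrings::DNAString(tail)
  n <- length(tail)
  mlen <- length(mito_seq)
  doubled <- Biostrings::xscat(mito_seq, mito_seq)
  max_mm <- floor((1 - min_identity) * n)
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") tail else Biostrings::reverseComplement(tail)
    m <- Biostrings::matchPattern(probe, doubled, max.mismatch = max_mm,
                                  with.indels = FALSE)
    m <- m[BiocGenerics::start(m) <= mlen]  # canonical (non-duplicated) starts
    if (length(m) > 0) {
      s0 <- BiocGenerics::start(m)[1] - 1L
      return(list(hit = TRUE, mito_start = s0 %% mlen,
                  mito_end = (s0 + n) %% mlen, strand = strand))
    }
  }
  list(hit = FALSE, mito_start = NA_integer_, mito_end = NA_integer_,
       strand = NA_character_)
}

#' Locate an insertion breakpoint from soft-clipped reads
#'
#' Within the region bracketing a linked cluster pair (padded by
#' \code{W_L}), finds positions where at least \code{min_clip_reads}
#' soft-clipped reads break identically (modal position, ties to the
#' leftmost). The site is precise only when a clipped tail of at least
#' \code{min_clip} bases realigns to the circular mitochondrial sequence on
#' either strand; otherwise the cluster-bounded interval is returned
#' imprecise.
#'
#' @param bam indexed BAM path.
#' @param chrom chromosome.
#' @param region_start,region_end 0-based half-open search region.
#' @param mito_seq mitochondrial \code{DNAString} (\code{NULL} skips the
#'   tail check, leaving sites imprecise).
#' @param min_clip minimum clipped-tail length for mito realignment.
#' @param min_clip_reads minimum identically-clipped reads for a precise
#'   call.
#' @param min_identity tail realignment identity.
#' @return list with \code{breakpoint} (0-based position of the first
#'   reference base after the insertion, \code{NA} if none), \code{precise},
#'   \code{softclip_support}, \code{mito_start}, \code{mito_end},
#'   \code{clip_read_names}, \code{clip_mapq}.
#' @export
find_softclip_breakpoint <- function(bam, chrom, region_start, region_end,
                                     mito_seq = NULL, min_clip = 20,
                                     min_clip_reads = 2, min_identity = 0.9) {
  clips <- collect_softclips(bam, chrom, region_start, region_end)
  imprecise <- list(breakpoint = NA_integer_, precise = FALSE,
                    softclip_support = 0L, mito_start = NA_integer_,
                    mito_end = NA_integer_, clip_read_names = character(0),
                    clip_mapq = integer(0))
  if (nrow(clips) == 0L) return(imprecise)
  clips <- clips[clips$boundary >= region_start & clips$boundary <= region_end,
                 , drop = FALSE]
  if (nrow(clips) == 0L) return(imprecise)
  tab <- table(clips$boundary)
  top <- max(tab)
  if (top < min_clip_reads) return(imprecise)
  b <- min(as.integer(names(tab)[tab == top]))   # modal, ties leftmost
  at_b <- clips[clips$boundary == b, , drop = FALSE]
  mito_start <- mito_end <- NA_integer_
  precise <- FALSE
  if (!is.null(mito_seq)) {
    long <- at_b[at_b$clip_len >= min_clip, , drop = FALSE]
    if (nrow(long) > 0) {
      long <- long[order(-long$clip_len), , drop = FALSE]
      for (i in seq_len(nrow(long))) {
        hit <- align_tail_to_mito(long$tail[i], mito_seq, min_identity)
        if (hit$hit) {
          precise <- TRUE
          mito_start <- hit$mito_start
          mito_end <- hit$mito_end
          break
        }
      }
    }
  }
  list(breakpoint = b, precise = precise, softclip_support = nrow(at_b),
       mito_start = mito_start, mito_end = mito_end,
       clip_read_names = at_b$read_name, clip_mapq = at_b$mapq)
}

#' Count reads spanning a breakpoint in support of the reference allele
#'
#' Reads aligned continuously across the insertion point (no soft clip of
#' \code{min_clip} or more) with at least \code{anchor} aligned bases on
#' each side support the reference (no-insertion) allele.
#'
#' @param bam indexed BAM path.
#' @param chrom chromosome.
#' @param breakpoint 0-based position of the first reference base after the
#'   insertion.
#' @param anchor required aligned bases on each side.
#' @param min_clip soft-clip length at or above which a read no longer
#'   counts as continuous.
#' @return list with \code{count} and \code{mapq} (vector for the counted
#'   reads).
#' @export
count_reference_spanning <- function(bam, chrom, breakpoint, anchor = 20,
                                     min_clip = 20) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  which <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(max(1, breakpoint - anchor + 1), breakpoint + anchor))
  param <- Rsamtools::ScanBamParam(flag = flag, which = which,
                                   what = c("pos", "cigar", "mapq"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- logical(length(x$pos))
  for (i in seq_along(x$pos)) {
    cp <- cigar_parts(x$cigar[i])
    start0 <- x$pos[i] - 1L
    end0 <- start0 + cp$ref_span
    keep[i] <- cp$lead < min_clip && cp$trail < min_clip &&
      start0 <= breakpoint - anchor && end0 >= breakpoint + anchor
  }
  list(count = sum(keep), mapq = x$mapq[keep])
}

#' Local read depth at a position
#'
#' Number of primary, non-duplicate reads whose aligned span covers the
#' position.
#'
#' @param bam indexed BAM path.
#' @param chrom chromosome.
#' @param pos 0-based position.
#' @return integer depth.
#' @export
local_depth <- function(bam, chrom, pos) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  param <- Rsamtools::ScanBamParam(flag = flag, which = which,
                                   what = c("pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  d <- 0L
  for (i in seq_along(x$pos)) {
    cp <- cigar_parts(x$cigar[i])
    start0 <- x$pos[i] - 1L
    if (start0 <= pos && start0 + cp$ref_span > pos) d <- d + 1L
  }
  d
}

#' Refine a breakpoint by pooling soft-clips across a cohort
#'
#' Pools soft-clipped reads over all samples in the region around a
#' discovered site; the modal identical break position whose longest clipped
#' tail realigns to the mitochondrial genome becomes the cohort breakpoint.
#' Falls back to the discovery interval when no such position exists.
#'
#' @param bams character vector of indexed BAM paths.
#' @param chrom chromosome.
#' @param region_start,region_end 0-based search region.
#' @param mito_seq mitochondrial \code{DNAString}.
#' @param min_clip,min_clip_reads,min_identity as in
#'   \code{\link{find_softclip_breakpoint}}.
#' @return list as from \code{\link{find_softclip_breakpoint}}.
#' @export
refine_breakpoint_cohort <- function(bams, chrom, region_start, region_end,
                                     mito_seq = NULL, min_clip = 20,
                                     min_clip_reads = 2, min_identity = 0.9) {
  clips <- do.call(rbind, lapply(bams, collect_softclips, chrom = chrom,
                                 region_start = region_start,
                                 region_end = region_end))
  imprecise <- list(breakpoint = NA_integer_, precise = FALSE,
                    softclip_support = 0L, mito_start = NA_integer_,
                    mito_end = NA_integer_)
  if (is.null(clips) || nrow(clips) == 0L) return(imprecise)
  clips <- clips[clips$boundary >= region_start & clips$boundary <= region_end,
                 , drop = FALSE]
  if (nrow(clips) == 0L) return(imprecise)
  tab <- table(clips$boundary)
  b <- min(as.integer(names(tab)[tab == max(tab)]))
  at_b <- clips[clips$boundary == b, , drop = FALSE]
  precise <- max(tab) >= min_clip_reads
  mito_start <- mito_end <- NA_integer_
  if (precise && !is.null(mito_seq)) {
    long <- at_b[order(-at_b$clip_len), , drop = FALSE]
    long <- long[long$clip_len >= min_clip, , drop = FALSE]
    precise <- FALSE
    for (i in seq_len(nrow(long))) {
      hit <- align_tail_to_mito(long$tail[i], mito_seq, min_identity)
      if (hit$hit) {
        precise <- TRUE
        mito_start <- hit$mito_start
        mito_end <- hit$mito_end
        break
      }
    }
  }
  list(breakpoint = b, precise = precise, softclip_support = nrow(at_b),
       mito_start = mito_start, mito_end = mito_end)
}
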