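#' Count insertion positions whose flanks overlap a feature track
#'
#' @param positions \code{GRanges} of insertion points (width-1 anchors) or a
#'   data.frame with columns \code{chrom}, \code{pos} (0-based).
#' @param track \code{GRanges} of feature intervals.
#' @param window flank size in bp added on each side of every position.
#' @return integer: number of positions whose +/- window flank intersects at
#'   least one track interval.
#' @export
overlap_statistic <- function(positions, track, window = 0) {
  gr <- as_position_granges(positions)
  if (length(gr) == 0L || length(track) == 0L) return(0L)
  flanks <- GenomicRanges::resize(gr, width = 2 * window + 1, fix = "center")
  # positions on chromosomes absent from the track simply count as
  # non-overlapping, so the differing-seqlevels warning is expected
  sum(suppressWarnings(
    IRanges::overlapsAny(flanks, track, ignore.strand = TRUE)))
}

as_position_granges <- function(positions) {
  if (methods::is(positions, "GRanges")) return(positions)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  GenomicRanges::GRanges(positions$chrom,
                         IRanges::IRanges(positions$pos + 1L, width = 1L))
}

#' Sample random positions matched to an observed insertion set
#'
#' Draws one random position per observed position on the same chromosome,
#' uniformly over non-gap bases. Used to build the permutation null for
#' enrichment testing.
#'
#' @param positions observed positions (\code{GRanges} or chrom/pos
#'   data.frame, 0-based).
#' @param genome named integer vector of chromosome lengths.
#' @param gaps optional \code{GRanges} of assembly gaps to exclude.
#' @return data.frame with columns \code{chrom} and \code{pos} (0-based),
#'   same number of rows and chromosome multiset as the input.
#' @export
sample_matched_positions <- function(positions, genome, gaps = NULL) {
  gr <- as_position_granges(positions)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  allowed <- allowed_bases(genome, gaps)
  pos <- integer(length(chroms))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    ab <- allowed[[chr]]
    if (is.null(ab) || sum(ab$width) == 0L) {
      stop("chromosome ", chr, " is fully gapped or absent from the genome")
    }
    pos[idx] <- sample_from_ranges(ab, length(idx))
  }
  data.frame(chrom = chroms, pos = pos, stringsAsFactors = FALSE)
}

# Per-chromosome non-gap intervals as 0-based start/width lists.
allowed_bases <- function(genome, gaps = NULL) {
  out <- list()
  for (chr in names(genome)) {
    full <- IRanges::IRanges(1L, genome[[chr]])
    if (!is.null(gaps)) {
      g <- gaps[as.character(GenomicRanges::seqnames(gaps)) == chr]
      keep <- IRanges::setdiff(full, IRanges::ranges(g))
    } else keep <- full
    out[[chr]] <- list(start = BiocGenerics::start(keep) - 1L,
                       width = BiocGenerics::width(keep))
  }
  out
}

# Uniform 0-based positions from a start/width interval list.
sample_from_ranges <- function(ab, n) {
  total <- sum(ab$width)
  u <- sample.int(total, n, replace = TRUE)
  cum <- cumsum(ab$width)
  # interval index i with cum[i-1] < u <= cum[i]
  i <- findInterval(u - 1L, c(0L, cum[-length(cum)]))
  prev <- c(0L, cum)[i]
  ab$start[i] + (u - prev - 1L)
}

# Flatten a track into per-chromosome sorted disjoint [start0, end0) arrays
# for vectorised point-overlap queries.
flatten_track <- function(track) {
  red <- GenomicRanges::reduce(track, ignore.strand = TRUE)
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(red)))) {
    r <- red[as.character(GenomicRanges::seqnames(red)) == chr]
    o <- order(BiocGenerics::start(r))
    out[[chr]] <- list(start = BiocGenerics::start(r)[o] - 1L,
                       end = BiocGenerics::end(r)[o])
  }
  out
}

# Count how many 0-based positions (with +/- window flank) hit the flattened
# track. Disjoint sorted intervals: the only candidate is the last interval
# starting at or before the flank end.
count_overlaps_flat <- function(chrom, pos, flat, window = 0) {
  hit <- logical(length(pos))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    tr <- flat[[chr]]
    if (is.null(tr)) next
    flank_end <- pos[idx] + window       # 0-based inclusive end
    flank_start <- pos[idx] - window
    i <- findInterval(flank_end, tr$start)
    ok <- i >= 1L
    ok[ok] <- tr$end[i[ok]] > flank_start[ok]
    hit[idx] <- ok
  }
  sum(hit)
}

#' Two-tailed permutation test of insertion positions against a feature track
#'
#' Compares the observed overlap statistic with its distribution over
#' \code{n_resamples} random position sets matched by chromosome and drawn
#' uniformly over non-gap bases. The two-tailed p-value uses the add-one
#' correction \code{p = 2 * min(#null >= obs, #null <= obs) + 1) / (n + 1)},
#' capped at 1, so p is never exactly zero.
#'
#' @param positions observed insertion positions (\code{GRanges} or
#'   chrom/pos data.frame, 0-based).
#' @param track feature \code{GRanges}.
#' @param genome named integer vector of chromosome lengths.
#' @param gaps optional gap \code{GRanges} excluded from resampling.
#' @param n_resamples number of null position sets.
#' @param window flank added to each position before overlap.
#' @param seed optional integer seed fixing the resampling.
#' @param statistic optional function \code{(chrom, pos)} (0-based position
#'   vector) returning a scalar statistic, e.g. mean flank GC percent;
#'   default is the feature-overlap count. Continuous statistics avoid the
#'   conservativeness the tie-inclusive two-tailed p-value has on heavily
#'   tied counts.
#' @return list with \code{observed}, \code{null} (numeric vector),
#'   \code{p_two_tailed} and \code{direction}
#'   (\code{"enriched"}/\code{"depleted"}/\code{"none"}).
#' @export
permutation_test <- function(positions, track, genome, gaps = NULL,
                             n_resamples = 1000, window = 0, seed = NULL,
                             statistic = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_resamples < 100) {
    warning("fewer than 100 resamples: p-value resolution will be poor")
  }
  gr <- as_position_granges(positions)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  pos0 <- BiocGenerics::start(gr) - 1L
  obs <- if (is.null(statistic)) overlap_statistic(gr, track, window)
         else statistic(chroms, pos0)
  allowed <- allowed_bases(genome, gaps)
  flat <- if (is.null(statistic)) flatten_track(track) else NULL
  null <- numeric(n_resamples)
  # draw all resamples per chromosome at once, then count per replicate
  n_pos <- length(chroms)
  draw <- matrix(0L, nrow = n_pos, ncol = n_resamples)
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    ab <- allowed[[chr]]
    if (is.null(ab) || sum(ab$width) == 0L) {
      stop("chromosome ", chr, " is fully gapped or absent from the genome")
    }
    draw[idx, ] <- sample_from_ranges(ab, length(idx) * n_resamples)
  }
  for (b in seq_len(n_resamples)) {
    null[b] <- if (is.null(statistic))
      count_overlaps_flat(chroms, draw[, b], flat, window)
    else statistic(chroms, draw[, b])
  }
  n_ge <- sum(null >= obs)
  n_le <- sum(null <= obs)
  p <- min(1, 2 * (min(n_ge, n_le) + 1) / (n_resamples + 1))
  med <- median(null)
  direction <- if (obs > med) "enriched" else if (obs < med) "depleted" else "none"
  list(observed = obs, null = null, p_two_tailed = p, direction = direction)
}

#' Flank base composition around insertion positions
#'
#' For each position, extracts the +/- \code{window} bp flank from the
#' reference and reports GC percent over non-N bases and the density of
#' AT/TA dinucleotides.
#'
#' @param positions chrom/pos data.frame (0-based) or \code{GRanges}.
#' @param genome_seq named \code{DNAStringSet} reference.
#' @param window flank size each side in bp (default 500).
#' @return data.frame with \code{chrom}, \code{pos}, \code{pct_gc},
#'   \code{at_dimer_density}, \code{truncated} (flank clipped at a contig
#'   end).
#' @export
flank_composition <- function(positions, genome_seq, window = 500) {
  gr <- as_position_granges(positions)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos1 <- BiocGenerics::start(gr)   # 1-based
  n <- length(gr)
  pct_gc <- at_den <- numeric(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    contig <- genome_seq[[chrom[i]]]
    s <- max(1L, pos1[i] - window)
    e <- min(length(contig), pos1[i] + window)
    trunc[i] <- (s > pos1[i] - window) || (e < pos1[i] + window)
    fl <- Biostrings::subseq(contig, s, e)
    counts <- Biostrings::letterFrequency(fl, c("G", "C", "A", "T"))
    non_n <- sum(counts)
    pct_gc[i] <- if (non_n > 0) 100 * sum(counts[c("G", "C")]) / non_n else NA_real_
    dimers <- Biostrings::countPattern("AT", fl) +
      Biostrings::countPattern("TA", fl)
    at_den[i] <- if (length(fl) > 1) dimers / (length(fl) - 1) else NA_real_
  }
  data.frame(chrom = chrom, pos = pos1 - 1L, pct_gc = pct_gc,
             at_dimer_density = at_den, truncated = trunc,
             stringsAsFactors = FALSE)
}

#' Classify insertion positions by genic context
#'
#' Labels each position by the highest-precedence overlapping annotation:
#' exon > UTR > intron > promoter/terminator (within \code{flank} bp of a
#' gene) > intergenic.
#'
#' @param positions chrom/pos data.frame (0-based) or \code{GRanges}.
#' @param genes \code{GRanges} of gene bodies.
#' @param exons,utrs optional \code{GRanges} of exons and UTRs.
#' @param flank promoter/terminator distance in bp (default 5000).
#' @return character vector of labels, one per position.
#' @export
classify_genic_context <- function(positions, genes, exons = NULL,
                                   utrs = NULL, flank = 5000) {
  gr <- as_position_granges(positions)
  lab <- rep("intergenic", length(gr))
  near <- IRanges::overlapsAny(
    gr, GenomicRanges::resize(genes, BiocGenerics::width(genes) + 2 * flank,
                              fix = "center"),
    ignore.strand = TRUE)
  lab[near] <- "promoter_terminator"
  in_gene <- IRanges::overlapsAny(gr, genes, ignore.strand = TRUE)
  lab[in_gene] <- "intronic"
  if (!is.null(utrs)) {
    lab[IRanges::overlapsAny(gr, utrs, ignore.strand = TRUE)] <- "utr"
  }
  if (!is.null(exons)) {
    lab[IRanges::overlapsAny(gr, exons, ignore.strand = TRUE)] <- "exonic"
  }
  lab
}
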