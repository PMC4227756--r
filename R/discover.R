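#' Score linked cluster candidates into numt calls
#'
#' For each candidate (linked forward/reverse cluster pair or one-sided
#' cluster): locates the breakpoint from soft-clipped reads, gathers
#' insertion-supporting reads (cluster members plus identically clipped
#' reads) and reference-spanning reads, computes genotype likelihoods, the
#' Phred insertion quality, and the PASS/fail filter verdict.
#'
#' @param bam indexed BAM path.
#' @param candidates data.frame from \code{\link{link_clusters}}.
#' @param clusters data.frame from \code{\link{cluster_reads}}.
#' @param pairs anchor data.frame from
#'   \code{\link{extract_candidate_pairs}}.
#' @param model an \code{insert_size_model}.
#' @param mito_seq mitochondrial \code{DNAString} for tail realignment
#'   (\code{NULL} leaves sites imprecise).
#' @param min_quality,min_reads,min_depth filter thresholds.
#' @param min_clip,min_clip_reads breakpoint-refinement parameters.
#' @param sample_id sample name recorded on each call.
#' @param mito_name mitochondrial contig name (distinguishes mito mates
#'   from known-numt mates when summarizing the source interval).
#' @return data.frame of calls (one per candidate with at least one
#'   supporting read): chrom, pos (0-based first base after the insertion),
#'   ci_start, ci_end, precise, support, ref_count, depth, quality, filter,
#'   gt, GQ, mito_start, mito_end, sample_id.
#' @export
call_sites <- function(bam, candidates, clusters, pairs, model,
                       mito_seq = NULL, min_quality = 50, min_reads = 4,
                       min_depth = 5, min_clip = 20, min_clip_reads = 2,
                       sample_id = "sample", mito_name = "chrM") {
  rows <- list()
  w <- model$W_L
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    member_idx <- integer(0)
    for (cid in c(cand$fwd_id, cand$rev_id)) {
      if (!is.na(cid)) member_idx <- c(member_idx, clusters$members[[cid]])
    }
    anchors <- pairs[member_idx, , drop = FALSE]
    two_sided <- !is.na(cand$fwd_id) && !is.na(cand$rev_id)
    region_start <- max(0, cand$gap_start - w)
    region_end <- cand$gap_end + w
    bp <- find_softclip_breakpoint(bam, cand$chrom, region_start, region_end,
                                   mito_seq, min_clip = min_clip,
                                   min_clip_reads = min_clip_reads)
    precise <- bp$precise && !is.na(bp$breakpoint)
    # one-sided candidates are never precise without soft-clip confirmation;
    # with it they are localized exactly like two-sided ones
    pos <- if (!is.na(bp$breakpoint)) bp$breakpoint
           else floor((cand$gap_start + cand$gap_end) / 2)
    ci_start <- if (precise) pos else cand$gap_start
    ci_end <- if (precise) pos else cand$gap_end
    alt_names <- unique(c(anchors$read_name, bp$clip_read_names))
    support <- length(alt_names)
    if (support == 0L) next
    clip_extra <- setdiff(bp$clip_read_names, anchors$read_name)
    alt_mapq <- c(anchors$mapq,
                  bp$clip_mapq[match(clip_extra, bp$clip_read_names)])
    ref <- count_reference_spanning(bam, cand$chrom, pos,
                                    min_clip = min_clip)
    alt_err <- mapq_to_error(alt_mapq)
    ref_err <- mapq_to_error(ref$mapq)
    gs <- genotype_sample(ref_err, alt_err)
    depth <- ref$count + support
    filt <- apply_filters(gs$quality, support, depth,
                          min_quality = min_quality, min_reads = min_reads,
                          min_depth = min_depth)
    # mitochondrial source interval: union of mate placements and the
    # realigned clipped tail (advisory; wrapped fragments report the
    # enclosing linear span)
    mate_pos <- anchors$mate_pos[!is.na(anchors$mate_pos) &
                                   anchors$mate_target == mito_name]
    mito_pts <- c(mate_pos, mate_pos + 100L,
                  if (!is.na(bp$mito_start)) c(bp$mito_start, bp$mito_end))
    mito_start <- if (length(mito_pts)) min(mito_pts) else NA_integer_
    mito_end <- if (length(mito_pts)) max(mito_pts) else NA_integer_
    rows[[length(rows) + 1]] <- data.frame(
      chrom = cand$chrom, pos = pos, ci_start = ci_start, ci_end = ci_end,
      precise = precise, two_sided = two_sided, support = support,
      ref_count = ref$count, depth = depth, quality = gs$quality,
      filter = if (filt$pass) "PASS"
               else paste(filt$fail_reasons, collapse = ";"),
      gt = gs$gt, GQ = gs$GQ,
      mito_start = mito_start, mito_end = mito_end,
      sample_id = sample_id, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ci_start = integer(0), ci_end = integer(0),
                      precise = logical(0), two_sided = logical(0),
                      support = integer(0), ref_count = integer(0),
                      depth = integer(0), quality = numeric(0),
                      filter = character(0), gt = character(0),
                      GQ = numeric(0), mito_start = integer(0),
                      mito_end = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Discover numt insertions in one sample
#'
#' Runs the per-sample discovery pipeline: insert-size model, extraction of
#' mitochondria-anchored pairs, orientation-aware clustering, forward/reverse
#' cluster linking, soft-clip breakpoint localization, and likelihood-based
#' scoring and filtering.
#'
#' @param bam coordinate-sorted, indexed BAM path.
#' @param mito_name mitochondrial contig name.
#' @param mito_seq mitochondrial \code{DNAString} (or \code{NULL}).
#' @param known_numts optional \code{GRanges} of known reference numts.
#' @param mapq_min minimum nuclear-anchor mapping quality.
#' @param min_quality,min_reads,min_depth call filters.
#' @param max_pairs pairs sampled for the insert-size model.
#' @param sample_id sample label.
#' @param verbose log per-stage counts.
#' @return list with \code{calls} (all scored candidates; PASS subset in
#'   \code{filter == "PASS"}), \code{model}, and \code{stats} (per-stage
#'   counts).
#' @export
discover_numts <- function(bam, mito_name, mito_seq = NULL,
                           known_numts = NULL, mapq_min = 10,
                           min_quality = 50, min_reads = 4, min_depth = 5,
                           max_pairs = 1e6, sample_id = NULL,
                           verbose = FALSE) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bam$", "", basename(bam))
  }
  model <- build_insert_size_model(bam, max_pairs = max_pairs)
  numt_log("insert-size", sprintf("mean=%.1f sd=%.1f W_L=%.1f",
                                  model$mean_insert, model$sd_insert,
                                  model$W_L), verbose = verbose)
  pairs <- extract_candidate_pairs(bam, mito_name, known_numts, mapq_min)
  numt_log("extract", nrow(pairs), " mito-anchored pairs", verbose = verbose)
  clusters <- cluster_reads(pairs, model)
  numt_log("cluster", nrow(clusters), " clusters", verbose = verbose)
  candidates <- link_clusters(clusters, model)
  numt_log("link", nrow(candidates), " candidates", verbose = verbose)
  calls <- call_sites(bam, candidates, clusters, pairs, model, mito_seq,
                      min_quality = min_quality, min_reads = min_reads,
                      min_depth = min_depth, sample_id = sample_id,
                      mito_name = mito_name)
  numt_log("call", nrow(calls), " calls (",
           sum(calls$filter == "PASS"), " PASS)", verbose = verbose)
  list(calls = calls, model = model,
       stats = list(n_pairs = nrow(pairs), n_clusters = nrow(clusters),
                    n_candidates = nrow(candidates), n_calls = nrow(calls),
                    n_pass = sum(calls$filter == "PASS")))
}
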