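#' Cluster mito-anchored reads by position and orientation
#'
#' Single-linkage clustering within each (chromosome, strand): consecutive
#' anchor positions at most \code{W_L} apart join the same cluster. Forward
#' (+) anchors flank the insertion upstream, reverse (-) anchors downstream;
#' the two orientations never merge.
#'
#' @param pairs anchor data.frame from \code{\link{extract_candidate_pairs}}.
#' @param model an \code{insert_size_model} (supplies \code{W_L}).
#' @return data.frame of clusters: \code{cluster_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open over member reads),
#'   \code{strand}, \code{n_reads}, \code{members} (list column of row
#'   indices into \code{pairs}).
#' @export
cluster_reads <- function(pairs, model) {
  if (nrow(pairs) == 0L) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_reads = integer(0),
                      members = I(list())))
  }
  w <- model$W_L
  o <- order(pairs$chrom, pairs$strand, pairs$pos)
  ps <- pairs[o, , drop = FALSE]
  grp_break <- c(TRUE, ps$chrom[-1] != ps$chrom[-nrow(ps)] |
                   ps$strand[-1] != ps$strand[-nrow(ps)] |
                   (ps$pos[-1] - ps$pos[-nrow(ps)]) > w)
  cid <- cumsum(grp_break)
  idx_split <- split(seq_len(nrow(ps)), cid)
  rows <- lapply(seq_along(idx_split), function(i) {
    ii <- idx_split[[i]]
    data.frame(cluster_id = i, chrom = ps$chrom[ii[1]],
               start = min(ps$pos[ii]), end = max(ps$end[ii]),
               strand = ps$strand[ii[1]], n_reads = length(ii),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(idx_split, function(ii) o[ii]))
  out
}

#' Link forward and reverse clusters around putative insertions
#'
#' A forward cluster pairs with the nearest downstream reverse cluster whose
#' start lies within \code{2 * W_L} of the forward cluster's end (forward ->
#' reverse orientation, the geometry of read pairs straddling an insertion).
#' Assignment is greedy by smallest gap, ties to the leftmost forward
#' cluster; each cluster joins at most one link. Unlinked clusters are
#' retained as one-sided candidates.
#'
#' @param clusters data.frame from \code{\link{cluster_reads}}.
#' @param model an \code{insert_size_model}.
#' @return data.frame of candidates: \code{fwd_id}, \code{rev_id} (either
#'   may be \code{NA} for one-sided sites), \code{chrom},
#'   \code{gap_start}, \code{gap_end} (interval bracketing the insertion).
#' @export
link_clusters <- function(clusters, model) {
  empty <- data.frame(fwd_id = integer(0), rev_id = integer(0),
                      chrom = character(0), gap_start = integer(0),
                      gap_end = integer(0))
  if (nrow(clusters) == 0L) return(empty)
  w2 <- 2 * model$W_L
  links <- list()
  used <- logical(nrow(clusters))
  for (chr in unique(clusters$chrom)) {
    fwd <- which(clusters$chrom == chr & clusters$strand == "+")
    rev <- which(clusters$chrom == chr & clusters$strand == "-")
    if (length(fwd) && length(rev)) {
      cand <- expand.grid(f = fwd, r = rev)
      cand$gap <- clusters$start[cand$r] - clusters$end[cand$f]
      # reverse cluster must sit at/after the forward cluster and be in range
      cand <- cand[clusters$start[cand$r] >= clusters$start[cand$f] &
                     cand$gap <= w2, , drop = FALSE]
      cand <- cand[order(pmax(cand$gap, 0), clusters$start[cand$f]), ,
                   drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        f <- cand$f[i]; r <- cand$r[i]
        if (used[f] || used[r]) next
        used[f] <- used[r] <- TRUE
        links[[length(links) + 1]] <- data.frame(
          fwd_id = f, rev_id = r, chrom = chr,
          gap_start = clusters$end[f], gap_end = clusters$start[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in which(!used)) {
    one_fwd <- clusters$strand[i] == "+"
    links[[length(links) + 1]] <- data.frame(
      fwd_id = if (one_fwd) i else NA_integer_,
      rev_id = if (one_fwd) NA_integer_ else i,
      chrom = clusters$chrom[i],
      gap_start = if (one_fwd) clusters$end[i] else clusters$start[i],
      gap_end = if (one_fwd) clusters$end[i] else clusters$start[i],
      stringsAsFactors = FALSE)
  }
  if (length(links) == 0L) return(empty)
  out <- do.call(rbind, links)
  out[order(out$chrom, out$gap_start), , drop = FALSE]
}
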