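#' Insert-size model from observed fragment lengths
#'
#' Computes the empirical mean and standard deviation of outer insert
#' lengths after discarding the extreme 0.5 percent tail on each side
#' (chimeric pairs and mapping artifacts otherwise inflate the spread), and
#' derives the clustering window \code{W_L = mean + 3 * sd}.
#'
#' @param inserts numeric vector of outer insert lengths from properly
#'   paired reads.
#' @return list of class \code{insert_size_model}: \code{mean_insert},
#'   \code{sd_insert}, \code{W_L}, \code{n_pairs_sampled}.
#' @export
insert_size_model <- function(inserts) {
  inserts <- inserts[is.finite(inserts) & inserts > 0]
  if (length(inserts) < 100) {
    stop("insufficient pairs to model insert size (need >= 100, got ",
         length(inserts), ")")
  }
  q <- stats::quantile(inserts, c(0.005, 0.995), names = FALSE, type = 1)
  kept <- inserts[inserts >= q[1] & inserts <= q[2]]
  mu <- mean(kept)
  s <- stats::sd(kept)
  if (is.na(s)) s <- 0
  structure(list(mean_insert = mu, sd_insert = s, W_L = mu + 3 * s,
                 n_pairs_sampled = length(kept)),
            class = "insert_size_model")
}

#' Build the insert-size model from an alignment file
#'
#' Samples up to \code{max_pairs} properly paired, primary, non-duplicate
#' alignments and models their outer insert length (TLEN).
#'
#' @param bam path to a coordinate-sorted BAM.
#' @param max_pairs maximum pairs sampled.
#' @return an \code{insert_size_model}.
#' @export
build_insert_size_model <- function(bam, max_pairs = 1e6) {
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "isize")
  isize <- Rsamtools::scanBam(bam, param = param)[[1]]$isize
  isize <- isize[!is.na(isize) & isize > 0]   # one end per pair
  if (length(isize) > max_pairs) isize <- isize[seq_len(max_pairs)]
  insert_size_model(isize)
}
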