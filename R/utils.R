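#' @importFrom stats median rbinom rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

# Length of a circular interval [start, end) on a contig of length `len`.
# end < start means the interval wraps the origin.
circular_length <- function(start, end, len) {
  d <- (end - start) %% len
  if (d == 0 && end != start) len else d
}

numt_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[numtcaller] %s: %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
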