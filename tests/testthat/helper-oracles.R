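# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Longhand product evaluation of the genotype likelihood.
oracle_likelihood <- function(ref_err, alt_err, g, m = 2) {
  k <- length(ref_err) + length(alt_err)
  acc <- 1 / m^k
  for (e in ref_err) acc <- acc * ((m - g) * (1 - e) + g * e)
  for (e in alt_err) acc <- acc * ((m - g) * e + g * (1 - e))
  acc
}

# All-pairs interval check for the flank-overlap count.
oracle_overlap <- function(chrom, pos0, track_df, window = 0) {
  hits <- 0L
  for (i in seq_along(pos0)) {
    fs <- pos0[i] - window
    fe <- pos0[i] + window          # inclusive 0-based flank
    any_hit <- FALSE
    for (j in seq_len(nrow(track_df))) {
      if (track_df$chrom[j] != chrom[i]) next
      if (track_df$start[j] <= fe && track_df$end[j] - 1 >= fs) {
        any_hit <- TRUE
        break
      }
    }
    hits <- hits + any_hit
  }
  hits
}

# Naive character scan for GC percent and AT/TA dimer density.
oracle_composition <- function(seq_char) {
  chars <- strsplit(toupper(seq_char), "")[[1]]
  non_n <- sum(chars %in% c("A", "C", "G", "T"))
  gc <- sum(chars %in% c("G", "C"))
  dimers <- 0L
  for (i in seq_len(length(chars) - 1)) {
    d <- paste0(chars[i], chars[i + 1])
    if (d %in% c("AT", "TA")) dimers <- dimers + 1L
  }
  list(pct_gc = 100 * gc / non_n,
       at_dimer_density = dimers / (length(chars) - 1))
}

# Naive column scan for diagnostic positions between two aligned strings.
oracle_diagnostic <- function(modern_aln, ancestral_aln) {
  m <- strsplit(toupper(modern_aln), "")[[1]]
  a <- strsplit(toupper(ancestral_aln), "")[[1]]
  pos <- 0L
  out <- integer(0)
  for (i in seq_along(m)) {
    if (m[i] != "-") pos <- pos + 1L
    if (m[i] != "-" && a[i] != "-" && m[i] != a[i] &&
        m[i] != "N" && a[i] != "N") {
      out <- c(out, pos)
    }
  }
  out
}

# Exhaustive ungapped alignment of a tail against the circular mito sequence
# at every offset, both strands.
oracle_tail_hit <- function(tail, mito_char, min_identity = 0.9) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  n <- nchar(tail)
  mlen <- nchar(mito_char)
  doubled <- paste0(mito_char, mito_char)
  need <- ceiling(min_identity * n)
  for (probe in c(tail, revcomp(tail))) {
    pc <- strsplit(probe, "")[[1]]
    for (off in seq_len(mlen)) {
      seg <- strsplit(substr(doubled, off, off + n - 1), "")[[1]]
      if (sum(pc == seg) >= need) return(TRUE)
    }
  }
  FALSE
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
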