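#' Diagnostic positions between modern and ancestral mitochondrial sequences
#'
#' Given a pairwise alignment of the modern and inferred ancestral
#' mitochondrial sequences (two equal-length character strings, gaps as
#' \code{"-"}), returns the modern-coordinate positions of substitution
#' columns: columns where both sequences carry a base and the bases differ.
#' Indel columns carry no dating signal and are excluded.
#'
#' @param modern_aln,ancestral_aln aligned sequences as single strings of
#'   identical length (gap character \code{"-"}).
#' @param region optional integer vector \code{c(start, end)} of 1-based
#'   modern-mtDNA coordinates to which the scan is restricted (the region the
#'   numt covers); \code{NULL} scans the whole alignment.
#' @return integer vector of 1-based modern mtDNA positions where the two
#'   sequences differ by substitution.
#' @export
diagnostic_sites <- function(modern_aln, ancestral_aln, region = NULL) {
  m <- strsplit(toupper(modern_aln), "")[[1]]
  a <- strsplit(toupper(ancestral_aln), "")[[1]]
  if (length(m) != length(a)) {
    stop("modern and ancestral alignment strings must have equal length")
  }
  modern_pos <- cumsum(m != "-")
  keep <- m != "-" & a != "-" & m != a & m != "N" & a != "N"
  pos <- modern_pos[keep]
  if (!is.null(region)) {
    pos <- pos[pos >= region[1] & pos <= region[2]]
  }
  pos
}

#' Count diagnostic positions where a numt matches the modern allele
#'
#' Walks a three-way alignment (modern mtDNA, ancestral mtDNA, numt) and at
#' each diagnostic position counts whether the numt carries the modern base.
#' Columns where the numt has a gap are excluded from both counts.
#'
#' @param modern_aln,ancestral_aln,numt_aln equal-length aligned strings.
#' @param sites optional precomputed diagnostic positions (1-based modern
#'   coordinates); computed from the first two strings when \code{NULL}.
#' @return list with \code{n_diagnostic} and \code{n_match_modern}.
#' @export
match_modern <- function(modern_aln, ancestral_aln, numt_aln, sites = NULL) {
  m <- strsplit(toupper(modern_aln), "")[[1]]
  a <- strsplit(toupper(ancestral_aln), "")[[1]]
  q <- strsplit(toupper(numt_aln), "")[[1]]
  if (length(q) != length(m) || length(a) != length(m)) {
    stop("all three alignment strings must have equal length")
  }
  modern_pos <- cumsum(m != "-")
  if (is.null(sites)) sites <- diagnostic_sites(modern_aln, ancestral_aln)
  col_ok <- m != "-" & a != "-" & q != "-" & q != "N"
  diag_col <- col_ok & modern_pos %in% sites & m != a
  list(
    n_diagnostic = sum(diag_col),
    n_match_modern = sum(diag_col & q == m)
  )
}

#' Estimate a numt insertion age from its allele-matching ratio
#'
#' The fraction of diagnostic positions (sites where the modern and ancestral
#' mitochondrial sequences differ) at which the numt carries the modern allele
#' places the insertion along the human lineage: a numt matching the modern
#' allele everywhere inserted recently; one matching the ancestral allele
#' everywhere inserted near the human-chimpanzee split. The matching
#' percentage is rounded to the nearest integer (half to even) and the age is
#' \code{(1 - pct/100) * divergence_mya}.
#'
#' @param n_diagnostic number of diagnostic positions covered by the numt.
#' @param n_match_modern number of those at which the numt matches the modern
#'   allele.
#' @param divergence_mya assumed human-chimpanzee divergence, million years.
#' @return list with \code{n_diagnostic}, \code{n_match_modern},
#'   \code{pct_modern} (integer percent, \code{NA} if no diagnostic sites),
#'   \code{age_mya} (numeric; 0 when pct is 100, \code{NA} if undatable) and
#'   \code{age_label} (\code{"<0.1"} for 100\% rows, \code{"NA"} when
#'   undatable, otherwise the formatted age).
#' @export
estimate_age <- function(n_diagnostic, n_match_modern, divergence_mya = 6) {
  stopifnot(n_diagnostic >= 0, n_match_modern >= 0,
            n_match_modern <= max(n_diagnostic, 0))
  if (n_diagnostic == 0) {
    return(list(n_diagnostic = 0L, n_match_modern = 0L,
                pct_modern = NA_integer_, age_mya = NA_real_,
                age_label = "NA"))
  }
  pct <- as.integer(round(100 * n_match_modern / n_diagnostic))
  age <- (100 - pct) * divergence_mya / 100
  label <- if (pct == 100L) "<0.1" else format(age, trim = TRUE)
  list(n_diagnostic = as.integer(n_diagnostic),
       n_match_modern = as.integer(n_match_modern),
       pct_modern = pct, age_mya = age, age_label = label)
}

#' Date a set of numt sequences against modern and ancestral mitochondria
#'
#' Convenience wrapper: aligns each numt to the modern mitochondrial sequence
#' (via \code{\link{snp_profile}} machinery), transfers coordinates through a
#' fixed modern/ancestral alignment, and tabulates the allele-matching ratio.
#' Input alignment strings follow \code{\link{diagnostic_sites}}.
#'
#' @param numts named \code{DNAStringSet} of numt insertion sequences.
#' @param modern_aln,ancestral_aln aligned modern/ancestral mtDNA strings.
#' @param modern_mt unaligned modern mtDNA \code{DNAString} (coordinates of
#'   the alignment's modern rows must match this sequence).
#' @param divergence_mya divergence assumption in million years.
#' @return data.frame with one row per numt mirroring the dating table:
#'   id, length, n_diagnostic, n_match_modern, pct_modern, age_mya, age_label.
#' @export
date_numts <- function(numts, modern_aln, ancestral_aln, modern_mt,
                       divergence_mya = 6) {
  stopifnot(methods::is(numts, "DNAStringSet"))
  ids <- names(numts)
  if (is.null(ids)) ids <- paste0("numt_", seq_along(numts))
  sites <- diagnostic_sites(modern_aln, ancestral_aln)
  anc_at <- ancestral_allele_map(modern_aln, ancestral_aln)
  rows <- lapply(seq_along(numts), function(i) {
    prof <- align_numt_to_mito(numts[[i]], modern_mt)
    covered <- sites[sites >= prof$mito_start & sites <= prof$mito_end]
    if (length(covered) == 0) {
      res <- estimate_age(0, 0, divergence_mya)
    } else {
      numt_base <- prof$base_at(covered)
      ok <- !is.na(numt_base)
      modern_base <- substring(gsub("-", "", modern_aln), covered, covered)
      n_diag <- sum(ok)
      n_match <- sum(ok & numt_base == modern_base)
      res <- estimate_age(n_diag, n_match, divergence_mya)
    }
    data.frame(id = ids[i], length = length(numts[[i]]),
               n_diagnostic = res$n_diagnostic,
               n_match_modern = res$n_match_modern,
               pct_modern = res$pct_modern, age_mya = res$age_mya,
               age_label = res$age_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # unused here but kept for symmetry with the diagnostic map
  attr(out, "n_diagnostic_total") <- length(sites)
  attr(out, "ancestral_map") <- NULL
  rm(anc_at)
  out
}

# Map modern coordinate -> ancestral base through the fixed pairwise alignment.
ancestral_allele_map <- function(modern_aln, ancestral_aln) {
  m <- strsplit(toupper(modern_aln), "")[[1]]
  a <- strsplit(toupper(ancestral_aln), "")[[1]]
  pos <- cumsum(m != "-")
  keep <- m != "-"
  setNames(a[keep], pos[keep])
}
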