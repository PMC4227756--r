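# Align a numt sequence to the (circular) modern mitochondrial genome.
# Global in the numt, local in a doubled copy of the mitochondrial sequence so
# fragments spanning the origin align contiguously; both strands are tried.
# Returns the mapped interval and per-column accessors.
align_numt_to_mito <- function(numt_seq, modern_mt, min_identity = 90) {
  if (is.character(numt_seq)) numt_seq <- Biostrings::DNAString(numt_seq)
  if (is.character(modern_mt)) modern_mt <- Biostrings::DNAString(modern_mt)
  mlen <- length(modern_mt)
  doubled <- Biostrings::xscat(modern_mt, modern_mt)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln_f <- Biostrings::pairwiseAlignment(numt_seq, doubled,
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  aln_r <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(numt_seq), doubled,
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  aln <- if (Biostrings::score(aln_f) >= Biostrings::score(aln_r)) aln_f else aln_r
  identity <- Biostrings::pid(aln)
  if (is.na(identity) || identity < min_identity) {
    stop("not of recent mitochondrial origin (alignment identity ",
         round(identity, 1), "% < ", min_identity, "%)")
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sub_start <- Biostrings::start(Biostrings::subject(aln))
  sub_pos <- sub_start - 1L + cumsum(sub != "-")
  keep <- sub != "-"
  # doubled-subject coordinate -> circular mito coordinate (1-based)
  mito_pos <- ((sub_pos[keep] - 1L) %% mlen) + 1L
  numt_base <- pat[keep]
  mito_base <- sub[keep]
  lookup <- setNames(numt_base, mito_pos)
  list(
    mito_start = ((sub_start - 1L) %% mlen) + 1L,
    mito_end = ((sub_pos[length(sub_pos)] - 1L) %% mlen) + 1L,
    wrapped = sub_pos[length(sub_pos)] > mlen,
    identity = identity,
    mito_pos = mito_pos, mito_base = mito_base, numt_base = numt_base,
    base_at = function(pos) unname(lookup[as.character(pos)])
  )
}

#' SNP profile of a numt insertion relative to the mitochondrial reference
#'
#' Aligns a numt insertion sequence to the modern mitochondrial genome
#' (circular, both strands; >= 90 percent identity required) and lists every
#' substitution as (mtDNA position, mtDNA allele, numt allele) in 1-based
#' mitochondrial coordinates. These profiles are the basis for screening
#' reported heteroplasmy calls that may in fact be nuclear numt alleles.
#'
#' @param numt_seq numt sequence (\code{DNAString} or character).
#' @param modern_mt mitochondrial reference sequence.
#' @param min_identity minimum alignment identity (percent) below which the
#'   sequence is rejected as not of recent mitochondrial origin.
#' @return data.frame with columns \code{position}, \code{mtdna_allele},
#'   \code{numt_allele}; zero rows when the numt is identical to the
#'   reference over its aligned span.
#' @export
snp_profile <- function(numt_seq, modern_mt, min_identity = 90) {
  aln <- align_numt_to_mito(numt_seq, modern_mt, min_identity = min_identity)
  is_sub <- aln$numt_base != "-" & aln$mito_base != "-" &
    aln$numt_base != aln$mito_base &
    aln$numt_base %in% c("A", "C", "G", "T") &
    aln$mito_base %in% c("A", "C", "G", "T")
  out <- data.frame(position = aln$mito_pos[is_sub],
                    mtdna_allele = aln$mito_base[is_sub],
                    numt_allele = aln$numt_base[is_sub],
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Match numt substitutions against reported heteroplasmy positions
#'
#' A reported mitochondrial heteroplasmy is flagged as potentially confounded
#' by a numt when both the position and the observed allele equal a
#' substitution carried by the numt.
#'
#' @param profile data.frame from \code{\link{snp_profile}} (columns
#'   \code{position}, \code{numt_allele}; a \code{numt_id} column is carried
#'   through when present).
#' @param reported data.frame of reported heteroplasmies with columns
#'   \code{position}, \code{allele}, \code{study}.
#' @return data.frame of matched rows (position, numt allele, study labels);
#'   zero rows when nothing matches.
#' @export
match_heteroplasmy <- function(profile, reported) {
  stopifnot(all(c("position", "numt_allele") %in% names(profile)),
            all(c("position", "allele") %in% names(reported)))
  if (nrow(profile) == 0L || nrow(reported) == 0L) {
    out <- data.frame(position = integer(0), numt_allele = character(0),
                      study = character(0), stringsAsFactors = FALSE)
    if ("numt_id" %in% names(profile)) out$numt_id <- character(0)
    return(out)
  }
  key_p <- paste(profile$position, toupper(profile$numt_allele))
  key_r <- paste(reported$position, toupper(reported$allele))
  hit <- match(key_p, key_r)
  matched <- which(!is.na(hit))
  out <- data.frame(position = profile$position[matched],
                    numt_allele = profile$numt_allele[matched],
                    study = if ("study" %in% names(reported))
                      as.character(reported$study[hit[matched]])
                    else NA_character_,
                    stringsAsFactors = FALSE)
  if ("numt_id" %in% names(profile)) out$numt_id <- profile$numt_id[matched]
  out
}
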