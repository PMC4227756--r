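#' Convert mapping qualities to per-read mapping-error probabilities
#'
#' \code{e = 10^(-MAPQ/10)}, capped into \code{[1e-6, 0.5]} so a single read
#' can never carry infinite weight nor be less informative than a coin flip.
#'
#' @param mapq numeric vector of Phred-scaled mapping qualities.
#' @return numeric vector of error probabilities.
#' @export
mapq_to_error <- function(mapq) {
  pmin(pmax(10^(-mapq / 10), 1e-6), 0.5)
}

#' Genotype likelihood for a numt insertion
#'
#' Likelihood of carrying \code{g} insertion alleles at a site of ploidy
#' \code{m}, given reference-supporting and insertion-supporting reads with
#' per-read mapping-error probabilities:
#' \deqn{L(g) = m^{-k} \prod_{ref} [(m-g)(1-e_j) + g e_j]
#'                      \prod_{alt} [(m-g) e_j + g(1-e_j)]}
#' where \code{k} is the total number of reads. Reference reads are most
#' likely under \code{g = 0}, insertion-supporting reads under \code{g = m}.
#'
#' @param ref_err,alt_err numeric vectors of mapping-error probabilities for
#'   reference-spanning and insertion-supporting reads.
#' @param g number of insertion alleles (0..m).
#' @param m ploidy (default 2).
#' @param log return the log-likelihood instead.
#' @return likelihood in \code{[0, 1]} (or its natural log).
#' @export
genotype_likelihood <- function(ref_err, alt_err, g, m = 2, log = FALSE) {
  if (g < 0 || g > m) stop("genotype g must be within [0, ploidy]")
  k <- length(ref_err) + length(alt_err)
  ref_fac <- (m - g) * (1 - ref_err) + g * ref_err
  alt_fac <- (m - g) * alt_err + g * (1 - alt_err)
  ll <- -k * base::log(m) + sum(base::log(ref_fac)) + sum(base::log(alt_fac))
  if (log) ll else exp(ll)
}

# L(g) for all g in 0..m at once.
likelihood_vector <- function(ref_err, alt_err, m = 2) {
  vapply(0:m, function(g) genotype_likelihood(ref_err, alt_err, g, m), 0)
}

#' Phred-scaled insertion quality
#'
#' Confidence that a site carries at least one insertion allele:
#' \code{-10*log10(L(0) / sum_g L(g))} under a flat genotype prior, capped at
#' 99.99 when \code{L(0)} underflows to zero.
#'
#' @param L numeric vector of likelihoods \code{L(g)}, \code{g = 0..m}.
#' @param cap maximum reported quality.
#' @return Phred-scaled quality.
#' @export
insertion_quality <- function(L, cap = 99.99) {
  if (all(L == 0)) stop("degenerate likelihoods: all L(g) are zero")
  p0 <- L[1] / sum(L)
  if (p0 == 0) return(cap)
  min(-10 * log10(p0), cap)
}

#' Apply the discovery filters to a candidate call
#'
#' A call passes when its Phred insertion quality is at least
#' \code{min_quality}, it has at least \code{min_reads} insertion-supporting
#' reads, and the total coverage at the insertion point is at least
#' \code{min_depth}. Every violated criterion is named.
#'
#' @param quality Phred insertion quality.
#' @param support number of insertion-supporting reads.
#' @param depth total read depth at the insertion point.
#' @param min_quality,min_reads,min_depth filter thresholds.
#' @return list with \code{pass} (logical) and \code{fail_reasons}
#'   (character vector, empty on PASS; subset of
#'   \code{"min-quality"}, \code{"min-reads"}, \code{"min-depth"}).
#' @export
apply_filters <- function(quality, support, depth,
                          min_quality = 50, min_reads = 4, min_depth = 5) {
  reasons <- character(0)
  if (quality < min_quality) reasons <- c(reasons, "min-quality")
  if (support < min_reads) reasons <- c(reasons, "min-reads")
  if (depth < min_depth) reasons <- c(reasons, "min-depth")
  list(pass = length(reasons) == 0L, fail_reasons = reasons)
}

#' Hardy-Weinberg genotype prior from a population allele frequency
#'
#' @param allele_frequency insertion allele frequency in \code{[0, 1]}.
#' @param m ploidy.
#' @return numeric vector of genotype priors for \code{g = 0..m}.
#' @export
hw_prior <- function(allele_frequency, m = 2) {
  stopifnot(allele_frequency >= 0, allele_frequency <= 1)
  vapply(0:m, function(g) {
    choose(m, g) * allele_frequency^g * (1 - allele_frequency)^(m - g)
  }, 0)
}

#' Genotype one sample at a numt site
#'
#' Combines genotype likelihoods with a genotype prior (flat in discovery
#' mode, Hardy-Weinberg under a population allele frequency in cohort mode)
#' and reports the maximum-posterior genotype.
#'
#' @param ref_err,alt_err per-read mapping-error probabilities.
#' @param prior numeric vector of genotype priors over \code{g = 0..m};
#'   \code{NULL} for a flat prior.
#' @param m ploidy.
#' @return list with \code{L} (likelihood vector), \code{posterior}
#'   (normalized), \code{genotype} (integer allele count), \code{gt}
#'   (VCF-style string), \code{GQ} (Phred confidence in the called genotype)
#'   and \code{quality} (insertion quality against g = 0).
#' @export
genotype_sample <- function(ref_err, alt_err, prior = NULL, m = 2) {
  L <- likelihood_vector(ref_err, alt_err, m)
  if (is.null(prior)) prior <- rep(1 / (m + 1), m + 1)
  stopifnot(length(prior) == m + 1)
  post <- prior * L
  if (sum(post) == 0) {
    # likelihood underflow: recompute in log space
    ll <- vapply(0:m, function(g)
      genotype_likelihood(ref_err, alt_err, g, m, log = TRUE), 0)
    lp <- base::log(prior) + ll
    lp <- lp - max(lp[is.finite(lp)])
    post <- exp(lp)
  }
  post <- post / sum(post)
  g_hat <- which.max(post) - 1L
  gq <- min(-10 * log10(max(1 - post[g_hat + 1L], 1e-10)), 99.99)
  gt <- paste(c(rep("0", m - g_hat), rep("1", g_hat)), collapse = "/")
  list(L = L, posterior = post, genotype = g_hat, gt = gt,
       GQ = gq, quality = insertion_quality(pmax(L, 0)))
}

#' Cohort genotyping with EM-estimated population allele frequency
#'
#' Iterates between (E) per-sample genotype posteriors under the current
#' Hardy-Weinberg prior and (M) re-estimating the insertion allele frequency
#' as the posterior-weighted mean allele count, until the frequency changes
#' by less than \code{tol} or \code{max_iter} iterations are reached. The
#' frequency is kept away from the 0/1 boundaries by a pseudocount of
#' \code{1/(2N + 2)}.
#'
#' @param sample_evidence list with one element per sample, each a list with
#'   numeric vectors \code{ref_err} and \code{alt_err}.
#' @param m ploidy.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the allele frequency.
#' @param af_init starting allele frequency.
#' @return list with \code{allele_frequency}, \code{n_iter},
#'   \code{converged}, \code{genotypes} (integer vector) and
#'   \code{posteriors} (N x (m+1) matrix).
#' @export
em_population_genotyping <- function(sample_evidence, m = 2, max_iter = 10,
                                     tol = 1e-4, af_init = 0.1) {
  n <- length(sample_evidence)
  if (n == 0L) stop("empty cohort")
  logL <- t(vapply(sample_evidence, function(s) {
    vapply(0:m, function(g)
      genotype_likelihood(s$ref_err, s$alt_err, g, m, log = TRUE), 0)
  }, numeric(m + 1)))
  pc <- 1 / (2 * n + 2)
  af <- af_init
  converged <- FALSE
  iter <- 0L
  post <- NULL
  repeat {
    iter <- iter + 1L
    lp <- sweep(logL, 2, base::log(hw_prior(af, m)), "+")
    lp <- lp - apply(lp, 1, max)
    post <- exp(lp)
    post <- post / rowSums(post)
    af_new <- sum(post %*% (0:m)) / (m * n)
    af_new <- min(max(af_new, pc), 1 - pc)
    if (abs(af_new - af) < tol) {
      af <- af_new
      converged <- TRUE
      break
    }
    af <- af_new
    if (iter >= max_iter) break
  }
  list(allele_frequency = af, n_iter = iter, converged = converged,
       genotypes = max.col(post) - 1L, posteriors = post)
}
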