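test_that("heterozygote likelihood is exactly 2^-k for any error mix", {
  set.seed(21)
  for (trial in 1:50) {
    l <- sample(0:6, 1); a <- sample(0:6, 1)
    ref <- runif(l, 0, 0.5); alt <- runif(a, 0, 0.5)
    k <- l + a
    expect_equal(genotype_likelihood(ref, alt, g = 1), 2^-k, tolerance = 1e-12)
  }
})

test_that("error-free pure-reference reads give L(0)=1 and L(2)=0", {
  ref <- rep(0, 2)
  expect_equal(genotype_likelihood(ref, numeric(0), 0), 1)
  expect_equal(genotype_likelihood(ref, numeric(0), 2), 0)
})

test_that("likelihoods match the longhand product oracle", {
  set.seed(22)
  for (trial in 1:100) {
    l <- sample(0:8, 1); a <- sample(0:8, 1)
    ref <- runif(l, 1e-6, 0.5); alt <- runif(a, 1e-6, 0.5)
    for (g in 0:2) {
      expect_equal(genotype_likelihood(ref, alt, g),
                   oracle_likelihood(ref, alt, g), tolerance = 1e-12)
    }
  }
})

test_that("the worked mixed-evidence case genotypes heterozygous", {
  ref <- c(0.01, 0.01); alt <- c(0.05, 0.05, 0.05)
  L <- vapply(0:2, function(g) genotype_likelihood(ref, alt, g), 0)
  L_oracle <- vapply(0:2, function(g) oracle_likelihood(ref, alt, g), 0)
  expect_equal(L, L_oracle, tolerance = 1e-12)
  expect_equal(L[2], 0.03125)
  expect_equal(which.max(L) - 1L, 1L)
  q_oracle <- -10 * log10(L_oracle[1] / sum(L_oracle))
  expect_equal(insertion_quality(L), q_oracle, tolerance = 1e-9)
  expect_equal(round(q_oracle, 1), 24.1)
})

test_that("log-space and direct-product likelihoods agree for k up to 30", {
  set.seed(23)
  for (trial in 1:30) {
    l <- sample(0:15, 1); a <- sample(1:15, 1)
    ref <- runif(l, 1e-6, 0.5); alt <- runif(a, 1e-6, 0.5)
    for (g in 0:2) {
      direct <- genotype_likelihood(ref, alt, g)
      logv <- genotype_likelihood(ref, alt, g, log = TRUE)
      if (direct > 0) {
        expect_equal(exp(logv), direct, tolerance = 1e-10)
      }
    }
  }
})

test_that("genotype index outside ploidy is an error", {
  expect_error(genotype_likelihood(0.1, 0.1, 3), "within")
  expect_error(genotype_likelihood(0.1, 0.1, -1), "within")
})

test_that("insertion quality handles symmetric and degenerate cases", {
  expect_equal(insertion_quality(c(1, 1, 1) / 3), -10 * log10(1 / 3),
               tolerance = 1e-9)
  expect_equal(insertion_quality(c(0, 0.5, 0.5)), 99.99)
  expect_error(insertion_quality(c(0, 0, 0)), "degenerate")
})

test_that("adding alt evidence never shifts support toward g=0", {
  set.seed(24)
  for (trial in 1:50) {
    ref <- runif(sample(1:5, 1), 1e-6, 0.5)
    alt <- runif(sample(1:5, 1), 1e-6, 0.5)
    e_new <- runif(1, 1e-6, 0.499)
    r0 <- genotype_likelihood(ref, alt, 0) / genotype_likelihood(ref, alt, 2)
    r1 <- genotype_likelihood(ref, c(alt, e_new), 0) /
      genotype_likelihood(ref, c(alt, e_new), 2)
    expect_lte(r1, r0 * (1 + 1e-12))
  }
})

test_that("filters pass at thresholds and name each failing criterion", {
  expect_true(apply_filters(50, 4, 5)$pass)
  f1 <- apply_filters(49.9, 4, 5)
  expect_false(f1$pass); expect_equal(f1$fail_reasons, "min-quality")
  f2 <- apply_filters(80, 3, 10)
  expect_false(f2$pass); expect_equal(f2$fail_reasons, "min-reads")
  f3 <- apply_filters(80, 4, 4)
  expect_false(f3$pass); expect_equal(f3$fail_reasons, "min-depth")
  f4 <- apply_filters(10, 1, 1)
  expect_setequal(f4$fail_reasons, c("min-quality", "min-reads", "min-depth"))
})

test_that("pure reference evidence genotypes 0/0 and posteriors normalize", {
  gs <- genotype_sample(rep(0.01, 10), numeric(0))
  expect_equal(gs$gt, "0/0")
  expect_equal(sum(gs$posterior), 1, tolerance = 1e-9)
})

test_that("a strong population prior can flip a marginal call", {
  ref <- c(0.01, 0.01); alt <- c(0.2, 0.2, 0.2)
  flat <- genotype_sample(ref, alt)
  rare <- genotype_sample(ref, alt, prior = hw_prior(1e-6))
  expect_equal(sum(rare$posterior), 1, tolerance = 1e-9)
  expect_gte(flat$genotype, rare$genotype)
  expect_equal(rare$genotype, 0L)
})

test_that("EM on a pure-reference cohort floors the allele frequency", {
  ev <- replicate(40, list(ref_err = rep(0.01, 10), alt_err = numeric(0)),
                  simplify = FALSE)
  em <- em_population_genotyping(ev)
  expect_equal(em$allele_frequency, 1 / (2 * 40 + 2), tolerance = 1e-6)
  expect_true(all(em$genotypes == 0))
})

test_that("identical likelihoods give identical posteriors", {
  ev <- list(list(ref_err = c(0.01, 0.01), alt_err = c(0.05, 0.05)),
             list(ref_err = c(0.01, 0.01), alt_err = c(0.05, 0.05)))
  em <- em_population_genotyping(ev)
  expect_equal(em$posteriors[1, ], em$posteriors[2, ])
})

test_that("an empty cohort is an error", {
  expect_error(em_population_genotyping(list()), "empty")
})

# Binomial read-level evidence for one sample of known genotype: coverage
# reads split between alleles by g/2, mapping errors near 1e-3.
sample_evidence_for <- function(g, coverage = 10) {
  n_alt <- rbinom(1, coverage, g / 2)
  list(ref_err = rep(0.001, coverage - n_alt), alt_err = rep(0.001, n_alt))
}

test_that("EM recovers cohort allele frequencies with small bias", {
  set.seed(25)
  for (af in c(0.05, 0.3, 0.5)) {
    est <- replicate(20, {
      g <- rbinom(200, 2, af)
      ev <- lapply(g, sample_evidence_for)
      em <- em_population_genotyping(ev)
      expect_lte(em$n_iter, 10)
      em$allele_frequency
    })
    expect_lt(abs(mean(est) - af), 0.03)
  }
})

test_that("EM genotypes a simulated cohort with high concordance at 8x", {
  set.seed(26)
  g <- rbinom(200, 2, 0.3)
  ev <- lapply(g, sample_evidence_for, coverage = 8)
  em <- em_population_genotyping(ev)
  expect_gte(mean(em$genotypes == g), 0.95)
})
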