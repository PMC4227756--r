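gr_track <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

test_that("point overlaps follow the half-open interval convention", {
  track <- gr_track(data.frame(chrom = "chr1", start = 90, end = 110))
  expect_equal(overlap_statistic(data.frame(chrom = "chr1", pos = 100),
                                 track), 1L)
  expect_equal(overlap_statistic(data.frame(chrom = "chr1", pos = 100),
                                 GenomicRanges::GRanges()), 0L)
  # window pulls a nearby feature into range
  far <- gr_track(data.frame(chrom = "chr1", start = 150, end = 160))
  expect_equal(overlap_statistic(data.frame(chrom = "chr1", pos = 100), far,
                                 window = 0), 0L)
  expect_equal(overlap_statistic(data.frame(chrom = "chr1", pos = 100), far,
                                 window = 60), 1L)
})

test_that("overlap counts match the all-pairs oracle on random instances", {
  set.seed(41)
  for (trial in 1:100) {
    n_pos <- sample(1:15, 1)
    n_int <- sample(1:10, 1)
    chroms <- sample(c("chrA", "chrB"), n_pos, replace = TRUE)
    pos <- sample.int(10000, n_pos) - 1L
    tr <- data.frame(chrom = sample(c("chrA", "chrB"), n_int, replace = TRUE),
                     start = sample.int(9900, n_int) - 1L)
    tr$end <- tr$start + sample.int(200, n_int)
    w <- sample(0:50, 1)
    got <- overlap_statistic(data.frame(chrom = chroms, pos = pos),
                             gr_track(tr), window = w)
    expect_equal(got, oracle_overlap(chroms, pos, tr, w),
                 info = paste("trial", trial))
  }
})

test_that("the flat fast-path overlap count equals the GRanges path", {
  set.seed(42)
  for (trial in 1:50) {
    n_int <- sample(1:20, 1)
    tr <- data.frame(chrom = "chr1", start = sample.int(50000, n_int) - 1L)
    tr$end <- tr$start + sample.int(500, n_int)
    track <- gr_track(tr)
    pos <- sample.int(50000, 30) - 1L
    w <- sample(0:100, 1)
    flat <- numtcaller:::flatten_track(track)
    got <- numtcaller:::count_overlaps_flat(rep("chr1", 30), pos, flat, w)
    want <- overlap_statistic(data.frame(chrom = "chr1", pos = pos), track, w)
    expect_equal(got, want)
  }
})

test_that("matched sampling preserves chromosomes and avoids gaps", {
  set.seed(43)
  genome <- c(chr8 = 10000L, chr9 = 8000L)
  obs <- data.frame(chrom = c("chr8", "chr8", "chr8", "chr9"),
                    pos = c(1, 2, 3, 4))
  out <- sample_matched_positions(obs, genome)
  expect_equal(out$chrom, obs$chrom)
  gaps <- GenomicRanges::GRanges("chr8", IRanges::IRanges(1, 5000))
  out2 <- sample_matched_positions(obs[obs$chrom == "chr8", ], genome, gaps)
  expect_true(all(out2$pos >= 5000 & out2$pos < 10000))
  expect_error(sample_matched_positions(
    obs, genome, GenomicRanges::GRanges("chr8", IRanges::IRanges(1, 10000))),
    "fully gapped")
})

test_that("matched sampling is uniform over allowed bases", {
  set.seed(44)
  genome <- c(chrU = 1000L)
  gaps <- GenomicRanges::GRanges("chrU", IRanges::IRanges(201, 400))
  obs <- data.frame(chrom = rep("chrU", 100), pos = rep(0L, 100))
  draws <- unlist(replicate(1000, sample_matched_positions(obs, genome,
                                                           gaps)$pos,
                            simplify = FALSE))
  expect_equal(length(draws), 1e5)
  expect_false(any(draws >= 200 & draws < 400))
  bins <- table(cut(draws, breaks = c(0, 100, 200, 400, 500, 600, 700, 800,
                                      900, 1000), right = FALSE))
  bins <- bins[bins > 0]
  expected <- c(100, 100, 100, 100, 100, 100, 100, 100) / 800 * 1e5
  chi <- sum((as.numeric(bins) - expected)^2 / expected)
  p <- stats::pchisq(chi, df = length(bins) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("permutation p-values follow the add-one two-tailed formula", {
  set.seed(45)
  genome <- c(chr1 = 100000L)
  pos <- data.frame(chrom = rep("chr1", 10),
                    pos = as.integer(seq(5000, 95000, length.out = 10)))
  # track covering everything: observed equals every null -> p capped at 1
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  r_full <- permutation_test(pos, full, genome, n_resamples = 200)
  expect_equal(r_full$p_two_tailed, 1)
  # statistic beyond every null value -> p = 2/(n+1)
  stat_extreme <- local({
    first <- TRUE
    function(chrom, p) {
      if (first) { first <<- FALSE; return(1e9) }
      sum(p)
    }
  })
  r_ext <- permutation_test(pos, full, genome, n_resamples = 1000,
                            statistic = stat_extreme)
  expect_equal(r_ext$p_two_tailed, 2 / 1001)
  expect_equal(r_ext$direction, "enriched")
})

test_that("permutation p is invariant to the order of null replicates", {
  set.seed(46)
  genome <- c(chr1 = 50000L)
  tr <- data.frame(chrom = "chr1", start = seq(0, 49000, by = 1000))
  tr$end <- tr$start + 300
  pos <- data.frame(chrom = rep("chr1", 20),
                    pos = sample.int(50000, 20) - 1L)
  r <- permutation_test(pos, gr_track(tr), genome, n_resamples = 300,
                        seed = 5)
  recompute_p <- function(null, obs, n) {
    min(1, 2 * (min(sum(null >= obs), sum(null <= obs)) + 1) / (n + 1))
  }
  expect_equal(r$p_two_tailed, recompute_p(r$null, r$observed, 300))
  expect_equal(r$p_two_tailed, recompute_p(sample(r$null), r$observed, 300))
})

test_that("flank composition matches the naive scan", {
  gs <- Biostrings::DNAStringSet(c(chrT = "GCGC"))
  r <- flank_composition(data.frame(chrom = "chrT", pos = 1), gs, window = 2)
  expect_equal(r$pct_gc, 100)
  expect_true(r$truncated)
  gs2 <- Biostrings::DNAStringSet(c(chrT = "ATAT"))
  r2 <- flank_composition(data.frame(chrom = "chrT", pos = 1), gs2,
                          window = 2)
  expect_equal(r2$at_dimer_density, 1)
  set.seed(47)
  seqchar <- random_dna_string(1000)
  gs3 <- Biostrings::DNAStringSet(c(chrR = seqchar))
  for (pos in c(0, 499, 999)) {
    r3 <- flank_composition(data.frame(chrom = "chrR", pos = pos), gs3,
                            window = 100)
    s <- max(1, pos + 1 - 100); e <- min(1000, pos + 1 + 100)
    want <- oracle_composition(substr(seqchar, s, e))
    expect_equal(r3$pct_gc, want$pct_gc, tolerance = 1e-12)
    expect_equal(r3$at_dimer_density, want$at_dimer_density,
                 tolerance = 1e-12)
  }
})

test_that("genic context labels follow the precedence order", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 20000))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 10500))
  utrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10400, 10600))
  pos <- data.frame(chrom = rep("chr1", 5),
                    pos = c(10100, 10550, 15000, 22000, 40000))
  lab <- classify_genic_context(pos, genes, exons, utrs)
  expect_equal(lab, c("exonic", "utr", "intronic", "promoter_terminator",
                      "intergenic"))
})
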