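test_that("implant builds the expected haplotype lengths", {
  set.seed(31)
  nuc <- Biostrings::DNAString(random_dna_string(50000))
  mito <- Biostrings::DNAString(random_dna_string(16569))
  h <- implant_numt(nuc, mito, list(nuclear_pos = 25000, mito_start = 2000,
                                    mito_end = 2600, strand = "+"))
  expect_equal(length(h$seq), 50600)
  expect_equal(h$fragment_length, 600)
  # circular wrap: [16000, 300) on 16,569 bp = 569 + 300
  h2 <- implant_numt(nuc, mito, list(nuclear_pos = 100, mito_start = 16000,
                                     mito_end = 300, strand = "+"))
  expect_equal(h2$fragment_length, 869)
  # full-genome fragment
  h3 <- implant_numt(nuc, mito, list(nuclear_pos = 100, mito_start = 0,
                                     mito_end = 16569, strand = "+"))
  expect_equal(h3$fragment_length, 16569)
  expect_error(implant_numt(nuc, mito, list(nuclear_pos = 100,
                                            mito_start = 5, mito_end = 5,
                                            strand = "+")),
               "zero-length")
})

test_that("implanted sequence content round-trips", {
  set.seed(32)
  nuc <- Biostrings::DNAString(random_dna_string(1000))
  mito <- Biostrings::DNAString(random_dna_string(300))
  h <- implant_numt(nuc, mito, list(nuclear_pos = 400, mito_start = 50,
                                    mito_end = 150, strand = "+"))
  expect_equal(as.character(Biostrings::subseq(h$seq, 401, 500)),
               as.character(Biostrings::subseq(mito, 51, 150)))
  hm <- implant_numt(nuc, mito, list(nuclear_pos = 400, mito_start = 50,
                                     mito_end = 150, strand = "-"))
  expect_equal(as.character(Biostrings::subseq(hm$seq, 401, 500)),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(mito, 51, 150))))
})

test_that("pair count tracks coverage and reads are exact substrings", {
  cfg <- sim_config(nuclear_length = 50000, coverage = 10, seed = 33)
  sim <- simulate_sample(cfg)
  expected <- 10 * 50000 / (2 * 100)
  expect_lt(abs(sim$n_pairs - expected) / expected, 0.1)
  hap <- as.character(sim$nuclear_seq)
  some <- sim$records[sample.int(nrow(sim$records), 50), ]
  for (i in seq_len(nrow(some))) {
    expect_true(grepl(some$seq[i], hap, fixed = TRUE))
  }
})

test_that("the same seed reproduces byte-identical records", {
  cfg <- sim_config(nuclear_length = 20000, coverage = 5,
                    numt_spec = list(list(nuclear_pos = 10000,
                                          mito_start = 100, mito_end = 700,
                                          strand = "+", genotype = 1)),
                    seed = 34)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("every simulated pair appears exactly once in the fixture", {
  sim <- shared_sim()
  counts <- table(sim$records$qname)
  expect_true(all(counts == 2))           # both mates, once each
  expect_equal(length(counts), sim$n_pairs)
  # round-trip through the BAM preserves the record count
  n_in_bam <- Rsamtools::countBam(sim$bam)$records
  expect_equal(n_in_bam, nrow(sim$records))
})

test_that("junction reads are soft-clipped with tails reconstructing the read", {
  sim <- shared_sim()
  clipped <- sim$records[grepl("S", sim$records$cigar) &
                           sim$records$rname == "chr1", ]
  expect_gt(nrow(clipped), 0)
  hap <- paste0(substr(as.character(sim$nuclear_seq), 1, 25000),
                substr(paste0(as.character(sim$mito_seq),
                              as.character(sim$mito_seq)), 2001, 3000),
                substr(as.character(sim$nuclear_seq), 25001, 50000))
  for (i in seq_len(min(nrow(clipped), 20))) {
    expect_true(grepl(clipped$seq[i], hap, fixed = TRUE))
  }
})

test_that("reads wholly inside the insert map to the mito contig", {
  sim <- shared_sim()
  mito_reads <- sim$records[sim$records$rname == "chrM", ]
  expect_gt(nrow(mito_reads), 0)
  # all simulated mito alignments fall inside the implanted [2000,3000)
  expect_true(all(mito_reads$pos >= 2000 & mito_reads$pos < 3000))
})

test_that("base errors perturb reads at roughly the configured rate", {
  cfg <- sim_config(nuclear_length = 20000, coverage = 5, base_error = 0.01,
                    seed = 35)
  sim <- simulate_sample(cfg)
  hap <- as.character(sim$nuclear_seq)
  nuc_reads <- sim$records[sim$records$cigar == "100M" &
                             sim$records$rname == "chr1", ]
  mm <- vapply(seq_len(nrow(nuc_reads)), function(i) {
    ref <- substr(hap, nuc_reads$pos[i] + 1, nuc_reads$pos[i] + 100)
    sum(strsplit(ref, "")[[1]] != strsplit(nuc_reads$seq[i], "")[[1]])
  }, 0)
  rate <- sum(mm) / (100 * nrow(nuc_reads))
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)
})

test_that("an insert mean below the read length is rejected", {
  expect_error(sim_config(insert_mean = 80, read_length = 100),
               "read_length")
})
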