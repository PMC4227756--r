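test_that("identically clipped reads with mito tails give a precise breakpoint", {
  set.seed(11)
  mito <- Biostrings::DNAString(random_dna_string(2000))
  tail <- as.character(Biostrings::subseq(mito, 301, 340))
  recs <- do.call(rbind, lapply(1:3, function(i) {
    sam_rec(paste0("c", i), 0L, "chr1", 960L + i * 2, 60L,
            sprintf("%dM40S", 40 - i * 2 + 2),
            seq = paste0(random_dna_string(40 - i * 2 + 2), tail))
  }))
  # three right-clips all breaking at 960 + 2i + (42 - 2i) = 1002
  bam <- make_test_bam(recs)
  bp <- find_softclip_breakpoint(bam, "chr1", 900, 1100, mito)
  expect_equal(bp$breakpoint, 1002L)
  expect_true(bp$precise)
  expect_equal(bp$softclip_support, 3L)
  expect_equal(bp$mito_start, 300L)
})

test_that("no soft-clips leaves the site imprecise", {
  bam <- make_test_bam(sam_rec("p", 0L, "chr1", 1000L, 60L, "100M"))
  bp <- find_softclip_breakpoint(bam, "chr1", 900, 1200, NULL)
  expect_true(is.na(bp$breakpoint))
  expect_false(bp$precise)
})

test_that("clipped tails from an unrelated sequence fail the mito check", {
  set.seed(12)
  mito <- Biostrings::DNAString(random_dna_string(2000))
  alien <- random_dna_string(40)
  expect_false(oracle_tail_hit(alien, as.character(mito)))  # sanity
  recs <- rbind(
    sam_rec("u1", 0L, "chr1", 962L, 60L, "40M40S",
            seq = paste0(random_dna_string(40), alien)),
    sam_rec("u2", 0L, "chr1", 952L, 60L, "50M40S",
            seq = paste0(random_dna_string(50), alien)))
  bam <- make_test_bam(recs)
  bp <- find_softclip_breakpoint(bam, "chr1", 900, 1100, mito)
  expect_equal(bp$breakpoint, 1002L)
  expect_false(bp$precise)
})

test_that("tail realignment agrees with exhaustive circular-offset scan", {
  set.seed(13)
  mito <- Biostrings::DNAString(random_dna_string(400))
  mito_char <- as.character(mito)
  n_agree <- 0
  for (trial in 1:100) {
    kind <- trial %% 4
    tail <- if (kind == 0) {
      s <- sample.int(400, 1)                 # true fragment, may wrap origin
      substr(paste0(mito_char, mito_char), s, s + 29)
    } else if (kind == 1) {
      random_dna_string(30)                   # unrelated
    } else if (kind == 2) {                   # fragment with 2 mismatches
      s <- sample.int(370, 1)
      frag <- strsplit(substr(mito_char, s, s + 29), "")[[1]]
      idx <- sample.int(30, 2)
      for (i in idx) frag[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                               frag[i]), 1)
      paste(frag, collapse = "")
    } else {                                  # reverse-complement fragment
      s <- sample.int(370, 1)
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(mito, s, s + 29)))
    }
    got <- align_tail_to_mito(tail, mito)$hit
    want <- oracle_tail_hit(tail, mito_char)
    expect_equal(got, want, info = paste("trial", trial))
    n_agree <- n_agree + (got == want)
  }
  expect_equal(n_agree, 100)
})

test_that("reference-spanning counts exclude clipped and breakpoint-edge reads", {
  recs <- rbind(
    sam_rec("span", 0L, "chr1", 970L, 60L, "100M"),      # 32/68 around 1002
    sam_rec("edge", 0L, "chr1", 902L, 60L, "100M"),      # ends exactly at 1002
    sam_rec("clip", 0L, "chr1", 962L, 60L, "40M60S"),    # clipped at 1002
    sam_rec("thin", 0L, "chr1", 992L, 60L, "100M"))      # only 10 bp left anchor
  bam <- make_test_bam(recs)
  res <- count_reference_spanning(bam, "chr1", 1002L, anchor = 20)
  expect_equal(res$count, 1L)
})

test_that("cohort pooling refines to the modal break position", {
  set.seed(14)
  mito <- Biostrings::DNAString(random_dna_string(2000))
  tail <- as.character(Biostrings::subseq(mito, 101, 140))
  bam_of <- function(boundaries) {
    recs <- do.call(rbind, lapply(seq_along(boundaries), function(i) {
      b <- boundaries[i]
      sam_rec(paste0("r", i), 0L, "chr1", b - 40L, 60L, "40M40S",
              seq = paste0(random_dna_string(40), tail))
    }))
    make_test_bam(recs)
  }
  bams <- c(bam_of(c(1000L, 1000L)), bam_of(c(1000L, 1000L)),
            bam_of(1002L))
  ref <- refine_breakpoint_cohort(bams, "chr1", 900, 1100, mito)
  expect_equal(ref$breakpoint, 1000L)
  expect_true(ref$precise)
})

test_that("cohort refinement falls back when no sample has clips", {
  bams <- c(make_test_bam(sam_rec("a", 0L, "chr1", 900L, 60L, "100M")),
            make_test_bam(sam_rec("b", 0L, "chr1", 950L, 60L, "100M")))
  ref <- refine_breakpoint_cohort(bams, "chr1", 800, 1200, NULL)
  expect_true(is.na(ref$breakpoint))
  expect_false(ref$precise)
})
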