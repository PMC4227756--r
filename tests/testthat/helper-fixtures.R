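# Hand-built alignment records -> sorted indexed BAM, for unit tests that
# need precise control over individual reads.

sam_rec <- function(qname, flag, rname, pos0, mapq, cigar, rnext = "=",
                    pnext0 = pos0, tlen = 0L, seq = NULL, seqlen = 100L) {
  if (is.null(seq)) seq <- random_dna_string(seqlen)
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos0,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext0 + 1L,
             tlen = tlen, seq = seq, stringsAsFactors = FALSE)
}

make_test_bam <- function(records, nuclear_length = 10000,
                          mito_length = 2000, nuclear_name = "chr1",
                          mito_name = "chrM", sample_id = "T1",
                          dir = tempfile("tbam")) {
  cfg <- list(sample_id = sample_id, nuclear_name = nuclear_name,
              nuclear_length = nuclear_length, mito_name = mito_name,
              mito_length = mito_length)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fixture(records, cfg, dir)
}

# One shared 20x homozygous-implant simulation reused by several test files.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        nuclear_length = 50000, coverage = 20,
        numt_spec = list(list(nuclear_pos = 25000, mito_start = 2000,
                              mito_end = 3000, strand = "+", genotype = 2)),
        seed = 20240901)
      cache <<- simulate_sample(cfg)
    }
    cache
  }
})
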