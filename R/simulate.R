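#' Simulation configuration for implanted numt fixtures
#'
#' Describes a synthetic diploid nuclear locus with zero or more implanted
#' mitochondrial fragments and the paired-end sequencing of it by an
#' idealized aligner. All randomness is fixed by \code{seed}.
#'
#' @param nuclear_length nuclear contig length in bp.
#' @param mito_length mitochondrial contig length in bp (human: 16,569).
#' @param numt_spec list of implants; each a list with \code{nuclear_pos}
#'   (0-based insertion point), \code{mito_start}/\code{mito_end} (0-based
#'   half-open on the circular mitochondrial genome; end < start wraps the
#'   origin), \code{strand} (\code{"+"}/\code{"-"}) and \code{genotype}
#'   (0, 1 or 2 insertion alleles).
#' @param coverage haploid-genome sequence coverage (x).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd Normal fragment-length model in bp.
#' @param base_error per-base substitution error rate.
#' @param seed integer seed fixing all randomness.
#' @param sample_id sample name written to the fixture.
#' @param nuclear_name,mito_name contig names.
#' @param repeat_flank optional 0-based half-open interval
#'   \code{c(start, end)} on the nuclear contig; reads aligned starting
#'   inside it get MAPQ 0, emulating a repetitive flank.
#' @param nuclear_seq,mito_seq optional explicit \code{DNAString} references;
#'   random sequences are generated when absent.
#' @return a \code{numt_sim_config} list.
#' @export
sim_config <- function(nuclear_length = 50000, mito_length = 16569,
                       numt_spec = list(), coverage = 10, read_length = 100,
                       insert_mean = 300, insert_sd = 30, base_error = 0,
                       seed = 1, sample_id = "S1", nuclear_name = "chr1",
                       mito_name = "chrM", repeat_flank = NULL,
                       nuclear_seq = NULL, mito_seq = NULL) {
  stopifnot(coverage > 0, read_length > 0, insert_sd >= 0)
  if (insert_mean < read_length) {
    stop("insert_mean must be at least read_length")
  }
  for (sp in numt_spec) {
    stopifnot(sp$nuclear_pos >= 0, sp$nuclear_pos <= nuclear_length)
    if (circular_length(sp$mito_start %% mito_length,
                        sp$mito_end %% mito_length, mito_length) == 0 &&
        sp$mito_start != 0) {
      stop("zero-length fragment")
    }
  }
  structure(list(nuclear_length = nuclear_length, mito_length = mito_length,
                 numt_spec = numt_spec, coverage = coverage,
                 read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, base_error = base_error, seed = seed,
                 sample_id = sample_id, nuclear_name = nuclear_name,
                 mito_name = mito_name, repeat_flank = repeat_flank,
                 nuclear_seq = nuclear_seq, mito_seq = mito_seq),
            class = "numt_sim_config")
}

random_dna <- function(n) {
  Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = ""))
}

#' Implant a mitochondrial fragment into a nuclear sequence
#'
#' Builds the alternate haplotype \code{nuclear[0:pos] + fragment +
#' nuclear[pos:]} and a segment map recording, for every haplotype segment,
#' its source contig, source offset and strand. Fragments may wrap the
#' circular mitochondrial origin; minus-strand fragments are inserted
#' reverse-complemented.
#'
#' @param nuclear_seq nuclear \code{DNAString}.
#' @param mito_seq mitochondrial \code{DNAString} (circular).
#' @param spec one implant spec (see \code{\link{sim_config}}).
#' @return list with \code{seq} (haplotype \code{DNAString}) and
#'   \code{segments} (data.frame: hap_start 0-based, len, source, src_start,
#'   strand), plus \code{fragment_length}.
#' @export
implant_numt <- function(nuclear_seq, mito_seq, spec) {
  pos <- spec$nuclear_pos
  mlen <- length(mito_seq)
  ms <- spec$mito_start %% mlen
  me <- spec$mito_end %% mlen
  frag_len <- circular_length(ms, me, mlen)
  if (spec$mito_start == 0 && spec$mito_end %% mlen == 0 &&
      spec$mito_end > 0) frag_len <- mlen
  if (frag_len == 0) stop("zero-length fragment")
  frag <- Biostrings::subseq(Biostrings::xscat(mito_seq, mito_seq),
                             start = ms + 1L, width = frag_len)
  strand <- if (is.null(spec$strand)) "+" else spec$strand
  if (strand == "-") frag <- Biostrings::reverseComplement(frag)
  hap <- Biostrings::xscat(Biostrings::subseq(nuclear_seq, 1, pos),
                           frag,
                           Biostrings::subseq(nuclear_seq, pos + 1,
                                              length(nuclear_seq)))
  segments <- data.frame(
    hap_start = c(0L, pos, pos + frag_len),
    len = c(pos, frag_len, length(nuclear_seq) - pos),
    source = c("nuc", "mito", "nuc"),
    src_start = c(0L, ms, pos),
    strand = c("+", strand, "+"),
    stringsAsFactors = FALSE)
  segments <- segments[segments$len > 0, , drop = FALSE]
  list(seq = hap, segments = segments, fragment_length = frag_len)
}

plain_segments <- function(nuclear_len) {
  data.frame(hap_start = 0L, len = nuclear_len, source = "nuc",
             src_start = 0L, strand = "+", stringsAsFactors = FALSE)
}

#' Simulate paired-end fragments from a haplotype mixture
#'
#' Fragment lengths are Normal(\code{insert_mean}, \code{insert_sd}),
#' truncated below at \code{read_length}; start positions are uniform; each
#' pair picks one of the two chromosomal haplotypes at random (so a
#' heterozygote is a 50/50 mixture). Substitution errors are applied at
#' \code{base_error} per base.
#'
#' @param haplotypes list of two haplotype objects (as from
#'   \code{\link{implant_numt}} or \code{seq}+\code{segments} for the plain
#'   chromosome).
#' @param config a \code{numt_sim_config}.
#' @return data.frame of pairs with haplotype index, fragment start (0-based
#'   on that haplotype) and fragment length.
#' @export
simulate_pairs <- function(haplotypes, config) {
  stopifnot(length(haplotypes) == 2)
  rl <- config$read_length
  mean_hap_len <- mean(vapply(haplotypes, function(h) length(h$seq), 0))
  n_pairs <- round(config$coverage * mean_hap_len / (2 * rl))
  hap_idx <- sample.int(2, n_pairs, replace = TRUE)
  frag_len <- pmax(rl, round(rnorm(n_pairs, config$insert_mean,
                                   config$insert_sd)))
  hap_len <- vapply(haplotypes, function(h) length(h$seq), 0)[hap_idx]
  frag_len <- pmin(frag_len, hap_len)
  start <- floor(runif(n_pairs) * (hap_len - frag_len + 1))
  data.frame(pair_id = seq_len(n_pairs), hap = hap_idx, start = start,
             frag_len = frag_len)
}

# Project read intervals [a, b) on a haplotype onto the un-inserted
# reference via the segment map; vectorised over reads. Each read aligns
# within the segment holding most of it, the remainder soft-clipped.
project_reads <- function(a, b, segments, config) {
  n <- length(a)
  ns <- nrow(segments)
  ov <- matrix(0L, n, ns)
  for (k in seq_len(ns)) {
    ov[, k] <- pmax(0L, pmin(b, segments$hap_start[k] + segments$len[k]) -
                      pmax(a, segments$hap_start[k]))
  }
  i <- max.col(ov, ties.method = "first")
  hs <- segments$hap_start[i]; sl <- segments$len[i]
  src <- segments$src_start[i]
  is_mito <- segments$source[i] == "mito"
  is_minus <- is_mito & segments$strand[i] == "-"
  clip_left <- pmax(0L, hs - a)
  clip_right <- pmax(0L, b - (hs + sl))
  aligned <- (b - a) - clip_left - clip_right
  off <- (a + clip_left) - hs
  pos <- src + off                                  # nuclear default
  flip <- rep(FALSE, n)
  mlen <- config$mito_length
  if (any(is_mito & !is_minus)) {
    j <- which(is_mito & !is_minus)
    mpos <- (src[j] + off[j]) %% mlen
    over <- pmax(0L, (mpos + aligned[j]) - mlen)  # clip past the linear end
    pos[j] <- mpos
    clip_right[j] <- clip_right[j] + over
    aligned[j] <- aligned[j] - over
  }
  if (any(is_minus)) {
    j <- which(is_minus)
    frag_off_end <- sl[j] - off[j]
    mpos <- (src[j] + frag_off_end - aligned[j]) %% mlen
    over <- pmax(0L, (mpos + aligned[j]) - mlen)
    pos[j] <- mpos + over
    cl <- clip_left[j]
    clip_left[j] <- clip_right[j]
    clip_right[j] <- cl + over
    aligned[j] <- aligned[j] - over
    flip[j] <- TRUE
  }
  data.frame(rname = ifelse(is_mito, config$mito_name, config$nuclear_name),
             pos = pos, clip_left = clip_left, clip_right = clip_right,
             aligned = aligned, mito = is_mito, flip = flip,
             stringsAsFactors = FALSE)
}

make_cigar <- function(clip_left, aligned, clip_right) {
  paste0(ifelse(clip_left > 0, paste0(clip_left, "S"), ""),
         aligned, "M",
         ifelse(clip_right > 0, paste0(clip_right, "S"), ""))
}

# Substitution errors at `rate` per base, vectorised over a character vector
# of reads.
apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    for (h in hit) {
      chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1)
    }
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Project simulated pairs into alignment records against the reference
#'
#' Reads wholly inside nuclear flanks align normally (MAPQ 60); reads wholly
#' inside an implanted fragment align to the mitochondrial contig (modulo
#' circularity); junction-spanning reads are soft-clipped at the breakpoint
#' with the clipped bases preserved. Mate fields and SAM flags are set
#' consistently; pairs whose two ends both align to the nuclear contig in
#' FR orientation are flagged properly paired.
#'
#' @param pairs data.frame from \code{\link{simulate_pairs}}.
#' @param haplotypes the haplotype list the pairs were drawn from.
#' @param config a \code{numt_sim_config}.
#' @return data.frame of SAM records (two rows per pair).
#' @export
project_alignments <- function(pairs, haplotypes, config) {
  rl <- config$read_length
  per_hap <- lapply(seq_along(haplotypes), function(h) {
    sel <- which(pairs$hap == h)
    if (length(sel) == 0L) return(NULL)
    hap <- haplotypes[[h]]
    hap_str <- as.character(hap$seq)
    s <- pairs$start[sel]; fl <- pairs$frag_len[sel]
    w <- pmin(rl, fl)
    a1 <- s; b1 <- s + w
    a2 <- s + fl - w; b2 <- s + fl
    p1 <- project_reads(a1, b1, hap$segments, config)
    p2 <- project_reads(a2, b2, hap$segments, config)
    seq1 <- apply_base_errors(substring(hap_str, a1 + 1, b1),
                              config$base_error)
    seq2 <- apply_base_errors(substring(hap_str, a2 + 1, b2),
                              config$base_error)
    # read1 is sequenced forward on the haplotype, read2 reverse; SEQ is
    # stored reference-forward, which equals haplotype orientation except
    # when a read sits in a minus-strand insert segment (flip).
    if (any(p1$flip)) {
      seq1[p1$flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seq1[p1$flip])))
    }
    if (any(p2$flip)) {
      seq2[p2$flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seq2[p2$flip])))
    }
    rev1 <- p1$flip
    rev2 <- !p2$flip
    proper <- !p1$mito & !p2$mito & !rev1 & rev2
    flag1 <- 1L + 2L * proper + 16L * rev1 + 32L * rev2 + 64L
    flag2 <- 1L + 2L * proper + 16L * rev2 + 32L * rev1 + 128L
    qname <- sprintf("%s_pair_%06d", config$sample_id, pairs$pair_id[sel])
    same_ref <- p1$rname == p2$rname
    sp <- pmin(p1$pos, p2$pos)
    ep <- pmax(p1$pos + p1$aligned, p2$pos + p2$aligned)
    sgn <- ifelse(p1$pos <= p2$pos, 1L, -1L)
    tlen1 <- ifelse(same_ref, sgn * (ep - sp), 0L)
    data.frame(
      qname = c(qname, qname),
      flag = c(flag1, flag2),
      rname = c(p1$rname, p2$rname),
      pos = c(p1$pos, p2$pos),
      mapq = c(mapq_for(p1, config), mapq_for(p2, config)),
      cigar = c(make_cigar(p1$clip_left, p1$aligned, p1$clip_right),
                make_cigar(p2$clip_left, p2$aligned, p2$clip_right)),
      rnext = c(ifelse(same_ref, "=", p2$rname),
                ifelse(same_ref, "=", p1$rname)),
      pnext = c(p2$pos, p1$pos) + 1L,
      tlen = c(tlen1, -tlen1),
      seq = c(seq1, seq2), stringsAsFactors = FALSE)
  })
  do.call(rbind, per_hap)
}

mapq_for <- function(p, config) {
  mq <- rep(60L, nrow(p))
  if (!is.null(config$repeat_flank)) {
    hit <- !p$mito & p$pos >= config$repeat_flank[1] &
      p$pos < config$repeat_flank[2]
    mq[hit] <- 0L
  }
  mq
}

#' Simulate one sample and write a sorted, indexed fixture
#'
#' Runs the full generator: builds references and haplotypes, simulates
#' pairs, projects them against the un-inserted reference, and writes a
#' coordinate-sorted indexed BAM plus FASTA references and a truth table.
#'
#' @param config a \code{numt_sim_config}.
#' @param out_dir output directory (created if needed).
#' @param write_fasta also write the reference FASTA (default TRUE).
#' @return list with paths (\code{bam}, \code{fasta}, \code{truth}) and the
#'   in-memory \code{truth} data.frame, reference sequences and record count.
#' @export
simulate_sample <- function(config, out_dir = tempfile("numtsim"),
                            write_fasta = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  nuc <- if (is.null(config$nuclear_seq)) random_dna(config$nuclear_length)
         else config$nuclear_seq
  mito <- if (is.null(config$mito_seq)) random_dna(config$mito_length)
          else config$mito_seq
  config$nuclear_length <- length(nuc)
  config$mito_length <- length(mito)
  plain <- list(seq = nuc, segments = plain_segments(length(nuc)))
  truth <- list()
  # haplotype pair: implant according to genotype of the (single-locus) specs
  hap1 <- plain; hap2 <- plain
  for (j in seq_along(config$numt_spec)) {
    sp <- config$numt_spec[[j]]
    imp <- implant_numt(nuc, mito, sp)
    g <- sp$genotype
    if (g >= 1) hap1 <- imp
    if (g >= 2) hap2 <- imp
    truth[[j]] <- data.frame(
      site_id = sprintf("sim_numt_%d", j), sample_id = config$sample_id,
      chrom = config$nuclear_name, breakpoint = sp$nuclear_pos,
      mito_start = sp$mito_start %% config$mito_length,
      mito_end = sp$mito_end %% config$mito_length,
      fragment_length = imp$fragment_length,
      strand = if (is.null(sp$strand)) "+" else sp$strand,
      genotype = g, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(site_id = character(0), sample_id = character(0),
               chrom = character(0), breakpoint = integer(0),
               mito_start = integer(0), mito_end = integer(0),
               fragment_length = integer(0), strand = character(0),
               genotype = integer(0), stringsAsFactors = FALSE)
  pairs <- simulate_pairs(list(hap1, hap2), config)
  recs <- project_alignments(pairs, list(hap1, hap2), config)
  bam <- write_fixture(recs, config, out_dir)
  fasta <- NULL
  if (write_fasta) {
    fasta <- file.path(out_dir, "reference.fa")
    refs <- Biostrings::DNAStringSet(list(nuc, mito))
    names(refs) <- c(config$nuclear_name, config$mito_name)
    Biostrings::writeXStringSet(refs, fasta)
  }
  truth_path <- file.path(out_dir, paste0(config$sample_id, ".truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(bam = bam, fasta = fasta, truth_path = truth_path, truth = truth,
       nuclear_seq = nuc, mito_seq = mito, n_pairs = nrow(pairs),
       records = recs, config = config)
}

#' Write alignment records as a coordinate-sorted, indexed BAM
#'
#' @param records data.frame from \code{\link{project_alignments}}.
#' @param config the \code{numt_sim_config} (contig names and lengths).
#' @param out_dir output directory.
#' @return path to the sorted BAM (index alongside).
#' @export
write_fixture <- function(records, config, out_dir) {
  sam <- file.path(out_dir, paste0(config$sample_id, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", config$nuclear_name,
                   config$nuclear_length),
           sprintf("@SQ\tSN:%s\tLN:%d", config$mito_name, config$mito_length),
           sprintf("@RG\tID:%s\tSM:%s", config$sample_id, config$sample_id))
  rname_order <- match(records$rname, c(config$nuclear_name, config$mito_name))
  records <- records[order(rname_order, records$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  records$qname, records$flag, records$rname,
                  records$pos + 1L, records$mapq, records$cigar,
                  records$rnext, records$pnext, records$tlen, records$seq)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate a genotyped cohort at one numt locus
#'
#' Draws each sample's genotype from Hardy-Weinberg proportions at the given
#' allele frequency and simulates an aligned fixture per sample over a shared
#' reference.
#'
#' @param n_samples number of samples.
#' @param allele_frequency population insertion allele frequency.
#' @param base_config a \code{numt_sim_config} whose single
#'   \code{numt_spec} entry defines the locus (its genotype field is
#'   overridden per sample).
#' @param out_dir output directory.
#' @return list with \code{samples} (per-sample simulate_sample outputs),
#'   \code{genotypes} (integer vector of truth genotypes),
#'   \code{nuclear_seq}, \code{mito_seq}.
#' @export
simulate_cohort <- function(n_samples, allele_frequency, base_config,
                            out_dir = tempfile("numtcohort")) {
  stopifnot(length(base_config$numt_spec) == 1)
  set.seed(base_config$seed)
  genotypes <- rbinom(n_samples, 2, allele_frequency)
  nuc <- if (is.null(base_config$nuclear_seq))
    random_dna(base_config$nuclear_length) else base_config$nuclear_seq
  mito <- if (is.null(base_config$mito_seq))
    random_dna(base_config$mito_length) else base_config$mito_seq
  seeds <- sample.int(.Machine$integer.max %/% 2, n_samples)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg <- base_config
    cfg$nuclear_seq <- nuc
    cfg$mito_seq <- mito
    cfg$seed <- seeds[i]
    cfg$sample_id <- sprintf("S%03d", i)
    cfg$numt_spec[[1]]$genotype <- genotypes[i]
    samples[[i]] <- simulate_sample(cfg, file.path(out_dir, cfg$sample_id),
                                    write_fasta = (i == 1))
  }
  list(samples = samples, genotypes = genotypes, nuclear_seq = nuc,
       mito_seq = mito, out_dir = out_dir)
}
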