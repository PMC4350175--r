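#' Pooled-sequencing configuration
#'
#' @param mean_depth mean read depth per site.
#' @param depth_law `"poisson"` (default) or `"fixed"`; fixed depth is used
#'   by the exact detection-probability companion.
#' @param strand_prob probability a read is forward-strand.
#' @param base_error_rate per-base sequencing error probability. Errors are
#'   symmetric over the three non-reference bases, so the effective error
#'   rate toward the tracked alternate allele is `base_error_rate / 3`.
#' @param read_len read length in bp.
#' @return object of class `seq_config`.
#' @export
seq_config <- function(mean_depth = 800, depth_law = c("poisson", "fixed"),
                       strand_prob = 0.5, base_error_rate = 0.001,
                       read_len = 101) {
  depth_law <- match.arg(depth_law)
  cfg <- structure(list(mean_depth = mean_depth, depth_law = depth_law,
                        strand_prob = strand_prob,
                        base_error_rate = base_error_rate,
                        read_len = as.integer(read_len)),
                   class = "seq_config")
  errs <- check_seq_config(cfg)
  if (length(errs)) stop("invalid seq_config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

check_seq_config <- function(cfg) {
  errs <- character()
  if (!(cfg$mean_depth > 0)) errs <- c(errs, "mean_depth: must be > 0")
  if (!(cfg$base_error_rate >= 0 && cfg$base_error_rate < 0.25))
    errs <- c(errs, "base_error_rate: must be in [0, 0.25)")
  if (!(cfg$strand_prob > 0 && cfg$strand_prob < 1))
    errs <- c(errs, "strand_prob: must be in (0, 1)")
  if (!(cfg$read_len >= 1)) errs <- c(errs, "read_len: must be >= 1")
  errs
}

#' Simulate strand-split site counts for true allele frequencies
#'
#' Depth is Poisson (or fixed) around `mean_depth`; each read is
#' forward-strand with probability `strand_prob` and supports the alternate
#' allele with probability `f (1 - e) + (1 - f) e / 3`.
#'
#' @param true_freq vector of true allele frequencies in `[0, 1]`.
#' @param cfg a [seq_config()].
#' @return data.frame with columns `depth_fwd`, `depth_rev`, `alt_fwd`,
#'   `alt_rev`, one row per frequency.
#' @export
sample_site_counts <- function(true_freq, cfg) {
  stopifnot(all(true_freq >= 0 & true_freq <= 1))
  n <- length(true_freq)
  depth <- switch(cfg$depth_law,
                  poisson = rpois(n, cfg$mean_depth),
                  fixed = rep(as.integer(round(cfg$mean_depth)), n))
  e <- cfg$base_error_rate
  p_alt <- true_freq * (1 - e) + (1 - true_freq) * e / 3
  depth_fwd <- rbinom(n, depth, cfg$strand_prob)
  depth_rev <- depth - depth_fwd
  alt_fwd <- rbinom(n, depth_fwd, p_alt)
  alt_rev <- rbinom(n, depth_rev, p_alt)
  data.frame(depth_fwd = depth_fwd, depth_rev = depth_rev,
             alt_fwd = alt_fwd, alt_rev = alt_rev)
}

#' Sequence one population sample
#'
#' @param truth_at_day data.frame with columns `mutation_id` and `freq`
#'   (true frequencies at one sample day).
#' @param sample_day the day label attached to the output.
#' @param cfg a [seq_config()].
#' @return SiteCounts data.frame: `mutation_id`, `sample_day`, strand-split
#'   depths and alternate counts; one row per truth mutation.
#' @export
make_sample <- function(truth_at_day, sample_day, cfg) {
  stopifnot(all(c("mutation_id", "freq") %in% names(truth_at_day)))
  sc <- sample_site_counts(truth_at_day$freq, cfg)
  cbind(data.frame(mutation_id = truth_at_day$mutation_id,
                   sample_day = rep_len(sample_day, nrow(truth_at_day)),
                   stringsAsFactors = FALSE),
        sc)
}

# encode one integer Phred vector as a Phred+33 string
phred_string <- function(q) intToUtf8(as.integer(q) + 33L)

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

#' Generate paired reads with planted duplicates and trim spans
#'
#' Fixture generator for the trimming/deduplication stage: a known subset of
#' pairs are exact PCR duplicates (byte-identical copies of an earlier pair,
#' so they trip the first-20-bases rule deterministically) and each read
#' carries a planted high-quality segment inside low-quality (Q2) flanks so
#' the correct trim span is known.
#'
#' @param n_fragments number of read pairs.
#' @param dup_fraction fraction of pairs that are duplicates of earlier
#'   pairs (`round(n_fragments * dup_fraction)` pairs, appended last).
#' @param cfg a [seq_config()] (supplies `read_len`).
#' @param q_high,q_low Phred scores inside/outside the planted span.
#' @param min_span minimum planted span length.
#' @return data.frame with columns `read1_seq`, `read1_qual`, `read2_seq`,
#'   `read2_qual`, `is_duplicate_of` (NA or the 1-based index of the
#'   original pair), and planted spans `trim1_start`, `trim1_end`,
#'   `trim2_start`, `trim2_end` (1-based inclusive).
#' @export
make_read_pairs <- function(n_fragments, dup_fraction, cfg,
                            q_high = 35L, q_low = 2L, min_span = 30L) {
  stopifnot(dup_fraction >= 0, dup_fraction < 1, n_fragments >= 1)
  n_dup <- as.integer(round(n_fragments * dup_fraction))
  n_orig <- n_fragments - n_dup
  L <- cfg$read_len
  plant <- function(n) {
    span_len <- sample(min_span:L, n, replace = TRUE)
    start <- vapply(span_len, function(sl) sample.int(L - sl + 1L, 1L), 0L)
    qual <- vapply(seq_len(n), function(i) {
      q <- rep(q_low, L)
      q[start[i]:(start[i] + span_len[i] - 1L)] <- q_high
      phred_string(q)
    }, "")
    list(qual = qual, start = start, end = start + span_len - 1L)
  }
  p1 <- plant(n_orig); p2 <- plant(n_orig)
  batch <- data.frame(
    read1_seq = random_dna(n_orig, L), read1_qual = p1$qual,
    read2_seq = random_dna(n_orig, L), read2_qual = p2$qual,
    is_duplicate_of = NA_integer_,
    trim1_start = p1$start, trim1_end = p1$end,
    trim2_start = p2$start, trim2_end = p2$end,
    stringsAsFactors = FALSE
  )
  if (n_dup > 0) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    dup <- batch[src, ]
    dup$is_duplicate_of <- src
    batch <- rbind(batch, dup)
    rownames(batch) <- NULL
  }
  batch
}

#' Write / read a pair batch as two FASTQ files
#'
#' Standard 4-line FASTQ records, Phred+33, via Biostrings.
#'
#' @param batch a read-pair data.frame (see [make_read_pairs()]).
#' @param file1,file2 output paths for mate 1 and mate 2.
#' @return `write_fastq_pairs`: the file paths, invisibly;
#'   `read_fastq_pairs`: a data.frame with `read1_seq`, `read1_qual`,
#'   `read2_seq`, `read2_qual`.
#' @export
write_fastq_pairs <- function(batch, file1, file2) {
  ids <- sprintf("pair%06d", seq_len(nrow(batch)))
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(batch$read1_seq, batch$read1_qual, file1)
  write_one(batch$read2_seq, batch$read2_qual, file2)
  invisible(c(file1, file2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(file1, file2) {
  read_one <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  r1 <- read_one(file1); r2 <- read_one(file2)
  if (length(r1$seq) != length(r2$seq))
    stop("mate files contain different numbers of reads")
  data.frame(read1_seq = unname(r1$seq), read1_qual = unname(r1$qual),
             read2_seq = unname(r2$seq), read2_qual = unname(r2$qual),
             stringsAsFactors = FALSE)
}
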