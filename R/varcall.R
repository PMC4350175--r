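#' Variant-calling policy for pooled samples
#'
#' The filters applied to every site in every sample: coverage on both
#' strands, a minimum number of reads supporting the mutant allele, and a
#' minimum reportable frequency.
#'
#' @param min_alt_reads minimum reads supporting the mutant allele.
#' @param require_both_strand_coverage site must be covered by at least one
#'   read on each strand. If `alt_on_both_strands` is `TRUE` the stricter
#'   variant is used: the *mutant allele* must be seen on both strands.
#' @param min_report_freq minimum allele frequency reported (default 1%).
#' @param alt_on_both_strands see above; default `FALSE` (the condition
#'   attaches to site coverage, not to mutant reads).
#' @return object of class `call_policy`.
#' @export
call_policy <- function(min_alt_reads = 3L, require_both_strand_coverage = TRUE,
                        min_report_freq = 0.01, alt_on_both_strands = FALSE) {
  stopifnot(min_alt_reads >= 1, min_report_freq > 0, min_report_freq < 1)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 require_both_strand_coverage = isTRUE(require_both_strand_coverage),
                 min_report_freq = min_report_freq,
                 alt_on_both_strands = isTRUE(alt_on_both_strands)),
            class = "call_policy")
}

#' Apply the pooled-calling filters to one sample of site counts
#'
#' Frequency is estimated as total mutant reads over total coverage. A site
#' is called (`called = TRUE`) only if it passes the strand, support and
#' frequency filters; uncalled sites are retained with their filter flags
#' so downstream trajectory assembly can record them as frequency 0.
#' Zero-coverage sites are never called and are flagged `no_coverage`.
#'
#' @param sites SiteCounts data.frame (columns `depth_fwd`, `depth_rev`,
#'   `alt_fwd`, `alt_rev`, plus `mutation_id`/`sample_day` if present).
#' @param policy a [call_policy()].
#' @return data.frame with `alt_count`, `depth`, `frequency`, filter flags
#'   `pass_strand`, `pass_support`, `pass_freq`, `no_coverage`, and
#'   `called`; input order and identifier columns preserved.
#' @export
call_sample <- function(sites, policy = call_policy()) {
  stopifnot(all(c("depth_fwd", "depth_rev", "alt_fwd", "alt_rev") %in%
                  names(sites)))
  if (any(sites$alt_fwd > sites$depth_fwd | sites$alt_rev > sites$depth_rev))
    stop("alt counts exceed strand depth")
  depth <- sites$depth_fwd + sites$depth_rev
  alt <- sites$alt_fwd + sites$alt_rev
  frequency <- ifelse(depth > 0, alt / depth, 0)
  pass_strand <- if (!policy$require_both_strand_coverage) depth > 0
  else if (policy$alt_on_both_strands) sites$alt_fwd > 0 & sites$alt_rev > 0
  else sites$depth_fwd > 0 & sites$depth_rev > 0
  pass_support <- alt >= policy$min_alt_reads
  pass_freq <- frequency >= policy$min_report_freq
  out <- sites[, intersect(c("mutation_id", "sample_day"), names(sites)),
               drop = FALSE]
  out$alt_count <- alt
  out$depth <- depth
  out$frequency <- frequency
  out$pass_strand <- pass_strand
  out$pass_support <- pass_support
  out$pass_freq <- pass_freq
  out$no_coverage <- depth == 0
  out$called <- pass_strand & pass_support & pass_freq & depth > 0
  out
}

#' Call a single site
#'
#' @param site one-row SiteCounts data.frame (or a list with the four count
#'   fields).
#' @param policy a [call_policy()].
#' @return one-row data.frame as in [call_sample()] if the site is called,
#'   otherwise `NULL` (ABSENT).
#' @export
call_site <- function(site, policy = call_policy()) {
  res <- call_sample(as.data.frame(site[c("depth_fwd", "depth_rev",
                                          "alt_fwd", "alt_rev")]), policy)
  if (res$called) res else NULL
}

#' Exact detection probability of the pooled-calling filters
#'
#' Under the sequencing model with no base errors and fixed depth `D`, a
#' site carrying a true allele frequency `f` passes the filters iff the
#' mutant read count `X ~ Binomial(D, f)` reaches
#' `max(min_alt_reads, ceiling(min_report_freq * D))` and both strands are
#' covered, which happens with probability `1 - 2 (1/2)^D` independently of
#' `X` (strand assignment is independent of mutant status).
#'
#' @param f true allele frequency in `[0, 1]`.
#' @param mean_depth fixed per-site depth `D`.
#' @param policy a [call_policy()].
#' @return probability that the site is called.
#' @export
detection_probability <- function(f, mean_depth, policy = call_policy()) {
  stopifnot(all(f >= 0 & f <= 1), mean_depth >= 1)
  D <- as.integer(round(mean_depth))
  k <- max(policy$min_alt_reads, ceiling(policy$min_report_freq * D))
  p_strand <- if (policy$require_both_strand_coverage) 1 - 2 * 0.5^D else 1
  (1 - pbinom(k - 1, D, f)) * p_strand
}

#' Write called sites as a minimal VCF
#'
#' One record per called site: CHROM/POS/REF/ALT with INFO fields DP
#' (depth), AF (allele frequency), SAF/SAR (strand-split mutant support).
#'
#' @param calls output of [call_sample()] (possibly several days bound
#'   together), joined with mutation metadata.
#' @param meta mutation metadata data.frame with `id`, `position`, `ref`,
#'   `alt` columns.
#' @param sites the SiteCounts used for calling (for SAF/SAR).
#' @param path output file.
#' @param chrom chromosome name used in the records.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, meta, sites, path, chrom = "sim") {
  called <- which(calls$called)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
           "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
           "##INFO=<ID=DAY,Number=1,Type=Float,Description=\"Sample day\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (length(called)) {
    m <- meta[match(calls$mutation_id[called], meta$id), ]
    day <- if ("sample_day" %in% names(calls)) calls$sample_day[called] else NA
    info <- sprintf("DP=%d;AF=%.6g;SAF=%d;SAR=%d%s",
                    calls$depth[called], calls$frequency[called],
                    sites$alt_fwd[called], sites$alt_rev[called],
                    ifelse(is.na(day), "", sprintf(";DAY=%g", day)))
    rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                   chrom, m$position, m$id, m$ref,
                   ifelse(m$alt %in% c("A", "C", "G", "T"), m$alt, "<ABS>"),
                   info)
  } else rec <- character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
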