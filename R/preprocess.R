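#' Phred score to error probability
#'
#' @param q Phred quality score(s), `q >= 0`.
#' @return per-base error probability `10^(-q/10)`.
#' @export
error_prob <- function(q) {
  if (any(q < 0)) stop("Phred scores must be >= 0")
  10^(-q / 10)
}

#' Trimming policy
#'
#' A read is reduced to its longest contiguous segment in which every base
#' has error probability at most `p_max`; the segment is kept only if it is
#' strictly longer than `min_len` bases.
#'
#' @param p_max maximum per-base error probability (default 0.05).
#' @param min_len segments must be longer than this many bp (strict;
#'   default 25, i.e. kept iff length >= 26).
#' @return object of class `trim_policy`.
#' @export
trim_policy <- function(p_max = 0.05, min_len = 25L) {
  stopifnot(p_max > 0, p_max < 1, min_len >= 1)
  structure(list(p_max = p_max, min_len = as.integer(min_len)),
            class = "trim_policy")
}

decode_phred <- function(qual) {
  if (is.character(qual)) utf8ToInt(qual) - 33L else as.integer(qual)
}

#' Trim a read to its longest high-quality segment
#'
#' Finds the longest contiguous run of bases whose error probability is at
#' most `policy$p_max` (ties broken leftmost) and rejects the read if the
#' run is not longer than `policy$min_len`.
#'
#' @param qualities Phred scores: integer vector or a Phred+33 string.
#' @param policy a [trim_policy()].
#' @return integer `c(start, end)` (1-based, inclusive) of the kept span,
#'   or `NULL` if the read is rejected.
#' @export
trim_read <- function(qualities, policy = trim_policy()) {
  q <- decode_phred(qualities)
  if (length(q) == 0) stop("empty quality vector")
  ok <- error_prob(q) <= policy$p_max
  r <- rle(ok)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  best <- good[which.max(r$lengths[good])]  # which.max is leftmost on ties
  if (r$lengths[best] <= policy$min_len) return(NULL)
  c(starts[best], ends[best])
}

pair_key <- function(batch, k = 20L) {
  paste(substr(batch$read1_seq, 1L, k), substr(batch$read2_seq, 1L, k),
        sep = "|")
}

#' Remove PCR-duplicate read pairs
#'
#' A pair is a duplicate when the first 20 bases of *both* mates equal
#' those of an earlier pair (mate order matters). The first occurrence is
#' kept; input order is preserved. Reads shorter than 20 bp contribute
#' their full sequence to the key.
#'
#' @param batch read-pair data.frame with `read1_seq` and `read2_seq`
#'   columns (extra columns are carried through).
#' @return the deduplicated batch; attribute `"removed"` holds the dropped
#'   row indices.
#' @export
dedup_pairs <- function(batch) {
  keep <- !duplicated(pair_key(batch))
  out <- batch[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- which(!keep)
  out
}

#' Deduplicate and trim a batch of read pairs
#'
#' Applies [dedup_pairs()] and then [trim_read()] to both mates; pairs in
#' which either mate is rejected are dropped. A summary (pairs in, pairs
#' after dedup, pairs kept after trimming) is emitted as a message and
#' attached as attribute `"summary"`.
#'
#' @param batch read-pair data.frame (see [make_read_pairs()]).
#' @param policy a [trim_policy()].
#' @param verbose emit the summary line.
#' @return batch of trimmed pairs (sequences and qualities cut to the kept
#'   span; `trim1`/`trim2` columns record the spans).
#' @export
preprocess_pairs <- function(batch, policy = trim_policy(), verbose = TRUE) {
  n_in <- nrow(batch)
  dd <- dedup_pairs(batch)
  n_dedup <- nrow(dd)
  s1 <- lapply(dd$read1_qual, trim_read, policy = policy)
  s2 <- lapply(dd$read2_qual, trim_read, policy = policy)
  ok <- !vapply(s1, is.null, TRUE) & !vapply(s2, is.null, TRUE)
  out <- dd[ok, , drop = FALSE]
  s1 <- s1[ok]; s2 <- s2[ok]
  cut <- function(x, sp) substr(x, sp[1], sp[2])
  out$read1_seq <- mapply(cut, out$read1_seq, s1, USE.NAMES = FALSE)
  out$read1_qual <- mapply(cut, out$read1_qual, s1, USE.NAMES = FALSE)
  out$read2_seq <- mapply(cut, out$read2_seq, s2, USE.NAMES = FALSE)
  out$read2_qual <- mapply(cut, out$read2_qual, s2, USE.NAMES = FALSE)
  out$trim1_start <- vapply(s1, `[`, 0L, 1L)
  out$trim1_end <- vapply(s1, `[`, 0L, 2L)
  out$trim2_start <- vapply(s2, `[`, 0L, 1L)
  out$trim2_end <- vapply(s2, `[`, 0L, 2L)
  rownames(out) <- NULL
  summary <- c(pairs_in = n_in, pairs_after_dedup = n_dedup,
               pairs_kept = nrow(out))
  if (verbose)
    message(sprintf("[preprocess] pairs in: %d, after dedup: %d, kept after trim: %d",
                    n_in, n_dedup, nrow(out)))
  attr(out, "summary") <- summary
  out
}
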