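# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately avoid the code paths they check.

# longest contiguous run of qualifying bases by O(L^2) enumeration
brute_force_trim <- function(q, p_max = 0.05, min_len = 25L) {
  ok <- 10^(-q / 10) <= p_max
  best <- NULL
  best_len <- 0L
  for (s in seq_along(q)) {
    for (e in s:length(q)) {
      if (all(ok[s:e]) && (e - s + 1L) > best_len) {
        best <- c(s, e)
        best_len <- e - s + 1L
      }
    }
  }
  if (best_len > min_len) best else NULL
}

# exact binomial tail by direct summation (no pbinom)
binom_tail_sum <- function(k, D, f) {
  if (f == 0) return(if (k <= 0) 1 else 0)
  ks <- k:D
  sum(exp(lchoose(D, ks) + ks * log(f) + (D - ks) * log1p(-f)))
}

# a trajectory table built directly from a frequency matrix
table_from_matrix <- function(freq, meta = NULL, sample_days = NULL) {
  if (is.null(sample_days)) sample_days <- seq_len(ncol(freq))
  if (!is.null(meta)) rownames(freq) <- meta$id
  else if (is.null(rownames(freq)))
    rownames(freq) <- sprintf("m%05d", seq_len(nrow(freq)))
  if (is.null(meta))
    meta <- data.frame(id = rownames(freq),
                       position = seq_len(nrow(freq)),
                       ref = "A", alt = "C", mut_class = "SNP",
                       gene = "geneA", effect = "nonsynonymous",
                       role = "neutral", stringsAsFactors = FALSE)
  colnames(freq) <- paste0("day", sample_days)
  structure(list(freq = freq, meta = meta, sample_days = sample_days),
            class = "trajectory_table")
}

# tiny simulation config used across popsim tests
tiny_config <- function(N = 1e4, ...) {
  sim_config(N = N, genome_length = 1e4, mu = 0, duration_days = 10,
             sample_days = c(0, 5, 10), ...)
}

# noisy estimated trajectories for planted true trajectories: sequence at
# depth `depth`, call with default policy, return estimated frequency matrix
estimate_trajectories <- function(true_freq, cfg = seq_config(),
                                  policy = call_policy()) {
  est <- matrix(0, nrow = nrow(true_freq), ncol = ncol(true_freq),
                dimnames = dimnames(true_freq))
  for (j in seq_len(ncol(true_freq))) {
    sc <- sample_site_counts(true_freq[, j], cfg)
    res <- call_sample(sc, policy)
    est[res$called, j] <- res$frequency[res$called]
  }
  est
}
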