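#' L-infinity distance between two trajectories
#'
#' Linked alleles in one genome must match in *level* at every sample day,
#' not merely in shape, so cohort detection uses the maximum absolute
#' per-day difference.
#'
#' @param a,b numeric frequency vectors on the same sample-day grid.
#' @return non-negative scalar; zero iff identical.
#' @export
trajectory_distance <- function(a, b) {
  if (length(a) != length(b)) stop("trajectories on different sample-day grids")
  max(abs(a - b))
}

#' Cluster concordant trajectories into linked cohorts
#'
#' Mutations whose peak frequency reaches `min_peak` are clustered by
#' single-linkage under the L-infinity trajectory distance with threshold
#' `eps`; mutations below `min_peak` are left unclustered (`NA` cohort).
#' Rows are processed in mutation-id order so the result is deterministic
#' and permutation-invariant up to cohort labelling.
#'
#' @param table a [build_table()] result.
#' @param eps maximum L-infinity distance within a cohort (single linkage).
#' @param min_peak minimum peak frequency for a mutation to be clustered.
#' @return object of class `cohort_set`: list with `membership`
#'   (data.frame `mutation_id`, `cohort`), and `cohorts` (list, each with
#'   `members`, `rep_traj` = per-day mean, `driver_genes` = driver genes
#'   represented among members).
#' @export
detect_cohorts <- function(table, eps = 0.05, min_peak = 0.05) {
  peak <- apply(table$freq, 1, max)
  idx <- which(peak >= min_peak)
  if (length(idx) > 1) idx <- idx[order(rownames(table$freq)[idx])]
  membership <- data.frame(
    mutation_id = if (is.null(rownames(table$freq))) table$meta$id
                  else rownames(table$freq),
    cohort = rep(NA_integer_, nrow(table$freq)), stringsAsFactors = FALSE)
  cohorts <- list()
  if (length(idx) == 1) {
    membership$cohort[idx] <- 1L
  } else if (length(idx) > 1) {
    sub <- table$freq[idx, , drop = FALSE]
    d <- stats::dist(sub, method = "maximum")
    cl <- stats::cutree(stats::hclust(d, method = "single"), h = eps)
    membership$cohort[idx] <- as.integer(cl)
  }
  ids <- sort(unique(membership$cohort[!is.na(membership$cohort)]))
  for (cid in ids) {
    mem <- membership$mutation_id[!is.na(membership$cohort) &
                                    membership$cohort == cid]
    rows <- match(mem, rownames(table$freq))
    roles <- table$meta$role[match(mem, table$meta$id)]
    genes <- table$meta$gene[match(mem, table$meta$id)]
    cohorts[[cid]] <- list(
      members = mem,
      rep_traj = colMeans(table$freq[rows, , drop = FALSE]),
      driver_genes = unique(genes[roles %in% c("driver_strong", "driver_late")])
    )
  }
  structure(list(membership = membership, cohorts = cohorts,
                 eps = eps, min_peak = min_peak), class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("cohort_set:", length(x$cohorts), "cohorts over",
      sum(!is.na(x$membership$cohort)), "clustered mutations",
      sprintf("(eps = %g, min_peak = %g)\n", x$eps, x$min_peak))
  invisible(x)
}

#' Classify the selective-sweep regime of a gene
#'
#' Verdicts over the gene's allele trajectories: `hard` when exactly one
#' allele ever reaches `hard_hi`, that allele rose from an undetectable or
#' near-detection-limit origin (first detected frequency at most
#' `origin_max`, or first detection later than the first sample), and no
#' other allele ever reaches `soft_min`; `soft` when two or more alleles
#' each reach `soft_min` (multiple adaptive alleles spreading together);
#' `incomplete` when a single allele reaches `soft_min` without satisfying
#' the hard criteria; `none` otherwise.
#'
#' @param alleles matrix of allele trajectories (alleles x sample days),
#'   rownames = allele/mutation ids.
#' @param hard_hi frequency a hard sweep must reach (default 0.90).
#' @param soft_min frequency at which an allele counts as established
#'   (default 0.10).
#' @param origin_max maximum first-detected frequency for a de novo origin
#'   (default 0.01, the detection limit).
#' @return list of class `sweep_call`: `verdict`, `evidence` (data.frame of
#'   allele peaks and first-detection values).
#' @export
classify_gene_sweep <- function(alleles, hard_hi = 0.90, soft_min = 0.10,
                                origin_max = 0.01) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 1)
  if (nrow(alleles) == 0) stop("no allele trajectories supplied")
  peak <- apply(alleles, 1, max)
  first_idx <- apply(alleles, 1, function(x)
    if (any(x > 0)) which(x > 0)[1] else NA_integer_)
  first_val <- vapply(seq_len(nrow(alleles)), function(i)
    if (is.na(first_idx[i])) 0 else alleles[i, first_idx[i]], 0)
  evidence <- data.frame(
    allele = if (is.null(rownames(alleles)))
      paste0("allele", seq_len(nrow(alleles))) else rownames(alleles),
    peak = peak, first_detected = first_val, first_day_index = first_idx,
    stringsAsFactors = FALSE)
  hi <- which(peak >= hard_hi)
  est <- which(peak >= soft_min)
  verdict <- if (length(hi) == 1 &&
                 (first_val[hi] <= origin_max || first_idx[hi] > 1) &&
                 !any(peak[-hi] >= soft_min)) "hard"
  else if (length(est) >= 2) "soft"
  else if (length(est) == 1) "incomplete"
  else "none"
  structure(list(verdict = verdict, evidence = evidence),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  cat("sweep_call:", x$verdict, "|", nrow(x$evidence), "allele(s), max peak",
      sprintf("%.3f\n", max(x$evidence$peak)))
  invisible(x)
}

#' Sweep verdicts for every gene in a trajectory table
#'
#' @param table a [build_table()] result.
#' @param ... thresholds passed to [classify_gene_sweep()].
#' @return data.frame with `gene`, `verdict`, `n_alleles`, `peak_freq`.
#' @export
classify_all_genes <- function(table, ...) {
  keep <- protein_altering(table$meta) & table$meta$gene != "intergenic" &
    rowSums(table$freq > 0) > 0
  genes <- unique(table$meta$gene[keep])
  if (length(genes) == 0)
    return(data.frame(gene = character(0), verdict = character(0),
                      n_alleles = integer(0), peak_freq = numeric(0)))
  rows <- lapply(genes, function(g) {
    idx <- which(keep & table$meta$gene == g)
    sc <- classify_gene_sweep(table$freq[idx, , drop = FALSE], ...)
    data.frame(gene = g, verdict = sc$verdict, n_alleles = length(idx),
               peak_freq = max(sc$evidence$peak), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_freq, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag hitchhikers inside driver-containing cohorts
#'
#' Members of a cohort that contains at least one driver-gene mutation, but
#' whose own role is neutral/passenger or mutator, are rising through
#' linkage rather than their own benefit.
#'
#' @param cohorts a [detect_cohorts()] result.
#' @param meta mutation metadata with `id` and `role`.
#' @return data.frame `mutation_id`, `cohort`, `role`, `driver_genes`
#'   (comma-separated driver context).
#' @export
detect_hitchhikers <- function(cohorts, meta) {
  out <- list()
  for (cid in seq_along(cohorts$cohorts)) {
    co <- cohorts$cohorts[[cid]]
    if (is.null(co) || length(co$driver_genes) == 0) next
    roles <- meta$role[match(co$members, meta$id)]
    hh <- roles %in% c("passenger", "neutral", "mutator")
    if (any(hh))
      out[[length(out) + 1]] <- data.frame(
        mutation_id = co$members[hh], cohort = cid, role = roles[hh],
        driver_genes = paste(co$driver_genes, collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mutation_id = character(0), cohort = integer(0),
                      role = character(0), driver_genes = character(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Succession of dominant alleles within a gene
#'
#' Per sample day, the allele of maximal frequency provided it reaches
#' `dominance_min` (ties broken by allele id); consecutive days with the
#' same dominant allele are collapsed into runs.
#'
#' @param alleles matrix of allele trajectories (alleles x days), rownames
#'   = allele ids; columns aligned with `sample_days`.
#' @param sample_days day labels for the columns.
#' @param dominance_min minimum frequency to count as dominant.
#' @return data.frame with `allele`, `from_day`, `to_day`, one row per run;
#'   zero rows when no allele is ever dominant.
#' @export
dominant_allele_succession <- function(alleles, sample_days,
                                       dominance_min = 0.10) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 1)
  stopifnot(ncol(alleles) == length(sample_days))
  ids <- if (is.null(rownames(alleles)))
    paste0("allele", seq_len(nrow(alleles))) else rownames(alleles)
  ord <- order(ids)
  dom <- vapply(seq_len(ncol(alleles)), function(j) {
    col <- alleles[ord, j]
    k <- which.max(col)  # leftmost max = smallest allele id on ties
    if (col[k] >= dominance_min) ids[ord][k] else NA_character_
  }, "")
  keep <- !is.na(dom)
  if (!any(keep))
    return(data.frame(allele = character(0), from_day = numeric(0),
                      to_day = numeric(0)))
  r <- rle(dom[keep])
  days <- sample_days[keep]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(allele = r$values, from_day = days[starts],
             to_day = days[ends], stringsAsFactors = FALSE)
}

#' Rand index between two partitions
#'
#' Fraction of object pairs on which two clusterings agree (same/different
#' cluster); 1 for identical partitions.
#'
#' @param a,b cluster labels of the same objects.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}
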