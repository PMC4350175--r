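#' Assemble per-mutation frequency trajectories
#'
#' Builds the mutation x sample-day frequency matrix from per-sample call
#' results. Sites that were not called (ABSENT) are recorded as frequency
#' 0, never missing, so trajectories are totally ordered and distances are
#' well defined.
#'
#' @param calls data.frame of call results for all samples (rows from
#'   [call_sample()], with `mutation_id` and `sample_day`).
#' @param meta mutation metadata data.frame with at least `id`, `gene`,
#'   `effect`, `mut_class` columns.
#' @param sample_days the full ordered vector of sample days.
#' @return object of class `trajectory_table`: list with `freq` (matrix,
#'   rownames = mutation ids, one column per day), `meta`, `sample_days`.
#' @export
build_table <- function(calls, meta, sample_days) {
  stopifnot(all(c("mutation_id", "sample_day", "frequency", "called") %in%
                  names(calls)))
  unknown <- setdiff(unique(calls$mutation_id), meta$id)
  if (length(unknown))
    stop("calls reference unknown mutation(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  bad_day <- setdiff(unique(calls$sample_day), sample_days)
  if (length(bad_day))
    stop("calls reference unknown sample day(s): ",
         paste(bad_day, collapse = ", "))
  freq <- matrix(0, nrow = nrow(meta), ncol = length(sample_days),
                 dimnames = list(meta$id, paste0("day", sample_days)))
  hit <- calls$called
  freq[cbind(match(calls$mutation_id[hit], meta$id),
             match(calls$sample_day[hit], sample_days))] <-
    calls$frequency[hit]
  structure(list(freq = freq, meta = meta, sample_days = sample_days),
            class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat("trajectory_table:", nrow(x$freq), "mutations x",
      length(x$sample_days), "sample days;",
      sum(rowSums(x$freq > 0) > 0), "ever detected\n")
  invisible(x)
}

#' Occurrence spectrum of detected mutations
#'
#' For every mutation detected at least once, the number of sample days at
#' which it was detected; tabulated as a histogram whose bins sum to the
#' total number of ever-detected mutations.
#'
#' @param table a [build_table()] result.
#' @return data.frame with `n_samples` (1..number of days) and `n_mutations`.
#' @export
occurrence_spectrum <- function(table) {
  n_days <- rowSums(table$freq > 0)
  n_days <- n_days[n_days > 0]
  tab <- tabulate(n_days, nbins = length(table$sample_days))
  out <- data.frame(n_samples = seq_along(tab), n_mutations = tab)
  out[out$n_mutations > 0, , drop = FALSE]
}

#' Classify a mutation trajectory by persistence
#'
#' Nested classes over the number of sample days with nonzero frequency:
#' singleton (exactly 1), recurrent (>= 2), repeated (>= 3, the gene-table
#' criterion), persistent (every sample day). The most specific label is
#' returned; an all-zero trajectory is `"undetected"`.
#'
#' @param trajectory numeric frequency vector over all sample days.
#' @return one of `"undetected"`, `"singleton"`, `"recurrent"`,
#'   `"repeated"`, `"persistent"`.
#' @export
classify_mutation <- function(trajectory) {
  n <- sum(trajectory > 0)
  if (n == 0) return("undetected")
  if (n == length(trajectory)) return("persistent")
  if (n >= 3) return("repeated")
  if (n >= 2) return("recurrent")
  "singleton"
}

#' @rdname classify_mutation
#' @param table a [build_table()] result.
#' @return `classify_mutations`: named character vector over all mutations.
#' @export
classify_mutations <- function(table) {
  apply(table$freq, 1, classify_mutation)
}

#' Mutational load at one sample day
#'
#' Number of mutations detected (nonzero frequency) at the given day, split
#' by mutation class.
#'
#' @param table a [build_table()] result.
#' @param day a day in `table$sample_days`.
#' @return named integer vector over `SNP`, `S-indel`, `L-indel`,
#'   `duplication`, plus `total`.
#' @export
mutational_load <- function(table, day) {
  i <- match(day, table$sample_days)
  if (is.na(i)) stop("unknown sample day: ", day)
  present <- table$freq[, i] > 0
  classes <- c("SNP", "S-indel", "L-indel", "duplication")
  counts <- vapply(classes, function(cl)
    sum(present & table$meta$mut_class == cl), 0L)
  c(counts, total = sum(present))
}

protein_altering <- function(meta) meta$effect == "nonsynonymous"

#' Gene-level summary of repeated protein-altering mutations
#'
#' One row per gene carrying at least one protein-altering mutation in
#' class "repeated" (detected at >= 3 sample days): the number of samples
#' at which any such allele was detected, the number of distinct alleles,
#' and the peak of the per-day *summed* allele frequency (capped at 1), the
#' definition under which successive dominant alleles of one gene share a
#' single high peak. Sorted by peak frequency, descending.
#'
#' @param table a [build_table()] result.
#' @return data.frame with `gene`, `n_samples_present`, `n_alleles`,
#'   `peak_freq`.
#' @export
gene_summary <- function(table) {
  keep <- protein_altering(table$meta) & table$meta$gene != "intergenic" &
    apply(table$freq, 1, function(x) sum(x > 0) >= 3)
  if (!any(keep))
    return(data.frame(gene = character(0), n_samples_present = integer(0),
                      n_alleles = integer(0), peak_freq = numeric(0)))
  genes <- unique(table$meta$gene[keep])
  rows <- lapply(genes, function(g) {
    idx <- which(keep & table$meta$gene == g)
    sub <- table$freq[idx, , drop = FALSE]
    daysum <- colSums(sub)
    data.frame(gene = g,
               n_samples_present = sum(colSums(sub > 0) > 0),
               n_alleles = length(idx),
               peak_freq = min(1, max(daysum)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_freq, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Summed allele-frequency time series of one gene
#'
#' Per-day sum of the gene's protein-altering allele frequencies, the
#' genotypic counterpart of a phenotypic sweep curve. Sums above 1 (which
#' can only arise from multiple alleles co-occurring in one genome, or
#' estimation noise) are capped at 1 with a warning.
#'
#' @param table a [build_table()] result.
#' @param gene gene name present in the metadata.
#' @return named numeric vector over sample days.
#' @export
gene_frequency_sum <- function(table, gene) {
  if (!gene %in% table$meta$gene) stop("unknown gene: ", gene)
  idx <- which(table$meta$gene == gene & protein_altering(table$meta))
  s <- colSums(table$freq[idx, , drop = FALSE])
  if (any(s > 1)) {
    warning("summed allele frequency of ", gene,
            " exceeds 1 at some days (capped); possible same-genome alleles")
    s <- pmin(s, 1)
  }
  s
}
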