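#' Generate a random genome sequence
#'
#' Draws a uniform-composition nucleotide sequence used as the reference of
#' the simulated chemostat population. Returned as a plain character vector
#' of single bases so that downstream codon arithmetic stays in fast base-R
#' indexing; use [genome_as_dnastring()] for a Biostrings view.
#'
#' @param length genome length in bp.
#' @return character vector of "A"/"C"/"G"/"T", length `length`.
#' @export
random_genome <- function(length) {
  stopifnot(length >= 1)
  sample(c("A", "C", "G", "T"), length, replace = TRUE)
}

#' @rdname random_genome
#' @param genome character vector of bases.
#' @export
genome_as_dnastring <- function(genome) {
  Biostrings::DNAString(paste(genome, collapse = ""))
}

#' Default gene models for the simulated chemostat genome
#'
#' Lays out non-overlapping protein-coding genes on the genome and assigns
#' the lineage roles the analysis targets: strongly beneficial driver genes
#' (rpoS/mglD/malT-like loss-of-function targets), late drivers (malE,
#' sdhC-like), a negative frequency-dependent gene (hfq-like), a
#' fitness-neutral mutator (mutL-like), and neutral filler genes. Selection
#' coefficients are per-generation and multiplicative across distinct
#' mutated driver genes.
#'
#' @param genome_length genome length in bp.
#' @param gene_length coding length per gene (multiple of 3).
#' @param gap intergenic gap between consecutive genes.
#' @return data.frame with columns `name`, `start`, `end`, `strand`,
#'   `role`, `s`, `n_target_sites` (1-based inclusive coordinates).
#' @export
default_gene_models <- function(genome_length = 1e5, gene_length = 900,
                                gap = 100) {
  stopifnot(gene_length %% 3 == 0, gap >= 0)
  pitch <- gene_length + gap
  n_genes <- (genome_length - gap) %/% pitch
  stopifnot(n_genes >= 1)
  start <- gap + (seq_len(n_genes) - 1L) * pitch + 1L
  end <- start + gene_length - 1L
  name <- sprintf("neu%03d", seq_len(n_genes))
  role <- rep("neutral", n_genes)
  s <- rep(0, n_genes)
  # named genes spread evenly across the genome, whatever its size
  special <- list(
    rpoS = list(role = "driver_strong", s = 0.12),
    mglD = list(role = "driver_strong", s = 0.10),
    malT = list(role = "driver_strong", s = 0.09),
    malE = list(role = "driver_late",   s = 0.06),
    sdhC = list(role = "driver_late",   s = 0.07),
    hfq  = list(role = "freq_dep",      s = 0),
    mutL = list(role = "mutator",       s = 0)
  )
  if (n_genes < length(special))
    stop("genome too small to place the ", length(special),
         " named genes; need >= ", length(special) * pitch + gap, " bp")
  idx <- unique(pmax(1L, round((seq_along(special) - 0.5) /
                                 length(special) * n_genes)))
  stopifnot(length(idx) == length(special))
  for (k in seq_along(special)) {
    name[idx[k]] <- names(special)[k]
    role[idx[k]] <- special[[k]]$role
    s[idx[k]] <- special[[k]]$s
  }
  strand <- rep("+", n_genes)
  strand[seq_len(n_genes) %% 7 == 0] <- "-"
  gm <- data.frame(
    name = name, start = start, end = end, strand = strand,
    role = role, s = s,
    n_target_sites = as.integer(round(2 / 3 * gene_length)),
    stringsAsFactors = FALSE
  )
  validate_gene_models(gm, genome_length)
  gm
}

validate_gene_models <- function(gene_models, genome_length) {
  gm <- gene_models[order(gene_models$start), ]
  if (any(gm$start < 1) || any(gm$end > genome_length))
    stop("gene models outside genome coordinates")
  if (any(gm$end < gm$start))
    stop("gene end before start")
  if (any((gm$end - gm$start + 1L) %% 3 != 0))
    stop("coding gene length must be a multiple of 3")
  if (nrow(gm) > 1 && any(gm$start[-1] <= gm$end[-nrow(gm)]))
    stop("gene models overlap")
  if (any(gm$s < 0)) stop("selection coefficients must be >= 0")
  if (!all(gm$role %in% c("driver_strong", "driver_late", "freq_dep",
                          "mutator", "neutral")))
    stop("unknown gene role")
  invisible(gene_models)
}

#' Locate the gene covering each position
#'
#' @param positions integer vector of 1-based genome coordinates.
#' @param gene_models gene-model data.frame (see [default_gene_models()]).
#' @return character vector of gene names, `"intergenic"` where no gene
#'   covers the position.
#' @export
gene_at <- function(positions, gene_models) {
  gm <- gene_models[order(gene_models$start), ]
  idx <- findInterval(positions, gm$start)
  out <- rep("intergenic", length(positions))
  hit <- idx >= 1 & positions <= gm$end[pmax(idx, 1L)]
  out[hit] <- gm$name[idx[hit]]
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding effect of a SNP
#'
#' Strand-aware codon translation under the standard genetic code:
#' positions outside any gene are `"noncoding"`; inside a gene the affected
#' codon is translated before and after the substitution and compared.
#' Stop gain and start-codon disruption count as nonsynonymous.
#'
#' @param position 1-based genome coordinate (vectorised).
#' @param ref,alt reference and alternate bases.
#' @param gene_models gene-model data.frame.
#' @param genome character vector of bases (the reference sequence).
#' @return character vector in `{"nonsynonymous","synonymous","noncoding"}`.
#' @export
annotate_effect <- function(position, ref, alt, gene_models, genome) {
  stopifnot(length(position) == length(ref), length(ref) == length(alt))
  if (any(position < 1 | position > length(genome)))
    stop("position outside genome")
  gm <- gene_models[order(gene_models$start), ]
  idx <- findInterval(position, gm$start)
  inside <- idx >= 1 & position <= gm$end[pmax(idx, 1L)]
  out <- rep("noncoding", length(position))
  code <- Biostrings::GENETIC_CODE
  for (k in which(inside)) {
    g <- gm[idx[k], ]
    if (g$strand == "+") {
      off <- position[k] - g$start
      cstart <- g$start + (off %/% 3L) * 3L
      codon <- genome[cstart:(cstart + 2L)]
      cpos <- off %% 3L + 1L
      ref_b <- ref[k]; alt_b <- alt[k]
    } else {
      off <- g$end - position[k]
      cend <- g$end - (off %/% 3L) * 3L
      codon <- unname(COMPLEMENT[genome[cend:(cend - 2L)]])
      cpos <- off %% 3L + 1L
      ref_b <- unname(COMPLEMENT[ref[k]])
      alt_b <- unname(COMPLEMENT[alt[k]])
    }
    if (!identical(codon[cpos], ref_b))
      stop("ref base does not match genome at position ", position[k])
    mut <- codon
    mut[cpos] <- alt_b
    aa_ref <- code[[paste(codon, collapse = "")]]
    aa_alt <- code[[paste(mut, collapse = "")]]
    out[k] <- if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
  }
  out
}
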