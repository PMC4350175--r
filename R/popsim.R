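#' Generations per day in a chemostat
#'
#' At steady state the population turns over at the dilution rate, so the
#' number of doubling-equivalent generations per day is `24 * D / ln 2`.
#'
#' @param dilution_rate fractional volume replacement per hour (h^-1).
#' @return generations per day.
#' @export
generations_per_day <- function(dilution_rate) {
  if (any(dilution_rate < 0)) stop("dilution_rate must be >= 0")
  24 * dilution_rate / log(2)
}

#' Simulation configuration
#'
#' Bundles the chemostat-evolution study conditions: population size,
#' genome, per-base mutation rate, mutator fold-increase, dilution rate,
#' duration, sampling days, gene models, the negative frequency-dependence
#' parameters and the epistasis rule (frequency-dependent benefit is
#' nullified on backgrounds already carrying a strong-driver mutation).
#'
#' @param N population size (individuals held constant by the chemostat).
#' @param genome_length genome length in bp.
#' @param mu per-base per-generation mutation rate.
#' @param mutator_fold multiplier applied to `mu` in mutator carriers.
#' @param dilution_rate chemostat dilution rate, h^-1.
#' @param duration_days experiment length in days.
#' @param sample_days days at which the population is sampled; defaults to
#'   11 samples over 60 days, truncated to `duration_days` (0 if none fit).
#' @param gene_models gene-model data.frame; default [default_gene_models()].
#' @param freq_dep numeric `c(s_h, c)`: fitness of a frequency-dependent
#'   carrier is `1 + s_h - c * x_h` with `x_h` the current carrier frequency.
#' @param class_fractions named probabilities over mutation classes
#'   `SNP`, `S-indel`, `L-indel`, `duplication`.
#' @param init_lineages optional list of founder lineages, each a list with
#'   elements `freq`, `genes` (character, possibly repeated) and
#'   `n_passengers` (intergenic neutral markers); see [seed_lineage()].
#' @param seed root random seed for [run_simulation()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(N = 1e6, genome_length = 1e5, mu = 1e-9,
                       mutator_fold = 100, dilution_rate = 0.1,
                       duration_days = 60, sample_days = NULL,
                       gene_models = NULL,
                       freq_dep = c(s_h = 0.15, c = 1.0),
                       class_fractions = c(SNP = 2664, `S-indel` = 45,
                                           `L-indel` = 4, duplication = 1) / 2714,
                       init_lineages = list(), seed = 1L) {
  if (is.null(sample_days)) {
    sample_days <- c(5, 7, 14, 20, 28, 35, 40, 45, 50, 56, 60)
    sample_days <- sample_days[sample_days <= duration_days]
    if (length(sample_days) == 0) sample_days <- 0
  }
  if (is.null(gene_models)) gene_models <- default_gene_models(genome_length)
  cfg <- structure(list(
    N = as.integer(N), genome_length = as.integer(genome_length), mu = mu,
    mutator_fold = mutator_fold, dilution_rate = dilution_rate,
    duration_days = duration_days, sample_days = sample_days,
    gene_models = gene_models, freq_dep = freq_dep,
    class_fractions = class_fractions, init_lineages = init_lineages,
    seed = as.integer(seed)
  ), class = "sim_config")
  errs <- check_sim_config(cfg)
  if (length(errs)) stop("invalid sim_config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

check_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$N >= 1e3, "N: must be >= 1000")
  chk(cfg$genome_length >= 3, "genome_length: must be >= 3")
  chk(is.finite(cfg$mu) && cfg$mu >= 0, "mu: must be a finite non-negative rate")
  chk(is.finite(cfg$mu * cfg$genome_length * cfg$N),
      "mu * genome_length * N: must be finite")
  chk(cfg$mutator_fold >= 1, "mutator_fold: must be >= 1")
  chk(cfg$dilution_rate >= 0, "dilution_rate: must be >= 0")
  chk(cfg$duration_days >= 0, "duration_days: must be >= 0")
  chk(!is.unsorted(cfg$sample_days, strictly = TRUE),
      "sample_days: must be strictly increasing")
  chk(all(cfg$sample_days >= 0 & cfg$sample_days <= cfg$duration_days),
      "sample_days: must lie within [0, duration_days]")
  chk(length(cfg$freq_dep) == 2 && all(is.finite(cfg$freq_dep)),
      "freq_dep: must be numeric (s_h, c)")
  chk(abs(sum(cfg$class_fractions) - 1) < 1e-8 && all(cfg$class_fractions >= 0),
      "class_fractions: must be non-negative and sum to 1")
  gm_err <- tryCatch({ validate_gene_models(cfg$gene_models, cfg$genome_length); NULL },
                     error = function(e) conditionMessage(e))
  if (!is.null(gm_err)) errs <- c(errs, paste0("gene_models: ", gm_err))
  errs
}

#' Create the ancestral population state
#'
#' The state is an environment (reference semantics, so generation stepping
#' does not copy the mutation registry) holding genotype counts, per-genotype
#' mutation-id sets, cached fitness components and the mutation registry.
#'
#' @param config a [sim_config()].
#' @param genome reference sequence (character vector); generated from the
#'   current RNG state when missing.
#' @return object of class `population_state`.
#' @export
new_population <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- random_genome(config$genome_length)
  st <- new.env(parent = emptyenv())
  st$generation <- 0L
  st$genome <- genome
  st$count <- config$N
  st$gid <- 1L
  st$next_gid <- 2L
  st$geno_muts <- list(integer(0))
  st$geno_drivers <- list(character(0))
  st$w_static <- 1
  st$fd_carrier <- FALSE
  st$has_strong <- FALSE
  st$mutator <- FALSE
  st$n_mut <- 0L
  st$mut <- list(position = integer(0), ref = character(0), alt = character(0),
                 mut_class = character(0), gene = character(0),
                 effect = character(0), role = character(0),
                 origin_gid = integer(0), origin_gen = integer(0))
  class(st) <- c("population_state", "environment")
  st
}

#' @export
print.population_state <- function(x, ...) {
  cat("population_state: generation", x$generation, "|",
      length(x$count), "genotypes |", sum(x$count), "individuals |",
      x$n_mut, "mutations recorded\n")
  invisible(x)
}

# protein-altering change => the gene's role is conferred on the mutation
role_of_mutation <- function(gene, gene_role, mut_class, effect) {
  coding <- gene != "intergenic"
  altering <- (mut_class == "SNP" & effect == "nonsynonymous") |
    (mut_class %in% c("S-indel", "L-indel") & coding)
  ifelse(coding & gene_role != "neutral" & altering, gene_role, "passenger")
}

register_mutations <- function(state, position, ref, alt, mut_class, gene,
                               effect, role, origin_gid, origin_gen) {
  n <- length(position)
  ids <- state$n_mut + seq_len(n)
  state$mut$position <- c(state$mut$position, as.integer(position))
  state$mut$ref <- c(state$mut$ref, ref)
  state$mut$alt <- c(state$mut$alt, alt)
  state$mut$mut_class <- c(state$mut$mut_class, mut_class)
  state$mut$gene <- c(state$mut$gene, gene)
  state$mut$effect <- c(state$mut$effect, effect)
  state$mut$role <- c(state$mut$role, role)
  state$mut$origin_gid <- c(state$mut$origin_gid,
                            rep_len(as.integer(origin_gid), n))
  state$mut$origin_gen <- c(state$mut$origin_gen,
                            rep_len(as.integer(origin_gen), n))
  state$n_mut <- state$n_mut + n
  ids
}

#' Mutation registry of a population state
#'
#' @param state a `population_state`.
#' @return data.frame of mutation records (one row per mutation id).
#' @export
mutation_records <- function(state) {
  data.frame(id = seq_len(state$n_mut),
             position = state$mut$position, ref = state$mut$ref,
             alt = state$mut$alt, mut_class = state$mut$mut_class,
             gene = state$mut$gene, effect = state$mut$effect,
             role = state$mut$role, origin_gid = state$mut$origin_gid,
             origin_gen = state$mut$origin_gen,
             stringsAsFactors = FALSE)
}

# derive cached fitness flags for a child = parent + one new mutation
child_flags <- function(state, parent, role, gene, s_gene) {
  drv <- state$geno_drivers[[parent]]
  w <- state$w_static[parent]
  if (role %in% c("driver_strong", "driver_late") && !(gene %in% drv)) {
    drv <- c(drv, gene)
    w <- w * (1 + s_gene)
  }
  list(drivers = drv, w = w,
       fd = state$fd_carrier[parent] || role == "freq_dep",
       strong = state$has_strong[parent] || role == "driver_strong",
       mutator = state$mutator[parent] || role == "mutator")
}

#' Fitness of a genotype
#'
#' Multiplicative benefit over distinct mutated driver genes (allele
#' multiplicity within one gene is redundant: loss-of-function-like), times
#' the negative frequency-dependent term `1 + s_h - c * x_h` (clipped at 0)
#' when the genotype carries a frequency-dependent mutation and no
#' strong-driver mutation (epistatic exclusion). Passengers and the mutator
#' contribute factor 1.
#'
#' @param mutation_ids integer vector of mutation ids (a genotype).
#' @param state the current `population_state` (supplies the registry and
#'   the carrier frequency `x_h`).
#' @param config a [sim_config()].
#' @return non-negative fitness.
#' @export
fitness_of <- function(mutation_ids, state, config) {
  if (length(mutation_ids) == 0) return(1)
  role <- state$mut$role[mutation_ids]
  gene <- state$mut$gene[mutation_ids]
  drv <- role %in% c("driver_strong", "driver_late")
  genes_drv <- unique(gene[drv])
  gm <- config$gene_models
  w <- prod(1 + gm$s[match(genes_drv, gm$name)])
  if (any(role == "freq_dep") && !any(role == "driver_strong")) {
    x_h <- freq_dep_carrier_frequency(state, config)
    w <- w * max(0, 1 + config$freq_dep[[1]] - config$freq_dep[[2]] * x_h)
  }
  w
}

freq_dep_carrier_frequency <- function(state, config) {
  sum(state$count[state$fd_carrier]) / config$N
}

#' Seed a founder lineage into the ancestral population
#'
#' Plants a genotype at a given initial frequency carrying one
#' protein-altering SNP in each named gene (repeats allowed, giving extra
#' alleles of the same gene) plus `n_passengers` intergenic neutral SNPs.
#' All planted mutations are perfectly linked, which makes this the
#' ground-truth generator for cohort-recovery experiments.
#'
#' @param state `population_state` straight from [new_population()].
#' @param config a [sim_config()].
#' @param freq initial lineage frequency in (0, 1).
#' @param genes character vector of gene names to mutate.
#' @param n_passengers number of intergenic neutral SNPs to add.
#' @return the lineage's genotype id (invisibly mutates `state`).
#' @export
seed_lineage <- function(state, config, freq, genes = character(),
                         n_passengers = 0) {
  stopifnot(freq > 0, freq < 1)
  n0 <- round(freq * config$N)
  if (state$count[1] - n0 <= 0) stop("not enough ancestral individuals left")
  gm <- config$gene_models
  pos <- integer(0); ref <- character(0); alt <- character(0)
  cls <- character(0); gn <- character(0); eff <- character(0)
  for (g in genes) {
    row <- gm[gm$name == g, ]
    if (nrow(row) != 1) stop("unknown gene: ", g)
    repeat {  # rejection-sample a nonsynonymous site in the gene
      p <- sample(row$start:row$end, 1)
      r <- state$genome[p]
      a <- sample(setdiff(c("A", "C", "G", "T"), r), 1)
      e <- annotate_effect(p, r, a, gm, state$genome)
      if (e == "nonsynonymous" && !(p %in% pos)) break
    }
    pos <- c(pos, p); ref <- c(ref, r); alt <- c(alt, a)
    cls <- c(cls, "SNP"); gn <- c(gn, g); eff <- c(eff, e)
  }
  intergenic <- setdiff(seq_len(config$genome_length),
                        unlist(Map(`:`, gm$start, gm$end)))
  if (n_passengers > 0) {
    p <- sample(intergenic, n_passengers)
    pos <- c(pos, p); ref <- c(ref, state$genome[p])
    alt <- c(alt, vapply(state$genome[p], function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), ""))
    cls <- c(cls, rep("SNP", n_passengers))
    gn <- c(gn, rep("intergenic", n_passengers))
    eff <- c(eff, rep("noncoding", n_passengers))
  }
  gid <- state$next_gid
  state$next_gid <- gid + 1L
  role <- role_of_mutation(gn, gm$role[match(gn, gm$name)], cls, eff)
  role[is.na(role)] <- "passenger"
  ids <- register_mutations(state, pos, ref, alt, cls, gn, eff, role,
                            origin_gid = gid, origin_gen = state$generation)
  k <- length(state$count) + 1L
  state$count[1] <- state$count[1] - n0
  state$count[k] <- n0
  state$gid[k] <- gid
  state$geno_muts[[k]] <- ids
  drv <- unique(gn[role %in% c("driver_strong", "driver_late")])
  state$geno_drivers[[k]] <- drv
  state$w_static[k] <- prod(1 + gm$s[match(drv, gm$name)])
  state$fd_carrier[k] <- any(role == "freq_dep")
  state$has_strong[k] <- any(role == "driver_strong")
  state$mutator[k] <- any(role == "mutator")
  invisible(gid)
}

#' Advance the population by one Wright-Fisher generation
#'
#' Offspring counts are multinomial with probabilities proportional to
#' `count * fitness`; each offspring then acquires new mutations at rate
#' `mu * genome_length` per genome (times `mutator_fold` for mutator
#' carriers), with uniform positions, class drawn from the configured
#' fractions and effect annotated from the genome. Population size is
#' conserved exactly. The state environment is modified in place and
#' returned invisibly.
#'
#' @param state a `population_state`.
#' @param config a [sim_config()].
#' @return the state, invisibly.
#' @export
step_generation <- function(state, config) {
  if (sum(state$count) == 0) stop("empty population")
  x_h <- freq_dep_carrier_frequency(state, config)
  fd_term <- max(0, 1 + config$freq_dep[[1]] - config$freq_dep[[2]] * x_h)
  w <- state$w_static * ifelse(state$fd_carrier & !state$has_strong, fd_term, 1)
  p <- state$count * w
  if (sum(p) <= 0) stop("population fitness collapsed to zero")
  offspring <- as.integer(rmultinom(1, config$N, p))

  U <- config$mu * config$genome_length
  if (U > 0) {
    lam <- offspring * U * ifelse(state$mutator, config$mutator_fold, 1)
    m <- rpois(length(lam), lam)
    m <- pmin(m, offspring)
    total <- sum(m)
    if (total > 0) {
      parent <- rep(seq_along(m), m)
      gm <- config$gene_models
      pos <- sample.int(config$genome_length, total, replace = TRUE)
      cls <- sample(names(config$class_fractions), total, replace = TRUE,
                    prob = config$class_fractions)
      gene <- gene_at(pos, gm)
      ref <- state$genome[pos]
      alt <- character(total)
      eff <- rep("noncoding", total)
      is_snp <- cls == "SNP"
      if (any(is_snp)) {
        alt[is_snp] <- vapply(ref[is_snp], function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
        eff[is_snp] <- annotate_effect(pos[is_snp], ref[is_snp], alt[is_snp],
                                       gm, state$genome)
      }
      alt[cls == "S-indel"] <- "indel:1"
      alt[cls == "L-indel"] <- "indel:large"
      alt[cls == "duplication"] <- "dup"
      coding_indel <- cls %in% c("S-indel", "L-indel") & gene != "intergenic"
      eff[coding_indel] <- "nonsynonymous"
      gene_role <- gm$role[match(gene, gm$name)]
      gene_role[is.na(gene_role)] <- "neutral"
      role <- role_of_mutation(gene, gene_role, cls, eff)
      gids <- state$next_gid + seq_len(total) - 1L
      state$next_gid <- state$next_gid + total
      ids <- register_mutations(state, pos, ref, alt, cls, gene, eff, role,
                                origin_gid = gids,
                                origin_gen = state$generation + 1L)
      base <- length(state$count)
      for (j in seq_len(total)) {
        pa <- parent[j]
        offspring[pa] <- offspring[pa] - 1L
        fl <- child_flags(state, pa, role[j], gene[j],
                          gm$s[match(gene[j], gm$name)])
        k <- base + j
        offspring[k] <- 1L
        state$gid[k] <- gids[j]
        state$geno_muts[[k]] <- c(state$geno_muts[[pa]], ids[j])
        state$geno_drivers[[k]] <- fl$drivers
        state$w_static[k] <- fl$w
        state$fd_carrier[k] <- fl$fd
        state$has_strong[k] <- fl$strong
        state$mutator[k] <- fl$mutator
      }
    }
  }

  keep <- offspring > 0L
  state$count <- offspring[keep]
  state$gid <- state$gid[keep]
  state$geno_muts <- state$geno_muts[keep]
  state$geno_drivers <- state$geno_drivers[keep]
  state$w_static <- state$w_static[keep]
  state$fd_carrier <- state$fd_carrier[keep]
  state$has_strong <- state$has_strong[keep]
  state$mutator <- state$mutator[keep]
  state$generation <- state$generation + 1L
  invisible(state)
}

#' Current frequency of every recorded mutation
#'
#' @param state a `population_state`.
#' @param config a [sim_config()].
#' @return numeric vector indexed by mutation id.
#' @export
population_frequencies <- function(state, config) {
  f <- numeric(state$n_mut)
  if (state$n_mut == 0 || length(state$count) == 0) return(f)
  len <- lengths(state$geno_muts)
  if (sum(len) > 0) {
    ids <- unlist(state$geno_muts, use.names = FALSE)
    wts <- rep(state$count, len)
    agg <- rowsum(wts, ids)
    f[as.integer(rownames(agg))] <- agg[, 1] / config$N
  }
  f
}

#' Run the full chemostat simulation
#'
#' Discretises the experiment into whole Wright-Fisher generations
#' (`ceiling(duration_days * generations_per_day)`), records the true
#' frequency of every mutation at the generation nearest each sample day,
#' and returns the truth table with a linkage map. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `truth_table`: list with `freq` (mutations x
#'   sample days matrix), `mutations` (registry data.frame), `linkage`
#'   (mutation id, origin genotype id, `traj_group` = groups of identical
#'   true trajectories), `sample_days`, `config`.
#' @export
run_simulation <- function(config) {
  set.seed(derive_seed(config$seed, "simulate"))
  state <- new_population(config)
  for (ln in config$init_lineages) {
    seed_lineage(state, config, freq = ln$freq,
                 genes = if (is.null(ln$genes)) character() else ln$genes,
                 n_passengers = if (is.null(ln$n_passengers)) 0 else ln$n_passengers)
  }
  gpd <- generations_per_day(config$dilution_rate)
  total_gens <- as.integer(ceiling(config$duration_days * gpd))
  sample_gens <- as.integer(round(config$sample_days * gpd))
  sample_gens <- pmin(sample_gens, total_gens)
  snapshots <- vector("list", length(sample_gens))
  for (i in which(sample_gens == 0L))
    snapshots[[i]] <- population_frequencies(state, config)
  if (total_gens > 0) {
    for (g in seq_len(total_gens)) {
      step_generation(state, config)
      hit <- which(sample_gens == g)
      for (i in hit) snapshots[[i]] <- population_frequencies(state, config)
    }
  }
  n_mut <- state$n_mut
  freq <- matrix(0, nrow = n_mut, ncol = length(sample_gens),
                 dimnames = list(mutation_id(seq_len(n_mut)),
                                 paste0("day", config$sample_days)))
  for (i in seq_along(snapshots)) {
    v <- snapshots[[i]]
    if (length(v)) freq[seq_along(v), i] <- v
  }
  mut <- mutation_records(state)
  mut$id <- mutation_id(mut$id)
  rownames(freq) <- mut$id
  traj_group <- if (n_mut > 0)
    match(apply(freq, 1, paste, collapse = "\r"),
          unique(apply(freq, 1, paste, collapse = "\r")))
  else integer(0)
  linkage <- data.frame(mutation_id = mut$id, origin_gid = mut$origin_gid,
                        traj_group = traj_group, stringsAsFactors = FALSE)
  structure(list(freq = freq, mutations = mut, linkage = linkage,
                 sample_days = config$sample_days, config = config,
                 final_state = state),
            class = "truth_table")
}

mutation_id <- function(i) sprintf("m%05d", i)

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$freq), "mutations x", ncol(x$freq),
      "sample days (", paste(x$sample_days, collapse = ", "), ")\n")
  invisible(x)
}

#' Deterministic trajectory of a selected lineage
#'
#' Infinite-population logistic recursion `x' = x(1+s) / (1 + s x)` against
#' a neutral resident, reported at the requested days.
#'
#' @param s selection coefficient per generation.
#' @param x0 initial frequency.
#' @param days numeric vector of days.
#' @param gens_per_day generations per day (see [generations_per_day()]).
#' @return frequency at each day.
#' @export
logistic_trajectory <- function(s, x0, days, gens_per_day) {
  gens <- round(days * gens_per_day)
  x <- x0
  out <- numeric(length(days))
  g_done <- 0
  for (i in order(gens)) {
    while (g_done < gens[i]) {
      x <- x * (1 + s) / (1 + s * x)
      g_done <- g_done + 1
    }
    out[i] <- x
  }
  out
}

#' Deterministic two-type recursion under negative frequency dependence
#'
#' Iterates `x' = x w(x) / (x w(x) + (1 - x))` with `w(x) = 1 + s_h - c x`
#' against a neutral resident until the change per step falls below `tol`.
#' The fixed point is `x* = s_h / c`.
#'
#' @param s_h frequency-dependent advantage at vanishing carrier frequency.
#' @param c linear decay of the advantage with carrier frequency.
#' @param x0 starting frequency.
#' @param tol convergence tolerance on `|x' - x|`.
#' @param max_iter iteration cap.
#' @return list with `x` (equilibrium), `iterations`, `trajectory`.
#' @export
freq_dep_recursion <- function(s_h, c, x0 = 0.05, tol = 1e-10,
                               max_iter = 1e5) {
  x <- x0
  traj <- x
  for (i in seq_len(max_iter)) {
    w <- max(0, 1 + s_h - c * x)
    x_new <- x * w / (x * w + (1 - x))
    traj <- c(traj, x_new)
    if (abs(x_new - x) < tol) return(list(x = x_new, iterations = i,
                                          trajectory = traj))
    x <- x_new
  }
  list(x = x, iterations = max_iter, trajectory = traj)
}

#' Derive a per-stage random seed from the root seed
#'
#' Deterministic and kept below 2^31 so it is always a valid integer seed.
#'
#' @param root integer root seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647L + 1)
}
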