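test_that("generations per day follow the dilution-rate doubling equivalence", {
  expect_equal(generations_per_day(0), 0)
  expect_equal(generations_per_day(0.1), 2.4 / log(2), tolerance = 1e-12)
  expect_equal(60 * generations_per_day(0.1), 207.748, tolerance = 1e-3)
  expect_error(generations_per_day(-0.1), "must be >= 0")
})

test_that("effect annotation matches a Biostrings translation oracle", {
  set.seed(11)
  genome <- random_genome(3000)
  gm <- data.frame(name = c("plus", "minus"), start = c(101, 1201),
                   end = c(400, 1500), strand = c("+", "-"),
                   role = "neutral", s = 0, n_target_sites = 200L,
                   stringsAsFactors = FALSE)
  # intergenic position
  expect_equal(annotate_effect(50, genome[50],
                               setdiff(c("A","C","G","T"), genome[50])[1],
                               gm, genome), "noncoding")
  # oracle: translate the whole mutated gene with Biostrings and compare
  oracle <- function(pos, alt) {
    g <- gm[gm$start <= pos & gm$end >= pos, ]
    mutated <- genome
    mutated[pos] <- alt
    get_aa <- function(gseq) {
      dna <- Biostrings::DNAString(paste(gseq[g$start:g$end], collapse = ""))
      if (g$strand == "-") dna <- Biostrings::reverseComplement(dna)
      as.character(Biostrings::translate(dna, no.init.codon = TRUE))
    }
    if (get_aa(genome) == get_aa(mutated)) "synonymous" else "nonsynonymous"
  }
  for (i in 1:200) {
    pos <- sample(c(101:400, 1201:1500), 1)
    ref <- genome[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    expect_equal(annotate_effect(pos, ref, alt, gm, genome),
                 oracle(pos, alt), label = paste("position", pos))
  }
})

test_that("stop-gain codon changes are nonsynonymous", {
  genome <- c(strsplit("ATGTATGGA", "")[[1]], rep("A", 3))
  gm <- data.frame(name = "g", start = 1, end = 9, strand = "+",
                   role = "neutral", s = 0, n_target_sites = 6L,
                   stringsAsFactors = FALSE)
  # TAT -> TAA: stop gain
  expect_equal(annotate_effect(6, "T", "A", gm, genome), "nonsynonymous")
  # GGA -> GGT: Gly -> Gly wobble
  expect_equal(annotate_effect(9, "A", "T", gm, genome), "synonymous")
})

test_that("fitness multiplies once per distinct driver gene", {
  set.seed(21)
  cfg <- tiny_config(seed = 21)
  st <- new_population(cfg)
  expect_equal(fitness_of(integer(0), st, cfg), 1.0)
  # two different rpoS alleles: benefit counted once
  seed_lineage(st, cfg, freq = 0.01, genes = c("rpoS", "rpoS"))
  s_rpoS <- cfg$gene_models$s[cfg$gene_models$name == "rpoS"]
  expect_equal(fitness_of(st$geno_muts[[2]], st, cfg), 1 + s_rpoS)
  expect_equal(st$w_static[2], 1 + s_rpoS)
  # two distinct driver genes multiply
  seed_lineage(st, cfg, freq = 0.01, genes = c("rpoS", "mglD"))
  s_mgl <- cfg$gene_models$s[cfg$gene_models$name == "mglD"]
  expect_equal(fitness_of(st$geno_muts[[3]], st, cfg),
               (1 + s_rpoS) * (1 + s_mgl))
})

test_that("frequency-dependent fitness term uses carrier frequency and epistasis", {
  set.seed(22)
  cfg <- tiny_config(freq_dep = c(s_h = 0.2, c = 1.0), seed = 22)
  st <- new_population(cfg)
  seed_lineage(st, cfg, freq = 0.2, genes = "hfq")
  # x_h = 0.2 -> term 1 + 0.2 - 0.2 = 1: the deterministic fixed point
  expect_equal(fitness_of(st$geno_muts[[2]], st, cfg), 1.0)
  # freq_dep on a strong-driver background confers nothing
  seed_lineage(st, cfg, freq = 0.01, genes = c("hfq", "rpoS"))
  s_rpoS <- cfg$gene_models$s[cfg$gene_models$name == "rpoS"]
  expect_equal(fitness_of(st$geno_muts[[3]], st, cfg), 1 + s_rpoS)
})

test_that("one generation conserves population size and respects mu = 0", {
  set.seed(31)
  cfg <- tiny_config(seed = 31)
  st <- new_population(cfg)
  seed_lineage(st, cfg, freq = 0.3, genes = "rpoS")
  for (i in 1:5) {
    step_generation(st, cfg)
    expect_identical(sum(st$count), cfg$N)
  }
  expect_equal(st$generation, 5L)
  expect_equal(st$n_mut, 1L)  # no new mutations at mu = 0
  # mutations do appear at mu > 0 and size is still conserved
  cfg2 <- sim_config(N = 1e4, genome_length = 1e4, mu = 1e-6,
                     duration_days = 10, sample_days = c(0, 10), seed = 31)
  st2 <- new_population(cfg2)
  for (i in 1:10) step_generation(st2, cfg2)
  expect_identical(sum(st2$count), cfg2$N)
  expect_gt(st2$n_mut, 0)
})

test_that("mean one-step frequency change matches deterministic selection", {
  set.seed(32)
  cfg <- tiny_config(N = 1e3, seed = 32)
  s <- cfg$gene_models$s[cfg$gene_models$name == "rpoS"]
  x0 <- 0.3
  expected <- x0 * (1 + s) / (1 + s * x0) - x0
  n_rep <- 1e4
  delta <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    st <- new_population(cfg)
    seed_lineage(st, cfg, freq = x0, genes = "rpoS")
    step_generation(st, cfg)
    delta[r] <- population_frequencies(st, cfg)[1] - x0
  }
  se <- sd(delta) / sqrt(n_rep)
  expect_lt(abs(mean(delta) - expected), 3 * se)
})

test_that("zero-duration simulation yields the ancestral state only", {
  cfg <- sim_config(N = 1e4, genome_length = 1e4, mu = 1e-7,
                    duration_days = 0, sample_days = 0, seed = 5)
  tt <- run_simulation(cfg)
  expect_equal(nrow(tt$freq), 0)
  expect_equal(ncol(tt$freq), 1)
})

test_that("simulations are reproducible under a fixed seed", {
  cfg <- sim_config(N = 1e4, genome_length = 1e4, mu = 1e-6,
                    duration_days = 10, sample_days = c(5, 10), seed = 99)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$freq, t2$freq)
  expect_identical(t1$mutations, t2$mutations)
})

test_that("truth frequencies are valid and linked mutations share trajectories", {
  set.seed(41)
  cfg <- sim_config(N = 1e4, genome_length = 1e4, mu = 0, duration_days = 20,
                    sample_days = c(5, 10, 20), seed = 41,
                    init_lineages = list(
                      list(freq = 0.05, genes = "rpoS", n_passengers = 3),
                      list(freq = 0.05, genes = "mglD", n_passengers = 2)))
  tt <- run_simulation(cfg)
  expect_true(all(tt$freq >= 0 & tt$freq <= 1))
  expect_equal(nrow(tt$freq), 4 + 3)
  # all mutations of one founder lineage have identical trajectories
  for (gid in unique(tt$linkage$origin_gid)) {
    rows <- tt$freq[tt$linkage$origin_gid == gid, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # and traj_group equals the origin grouping here (no further mutation)
  expect_equal(rand_index(tt$linkage$origin_gid, tt$linkage$traj_group), 1)
})

test_that("stronger drivers reach majority earlier", {
  crossing_gen <- function(s_label, seed) {
    genes <- if (s_label == "strong") "rpoS" else "malE"  # s = 0.12 vs 0.06
    cfg <- sim_config(N = 1e4, genome_length = 1e4, mu = 0,
                      duration_days = 60, sample_days = seq(5, 60, by = 5),
                      seed = seed,
                      init_lineages = list(list(freq = 0.01, genes = genes)))
    tt <- run_simulation(cfg)
    traj <- tt$freq[1, ]
    idx <- which(traj >= 0.5)
    if (length(idx)) idx[1] else Inf
  }
  strong <- vapply(1:12, function(s) crossing_gen("strong", s), 0)
  weak <- vapply(1:12, function(s) crossing_gen("weak", 100 + s), 0)
  expect_lt(wilcox.test(strong, weak, alternative = "less",
                        exact = FALSE)$p.value, 0.01)
})

test_that("deterministic frequency-dependent recursion converges to s_h / c", {
  res <- freq_dep_recursion(s_h = 0.2, c = 1.0, x0 = 0.05, tol = 1e-12)
  expect_equal(res$x, 0.2, tolerance = 1e-6)
  res2 <- freq_dep_recursion(s_h = 0.15, c = 1.0, x0 = 0.5, tol = 1e-12)
  expect_equal(res2$x, 0.15, tolerance = 1e-6)
})

test_that("config validation rejects inconsistent study conditions", {
  expect_error(sim_config(N = 100), "N")
  expect_error(sim_config(sample_days = c(10, 5)), "increasing")
  expect_error(sim_config(sample_days = c(5, 100), duration_days = 60),
               "within")
  expect_error(sim_config(mu = -1), "mu")
})
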