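test_that("trajectory distance is the elementwise maximum gap", {
  expect_equal(trajectory_distance(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(trajectory_distance(rep(0.3, 5), rep(0.5, 5)), 0.2)
  expect_error(trajectory_distance(1:3 / 10, 1:4 / 10), "grid")
  set.seed(16)
  for (i in 1:50) {
    a <- runif(11); b <- runif(11)
    expect_equal(trajectory_distance(a, b), max(abs(a - b)))
    expect_equal(trajectory_distance(a, b), trajectory_distance(b, a))
  }
})

test_that("cohort detection clusters concordant trajectories and skips low peaks", {
  days <- 1:6
  base <- c(0.01, 0.1, 0.4, 0.6, 0.5, 0.3)
  freq <- rbind(base, base + 0.01, c(0.6, 0.5, 0.3, 0.1, 0.05, 0.01),
                rep(0.02, 6))
  meta <- data.frame(id = c("m1", "m2", "m3", "m4"), position = 1:4,
                     ref = "A", alt = "C", mut_class = "SNP",
                     gene = c("rpoS", "neu001", "neu002", "neu003"),
                     effect = "nonsynonymous",
                     role = c("driver_strong", "passenger", "passenger",
                              "passenger"), stringsAsFactors = FALSE)
  tab <- table_from_matrix(freq, meta, days)
  co <- detect_cohorts(tab, eps = 0.05, min_peak = 0.05)
  mem <- co$membership$cohort
  names(mem) <- co$membership$mutation_id
  expect_equal(mem[["m1"]], mem[["m2"]])   # near-identical trajectories
  expect_false(mem[["m1"]] == mem[["m3"]]) # opposite dynamics
  expect_true(is.na(mem[["m4"]]))          # peak 0.02 < min_peak
  expect_equal(co$cohorts[[mem[["m1"]]]]$driver_genes, "rpoS")
  # all-zero table -> no cohorts
  co0 <- detect_cohorts(table_from_matrix(matrix(0, 3, 6)), 0.05, 0.05)
  expect_equal(length(co0$cohorts), 0)
})

test_that("cohort detection is invariant to row permutation", {
  set.seed(17)
  freq <- matrix(runif(60, 0, 0.8), nrow = 10)
  rownames(freq) <- sprintf("m%02d", 1:10)
  tab <- table_from_matrix(freq)
  perm <- sample(10)
  tab2 <- table_from_matrix(freq[perm, ], tab$meta[perm, ])
  co1 <- detect_cohorts(tab)
  co2 <- detect_cohorts(tab2)
  m1 <- co1$membership[order(co1$membership$mutation_id), ]
  m2 <- co2$membership[order(co2$membership$mutation_id), ]
  keep <- !is.na(m1$cohort)
  expect_identical(keep, !is.na(m2$cohort))
  expect_equal(rand_index(m1$cohort[keep], m2$cohort[keep]), 1)
})

test_that("linked mutations land in one cohort despite sequencing noise", {
  set.seed(18)
  days <- c(5, 7, 14, 20, 28, 35, 40, 45, 50, 56, 60)
  gpd <- generations_per_day(0.1)
  lineage <- logistic_trajectory(0.08, 0.01, days, gpd)
  other <- logistic_trajectory(0.15, 0.001, days, gpd)
  truth <- rbind(lineage, lineage, lineage, other)
  rownames(truth) <- c("a1", "a2", "a3", "b1")
  cfg <- seq_config(mean_depth = 800, base_error_rate = 0)
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    est <- estimate_trajectories(truth, cfg)
    co <- detect_cohorts(table_from_matrix(est, sample_days = days),
                         eps = 0.05, min_peak = 0.05)
    mem <- co$membership$cohort
    names(mem) <- co$membership$mutation_id
    same <- mem[["a1"]] == mem[["a2"]] && mem[["a2"]] == mem[["a3"]]
    apart <- mem[["b1"]] != mem[["a1"]]
    if (isTRUE(same) && isTRUE(apart)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("sweep verdicts reproduce the canonical gene patterns", {
  days <- c(5, 7, 14, 20, 28, 35, 40, 45, 50, 56, 60)
  gpd <- generations_per_day(0.1)
  # single allele rising 1% -> 95%, no other allele: hard
  hard <- matrix(logistic_trajectory(0.1, 1e-4, days, gpd), nrow = 1)
  hard <- hard / max(hard) * 0.95
  expect_equal(classify_gene_sweep(hard)$verdict, "hard")
  # 7 alleles, three successively dominant: soft
  shift <- function(x, k) c(rep(0, k), x)[seq_along(x)]
  a <- logistic_trajectory(0.12, 1e-4, days, gpd)
  soft <- rbind(pmax(a - shift(a, 3), 0), shift(a, 3) * 0.6, shift(a, 5) * 0.5,
                rep(0.02, 11), rep(0.03, 11), shift(a, 7) * 0.3, rep(0.01, 11))
  expect_equal(classify_gene_sweep(soft)$verdict, "soft")
  # single allele hovering at 0.15: incomplete
  inc <- matrix(c(0, 0.05, 0.1, 0.15, 0.12, 0.13, 0.15, 0.1, 0.12, 0.14, 0.1),
                nrow = 1)
  expect_equal(classify_gene_sweep(inc)$verdict, "incomplete")
  # nothing established: none
  expect_equal(classify_gene_sweep(matrix(rep(0.02, 11), 1))$verdict, "none")
  # one high allele plus an established second allele: soft, not hard
  two <- rbind(hard[1, ], rep(0.2, 11))
  expect_equal(classify_gene_sweep(two)$verdict, "soft")
  # high allele already at 50% at the first sample: origin rule blocks "hard"
  standing <- matrix(pmin(0.5 + seq(0, 0.45, length.out = 11), 0.95), 1)
  expect_equal(classify_gene_sweep(standing)$verdict, "incomplete")
  expect_error(classify_gene_sweep(matrix(0, 0, 11)), "no allele")
})

test_that("late-detected high sweeps satisfy the de novo origin rule", {
  # first detection above origin_max but later than the first sample:
  # rose from undetectable, still a hard sweep
  x <- c(0, 0, 0.05, 0.2, 0.5, 0.8, 0.92, 0.95, 0.95, 0.95, 0.95)
  expect_equal(classify_gene_sweep(matrix(x, 1))$verdict, "hard")
})

test_that("hitchhikers are flagged only inside driver-containing cohorts", {
  days <- 1:5
  base <- c(0.05, 0.2, 0.5, 0.6, 0.4)
  freq <- rbind(base, base, base + 0.01, rep(0.3, 5), rep(0.29, 5))
  meta <- data.frame(id = sprintf("m%d", 1:5), position = 1:5, ref = "A",
                     alt = "C", mut_class = "SNP",
                     gene = c("rpoS", "mutL", "neu001", "neu002", "neu003"),
                     effect = "nonsynonymous",
                     role = c("driver_strong", "mutator", "passenger",
                              "passenger", "passenger"),
                     stringsAsFactors = FALSE)
  tab <- table_from_matrix(freq, meta, days)
  co <- detect_cohorts(tab, eps = 0.05, min_peak = 0.05)
  hh <- detect_hitchhikers(co, meta)
  expect_setequal(hh$mutation_id, c("m2", "m3"))  # mutator + passenger
  expect_true(all(hh$driver_genes == "rpoS"))
  # the passenger-only cohort contributes no hitchhikers
  expect_false(any(c("m4", "m5") %in% hh$mutation_id))
})

test_that("dominant-allele succession collapses runs and breaks ties by id", {
  days <- c(5, 7, 14, 20, 28)
  alleles <- rbind(c(0.5, 0.4, 0.2, 0.05, 0.01),
                   c(0.05, 0.2, 0.45, 0.5, 0.6))
  rownames(alleles) <- c("a1", "a2")
  runs <- dominant_allele_succession(alleles, days)
  expect_equal(runs$allele, c("a1", "a2"))
  expect_equal(runs$from_day, c(5, 14))
  expect_equal(runs$to_day, c(7, 28))
  # all below threshold -> empty
  expect_equal(nrow(dominant_allele_succession(alleles / 10, days)), 0)
  # single allele above threshold throughout -> one run
  one <- dominant_allele_succession(alleles[2, , drop = FALSE] + 0.2, days)
  expect_equal(nrow(one), 1)
  # exact tie resolved toward the smaller allele id
  tie <- rbind(a2 = rep(0.3, 2), a1 = rep(0.3, 2))
  expect_equal(dominant_allele_succession(tie, 1:2)$allele, "a1")
})

test_that("Rand index agrees with pair enumeration", {
  # hand enumeration: partitions {1,2}{3} vs {1}{2,3} agree on 1 of 3 pairs
  expect_equal(rand_index(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_equal(rand_index(1:4, rep(1, 4)), 0)
  set.seed(19)
  a <- sample(3, 8, replace = TRUE); b <- sample(3, 8, replace = TRUE)
  agree <- 0; tot <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    tot <- tot + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  expect_equal(rand_index(a, b), agree / tot)
})
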