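test_that("partial-Bayesian genotype probabilities match hand evaluation", {
  tb <- toy_two_pop()
  fm <- allele_frequencies(tb)
  # popA counts {a:3, b:1}, global k = 2; heterozygote ab:
  # 2 (3 + 1/2)(1 + 1/2) / (5 * 6) = 0.35
  expect_equal(10^rm_loglik(tb, "A2", "A", fm), 0.35)
  # homozygote aa in popA: (3.5)(4.5) / 30 = 0.525
  expect_equal(10^rm_loglik(tb, "A1", "A", fm), 0.525)
  # homozygote bb scored in popA: (1.5)(2.5) / 30 = 0.125
  expect_equal(10^rm_loglik(tb, "B1", "A", fm), 0.125)
  # monomorphic population, k = 1, homozygote: probability 1
  tb2 <- genotype_table(paste0("i", 1:3), rep("P", 3), "L1",
                        matrix(7L, 3, 1), matrix(7L, 3, 1))
  expect_equal(rm_loglik(tb2, "i1", "P"), 0)
  expect_error(rm_loglik(tb, "nobody", "A"), "unknown individual")
})

test_that("multi-locus log-likelihood is the sum of per-locus logs", {
  set.seed(21)
  tb <- random_table(21, n_pops = 2, n_per_pop = 8, n_loci = 4,
                     max_allele = 5, missing_rate = 0.1)
  fm <- allele_frequencies(tb)
  id <- tb$individual_ids[3]
  total <- rm_loglik(tb, id, "pop2", fm)
  per_locus <- vapply(tb$locus_names, function(l) {
    sub <- gt_subset(tb, loci = l)
    if (all(is.na(sub$allele1[3, ]))) return(0)
    # k and counts must come from the same inventory: single-locus freqs
    rm_loglik(sub, id, "pop2", allele_frequencies(sub))
  }, numeric(1))
  expect_equal(total, sum(per_locus))
})

test_that("single-locus genotype probabilities sum to one by enumeration", {
  for (seed in c(1, 6)) {
    set.seed(seed)
    k <- sample(2:5, 1)
    n <- sample(4:10, 1)
    a1 <- matrix(sample.int(k, n, replace = TRUE), n, 1)
    a2 <- matrix(sample.int(k, n, replace = TRUE), n, 1)
    # guarantee all k alleles are in the global inventory
    a1[1:k, 1] <- 1:k
    tb <- genotype_table(paste0("i", 1:n), rep("P", n), "L1", a1, a2)
    fm <- allele_frequencies(tb)
    tot <- 0
    for (i in 1:k) for (j in i:k) {
      probe <- genotype_table(c(paste0("i", 1:n), "probe"),
                              rep("P", n + 1), "L1",
                              rbind(a1, i), rbind(a2, j))
      # score the probe against the original counts (probe excluded)
      tot <- tot + 10^rm_loglik(probe, "probe", "P", fm)
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("the Lh/Lmax statistic behaves at its boundaries", {
  tb <- toy_two_pop()
  cfg <- assignment_config(n_simulated = 200, seed = 4)
  res <- detect_migrants(tb, cfg)
  expect_true(all(res$statistic > 0 & res$statistic <= 1))
  # A1 (aa) is most likely in its own population -> statistic 1
  a1 <- res[res$individual == "A1", ]
  expect_equal(a1$statistic, 1)
  expect_equal(a1$assigned_source, "A")
  # an individual labelled A but most likely in B: statistic is the ratio
  tb3 <- genotype_table(c("A1", "A2", "A3", "B1", "B2"),
                        c("A", "A", "A", "B", "B"), "L1",
                        matrix(c(1L, 1L, 2L, 2L, 2L), 5, 1),
                        matrix(c(1L, 2L, 2L, 2L, 2L), 5, 1))
  res3 <- detect_migrants(tb3, cfg)
  a3 <- res3[res3$individual == "A3", ]
  lA <- 10^rm_loglik(tb3, "A3", "A")
  lB <- 10^rm_loglik(tb3, "A3", "B")
  expect_lt(lA, lB)
  expect_equal(a3$statistic, lA / lB)
  expect_equal(a3$assigned_source, "B")
  # single population: statistic identically 1, with a warning
  solo <- gt_subset(tb, individuals = c("A1", "A2"))
  expect_warning(res1 <- detect_migrants(solo, cfg), "single population")
  expect_true(all(res1$statistic == 1))
})

test_that("null distributions are reproducible, bounded and degenerate-safe", {
  sim <- simulate_dataset(simulation_config(2, 15, 6, f = 0.1, seed = 8))
  cfg <- assignment_config(n_simulated = 300, seed = 12)
  n1 <- null_distribution(sim$table, "P1", cfg)
  n2 <- null_distribution(sim$table, "P1", cfg)
  expect_identical(n1, n2)                       # fixed seed -> same draws
  expect_equal(length(n1), 300)
  expect_true(all(10^n1 > 0 & 10^n1 <= 1))
  expect_false(identical(n1, null_distribution(sim$table, "P2", cfg)))
})

test_that("detection is deterministic and p-values are valid", {
  sim <- simulate_dataset(simulation_config(3, 12, 8, f = 0.12, seed = 2))
  cfg <- assignment_config(n_simulated = 200, seed = 31)
  r1 <- detect_migrants(sim$table, cfg)
  r2 <- detect_migrants(sim$table, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_identical(r1$flagged_disperser, r1$p_value < cfg$alpha)
  # an observed statistic at least as large as every simulated value gets
  # p = 1 under the (r+1)/(N+1) estimator; statistic 1 is the maximum
  ones <- r1[r1$statistic == 1, ]
  expect_gt(nrow(ones), 0)
  expect_true(all(ones$p_value == 1))
})

test_that("residents are flagged at about the nominal rate under the null", {
  # residents simulated from their own populations: type-I error ~ alpha
  sim <- simulate_dataset(simulation_config(3, 60, 12, f = 0.08,
                                            alleles_max = 10, seed = 5))
  cfg <- assignment_config(alpha = 0.05, n_simulated = 400, seed = 77)
  res <- detect_migrants(sim$table, cfg)
  n <- nrow(res)
  rate <- mean(res$flagged_disperser)
  ci <- qbinom(c(0.005, 0.995), n, cfg$alpha) / n
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("true dispersers gain evidence as informative loci are added", {
  # expected -log10(Lh/Lmax) for a planted disperser does not decrease
  # with panel size (averaged over replicates)
  neglog <- matrix(NA_real_, 6, 2)
  for (r in 1:6) {
    sim <- simulate_dataset(simulation_config(2, 25, 20, f = 0.15,
                                              alleles_max = 8, seed = 100 + r))
    sim <- plant_dispersers(sim, data.frame(source = "P1", labelled = "P2",
                                            count = 1), seed = r)
    cfg <- assignment_config(n_simulated = 100, seed = r)
    id <- sim$truth$dispersers$individual[1]
    for (m in c(1, 2)) {
      sub <- gt_subset(sim$table, loci = sim$table$locus_names[1:(10 * m)])
      res <- detect_migrants(sub, cfg)
      neglog[r, m] <- -log10(res$statistic[res$individual == id])
    }
  }
  expect_gt(mean(neglog[, 2]), mean(neglog[, 1]) - 1e-9)
})

test_that("leave-one-out weakens the home likelihood of rare genotypes", {
  tb <- toy_two_pop()
  fm <- allele_frequencies(tb)
  cfg_in <- assignment_config(n_simulated = 100, seed = 1,
                              leave_one_out = FALSE)
  cfg_out <- assignment_config(n_simulated = 100, seed = 1,
                               leave_one_out = TRUE)
  r_in <- detect_migrants(tb, cfg_in)
  r_out <- detect_migrants(tb, cfg_out)
  # removing A2's own alleles makes its heterozygous genotype rarer at home
  expect_lt(r_out$loglik_A[r_out$individual == "A2"],
            r_in$loglik_A[r_in$individual == "A2"])
})
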