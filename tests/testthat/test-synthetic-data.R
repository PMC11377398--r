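test_that("genotype sampling follows Hardy-Weinberg proportions", {
  # symmetric case at maf = 0.5
  g <- sample_genotypes(rep(0.5, 2), n_samples = 4000, seed = 11)
  freq <- table(factor(g[, 1], levels = 0:2)) / 4000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.05))

  # near-zero maf gives an (almost surely) all-reference column
  g0 <- sample_genotypes(1e-9, n_samples = 1000, seed = 2)
  expect_true(all(g0 == 0L))

  # goodness of fit against expected HWE proportions at maf = 0.2
  g2 <- sample_genotypes(0.2, n_samples = 10000, seed = 3)
  counts <- table(factor(g2, levels = 0:2))
  gof <- chisq.test(counts, p = c(0.64, 0.32, 0.04))
  expect_gt(gof$p.value, 0.01)

  expect_error(sample_genotypes(c(0.2, 0.6), 10), "0, 0.5")
  expect_error(sample_genotypes(0, 10), "0, 0.5")
})

test_that("liability-threshold phenotype behaves at its limits", {
  cfg <- cohort_config(n_cases = 150, n_controls = 150, n_variants = 60,
                       n_genes = 20, n_causal_genes = 10, effect_sd = 0,
                       seed = 5)
  co <- simulate_cohort(cfg)
  # no genetic effect: the genetic score carries no label information
  expect_equal(compute_auc(co$truth$genetic_score, co$truth$true_label), 0.5)

  # strong effects: the genetic component alone separates the classes
  cfg2 <- cohort_config(n_cases = 150, n_controls = 150, n_variants = 60,
                        n_genes = 20, n_causal_genes = 10, effect_sd = 1,
                        seed = 5)
  co2 <- simulate_cohort(cfg2)
  expect_gt(compute_auc(co2$truth$genetic_score, co2$truth$true_label), 0.9)

  # prevalence 0.5 puts the threshold at the median of the liability pool
  maf <- draw_mafs(30, seed = 1)
  g <- sample_genotypes(maf, 400, seed = 1)
  tp <- make_topology(30, 10)
  tr <- simulate_phenotype(g, tp, cohort_config(
    n_cases = 150, n_controls = 150, n_variants = 30, n_genes = 10,
    n_causal_genes = 3, seed = 9))
  expect_equal(attr(tr, "threshold"), median(tr$liability),
               tolerance = 0.2)

  # requesting more samples than the pool supports fails loudly
  expect_error(
    simulate_phenotype(g, tp, cohort_config(
      n_cases = 350, n_controls = 150, n_variants = 30, n_genes = 10,
      n_causal_genes = 3)),
    "simulate more samples")
})

test_that("label-noise injection reproduces the published flip arithmetic", {
  truth <- tibble::tibble(
    sample_id = sprintf("S%05d", 1:11214),
    true_label = rep(c(1L, 0L), c(4969, 6245)),
    observed_label = rep(c(1L, 0L), c(4969, 6245)),
    flipped = FALSE,
    liability = 0, genetic_score = 0
  )
  noisy <- inject_label_noise(truth, case_flip_rate = 0.19,
                              control_flip_rate = 0.0034, seed = 4)
  # flipped members of each observed pool
  expect_identical(sum(noisy$flipped & noisy$observed_label == 1L), 944L)
  expect_identical(sum(noisy$flipped & noisy$observed_label == 0L), 21L)
  # the flipped mask is exactly the label disagreement
  expect_identical(noisy$flipped,
                   noisy$true_label != noisy$observed_label)

  # zero rates are the identity
  expect_identical(inject_label_noise(truth, 0, 0, seed = 4), truth)
})

test_that("simulated cohorts have the configured composition and are reproducible", {
  cfg <- cohort_config(n_cases = 120, n_controls = 100, n_variants = 50,
                       n_genes = 10, n_causal_genes = 4,
                       case_flip_rate = 0.1, control_flip_rate = 0.02,
                       seed = 31)
  co <- simulate_cohort(cfg)
  expect_identical(sum(co$truth$observed_label == 1L), 120L)
  expect_identical(sum(co$truth$observed_label == 0L), 100L)
  expect_identical(sum(co$truth$flipped & co$truth$observed_label == 1L),
                   as.integer(round(0.1 * 120)))
  expect_identical(sum(co$truth$flipped & co$truth$observed_label == 0L),
                   as.integer(round(0.02 * 100)))
  expect_identical(rownames(co$genotypes), co$truth$sample_id)

  # same seed, bit-identical cohort
  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)
  # different seed, different genotypes
  cfg3 <- cfg; cfg3$seed <- 32L
  expect_false(identical(simulate_cohort(cfg3)$genotypes, co$genotypes))
})

test_that("cohort configuration rejects inconsistent settings", {
  expect_error(cohort_config(n_genes = 500, n_variants = 100), "n_genes")
  expect_error(cohort_config(n_causal_genes = 200, n_genes = 100), "n_causal")
  expect_error(cohort_config(maf_low = 0.3, maf_high = 0.1), "maf_low")
  expect_error(cohort_config(case_flip_rate = 1.2), "rates")
})

test_that("permuted topologies keep the table invariants", {
  tp <- make_topology(40, 12, permute = TRUE, seed = 3)
  expect_identical(tp$variant_node, 0:39)
  first <- !duplicated(tp$gene_node)
  expect_identical(tp$gene_node[first], 0:(sum(first) - 1L))
  expect_identical(sort(unique(tp$gene)), sort(unique(
    make_topology(40, 12)$gene)))
})
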