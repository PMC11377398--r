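score_table_stub <- function(label, mean_score, n_runs = 10L,
                             misclassified_count = NULL) {
  wrong_side <- ifelse(label == 1, mean_score < 0.5, mean_score >= 0.5)
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_along(label)),
    label = as.integer(label),
    mean_score = mean_score,
    n_runs = as.integer(n_runs),
    misclassified_count = misclassified_count %||%
      as.integer(wrong_side * n_runs)
  )
  class(out) <- c("score_table", class(out))
  out
}

test_that("exclusion quotas reproduce the published arithmetic", {
  expect_identical(exclusion_quota(0.0034, 6245), 21L)
  expect_identical(exclusion_quota(0.19, 4969), 944L)
  expect_identical(exclusion_quota(0, 1e6), 0L)
  # the rounder broad-definition count is reachable via the override
  expect_identical(exclusion_quota(0.06, 4969), 298L)
  expect_identical(exclusion_quota(0.06, 4969, override = 300), 300L)
  expect_error(exclusion_quota(0.06, 10, override = 11), "exceeds")
  expect_error(exclusion_quota(1.2, 10), "rate")
})

test_that("exclusion selection orders by score with stable ties", {
  st <- score_table_stub(
    label = c(0, 0, 0, 0, 1, 1, 1, 1),
    mean_score = c(0.9, 0.6, 0.4, 0.2, 0.3, 0.45, 0.7, 0.3))
  ex <- select_exclusions(st, control_quota = 2, case_quota = 2,
                          mode = "broad")
  # top-scoring controls
  expect_setequal(ex$sample_id[ex$label == 0], c("S001", "S002"))
  # lowest-scoring cases; the 0.3 tie is broken by sample id
  expect_identical(ex$sample_id[ex$label == 1], c("S005", "S008"))

  # zero quotas select nothing
  none <- select_exclusions(st, control_quota = 0, case_quota = 0)
  expect_identical(nrow(none), 0L)
})

test_that("narrow mode requires misclassification in half the runs", {
  st <- score_table_stub(
    label = c(0, 0, 1, 1, 1),
    mean_score = c(0.2, 0.3, 0.45, 0.44, 0.7),
    misclassified_count = c(0L, 0L, 4L, 5L, 0L))
  # S003 scores below 0.5 but was misclassified in only 4/10 runs: not
  # eligible; only S004 qualifies, short of the quota
  expect_warning(
    ex <- select_exclusions(st, control_quota = 0, case_quota = 2,
                            mode = "narrow"),
    "eligible")
  expect_identical(ex$sample_id, "S004")
})

test_that("cohort filtering removes exactly the excluded rows", {
  x <- matrix(0L, 6, 3, dimnames = list(sprintf("S%03d", 1:6), NULL))
  y <- rep(c(0L, 1L), 3)
  out <- filter_cohort(x, y, c("S002", "S005"))
  expect_identical(rownames(out$x), c("S001", "S003", "S004", "S006"))
  expect_identical(length(out$labels), 4L)
  expect_error(filter_cohort(x, y, "S999"), "unknown")
  # empty exclusion list is the identity
  same <- filter_cohort(x, y, character(0))
  expect_identical(same$x, x)
})

test_that("stratified splits partition each class at the requested fractions", {
  y <- rep(c(0L, 1L), c(100, 100))
  sp <- stratified_split(y, seed = 5)
  expect_identical(sort(as.integer(unlist(sp))), 1:200)
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  for (cls in 0:1) {
    expect_identical(sum(y[sp$train] == cls), 60L)
    expect_identical(sum(y[sp$validation] == cls), 20L)
    expect_identical(sum(y[sp$test] == cls), 20L)
  }
  # uneven class counts are allocated by largest remainder
  y2 <- rep(c(0L, 1L), c(7, 13))
  sp2 <- stratified_split(y2, seed = 5)
  expect_identical(sum(unlist(lapply(sp2, length))), 20L)
  # different seeds permute differently
  expect_false(identical(stratified_split(y, seed = 1),
                         stratified_split(y, seed = 2)))
  expect_error(stratified_split(rep(c(0, 1), c(2, 100)), seed = 1),
               "too small")
})

test_that("rank-based AUC matches pairwise enumeration", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auc(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(compute_auc(c(0.1, 0.6, 0.4, 0.8), c(0, 0, 1, 1)), 0.75)
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(6:20, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 2)  # rounding forces ties
      expect_equal(compute_auc(s, y), auc_oracle(s, y))
    }
  })
  # invariant under strictly monotone transforms
  s <- runif(20); y <- rep(c(0, 1), 10)
  expect_equal(compute_auc(exp(3 * s), y), compute_auc(s, y))
  expect_error(compute_auc(s, rep(1, 20)), "both classes")
})

test_that("AUC comparison is a pooled-variance two-sample t-test", {
  a <- c(0.7, 0.72, 0.71); b <- c(0.74, 0.76, 0.78)
  got <- compare_auc(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_identical(got$df, 4L)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # hand-computed oracle on a fixed example
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(got$t, t_hand, tolerance = 1e-10)

  # two groups of ten give the published df structure
  expect_identical(compare_auc(runif(10), runif(10))$df, 18L)

  # degenerate cases
  same <- compare_auc(c(1, 1, 1), c(1, 1, 1))
  expect_identical(same$t, 0)
  expect_identical(same$p_value, 1)
  deg <- compare_auc(c(1, 1), c(0, 0))
  expect_true(deg$degenerate)
})

test_that("ensemble scoring is deterministic and counts misclassifications", {
  cfg <- cohort_config(n_cases = 60, n_controls = 60, n_variants = 30,
                       n_genes = 10, n_causal_genes = 4, effect_sd = 1,
                       seed = 12)
  co <- simulate_cohort(cfg)
  st <- ensemble_scores(co$genotypes, co$truth$observed_label, co$topology,
                        n_runs = 2, seed = 9, max_epochs = 5)
  expect_true(all(st$mean_score >= 0 & st$mean_score <= 1))
  expect_true(all(st$misclassified_count %in% 0:2))
  st2 <- ensemble_scores(co$genotypes, co$truth$observed_label, co$topology,
                         n_runs = 2, seed = 9, max_epochs = 5)
  expect_identical(as.data.frame(st), as.data.frame(st2))

  # a single run's mean equals that run's prediction
  st1 <- ensemble_scores(co$genotypes, co$truth$observed_label, co$topology,
                         n_runs = 1, seed = 9, max_epochs = 5)
  run_seed <- cohortsieve:::derive_seeds(9, 1)
  fit <- train_gennet(co$genotypes, co$truth$observed_label, co$topology,
                      seed = run_seed, max_epochs = 5)
  expect_equal(st1$mean_score, unname(predict(fit, co$genotypes)))
})

test_that("evaluation summaries are recomputable from the per-repeat list", {
  cfg <- cohort_config(n_cases = 60, n_controls = 60, n_variants = 30,
                       n_genes = 10, n_causal_genes = 4, effect_sd = 1,
                       seed = 13)
  co <- simulate_cohort(cfg)
  ev <- evaluate_model(co$genotypes, co$truth$observed_label, co$topology,
                       n_repeats = 3, seed = 4, max_epochs = 8, patience = 3)
  expect_identical(nrow(ev$aucs), 3L)
  expect_equal(ev$summary$mean_auc[ev$summary$split == "test"],
               mean(ev$aucs$test_auc))
  expect_equal(ev$summary$max_auc[ev$summary$split == "val"],
               max(ev$aucs$val_auc))
  gl <- glance(ev)
  expect_identical(gl$n_repeats, 3)
  expect_identical(tidy(ev), ev$aucs)
})
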