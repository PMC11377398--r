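# The two-stage outlier-detection pipeline: full-cohort ensemble
# test-on-train scoring, prevalence/misdiagnosis-quota exclusion, stage-2
# retraining on stratified splits, AUC evaluation and model comparison.

#' Ensemble test-on-train scores
#'
#' Stage 1 of the pipeline. Trains `n_runs` independently seeded networks
#' on *all* samples and predicts on the same samples — deliberately:
#' samples whose genetic profile deviates from their labelled class keep
#' receiving wrong-side scores even when the model has seen them during
#' training. Per-sample scores are averaged over the ensemble and per-run
#' misclassifications are counted at the 0.5 threshold (a score `>= 0.5`
#' is a case-side classification).
#'
#' @param x Samples x variants additive matrix.
#' @param labels 0/1 observed labels (1 = case).
#' @param topology Topology tibble.
#' @param n_runs Ensemble size.
#' @param seed Master seed; per-run seeds are derived from it
#'   deterministically.
#' @param ... Training options passed to [train_gennet()] (e.g.
#'   `max_epochs`, `batch_size`, `learning_rate`).
#' @return A `score_table` tibble: `sample_id`, `label`, `mean_score`,
#'   `n_runs`, `misclassified_count`; the trained ensemble is attached as
#'   attribute `models` and the per-run score matrix as `score_matrix`.
#' @export
ensemble_scores <- function(x, labels, topology, n_runs = 10, seed = 1L,
                            ...) {
  labels <- assert_binary_labels(labels)
  stopifnot(n_runs >= 1)
  run_seeds <- derive_seeds(seed, n_runs)
  models <- vector("list", n_runs)
  scores <- matrix(NA_real_, nrow(x), n_runs)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      train_gennet(x, labels, topology, seed = run_seeds[r], ...),
      error = function(e) abort(sprintf("training run %d failed: %s",
                                        r, conditionMessage(e))))
    models[[r]] <- fit
    scores[, r] <- predict(fit, x)
  }
  wrong <- sweep(scores >= 0.5, 1, labels == 1, `!=`)
  out <- tibble(
    sample_id = rownames(x) %||% sprintf("S%05d", seq_len(nrow(x))),
    label = labels,
    mean_score = rowMeans(scores),
    n_runs = as.integer(n_runs),
    misclassified_count = as.integer(rowSums(wrong))
  )
  class(out) <- c("score_table", class(out))
  attr(out, "models") <- models
  attr(out, "score_matrix") <- scores
  out
}

#' Exclusion quota from a rate and a pool size
#'
#' `floor(rate * pool_size)`, the rounding that reproduces the published
#' arithmetic: a 0.34% prevalence on 6,245 controls gives 21 and a 19%
#' misdiagnosis rate on 4,969 cases gives 944. An explicit `override`
#' substitutes a fixed count (e.g. the round number 300 sometimes quoted
#' for the broad 6% rate, where floor gives 298).
#'
#' @param rate Probability in \[0, 1\].
#' @param pool_size Number of samples in the class.
#' @param override Optional explicit count (must be `<= pool_size`).
#' @return Integer quota.
#' @export
#' @examples
#' exclusion_quota(0.0034, 6245)
#' exclusion_quota(0.19, 4969)
exclusion_quota <- function(rate, pool_size, override = NULL) {
  if (!is.null(override)) {
    if (override > pool_size) abort("`override` exceeds the pool size.")
    return(as.integer(override))
  }
  if (rate < 0 || rate > 1) abort("`rate` must lie in [0, 1].")
  as.integer(floor(rate * pool_size))
}

#' Select samples for exclusion
#'
#' Controls: the `control_quota` samples with the *highest* mean scores
#' (genetic profiles resembling cases — candidate undiagnosed cases).
#' Cases: the `case_quota` samples with the *lowest* mean scores (candidate
#' misdiagnoses). In `narrow` mode a case is only eligible if it was
#' misclassified in at least half of the ensemble runs; if fewer cases are
#' eligible than the quota, all eligible cases are excluded with a warning.
#' Ties are broken by `sample_id`, so selection is deterministic.
#'
#' @param scores A `score_table` from [ensemble_scores()].
#' @param control_rate Control exclusion rate (disease prevalence;
#'   default 0.34%).
#' @param case_rate Case exclusion rate (clinical misdiagnosis rate);
#'   defaults to 6% in `broad` mode and 19% in `narrow` mode.
#' @param mode `"broad"` or `"narrow"` diagnosis definition.
#' @param control_quota,case_quota Optional explicit counts overriding the
#'   rate arithmetic.
#' @return Tibble of excluded samples: `sample_id`, `label`, `mean_score`,
#'   `misclassified_count`, `reason`.
#' @export
select_exclusions <- function(scores, control_rate = 0.0034,
                              case_rate = NULL,
                              mode = c("broad", "narrow"),
                              control_quota = NULL, case_quota = NULL) {
  mode <- match.arg(mode)
  case_rate <- case_rate %||% if (mode == "broad") 0.06 else 0.19
  controls <- filter(scores, .data$label == 0L)
  cases <- filter(scores, .data$label == 1L)
  cq <- exclusion_quota(control_rate, nrow(controls), control_quota)
  kq <- exclusion_quota(case_rate, nrow(cases), case_quota)

  excl_controls <- controls |>
    arrange(desc(.data$mean_score), .data$sample_id) |>
    slice_head(n = cq) |>
    mutate(reason = "control_high_score")

  if (mode == "narrow") {
    eligible <- filter(cases,
                       .data$misclassified_count >= ceiling(.data$n_runs / 2))
    if (nrow(eligible) < kq) {
      warn(sprintf(
        "narrow mode: only %d of the %d-sample case quota are eligible; excluding all eligible cases.",
        nrow(eligible), kq))
    }
    cases <- eligible
  }
  excl_cases <- cases |>
    arrange(.data$mean_score, .data$sample_id) |>
    slice_head(n = kq) |>
    mutate(reason = "case_low_score")

  out <- bind_rows(excl_controls, excl_cases) |>
    select("sample_id", "label", "mean_score", "misclassified_count",
           "reason")
  as_tibble(out)
}

#' Remove excluded samples from a cohort matrix
#'
#' @param x Samples x variants matrix.
#' @param labels Label vector parallel to the rows of `x`.
#' @param exclusions Tibble from [select_exclusions()] or a character
#'   vector of sample ids.
#' @return `list(x = , labels = )` with the excluded rows removed; the
#'   variant set is untouched.
#' @export
filter_cohort <- function(x, labels, exclusions) {
  ids <- if (is.character(exclusions)) exclusions else exclusions$sample_id
  rn <- rownames(x) %||% sprintf("S%05d", seq_len(nrow(x)))
  unknown <- setdiff(ids, rn)
  if (length(unknown) > 0) {
    abort(paste0("unknown sample ids in `exclusions`: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  keep <- !(rn %in% ids)
  list(x = x[keep, , drop = FALSE], labels = labels[keep])
}

#' Stratified train/validation/test split
#'
#' Partitions sample indices into disjoint, exhaustive sets whose per-class
#' counts match the requested fractions up to largest-remainder rounding;
#' the class pools are fully shuffled first, so repeated calls with
#' different seeds give completely re-randomised splits.
#'
#' @param labels 0/1 label vector.
#' @param fractions Three fractions (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @return `list(train = , validation = , test = )` of integer index
#'   vectors.
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    abort("`fractions` must be three values summing to 1.")
  }
  parts <- list(train = integer(), validation = integer(), test = integer())
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- withr::with_seed(as.integer(seed) + as.integer(cls), sample(idx))
    counts <- largest_remainder(length(idx), fractions)
    if (any(counts == 0)) {
      abort(sprintf("class %s is too small to populate every split.", cls))
    }
    ends <- cumsum(counts)
    parts$train <- c(parts$train, idx[seq_len(ends[1])])
    parts$validation <- c(parts$validation, idx[(ends[1] + 1):ends[2]])
    parts$test <- c(parts$test, idx[(ends[2] + 1):ends[3]])
  }
  lapply(parts, sort)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random case scores above a random control, with ties
#' counting one half.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels (1 = case); both classes required.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' compute_auc(c(0.1, 0.6, 0.4, 0.8), c(0, 0, 1, 1))
compute_auc <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified evaluation of the network
#'
#' Stage 2 of the pipeline. For each repeat: draw a fresh stratified
#' 60/20/20 split, train with early stopping on the validation loss, and
#' record the validation and test AUC. Summary statistics (mean, sd, max
#' per split) are returned alongside the per-repeat values.
#'
#' @param x Samples x variants additive matrix.
#' @param labels 0/1 labels.
#' @param topology Topology tibble.
#' @param n_repeats Number of independent repeats.
#' @param fractions Split fractions (train, validation, test).
#' @param seed Master seed; per-repeat split and training seeds are derived
#'   from it.
#' @param ... Training options passed to [train_gennet()].
#' @return A `gennet_eval` object: `$aucs` (per-repeat tibble with columns
#'   `repeat_id`, `val_auc`, `test_auc`, `epochs`), `$summary` (per-split
#'   mean/sd/max), `$n_repeats`.
#' @export
evaluate_model <- function(x, labels, topology, n_repeats = 30,
                           fractions = c(0.6, 0.2, 0.2), seed = 1L, ...) {
  labels <- assert_binary_labels(labels)
  stopifnot(n_repeats >= 1)
  seeds <- derive_seeds(seed, 2L * n_repeats)
  res <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    sp <- stratified_split(labels, fractions, seed = seeds[2 * r - 1])
    fit <- train_gennet(
      x[sp$train, , drop = FALSE], labels[sp$train], topology,
      validation = list(x = x[sp$validation, , drop = FALSE],
                        y = labels[sp$validation]),
      seed = seeds[2 * r], ...)
    tibble(
      repeat_id = r,
      val_auc = compute_auc(predict(fit, x[sp$validation, , drop = FALSE]),
                            labels[sp$validation]),
      test_auc = compute_auc(predict(fit, x[sp$test, , drop = FALSE]),
                             labels[sp$test]),
      epochs = nrow(fit$history)
    )
  })
  long <- tidyr::pivot_longer(res, c("val_auc", "test_auc"),
                              names_to = "split", values_to = "auc")
  summary <- long |>
    group_by(split = sub("_auc$", "", .data$split)) |>
    summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
              max_auc = max(.data$auc), .groups = "drop")
  structure(list(aucs = res, summary = summary, n_repeats = n_repeats),
            class = "gennet_eval")
}

#' @export
print.gennet_eval <- function(x, ...) {
  cat(sprintf("<gennet_eval> %d repeats\n", x$n_repeats))
  print(x$summary)
  invisible(x)
}

#' Compare two AUC samples with a pooled-variance t-test
#'
#' Two-tailed unpaired t-test with pooled variance and
#' `df = n_a + n_b - 2`. The degenerate zero-variance situation is handled
#' explicitly: equal means give `t = 0, p = 1`; unequal means with zero
#' pooled variance are flagged (`degenerate = TRUE`, infinite `t`).
#'
#' @param aucs_a,aucs_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
compare_auc <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) >= 2, length(aucs_b) >= 2)
  df <- length(aucs_a) + length(aucs_b) - 2L
  delta <- mean(aucs_a) - mean(aucs_b)
  pooled <- ((length(aucs_a) - 1) * stats::var(aucs_a) +
               (length(aucs_b) - 1) * stats::var(aucs_b)) / df
  if (pooled == 0) {
    return(tibble(t = if (delta == 0) 0 else sign(delta) * Inf,
                  df = df, p_value = if (delta == 0) 1 else 0,
                  mean_a = mean(aucs_a), mean_b = mean(aucs_b),
                  degenerate = delta != 0))
  }
  ht <- t.test(aucs_a, aucs_b, var.equal = TRUE)
  tibble(t = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
         p_value = ht$p.value, mean_a = mean(aucs_a), mean_b = mean(aucs_b),
         degenerate = FALSE)
}

#' Run the full two-stage outlier pipeline
#'
#' Stage 1: ensemble test-on-train scoring on the whole cohort and
#' quota-driven exclusion of high-scoring controls and low-scoring cases.
#' Stage 2: repeated stratified evaluation of the network on the original
#' and on the filtered cohort, plus a pooled t-test comparing the two test
#' AUC samples. Entirely reproducible from `seed`.
#'
#' @inheritParams ensemble_scores
#' @inheritParams select_exclusions
#' @param n_repeats Evaluation repeats per cohort.
#' @param stage1_epochs Epoch cap for the full-data scoring models.
#' @param stage2_epochs Epoch cap for the evaluation models (early stopping
#'   on validation loss applies under this cap).
#' @param patience Early-stopping patience for stage 2.
#' @param ... Further training options for both stages (e.g. `batch_size`,
#'   `learning_rate`).
#' @return A `sieve_result` list: `scores`, `exclusions`, `eval_base`,
#'   `eval_filtered`, `comparison`, `seed`.
#' @export
run_outlier_pipeline <- function(x, labels, topology, n_runs = 10,
                                 control_rate = 0.0034, case_rate = NULL,
                                 mode = c("broad", "narrow"),
                                 control_quota = NULL, case_quota = NULL,
                                 n_repeats = 30, stage1_epochs = 200,
                                 stage2_epochs = 200, patience = 20,
                                 seed = 1L, ...) {
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, 3L)
  scores <- ensemble_scores(x, labels, topology, n_runs = n_runs,
                            seed = seeds[1], max_epochs = stage1_epochs, ...)
  exclusions <- select_exclusions(scores, control_rate, case_rate, mode,
                                  control_quota, case_quota)
  filtered <- filter_cohort(x, labels, exclusions)
  eval_base <- evaluate_model(x, labels, topology, n_repeats = n_repeats,
                              seed = seeds[2], max_epochs = stage2_epochs,
                              patience = patience, ...)
  eval_filtered <- evaluate_model(filtered$x, filtered$labels, topology,
                                  n_repeats = n_repeats, seed = seeds[3],
                                  max_epochs = stage2_epochs,
                                  patience = patience, ...)
  comparison <- compare_auc(eval_filtered$aucs$test_auc,
                            eval_base$aucs$test_auc)
  structure(list(scores = scores, exclusions = exclusions,
                 eval_base = eval_base, eval_filtered = eval_filtered,
                 comparison = comparison, seed = as.integer(seed)),
            class = "sieve_result")
}

#' @export
print.sieve_result <- function(x, ...) {
  cat("<sieve_result>\n")
  cat(sprintf("  stage 1: %d samples scored, %d excluded (%d controls, %d cases)\n",
              nrow(x$scores), nrow(x$exclusions),
              sum(x$exclusions$label == 0), sum(x$exclusions$label == 1)))
  cat(sprintf("  test AUC %.3f -> %.3f (t = %.2f, df = %d, p = %.3g)\n",
              x$comparison$mean_b, x$comparison$mean_a, x$comparison$t,
              x$comparison$df, x$comparison$p_value))
  invisible(x)
}
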