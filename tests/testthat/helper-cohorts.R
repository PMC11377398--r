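# Builders for small in-code fixtures.

# A hand-written variant cohort: `gt` is a list of genotype vectors, one per
# site, in sample order.
make_vc <- function(gt, ref = NULL, alt = NULL, chrom = NULL, qual = NULL,
                    dp = NULL) {
  n_sites <- length(gt)
  n_samples <- length(gt[[1]])
  samples <- sprintf("S%02d", seq_len(n_samples))
  sites <- tibble::tibble(
    chrom = chrom %||% rep("1", n_sites),
    pos = seq_len(n_sites) * 10L,
    id = sprintf("site%02d", seq_len(n_sites)),
    ref = ref %||% rep("A", n_sites),
    alt = alt %||% rep("G", n_sites),
    qual = qual %||% rep(60, n_sites)
  )
  gt_mat <- do.call(rbind, gt)
  colnames(gt_mat) <- samples
  variant_cohort(sites, gt_mat, dp)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small separable cohort for training tests: cases carry alt alleles at
# the first half of the variants.
make_separable <- function(n_per_class = 10, n_variants = 4, seed = 1) {
  withr::with_seed(seed, {
    half <- n_variants %/% 2
    x_case <- cbind(matrix(2L, n_per_class, half),
                    matrix(rbinom(n_per_class * (n_variants - half), 2, 0.1),
                           n_per_class))
    x_ctrl <- cbind(matrix(0L, n_per_class, half),
                    matrix(rbinom(n_per_class * (n_variants - half), 2, 0.1),
                           n_per_class))
    x <- rbind(x_case, x_ctrl)
    dimnames(x) <- list(sprintf("S%03d", seq_len(2 * n_per_class)),
                        sprintf("v%05d", seq_len(n_variants)))
    list(x = x, y = rep(c(1L, 0L), each = n_per_class))
  })
}

# Pearson chi-squared statistic computed from the textbook formula, as an
# oracle independent of the implementation under test.
pearson_oracle <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# AUC by explicit enumeration of all case-control pairs (ties count 1/2).
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  wins <- 0
  for (a in cs) for (b in ct) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(cs) * length(ct))
}
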