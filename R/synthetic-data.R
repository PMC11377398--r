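#' Configuration for a simulated case-control cohort
#'
#' Bundles every knob of the cohort simulator: cohort composition, the
#' minor-allele-frequency (MAF) spectrum, the genetic architecture of the
#' liability-threshold phenotype, and the label-noise rates standing in for
#' clinical misdiagnosis (mislabelled cases) and undiagnosed disease among
#' controls.
#'
#' MAFs are drawn log-uniformly on `[maf_low, maf_high]` so that rare
#' variants dominate the spectrum, as they do in exome data. `prevalence`
#' calibrates the liability threshold: the top `prevalence` fraction of the
#' simulated liability distribution becomes cases. The default of 0.5
#' produces a balanced ascertained cohort; population prevalence enters the
#' *exclusion* stage (see [select_exclusions()]), not the generator.
#'
#' @param n_cases,n_controls Number of case / control samples retained.
#' @param n_variants,n_genes Number of biallelic SNPs and of genes they are
#'   grouped into (`n_genes <= n_variants`).
#' @param maf_low,maf_high MAF range, each in (0, 0.5].
#' @param n_causal_genes Number of genes given a nonzero liability effect.
#' @param effect_sd Standard deviation of per-causal-gene effect sizes on
#'   the liability scale (environmental noise has unit variance).
#' @param prevalence Fraction of the simulated pool above the liability
#'   threshold, i.e. labelled case before down-sampling.
#' @param case_flip_rate,control_flip_rate Fractions of true cases /
#'   controls whose observed label is flipped by [inject_label_noise()].
#' @param seed Master seed; the same configuration always yields a
#'   bit-identical cohort.
#'
#' @return A `cohort_config` list.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cohort_config(n_cases = 50, n_controls = 50, n_variants = 40, n_genes = 10)
cohort_config <- function(n_cases = 1200, n_controls = 1200,
                          n_variants = 400, n_genes = 120,
                          maf_low = 0.005, maf_high = 0.5,
                          n_causal_genes = 30, effect_sd = 1,
                          prevalence = 0.5,
                          case_flip_rate = 0, control_flip_rate = 0,
                          seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_variants = as.integer(n_variants), n_genes = as.integer(n_genes),
    maf_low = maf_low, maf_high = maf_high,
    n_causal_genes = as.integer(n_causal_genes), effect_sd = effect_sd,
    prevalence = prevalence,
    case_flip_rate = case_flip_rate, control_flip_rate = control_flip_rate,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_causal_genes > n_genes) abort("`n_causal_genes` must be <= `n_genes`.")
    if (n_genes > n_variants) abort("`n_genes` must be <= `n_variants`.")
    if (maf_low > maf_high) abort("`maf_low` must be <= `maf_high`.")
    if (maf_low <= 0 || maf_high > 0.5) abort("MAF bounds must lie in (0, 0.5].")
    if (effect_sd < 0) abort("`effect_sd` must be non-negative.")
    rates <- c(prevalence, case_flip_rate, control_flip_rate)
    if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1].")
    if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1).")
  })
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  samples: %d cases + %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  variants: %d on %d genes (%d causal, effect_sd = %g)\n",
              x$n_variants, x$n_genes, x$n_causal_genes, x$effect_sd))
  cat(sprintf("  MAF in [%g, %g] (log-uniform); prevalence %g\n",
              x$maf_low, x$maf_high, x$prevalence))
  cat(sprintf("  flip rates: cases %g, controls %g; seed %d\n",
              x$case_flip_rate, x$control_flip_rate, x$seed))
  invisible(x)
}

#' Draw a minor-allele-frequency spectrum
#'
#' Log-uniform MAFs on `[maf_low, maf_high]`, mimicking the rare-variant
#' dominated spectrum of exome cohorts.
#'
#' @param n_variants Number of variants.
#' @param maf_low,maf_high Range, each in (0, 0.5].
#' @param seed Integer seed.
#' @return Numeric vector of length `n_variants`.
#' @export
draw_mafs <- function(n_variants, maf_low = 0.005, maf_high = 0.5, seed = 1L) {
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
    abort("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5.")
  }
  withr::with_seed(as.integer(seed),
                   exp(runif(n_variants, log(maf_low), log(maf_high))))
}

#' Sample Hardy-Weinberg genotypes
#'
#' Draws additive genotype codes (counts of the alternative allele) for
#' independent biallelic autosomal SNPs in Hardy-Weinberg proportions: at
#' variant `j` with alternative-allele frequency `p`, genotypes 0/1/2 occur
#' with probabilities `(1-p)^2`, `2p(1-p)`, `p^2`.
#'
#' @param maf Vector of alternative-allele frequencies, each in (0, 0.5].
#' @param n_samples Number of samples (rows).
#' @param seed Integer seed.
#' @return Integer matrix `n_samples x length(maf)` with values in
#'   \{0, 1, 2\}; row names `S...`, column names `v...`.
#' @export
#' @examples
#' g <- sample_genotypes(c(0.5, 0.1), n_samples = 100, seed = 1)
#' table(g[, 1])
sample_genotypes <- function(maf, n_samples, seed = 1L) {
  if (any(maf <= 0 | maf > 0.5)) {
    abort("all allele frequencies must lie in (0, 0.5].")
  }
  m <- length(maf)
  g <- withr::with_seed(
    as.integer(seed),
    matrix(rbinom(n_samples * m, 2L, rep(maf, each = n_samples)),
           nrow = n_samples, ncol = m)
  )
  dimnames(g) <- list(sprintf("S%05d", seq_len(n_samples)),
                      sprintf("v%05d", seq_len(m)))
  g
}

#' Build a variant-to-gene topology table
#'
#' Assigns each variant to exactly one gene, producing the table that defines
#' the sparse connectivity of the gene network (see [build_gennet()]). The
#' default assignment is contiguous: variant `i` (0-based) maps to gene
#' `floor(i * n_genes / n_variants)`. With `permute = TRUE` the gene
#' assignment is shuffled and gene nodes renumbered by first appearance, so
#' the table invariants (consecutive 0-based node ids) still hold.
#'
#' @param n_variants,n_genes Counts, `n_genes <= n_variants`.
#' @param variant_ids,gene_ids Optional identifier vectors.
#' @param permute Shuffle the variant-to-gene assignment?
#' @param seed Seed used only when `permute = TRUE`.
#' @return A tibble with columns `variant_node`, `variant`, `gene_node`,
#'   `gene` (0-based node indices).
#' @export
make_topology <- function(n_variants, n_genes,
                          variant_ids = NULL, gene_ids = NULL,
                          permute = FALSE, seed = 1L) {
  if (n_genes > n_variants) abort("`n_genes` must be <= `n_variants`.")
  variant_ids <- variant_ids %||% sprintf("v%05d", seq_len(n_variants))
  gene_ids <- gene_ids %||% sprintf("GENE%04d", seq_len(n_genes))
  stopifnot(length(variant_ids) == n_variants, length(gene_ids) == n_genes)
  assign0 <- floor((seq_len(n_variants) - 1) * n_genes / n_variants)
  if (permute) {
    assign0 <- withr::with_seed(as.integer(seed), sample(assign0))
  }
  # renumber gene nodes by first appearance to keep them consecutive 0-based
  node_of <- match(assign0, unique(assign0)) - 1L
  tibble(
    variant_node = seq_len(n_variants) - 1L,
    variant = variant_ids,
    gene_node = node_of,
    gene = gene_ids[assign0 + 1L]
  )
}

#' Simulate a liability-threshold phenotype
#'
#' Gene burden scores are the standardised per-gene sums of additive genotype
#' codes. A random subset of genes is causal, with effects drawn from
#' `Normal(0, effect_sd^2)`; liability is the causal burden plus standard
#' normal environmental noise. Samples above the upper-`prevalence` empirical
#' quantile of liability are cases; the case and control pools are then
#' down-sampled to `n_cases` and `n_controls`.
#'
#' @param genotypes Matrix from [sample_genotypes()] (samples x variants).
#' @param topology Variant-to-gene table from [make_topology()].
#' @param config A [cohort_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A tibble (one row per retained sample) with columns `sample_id`,
#'   `true_label`, `observed_label` (0 = control, 1 = case), `flipped`,
#'   `liability`, `genetic_score`; attributes `causal_genes`, `gene_effects`
#'   and `threshold` carry the generating truth.
#' @export
simulate_phenotype <- function(genotypes, topology, config, seed = config$seed) {
  if (!all(colnames(genotypes) %in% topology$variant)) {
    abort("`topology` must cover every variant in `genotypes`.")
  }
  genes <- unique(topology$gene)
  burden <- gene_burden(genotypes, topology)
  seeds <- derive_seeds(seed, 4L)
  causal <- withr::with_seed(seeds[1], sample(genes, config$n_causal_genes))
  beta <- withr::with_seed(seeds[2],
                           rnorm(config$n_causal_genes, 0, config$effect_sd))
  effects <- stats::setNames(numeric(length(genes)), genes)
  effects[causal] <- beta
  genetic <- drop(burden %*% effects[colnames(burden)])
  eps <- withr::with_seed(seeds[3], rnorm(nrow(genotypes)))
  liability <- genetic + eps
  threshold <- unname(quantile(liability, 1 - config$prevalence))
  is_case <- liability > threshold

  case_pool <- which(is_case)
  control_pool <- which(!is_case)
  if (length(case_pool) < config$n_cases ||
      length(control_pool) < config$n_controls) {
    abort(sprintf(
      paste0("simulated pool has %d cases and %d controls but %d/%d were ",
             "requested; simulate more samples or adjust `prevalence`."),
      length(case_pool), length(control_pool),
      config$n_cases, config$n_controls))
  }
  keep <- withr::with_seed(seeds[4], c(
    sample(case_pool, config$n_cases),
    sample(control_pool, config$n_controls)
  ))
  keep <- sort(keep)

  truth <- tibble(
    sample_id = rownames(genotypes)[keep],
    true_label = as.integer(is_case[keep]),
    observed_label = as.integer(is_case[keep]),
    flipped = FALSE,
    liability = liability[keep],
    genetic_score = genetic[keep]
  )
  attr(truth, "causal_genes") <- causal
  attr(truth, "gene_effects") <- effects
  attr(truth, "threshold") <- threshold
  truth
}

# Standardised per-gene burden matrix (samples x genes). Genes whose summed
# genotype is constant get an all-zero column rather than NaN.
gene_burden <- function(genotypes, topology) {
  idx <- match(colnames(genotypes), topology$variant)
  gene_of <- topology$gene[idx]
  genes <- unique(topology$gene)
  agg <- t(rowsum(t(genotypes), group = factor(gene_of, levels = genes)))
  mu <- colMeans(agg)
  s <- apply(agg, 2, sd)
  s[s == 0] <- Inf
  scale(agg, center = mu, scale = s)[, , drop = FALSE]
}

#' Inject label noise into a simulated cohort
#'
#' Plants mislabelled samples in each class pool, standing in for clinical
#' misdiagnosis (case-labelled samples whose genetics are control) and for
#' undiagnosed disease among controls (control-labelled samples whose
#' genetics are case). A "flipped case" is therefore a member of the
#' *case* pool carrying a wrong label: it is created by flipping the
#' observed label of a true control into the case pool — which is exactly
#' the sample the downstream case-exclusion step should recover. Flipped
#' controls are true cases relabelled as controls, symmetrically.
#'
#' Flip counts are `round(rate * pool size)` under R's round-half-even
#' rule, with the pool sizes of the incoming truth as the quota base: a
#' case pool of 4,969 at rate 0.19 yields 944 flipped cases, a control
#' pool of 6,245 at rate 0.0034 yields 21 flipped controls. Because flips
#' move samples between pools, [simulate_cohort()] requests compensated
#' pool sizes so the final cohort composition is exact.
#'
#' @param truth Tibble from [simulate_phenotype()].
#' @param case_flip_rate,control_flip_rate Flip fractions in \[0, 1\].
#' @param seed Integer seed.
#' @param case_flips,control_flips Optional explicit flip counts overriding
#'   the rate arithmetic.
#' @return `truth` with `observed_label` and `flipped` updated
#'   (`flipped[i]` iff `true_label[i] != observed_label[i]`).
#' @export
inject_label_noise <- function(truth, case_flip_rate, control_flip_rate,
                               seed = 1L, case_flips = NULL,
                               control_flips = NULL) {
  if (any(c(case_flip_rate, control_flip_rate) < 0 |
          c(case_flip_rate, control_flip_rate) > 1)) {
    abort("flip rates must lie in [0, 1].")
  }
  obs_cases <- which(truth$observed_label == 1L)
  obs_controls <- which(truth$observed_label == 0L)
  # quota base: pool sizes of the incoming truth
  n_case_flips <- case_flips %||%
    as.integer(round(case_flip_rate * length(obs_cases)))
  n_control_flips <- control_flips %||%
    as.integer(round(control_flip_rate * length(obs_controls)))
  # a flipped case is a true control relabelled into the case pool, and
  # vice versa; flips are drawn from correctly labelled samples only
  ctrl_pool <- intersect(obs_controls, which(truth$true_label == 0L))
  case_pool <- intersect(obs_cases, which(truth$true_label == 1L))
  if (n_case_flips > length(ctrl_pool) || n_control_flips > length(case_pool)) {
    abort("not enough correctly labelled samples to flip at these rates.")
  }
  seeds <- derive_seeds(seed, 2L)
  to_case <- withr::with_seed(seeds[1],
                              sample(ctrl_pool)[seq_len(n_case_flips)])
  to_control <- withr::with_seed(seeds[2],
                                 sample(case_pool)[seq_len(n_control_flips)])
  out <- truth
  out$observed_label[to_case] <- 1L
  out$observed_label[to_control] <- 0L
  out$flipped <- out$true_label != out$observed_label
  out
}

#' Simulate a complete case-control cohort
#'
#' One-call orchestration of the generator: draws a MAF spectrum, samples
#' Hardy-Weinberg genotypes for a pool large enough to satisfy the requested
#' case/control counts under `prevalence`, simulates the liability-threshold
#' phenotype, down-samples to the cohort, and injects label noise.
#'
#' @param config A [cohort_config()].
#' @return A `sim_cohort` list: `genotypes` (samples x variants, additive
#'   codes), `truth` (see [simulate_phenotype()], with noise injected),
#'   `topology`, `maf`, and `config`.
#' @export
#' @examples
#' cc <- cohort_config(n_cases = 40, n_controls = 40, n_variants = 30,
#'                     n_genes = 10, n_causal_genes = 3, seed = 7)
#' cohort <- simulate_cohort(cc)
#' table(cohort$truth$observed_label)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  # flips move samples between pools, so request compensated true-label
  # pools to land exactly on the configured observed composition
  k_case <- as.integer(round(config$case_flip_rate * config$n_cases))
  k_control <- as.integer(round(config$control_flip_rate * config$n_controls))
  cfg_true <- config
  cfg_true$n_cases <- config$n_cases - k_case + k_control
  cfg_true$n_controls <- config$n_controls - k_control + k_case
  need <- max(ceiling(cfg_true$n_cases / config$prevalence),
              ceiling(cfg_true$n_controls / (1 - config$prevalence)))
  n_pool <- ceiling(need * 1.15) + 20L
  seeds <- derive_seeds(config$seed, 4L)
  maf <- draw_mafs(config$n_variants, config$maf_low, config$maf_high,
                   seed = seeds[1])
  genotypes <- sample_genotypes(maf, n_pool, seed = seeds[2])
  topology <- make_topology(config$n_variants, config$n_genes)
  truth <- simulate_phenotype(genotypes, topology, cfg_true, seed = seeds[3])
  truth <- inject_label_noise(truth, config$case_flip_rate,
                              config$control_flip_rate, seed = seeds[4],
                              case_flips = k_case, control_flips = k_control)
  structure(
    list(genotypes = genotypes[truth$sample_id, , drop = FALSE],
         truth = truth, topology = topology, maf = maf, config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  cat(sprintf("  %d samples (%d observed cases) x %d variants on %d genes\n",
              nrow(x$genotypes), sum(x$truth$observed_label),
              ncol(x$genotypes), length(unique(x$topology$gene))))
  cat(sprintf("  %d flipped labels; seed %d\n",
              sum(x$truth$flipped), x$config$seed))
  invisible(x)
}
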