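# Variant screening: SNP/autosome restriction, additive encoding,
# chi-squared genotype association, topology construction.

SEX_CHROMS <- c("X", "Y")
AUTOSOMES <- as.character(1:22)

#' Restrict a cohort to autosomal SNPs
#'
#' Removes InDels (records where REF or ALT is longer than one base) and
#' variants on the sex chromosomes (`X`/`Y`, with or without a `chr` prefix,
#' case-insensitive). Records on chromosomes that are neither autosomes nor
#' sex chromosomes are kept conservatively, with a message.
#'
#' @param cohort A biallelic [variant_cohort()] (run [split_multiallelic()]
#'   first).
#' @return The restricted cohort.
#' @export
exclude_indels_and_sex_chromosomes <- function(cohort) {
  s <- cohort$sites
  chrom <- toupper(sub("^CHR", "", toupper(s$chrom)))
  is_snp <- nchar(s$ref) == 1 & nchar(s$alt) == 1 &
    !grepl(",", s$alt, fixed = TRUE)
  on_sex <- chrom %in% SEX_CHROMS
  unknown <- !(chrom %in% c(AUTOSOMES, SEX_CHROMS, "MT", "M"))
  if (any(unknown)) {
    inform(sprintf("%d variants on unrecognised chromosomes were kept.",
                   sum(unknown)))
  }
  subset_sites(cohort, which(is_snp & !on_sex))
}

#' Encode genotypes additively
#'
#' Maps diploid biallelic genotypes to alternative-allele counts:
#' `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`; missing genotypes stay `NA` at this
#' stage (the network resolves them at its input, see [train_gennet()]).
#'
#' @param cohort A biallelic [variant_cohort()].
#' @param sample_order Optional character vector fixing the row order of the
#'   result (default: cohort sample order).
#' @return Integer matrix, samples x variants, with `NA` for missing calls.
#' @export
encode_additive <- function(cohort, sample_order = NULL) {
  al <- parse_alleles(cohort$gt)
  if (any(al$a1 > 1L | al$a2 > 1L, na.rm = TRUE)) {
    abort("allele index > 1 found; split multi-allelic records first.")
  }
  x <- t(al$a1 + al$a2)
  dimnames(x) <- list(colnames(cohort$gt), cohort$sites$id)
  if (!is.null(sample_order)) {
    if (!all(sample_order %in% rownames(x))) abort("unknown sample in `sample_order`.")
    x <- x[sample_order, , drop = FALSE]
  }
  x
}

#' Tabulate genotypes by class
#'
#' Counts the three additive genotype codes among cases and controls;
#' missing genotypes are excluded from the counts.
#'
#' @param genotypes Integer vector of codes in \{0, 1, 2\} with `NA` for
#'   missing.
#' @param labels 0/1 vector (1 = case) of the same length.
#' @return A 2 x 3 integer matrix with rows `case`, `control` and columns
#'   `g0`, `g1`, `g2`.
#' @export
genotype_contingency <- function(genotypes, labels) {
  assert_binary_labels(labels)
  if (length(genotypes) != length(labels)) {
    abort("`genotypes` and `labels` must have equal length.")
  }
  ok <- !is.na(genotypes)
  if (!any(ok & labels == 1) || !any(ok & labels == 0)) {
    abort("one class has no called genotypes.")
  }
  tab <- table(factor(ifelse(labels == 1, "case", "control"),
                      levels = c("case", "control")),
               factor(genotypes, levels = 0:2))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(c("case", "control"), c("g0", "g1", "g2")))
  m
}

#' Pearson chi-squared test on a genotype contingency table
#'
#' Genotype columns with zero total are dropped before testing, so the
#' degrees of freedom shrink accordingly; a table with fewer than two
#' informative columns is flagged untestable rather than tested.
#'
#' @param table Counts matrix from [genotype_contingency()] (classes x
#'   genotypes).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `untestable`.
#' @export
#' @examples
#' tab <- rbind(case = c(10, 20, 70), control = c(30, 30, 40))
#' chi2_test(tab)
chi2_test <- function(table) {
  informative <- colSums(table) > 0
  tab <- table[, informative, drop = FALSE]
  if (ncol(tab) < 2) {
    return(tibble(statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, untestable = TRUE))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = as.integer(ht$parameter),
         p_value = unname(ht$p.value), untestable = FALSE)
}

#' Chi-squared association screen over all variants
#'
#' Runs [genotype_contingency()] + [chi2_test()] for every variant of an
#' additively encoded matrix.
#'
#' @param encoded Samples x variants matrix from [encode_additive()].
#' @param labels 0/1 vector (1 = case), one per sample.
#' @param alpha Significance level used to mark selected variants.
#' @return Tibble with one row per variant: `variant_id`, `statistic`,
#'   `df`, `p_value`, `untestable`, `selected` (`p_value < alpha`, no
#'   multiple-testing correction — the screen is deliberately liberal to
#'   preserve representativeness).
#' @export
test_associations <- function(encoded, labels, alpha = 0.05) {
  labels <- assert_binary_labels(labels)
  res <- purrr::map_dfr(seq_len(ncol(encoded)), function(j) {
    g <- encoded[, j]
    ok <- !is.na(g)
    if (!any(ok & labels == 1) || !any(ok & labels == 0)) {
      return(tibble(statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, untestable = TRUE))
    }
    chi2_test(genotype_contingency(g, labels))
  })
  mutate(res,
         variant_id = colnames(encoded),
         selected = !untestable & p_value < alpha,
         .before = 1)
}

#' Select associated variants
#'
#' Keeps variants with `p_value < alpha` (strict). Untestable variants are
#' never selected. No multiple-testing correction is applied: the screen is
#' a dimensionality-reduction step, not an inferential claim.
#'
#' @param results Tibble from [test_associations()].
#' @param alpha Significance level.
#' @return Character vector of selected variant ids, in input order.
#' @export
select_variants <- function(results, alpha = 0.05) {
  results$variant_id[!results$untestable &
                       !is.na(results$p_value) & results$p_value < alpha]
}

#' Build a topology table from an annotation
#'
#' Maps each selected variant to exactly one gene using an Annovar-style
#' annotation table (`variant_id`, `gene`; multiple rows per variant
#' allowed). Variants annotated to several genes are resolved to the
#' alphabetically first symbol, deterministically. Gene nodes are numbered
#' by first appearance.
#'
#' @param selected_variants Character vector of variant ids (row order of
#'   the result).
#' @param annotation Tibble with columns `variant_id`, `gene`.
#' @return A topology tibble (`variant_node`, `variant`, `gene_node`,
#'   `gene`).
#' @export
build_topology <- function(selected_variants, annotation) {
  stopifnot(all(c("variant_id", "gene") %in% names(annotation)))
  ann <- annotation |>
    filter(.data$variant_id %in% selected_variants) |>
    group_by(.data$variant_id) |>
    summarise(gene = min(.data$gene), .groups = "drop")
  idx <- match(selected_variants, ann$variant_id)
  if (anyNA(idx)) {
    abort(paste0("variants without a gene annotation: ",
                 paste(head(selected_variants[is.na(idx)], 5), collapse = ", ")))
  }
  gene <- ann$gene[idx]
  tp <- tibble(
    variant_node = seq_along(selected_variants) - 1L,
    variant = selected_variants,
    gene_node = match(gene, unique(gene)) - 1L,
    gene = gene
  )
  validate_topology(tp)
}

#' Summarise an allele-frequency spectrum
#'
#' Bins per-variant allele frequencies (e.g. rare `< 1%`, low-frequency
#' `1-5%`, common `>= 5%` with the default breaks) and reports counts and
#' percentages — the standard way the composition of a screened variant set
#' is described.
#'
#' @param af Numeric vector of allele frequencies in \[0, 1\].
#' @param breaks Increasing cut points strictly inside (0, 1).
#' @return Tibble with columns `bin`, `n`, `pct`.
#' @export
#' @examples
#' af_spectrum(c(0.001, 0.02, 0.2, 0.004))
af_spectrum <- function(af, breaks = c(0.01, 0.05)) {
  stopifnot(all(af >= 0 & af <= 1), all(diff(breaks) > 0))
  edges <- c(0, breaks, 1 + 1e-9)
  lab <- c(paste0("<", format(breaks[1])),
           if (length(breaks) > 1)
             paste0("[", format(breaks[-length(breaks)]), ",",
                    format(breaks[-1]), ")"),
           paste0(">=", format(breaks[length(breaks)])))
  bin <- cut(af, edges, labels = lab, right = FALSE)
  tibble(bin = factor(lab, levels = lab)) |>
    left_join(tibble(bin = bin) |> dplyr::count(.data$bin), by = "bin") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           pct = 100 * .data$n / length(af))
}
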