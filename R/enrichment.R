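# Over-representation analysis of a prioritised gene list against gene-set
# collections: enrichment ratio, one-sided hypergeometric p, BH FDR.

#' Enrichment ratio
#'
#' `(k / n) / (K / N)`: how over-represented a gene set is within a gene
#' list relative to its share of the reference universe.
#'
#' @param k Overlap between list and set.
#' @param n List size.
#' @param K Set size.
#' @param N Reference universe size.
#' @return Numeric ratio (vectorised).
#' @export
#' @examples
#' enrichment_ratio(5, 150, 10, 20000)
enrichment_ratio <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    abort("`n`, `K` and `N` must be positive.")
  }
  if (any(k > pmin(n, K))) abort("`k` cannot exceed min(n, K).")
  (k / n) / (K / N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\].
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line,
#' `name<TAB>description<TAB>gene<TAB>gene...`.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character gene vectors, with set descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort("malformed GMT: every line needs name, description, >= 1 gene.")
  sets <- lapply(parts, function(pp) unique(pp[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Over-representation analysis
#'
#' For each gene set, counts the overlap with the gene list, computes the
#' enrichment ratio and the one-sided (upper-tail) hypergeometric p-value
#' of observing at least that overlap when drawing `n` genes from a
#' reference universe of `N` genes of which `K` belong to the set, and
#' adjusts p-values across the collection by Benjamini-Hochberg. Gene
#' symbols are matched case-insensitively (upper-cased).
#'
#' @param gene_list Character vector of gene symbols (the prioritised
#'   list).
#' @param gene_sets Named list of gene vectors, e.g. from [read_gmt()].
#' @param reference_size Size `N` of the reference universe ("the entire
#'   genome" is not a number — this is a required input). Ignored when
#'   `reference_genes` is given.
#' @param reference_genes Optional explicit reference universe; list genes
#'   and set genes outside it are dropped (with a warning for the list)
#'   and `N` becomes its length.
#' @return Tibble: `set`, `k`, `n`, `K`, `N`, `enrichment_ratio`,
#'   `p_value`, `fdr`, sorted as given in `gene_sets`.
#' @export
ora_test <- function(gene_list, gene_sets, reference_size = NULL,
                     reference_genes = NULL) {
  if (length(gene_list) == 0) abort("`gene_list` is empty.")
  if (length(gene_sets) == 0) abort("`gene_sets` is empty.")
  genes <- unique(toupper(gene_list))
  sets <- lapply(gene_sets, function(s) unique(toupper(s)))
  if (!is.null(reference_genes)) {
    universe <- unique(toupper(reference_genes))
    dropped <- setdiff(genes, universe)
    if (length(dropped) > 0) {
      warn(sprintf("%d list genes are outside the reference universe and were dropped.",
                   length(dropped)))
      genes <- intersect(genes, universe)
      if (length(genes) == 0) abort("no list genes left in the reference universe.")
    }
    sets <- lapply(sets, intersect, universe)
    N <- length(universe)
  } else {
    if (is.null(reference_size)) {
      abort("supply `reference_size` (or `reference_genes`).")
    }
    N <- as.integer(reference_size)
  }
  n <- length(genes)
  purrr::imap_dfr(sets, function(s, nm) {
    K <- length(s)
    k <- length(intersect(genes, s))
    tibble(set = nm, k = k, n = n, K = K, N = N,
           enrichment_ratio = if (K > 0) enrichment_ratio(k, n, K, N) else NA_real_,
           p_value = if (K > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE)
                     else NA_real_)
  }) |>
    mutate(fdr = bh_fdr(.data$p_value))
}

#' Extract the top-ranked genes from an importance table
#'
#' @param importances Tibble from [gene_importances()] (sorted, with a
#'   `rank` column).
#' @param k Number of genes to keep (default the conventional 150 used for
#'   functional follow-up).
#' @return Character vector of gene symbols in rank order.
#' @export
top_gene_list <- function(importances, k = 150) {
  if (k > nrow(importances)) {
    abort(sprintf("`k` = %d exceeds the %d available genes.",
                  k, nrow(importances)))
  }
  arrange(importances, .data$rank)$gene[seq_len(k)]
}
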