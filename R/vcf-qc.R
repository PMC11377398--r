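# Variant-level quality control: per-site metric recomputation, depth and
# call-rate filtering, multi-allelic splitting with genotype masking, and
# phenotype-driven sample exclusion.

# Split diploid genotype strings into two integer allele matrices. Anything
# that is not "a/b" or "a|b" with numeric alleles (missing, half-called,
# haploid) is treated as missing.
parse_alleles <- function(gt) {
  called <- array(grepl("^[0-9]+[/|][0-9]+$", gt),
                  dim = dim(gt), dimnames = dimnames(gt))
  a1 <- a2 <- array(NA_integer_, dim = dim(gt), dimnames = dimnames(gt))
  a1[called] <- as.integer(sub("^([0-9]+)[/|].*$", "\\1", gt[called]))
  a2[called] <- as.integer(sub("^.*[/|]([0-9]+)$", "\\1", gt[called]))
  list(a1 = a1, a2 = a2, called = called)
}

subset_sites <- function(cohort, idx) {
  variant_cohort(cohort$sites[idx, , drop = FALSE],
                 cohort$gt[idx, , drop = FALSE],
                 if (!is.null(cohort$dp)) cohort$dp[idx, , drop = FALSE])
}

subset_samples <- function(cohort, keep) {
  variant_cohort(cohort$sites,
                 cohort$gt[, keep, drop = FALSE],
                 if (!is.null(cohort$dp)) cohort$dp[, keep, drop = FALSE])
}

#' Drop samples carrying an excluded phenotype label
#'
#' Removes from every site record the samples whose phenotype matches
#' `excluded_label` (e.g. dropping bipolar-disorder samples from a
#' schizophrenia case-control cohort). Every sample in the cohort must have
#' a phenotype entry.
#'
#' @param cohort A [variant_cohort()].
#' @param phenotypes Tibble with columns `sample_id`, `label`.
#' @param excluded_label Label value to remove.
#' @return The cohort without the excluded samples.
#' @export
drop_samples_by_phenotype <- function(cohort, phenotypes, excluded_label) {
  samples <- cohort_samples(cohort)
  idx <- match(samples, phenotypes$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing from the phenotype table: ",
                 paste(head(samples[is.na(idx)], 5), collapse = ", ")))
  }
  keep <- phenotypes$label[idx] != excluded_label
  if (!any(keep)) abort("excluding this label would empty the cohort.")
  subset_samples(cohort, keep)
}

#' Recompute per-site quality metrics
#'
#' Recalculates, from the genotypes and depths actually present, the three
#' metrics the site filter uses: mean read depth over samples with a
#' non-missing depth, genotype call rate, and alternative-allele frequency
#' among called alleles. A genotype with a missing depth still counts as
#' called (depth and genotype are independent tags).
#'
#' @param cohort A [variant_cohort()].
#' @return Tibble with columns `id`, `chrom`, `pos`, `mean_dp`, `call_rate`,
#'   `af` (one row per site; `mean_dp` is `NA` when no depths are stored).
#' @export
recompute_site_metrics <- function(cohort) {
  if (ncol(cohort$gt) == 0) abort("cohort has no samples.")
  al <- parse_alleles(cohort$gt)
  call_rate <- rowMeans(al$called)
  n_alt <- rowSums(al$a1 > 0, na.rm = TRUE) + rowSums(al$a2 > 0, na.rm = TRUE)
  n_alleles <- 2 * rowSums(al$called)
  af <- ifelse(n_alleles > 0, n_alt / n_alleles, NA_real_)
  if (is.null(cohort$dp)) {
    mean_dp <- rep(NA_real_, nrow(cohort$gt))
  } else {
    mean_dp <- rowMeans(cohort$dp, na.rm = TRUE)
    mean_dp[is.nan(mean_dp)] <- NA_real_
  }
  tibble(id = cohort$sites$id, chrom = cohort$sites$chrom,
         pos = cohort$sites$pos, mean_dp = unname(mean_dp),
         call_rate = unname(call_rate), af = unname(af))
}

#' Split multi-allelic sites into biallelic records
#'
#' Each site with `k` ALT alleles becomes `k` biallelic child records. In
#' the child for ALT allele `a`, any genotype containing an allele other
#' than the REF (0) or `a` is set to missing; the remaining genotypes are
#' re-coded to the \{0, 1\} alphabet. Biallelic sites pass through
#' unchanged. Child ids are suffixed with their ALT allele so ids stay
#' unique.
#'
#' @param cohort A [variant_cohort()].
#' @return A [variant_cohort()] in which every record is biallelic.
#' @export
split_multiallelic <- function(cohort) {
  n_alts <- lengths(strsplit(cohort$sites$alt, ",", fixed = TRUE))
  if (all(n_alts == 1)) return(cohort)
  al <- parse_alleles(cohort$gt)
  pieces <- lapply(seq_len(nrow(cohort$sites)), function(i) {
    alts <- strsplit(cohort$sites$alt[i], ",", fixed = TRUE)[[1]]
    if (length(alts) == 1) {
      return(list(sites = cohort$sites[i, ], gt = cohort$gt[i, , drop = FALSE],
                  dp = if (!is.null(cohort$dp)) cohort$dp[i, , drop = FALSE]))
    }
    a1 <- al$a1[i, ]; a2 <- al$a2[i, ]
    child_gt <- lapply(seq_along(alts), function(k) {
      ok <- al$called[i, ] & a1 %in% c(0L, k) & a2 %in% c(0L, k)
      out <- rep("./.", length(a1))
      out[ok] <- paste0(as.integer(a1[ok] == k), "/", as.integer(a2[ok] == k))
      matrix(out, nrow = 1, dimnames = list(NULL, colnames(cohort$gt)))
    })
    sites <- cohort$sites[rep(i, length(alts)), ]
    sites$alt <- alts
    sites$id <- paste0(sites$id, "_", alts)
    list(sites = sites, gt = do.call(rbind, child_gt),
         dp = if (!is.null(cohort$dp))
           cohort$dp[rep(i, length(alts)), , drop = FALSE])
  })
  variant_cohort(
    bind_rows(lapply(pieces, `[[`, "sites")),
    do.call(rbind, lapply(pieces, `[[`, "gt")),
    if (!is.null(cohort$dp)) do.call(rbind, lapply(pieces, `[[`, "dp"))
  )
}

#' Filter sites on quality, depth and call rate
#'
#' Keeps sites with `qual > min_qual`, mean depth `>= min_mean_dp` and call
#' rate `>= min_call_rate`, i.e. the exclusion conditions are strict
#' ("QUAL above 30", "mean depth below 8", "call rate below 90%"): a site
#' with mean depth exactly 8 or call rate exactly 0.90 is kept, a site with
#' QUAL exactly 30 is excluded. Metrics are recomputed on the records as
#' given, so children of [split_multiallelic()] are judged on their own
#' masked genotypes. Sites with no stored QUAL or depth information pass
#' the corresponding criterion.
#'
#' @param cohort A [variant_cohort()].
#' @param min_qual QUAL threshold (strict `>`).
#' @param min_mean_dp Mean-depth threshold (kept when `>=`).
#' @param min_call_rate Call-rate threshold (kept when `>=`).
#' @param whitelist Optional character vector of site ids allowed through an
#'   external recalibration step; when given, sites not listed are removed
#'   (pass-through hook, applied before the metric criteria).
#' @return The filtered cohort, with a `filter_log` attribute: a tibble of
#'   per-site metric values, verdicts and exclusion reasons.
#' @export
filter_sites <- function(cohort, min_qual = 30, min_mean_dp = 8,
                         min_call_rate = 0.90, whitelist = NULL) {
  metrics <- recompute_site_metrics(cohort)
  qual_ok <- is.na(cohort$sites$qual) | cohort$sites$qual > min_qual
  dp_ok <- is.na(metrics$mean_dp) | metrics$mean_dp >= min_mean_dp
  cr_ok <- metrics$call_rate >= min_call_rate
  wl_ok <- if (is.null(whitelist)) TRUE else metrics$id %in% whitelist
  kept <- qual_ok & dp_ok & cr_ok & wl_ok
  reason <- character(nrow(metrics))
  fails <- cbind(qual = !qual_ok, low_depth = !dp_ok,
                 low_call_rate = !cr_ok, not_whitelisted = !wl_ok)
  reason[!kept] <- apply(fails[!kept, , drop = FALSE], 1, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  log <- mutate(metrics, qual = cohort$sites$qual, kept = kept,
                reason = reason)
  out <- subset_sites(cohort, which(kept))
  attr(out, "filter_log") <- log
  out
}

#' Run the full variant-level QC chain
#'
#' Convenience wrapper: optionally drop samples by phenotype label, split
#' multi-allelic sites with genotype masking, then filter sites on
#' recomputed metrics. Metrics are recomputed after sample removal, so the
#' call-rate denominator reflects the retained samples only.
#'
#' @inheritParams filter_sites
#' @inheritParams drop_samples_by_phenotype
#' @param drop_label Optional phenotype label to exclude (requires
#'   `phenotypes`).
#' @return The QC-passed cohort with a `filter_log` attribute.
#' @export
qc_cohort <- function(cohort, phenotypes = NULL, drop_label = NULL,
                      min_qual = 30, min_mean_dp = 8, min_call_rate = 0.90,
                      whitelist = NULL) {
  if (!is.null(drop_label)) {
    if (is.null(phenotypes)) abort("`drop_label` requires `phenotypes`.")
    cohort <- drop_samples_by_phenotype(cohort, phenotypes, drop_label)
  }
  cohort <- split_multiallelic(cohort)
  filter_sites(cohort, min_qual, min_mean_dp, min_call_rate, whitelist)
}
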