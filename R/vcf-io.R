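#' Variant cohort container
#'
#' A light container for a multi-sample set of variant sites: a `sites`
#' tibble (`chrom`, `pos`, `id`, `ref`, `alt`, `qual`) plus parallel
#' sites-by-samples character matrices of genotypes (`"0/0"`, `"0/1"`, ...,
#' `"./."`) and optional integer depths. This is the working representation
#' for quality control and association screening.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`; `alt` may hold comma-separated alleles before
#'   [split_multiallelic()] is applied.
#' @param gt Character matrix (sites x samples) of diploid genotypes.
#' @param dp Optional numeric matrix (sites x samples) of read depths.
#' @return A `variant_cohort` object.
#' @export
variant_cohort <- function(sites, gt, dp = NULL) {
  sites <- as_tibble(sites)
  needed <- c("chrom", "pos", "id", "ref", "alt", "qual")
  if (!all(needed %in% names(sites))) {
    abort(paste0("`sites` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(sites) != nrow(gt)) abort("`gt` must have one row per site.")
  if (!is.null(dp) && !all(dim(dp) == dim(gt))) {
    abort("`dp` must match the dimensions of `gt`.")
  }
  if (is.null(colnames(gt))) abort("`gt` must carry sample names as colnames.")
  if (anyDuplicated(sites$id)) abort("site ids must be unique.")
  rownames(gt) <- sites$id
  if (!is.null(dp)) rownames(dp) <- sites$id
  structure(list(sites = sites, gt = gt, dp = dp), class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("<variant_cohort> %d sites x %d samples (%s depths)\n",
              nrow(x$sites), ncol(x$gt),
              if (is.null(x$dp)) "no" else "with"))
  invisible(x)
}

#' @rdname variant_cohort
#' @param x A `variant_cohort`.
#' @export
cohort_samples <- function(x) colnames(x$gt)

#' Read a multi-sample VCF into a variant cohort
#'
#' Parses a VCF (v4.x, plain or bgzipped) with `vcfR` and extracts the
#' per-sample `GT` and, when present, `DP` FORMAT fields.
#'
#' @param path Path to the VCF file.
#' @return A [variant_cohort()].
#' @export
read_vcf_cohort <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  sites <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"],
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = as.numeric(fix[, "QUAL"])
  )
  if (anyNA(sites$id) || anyDuplicated(sites$id)) {
    sites$id <- make.unique(
      ifelse(is.na(sites$id) | sites$id == ".",
             paste0(sites$chrom, ":", sites$pos), sites$id),
      sep = "_")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  dp <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("\\bDP\\b", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }
  variant_cohort(sites, gt, dp)
}

#' Write a variant cohort to a plain-text VCF
#'
#' Serialises a [variant_cohort()] as an uncompressed VCF v4.2 file with
#' `GT` (and `DP`, if depths are present) FORMAT fields.
#'
#' @param cohort A [variant_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_cohort <- function(cohort, path) {
  s <- cohort$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cohortsieve",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(cohort$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort$gt)), collapse = "\t")
  )
  if (is.null(cohort$dp)) {
    fmt <- "GT"
    cells <- cohort$gt
  } else {
    fmt <- "GT:DP"
    dp_chr <- ifelse(is.na(cohort$dp), ".",
                     format(cohort$dp, trim = TRUE, scientific = FALSE))
    cells <- matrix(paste(cohort$gt, dp_chr, sep = ":"),
                    nrow = nrow(cohort$gt))
  }
  body <- apply(cbind(s$chrom, s$pos, s$id, s$ref, s$alt,
                      format(s$qual, trim = TRUE), "PASS", ".", fmt, cells),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write and read phenotype tables
#'
#' The phenotype table is a two-column TSV `sample_id<TAB>label`. For
#' simulated cohorts labels are 0 (control) / 1 (case); arbitrary string
#' labels (e.g. a diagnosis to be excluded during QC) are also supported.
#'
#' @param phenotypes Tibble with columns `sample_id` and `label`.
#' @param path File path.
#' @return `read_phenotypes()` returns a tibble; `write_phenotypes()`
#'   returns `path` invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(all(c("sample_id", "label") %in% names(phenotypes)))
  write.table(phenotypes[, c("sample_id", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  as_tibble(read.delim(path, colClasses = c(sample_id = "character")))
}

#' Write and read topology tables
#'
#' The topology CSV has the exact header
#' `variant_node,variant,gene_node,gene` with 0-based node indices; it is the
#' interchange format defining the sparse variant-to-gene connectivity.
#'
#' @param topology Tibble from [make_topology()] or [build_topology()].
#' @param path File path.
#' @return `read_topology()` returns the topology tibble;
#'   `write_topology()` returns `path` invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(identical(names(topology),
                      c("variant_node", "variant", "gene_node", "gene")))
  write.csv(topology, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  tp <- as_tibble(read.csv(path, colClasses = c(
    variant_node = "integer", variant = "character",
    gene_node = "integer", gene = "character")))
  if (!identical(names(tp), c("variant_node", "variant", "gene_node", "gene"))) {
    abort("not a topology CSV: header must be variant_node,variant,gene_node,gene")
  }
  validate_topology(tp)
  tp
}

validate_topology <- function(tp) {
  if (nrow(tp) == 0) abort("topology is empty.")
  if (!identical(tp$variant_node, seq_len(nrow(tp)) - 1L)) {
    abort("variant_node must be consecutive 0-based indices.")
  }
  if (anyDuplicated(tp$variant)) abort("each variant must appear exactly once.")
  first <- !duplicated(tp$gene_node)
  if (!identical(tp$gene_node[first], seq_len(sum(first)) - 1L)) {
    abort("gene_node values must be consecutive 0-based by first appearance.")
  }
  pairs <- unique(tp[, c("gene_node", "gene")])
  if (anyDuplicated(pairs$gene_node) || anyDuplicated(pairs$gene)) {
    abort("gene_node and gene must map one-to-one.")
  }
  invisible(tp)
}

#' Write a simulated cohort to disk
#'
#' Emits everything downstream stages consume: a plain-text multi-sample VCF
#' (`<prefix>.vcf`, FORMAT `GT:DP`, synthetic QUAL), a phenotype TSV
#' (`<prefix>_phenotypes.tsv`, observed 0/1 labels), the ground-truth table
#' (`<prefix>_truth.tsv`), and the topology CSV (`<prefix>_topology.csv`).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param out_prefix Path prefix for the four files.
#' @param mean_dp Mean of the synthetic Poisson read depths.
#' @param min_dp Depths are truncated below at this value so that default QC
#'   thresholds are not tripped accidentally; set to 0 to disable.
#' @param qual Optional per-variant QUAL vector (default: uniform in
#'   \[40, 90\]).
#' @param depths Optional depth matrix (samples x variants) overriding the
#'   Poisson draw.
#' @param seed Seed for the synthetic QUAL/DP draws.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, out_prefix, mean_dp = 30, min_dp = 8,
                         qual = NULL, depths = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  seeds <- derive_seeds(seed, 2L)
  qual <- qual %||% withr::with_seed(seeds[1], runif(m, 40, 90))
  if (is.null(depths)) {
    depths <- withr::with_seed(seeds[2],
                               matrix(rpois(n * m, mean_dp), n, m))
    depths[depths < min_dp] <- as.integer(min_dp)
  }
  stopifnot(all(dim(depths) == dim(g)), length(qual) == m)

  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[g + 1L], nrow = n, dimnames = dimnames(g))
  gt[is.na(g)] <- "./."
  sites <- tibble(
    chrom = "1", pos = seq_len(m) * 100L, id = colnames(g),
    ref = "A", alt = "G", qual = round(qual, 1)
  )
  vc <- variant_cohort(sites, t(gt), t(depths))

  paths <- c(
    vcf = paste0(out_prefix, ".vcf"),
    phenotypes = paste0(out_prefix, "_phenotypes.tsv"),
    truth = paste0(out_prefix, "_truth.tsv"),
    topology = paste0(out_prefix, "_topology.csv")
  )
  write_vcf_cohort(vc, paths["vcf"])
  write_phenotypes(
    tibble(sample_id = cohort$truth$sample_id,
           label = cohort$truth$observed_label),
    paths["phenotypes"])
  write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_topology(cohort$topology, paths["topology"])
  invisible(paths)
}
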