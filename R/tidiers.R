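# broom-style tidiers for fitted objects.

#' Tidy a trained gene network
#'
#' One row per trainable parameter, identified by layer: `variant` (the
#' sparse variant-to-gene weights), `gene_bias`, `gene_output` (the
#' coefficients of the final logistic regression) and `output_bias`.
#'
#' @param x A `gennet`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `layer`, `estimate`.
#' @export
tidy.gennet <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$par$w), layer = "variant", estimate = unname(x$par$w)),
    tibble(term = names(x$par$b), layer = "gene_bias", estimate = unname(x$par$b)),
    tibble(term = names(x$par$u), layer = "gene_output", estimate = unname(x$par$u)),
    tibble(term = "(bias)", layer = "output_bias", estimate = x$par$c)
  )
}

#' Glance at a trained gene network
#'
#' @param x A `gennet`.
#' @param ... Unused.
#' @return One-row tibble: `n_variants`, `n_genes`, `n_params`, `epochs`,
#'   `final_loss`, `final_val_loss`.
#' @export
glance.gennet <- function(x, ...) {
  h <- x$history
  tibble(
    n_variants = length(x$par$w),
    n_genes = length(x$par$u),
    n_params = n_params(x),
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)]
  )
}

#' Tidy an evaluation result
#'
#' @param x A `gennet_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return The per-repeat tibble (`repeat_id`, `val_auc`, `test_auc`,
#'   `epochs`).
#' @export
tidy.gennet_eval <- function(x, ...) x$aucs

#' Glance at an evaluation result
#'
#' @param x A `gennet_eval`.
#' @param ... Unused.
#' @return One-row tibble with mean/sd/max AUC per split and `n_repeats`.
#' @export
glance.gennet_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "split",
                             values_from = c("mean_auc", "sd_auc", "max_auc"))
  mutate(wide, n_repeats = x$n_repeats)
}
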