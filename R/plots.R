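# ggplot2 visualisations for the main result types.

#' Plot an ensemble score table
#'
#' Histogram of per-sample mean ensemble scores by observed class, with the
#' 0.5 classification threshold marked; outlying samples sit on the wrong
#' side of the line.
#'
#' @param object A `score_table` from [ensemble_scores()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, bins = 40, ...) {
  df <- mutate(as_tibble(object),
               class = ifelse(.data$label == 1, "case", "control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_score,
                                   fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.7,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "mean ensemble score", y = "samples",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation result
#'
#' Per-repeat validation and test AUCs as jittered points over boxplots.
#'
#' @param object A `gennet_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gennet_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$aucs, c("val_auc", "test_auc"),
                              names_to = "split", values_to = "auc") |>
    mutate(split = sub("_auc$", "", .data$split))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$split, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param object A trained `gennet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gennet <- function(object, ...) {
  if (is.null(object$history)) abort("the network has not been trained.")
  long <- tidyr::pivot_longer(object$history, c("loss", "val_loss"),
                              names_to = "series", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Association screen overview plot
#'
#' A basic Manhattan-style export: `-log10(p)` per variant in input order,
#' with the selection threshold drawn.
#'
#' @param results Tibble from [test_associations()].
#' @param alpha Significance level drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_associations <- function(results, alpha = 0.05) {
  df <- results |>
    filter(!.data$untestable) |>
    mutate(index = row_number(), neglog10p = -log10(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neglog10p,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "variant", y = expression(-log[10](italic(p))),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
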