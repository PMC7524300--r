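#' @importFrom ggplot2 ggplot aes geom_point geom_boxplot geom_col geom_hline
#'   geom_errorbar facet_wrap labs theme_minimal autoplot position_dodge
#' @export
ggplot2::autoplot

#' Ordination scatter plot
#'
#' First two axes of a robust Aitchison ordination, optionally colored by
#' group.
#'
#' @param object A `milkphen_rpca` object.
#' @param metadata Optional metadata tibble (`infant_id`, `group`) for
#'   coloring.
#' @param axes Which two axes to draw (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.milkphen_rpca <- function(object, metadata = NULL, axes = c(1, 2),
                                   ...) {
  sc <- object$sample_scores
  ax <- names(object$proportion_explained)[axes]
  lab <- sprintf("%s (%.0f%%)", ax, 100 * object$proportion_explained[axes])
  df <- sc
  if (!is.null(metadata)) {
    df <- left_join(df, metadata[c("infant_id", "group")],
                    by = c(sample_id = "infant_id"))
  }
  p <- ggplot(df, aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  p <- if ("group" %in% names(df)) {
    p + geom_point(aes(color = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
  p + labs(x = lab[1], y = lab[2], color = "Milk consumption") +
    theme_minimal()
}

#' Alpha diversity boxplots by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Metadata tibble (`infant_id`, `group`).
#' @param metrics Metrics to draw.
#' @return A ggplot faceted by metric.
#' @export
plot_alpha_diversity <- function(alpha, metadata,
                                 metrics = c("shannon", "richness",
                                             "evenness")) {
  df <- left_join(alpha, metadata[c("infant_id", "group")],
                  by = c(sample_id = "infant_id"))
  long <- tidyr::pivot_longer(df, all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$group, y = .data$value,
                   fill = .data$group)) +
    geom_boxplot(show.legend = FALSE) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Milk consumption", y = NULL) +
    theme_minimal()
}

#' Pairwise-difference plot for a comparison table
#'
#' Draws the six pairwise group differences per feature, colored by whether
#' the Tukey-adjusted p-value falls below 0.05.
#'
#' @param comparison Tibble from [comparison_table()].
#' @param features Optional subset of features to draw.
#' @return A ggplot.
#' @export
plot_comparison <- function(comparison, features = NULL) {
  if (!is.null(features)) {
    comparison <- filter(comparison, .data$feature %in% features)
  }
  contrasts <- sub("^diff_", "",
                   grep("^diff_", names(comparison), value = TRUE))
  long <- purrr::map_dfr(contrasts, function(ct) {
    tibble(feature = comparison$feature, contrast = gsub("_", "-", ct),
           difference = comparison[[paste0("diff_", ct)]],
           adj_p = comparison[[paste0("p_", ct)]])
  })
  long$contrast <- factor(long$contrast, levels = gsub("_", "-", contrasts))
  ggplot(long, aes(x = .data$contrast, y = .data$difference,
                   fill = .data$adj_p < 0.05)) +
    geom_col() +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "Contrast (second minus first group)", y = "Adjusted difference",
         fill = "Tukey p < 0.05") +
    theme_minimal()
}
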