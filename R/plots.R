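#' Plot cluster QC mean ratios with Tukey fences
#'
#' @param object A `cluster_qc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_qc <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$cluster), y = .data$mean_ratio,
                     colour = .data$excluded)) +
    geom_point(size = 3) +
    geom_hline(aes(yintercept = .data$upper_fence), linetype = "dashed") +
    geom_hline(aes(yintercept = .data$lower_fence), linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    labs(x = "Cluster", y = "Mean genes-expressed / LISI ratio",
         colour = "Excluded") +
    theme_minimal()
}

#' Plot per-cell LISI distribution by label
#'
#' @param object A `lisi_vector` tibble.
#' @param labels Optional per-cell grouping (e.g. batch) for faceting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lisi_vector <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(labels)) df$group <- labels
  p <- ggplot(df, aes(x = .data$lisi)) +
    geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    labs(x = "LISI", y = "Cells") +
    theme_minimal()
  if (!is.null(labels)) p <- p + facet_wrap(~group)
  p
}

#' Violin plot of the disease score by condition
#'
#' @param score Tibble from [disease_score()].
#' @param meta Tibble with `barcode` and `condition`.
#' @return A ggplot object.
#' @export
plot_disease_score <- function(score, meta) {
  df <- inner_join(score, meta |> select("barcode", "condition"), by = "barcode")
  ggplot(df, aes(x = .data$condition, y = .data$score, fill = .data$condition)) +
    geom_violin(scale = "width") +
    geom_boxplot(width = 0.15, fill = "white", outlier.size = 0.4) +
    labs(x = NULL, y = "Disease score (mean log2-normalized panel expression)") +
    guides(fill = "none") +
    theme_minimal()
}

#' Heatmap of interaction-count deltas (disease minus healthy)
#'
#' @param object An `interaction_delta`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_delta <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$receiver, y = .data$donor,
                           fill = .data$delta)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$delta), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "Receiver", y = "Donor",
         fill = "Δ interactions\n(disease - healthy)") +
    theme_minimal()
}
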