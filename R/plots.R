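#' Volcano plot of a differential-expression table
#'
#' Plots the extent (M-value, x-axis) against the significance
#' (-log10 adjusted p, y-axis) of differential expression; dashed lines
#' mark the significance level and, when the table carries one, the
#' |M| cut-off used for DE calls.
#'
#' @param de A `cm_de_table`.
#' @param label_top Number of most significant features to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, label_top = 5L) {
  alpha <- attr(de, "alpha") %||% 0.05
  min_abs_m <- attr(de, "min_abs_m")
  d <- tidy(de) |> filter(!is.na(.data$p_adj))
  top <- d |> arrange(.data$p_adj) |> head(label_top)
  p <- ggplot(d, aes(x = .data$m, y = -log10(.data$p_adj))) +
    geom_point(aes(colour = .data$significant), alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_text(data = top, aes(label = .data$feature_id),
              vjust = -0.6, size = 2.8) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    labs(x = "M (log2 fold change, case vs control)",
         y = expression(-log[10] ~ "adjusted p"),
         colour = sprintf("p_adj < %.2g", alpha)) +
    theme_minimal()
  if (!is.null(min_abs_m)) {
    p <- p + geom_vline(xintercept = c(-min_abs_m, min_abs_m),
                        linetype = "dashed")
  }
  p
}

#' @rdname plot_volcano
#' @param object A `cm_de_table`.
#' @param ... Passed to [plot_volcano()].
#' @export
autoplot.cm_de_table <- function(object, ...) plot_volcano(object, ...)

#' Plot PCA sample scores with the inferred confounder
#'
#' @param pca The score tibble returned by [pca_confounder()].
#' @param samples Optional sample sheet; when given, points are shaped by
#'   group so confounder and condition structure can be compared.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, samples = NULL) {
  d <- pca
  if (!is.null(samples)) {
    d <- d |> left_join(samples |> select("sample_id", "group"), by = "sample_id")
  }
  ve <- attr(pca, "variance_explained")
  lab <- function(i) {
    if (!is.null(ve) && length(ve) >= i) {
      sprintf("PC%d (%.0f%%)", i, 100 * ve[i])
    } else sprintf("PC%d", i)
  }
  aes_args <- if (!is.null(samples)) {
    aes(x = .data$PC1, y = .data$PC2, colour = .data$covariate,
        shape = .data$group)
  } else {
    aes(x = .data$PC1, y = .data$PC2, colour = .data$covariate)
  }
  ggplot(d, aes_args) +
    geom_point(size = 3) +
    geom_text(aes(label = .data$sample_id), vjust = -1, size = 2.8,
              show.legend = FALSE) +
    labs(x = lab(1), y = lab(2), colour = "PC1 sign") +
    theme_minimal()
}

#' Plot module sizes and cohesiveness
#'
#' @param modules Module tibble from [cluster_graph()].
#' @return A ggplot object.
#' @export
plot_modules <- function(modules) {
  ggplot(modules, aes(x = .data$size, y = .data$cohesiveness,
                      label = .data$module_id)) +
    geom_point(aes(size = .data$density), alpha = 0.7) +
    geom_text(vjust = -1, size = 3) +
    labs(x = "module size (genes)", y = "cohesiveness", size = "density") +
    theme_minimal()
}
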