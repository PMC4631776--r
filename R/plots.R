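#' Plot spectra from a dataset
#'
#' Overlaid absorbance traces, coloured by species. With many spectra a
#' random subset keeps the figure readable.
#'
#' @param object An `ir_dataset`.
#' @param n_max Maximum number of spectra drawn (random subset beyond it).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ir_dataset <- function(object, n_max = 12, ...) {
  long <- tidy(object)
  ids <- unique(long$spectrum_id)
  if (length(ids) > n_max) {
    long <- long[long$spectrum_id %in% sample(ids, n_max), ]
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                                     group = .data$spectrum_id,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber~(cm^-1)), y = "Absorbance",
                  colour = "Species") +
    ggplot2::theme_minimal()
}

#' Scatter plot of discriminant factor scores
#'
#' Plots two discriminant factors of classified spectra, coloured by true
#' species, with class centroids overlaid.
#'
#' @param classification An `ir_classification`.
#' @param lda The `ir_lda` used (for centroids); optional.
#' @param factors Which two factors to plot.
#' @return A ggplot object.
#' @export
plot_factor_scores <- function(classification, lda = NULL, factors = c(1, 2)) {
  stopifnot(inherits(classification, "ir_classification"), length(factors) == 2)
  preds <- classification$predictions
  fx <- paste0("factor_", factors[1])
  fy <- paste0("factor_", factors[2])
  p <- ggplot2::ggplot(preds, ggplot2::aes(x = .data[[fx]], y = .data[[fy]],
                                           colour = .data$true_species)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("Factor %d", factors[1]),
                  y = sprintf("Factor %d", factors[2]),
                  colour = "Species") +
    ggplot2::theme_minimal()
  if (!is.null(lda)) {
    cent <- tibble::as_tibble(lda$centroids[, factors, drop = FALSE],
                              rownames = "species")
    names(cent) <- c("species", fx, fy)
    p <- p + ggplot2::geom_point(data = cent, shape = 4, size = 3,
                                 colour = "black")
  }
  p
}

#' Bar chart of scaled marker composition per species and layer
#'
#' Mirrors the standard composition figure: one panel per marker, scaled
#' mean area (0 = lowest species mean, 1 = highest) per species, split by
#' sample type, with raw-sd-derived error bars where available.
#'
#' @param composition Output of [aggregate_by_species()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$species, y = .data$scaled_mean,
                               fill = .data$sample_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::facet_wrap(~marker, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Scaled band area", fill = "Sample type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Dendrogram plot with optional grouping threshold
#'
#' @param tree An `hclust` from [ward_linkage()].
#' @param threshold Optional height threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, threshold = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  xpos <- numeric(n)
  xpos[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_y <- tree$height
  seg <- vector("list", nrow(tree$merge))
  child_xy <- function(v) {
    if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
  }
  for (m in seq_len(nrow(tree$merge))) {
    a <- child_xy(tree$merge[m, 1])
    b <- child_xy(tree$merge[m, 2])
    node_x[m] <- (a[1] + b[1]) / 2
    seg[[m]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[m], node_y[m]), yend = c(node_y[m], node_y[m], b[2]))
  }
  segments <- dplyr::bind_rows(seg)
  labels <- tibble::tibble(x = seq_len(n), label = tree$labels[tree$order])
  p <- ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labels$x, labels = labels$label) +
    ggplot2::labs(x = NULL, y = "Merge height (Euclidean distance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
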