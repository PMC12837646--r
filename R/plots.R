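# ggplot2 views of the result objects. These are deliberately plain; the
# tables behind them are the primary interface.

#' Plot a correlation matrix
#'
#' Heatmap of the pairwise Pearson correlations, annotated with r values.
#'
#' @param object A `uae_corr` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_corr <- function(object, ...) {
  lv <- unique(object$response_x)
  df <- dplyr::mutate(as_tibble(object),
                      response_x = factor(.data$response_x, levels = lv),
                      response_y = factor(.data$response_y, levels = rev(lv)))
  ggplot(df, aes(.data$response_x, .data$response_y, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 2.6) +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot a PCA biplot
#'
#' Sample scores on the first two components with response loadings overlaid
#' as arrows (scaled to the score range).
#'
#' @param object A `uae_pca` from [pca_responses()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_pca <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  k <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(ld$PC1, ld$PC2)))
  v <- object$variance$percent
  ggplot(sc, aes(.data$PC1, .data$PC2)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_vline(xintercept = 0, linetype = 3) +
    geom_segment(data = ld, aes(x = 0, y = 0, xend = .data$PC1 * k,
                                yend = .data$PC2 * k),
                 arrow = arrow(length = unit(2, "mm")), colour = "grey40") +
    geom_text(data = ld, aes(x = .data$PC1 * k, y = .data$PC2 * k,
                             label = .data$response),
              colour = "grey30", size = 3, vjust = -0.4) +
    geom_point(colour = "#2166ac") +
    geom_text(aes(label = .data$sample_id), vjust = -0.6, size = 3) +
    labs(x = sprintf("PC1 (%.2f%%)", v[1]), y = sprintf("PC2 (%.2f%%)", v[2])) +
    theme_minimal()
}

#' Plot a dendrogram
#'
#' Classic dendrogram of the sample clustering, drawn from the merge table.
#'
#' @param object A `uae_hca` from [hcluster_responses()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_hca <- function(object, ...) {
  h <- object$hclust
  n <- length(object$labels)
  xleaf <- setNames(seq_len(n), h$order)      # leaf index -> x position
  xpos <- numeric(nrow(h$merge)); ypos <- h$height
  segs <- list()
  node_x <- function(id) if (id < 0) xleaf[[as.character(-id)]] else xpos[id]
  node_y <- function(id) if (id < 0) 0 else ypos[id]
  for (i in seq_len(nrow(h$merge))) {
    l <- h$merge[i, 1]; r <- h$merge[i, 2]
    xl <- node_x(l); xr <- node_x(r)
    xpos[i] <- (xl + xr) / 2
    segs[[length(segs) + 1]] <- tibble(
      x = c(xl, xl, xr), xend = c(xl, xr, xr),
      y = c(node_y(l), ypos[i], ypos[i]),
      yend = c(ypos[i], ypos[i], node_y(r)))
  }
  leaves <- tibble(x = seq_len(n),
                   label = object$labels[h$order])
  ggplot(dplyr::bind_rows(segs)) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = leaves, aes(.data$x, -0.02 * max(ypos),
                                 label = .data$label), size = 3) +
    labs(x = NULL, y = sprintf("%s linkage distance", object$metric)) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid.major.x = element_blank())
}

#' Plot a standard-score ranking
#'
#' Bar chart of the combined score per sample, highest first.
#'
#' @param object A `uae_zscore` from [zscore_rank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_zscore <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      sample_id = stats::reorder(factor(.data$sample_id),
                                                 -.data$mean_score))
  ggplot(df, aes(.data$sample_id, .data$mean_score)) +
    geom_col(fill = "#2166ac") +
    labs(x = "sample", y = "combined score") +
    theme_minimal()
}

#' Plot a Pareto front
#'
#' Scatter of the front in two chosen objectives, shaded by a third when
#' available.
#'
#' @param object A `uae_pareto` from [ga_optimize()].
#' @param x,y Objective column names (defaults: the first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_pareto <- function(object, x = NULL, y = NULL, ...) {
  obj_cols <- setdiff(names(object), FACTOR_NAMES)
  x <- x %||% obj_cols[1]; y <- y %||% obj_cols[2]
  ggplot(as_tibble(object), aes(.data[[x]], .data[[y]])) +
    geom_point(colour = "#2166ac") +
    labs(x = x, y = y) +
    theme_minimal()
}

#' Plot predicted versus observed responses
#'
#' One panel per response with the identity line; tight scatter around the
#' line indicates a good surrogate fit.
#'
#' @param object A fitted `uae_mlp`.
#' @param design,responses The campaign the fit should be displayed on
#'   (defaults to the bundled campaign).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uae_mlp <- function(object, design = load_design(),
                             responses = load_responses(), ...) {
  obs <- response_matrix(responses, outputs = object$outputs)
  pred <- as.matrix(predict(object, design))
  df <- tibble(response = rep(object$outputs, each = nrow(obs)),
               observed = as.vector(obs), predicted = as.vector(pred),
               partition = rep(object$split %||% "all", length(object$outputs)))
  ggplot(df, aes(.data$observed, .data$predicted, colour = .data$partition)) +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    geom_point() +
    facet_wrap(~response, scales = "free") +
    theme_minimal()
}
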