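#' Bar chart of normalized LOCO preference estimates
#'
#' Mirrors the usual presentation of the model estimates: one panel per
#' reference (left-out) food, bars showing the min-max-normalized
#' utility contrasts of the remaining alternatives.
#'
#' @param loco A LOCO table ([loco_report()]).
#' @return A ggplot object.
#' @export
plot_preference_estimates <- function(loco) {
  dat <- normalize_estimates(loco)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$alternative, y = .data$normalized)
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~reference, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = NULL, y = "normalized estimate",
      title = paste0("Preference contrasts (",
                     unique(dat$stage), " set)")
    ) +
    ggplot2::theme_minimal()
}

#' Biplot of the descriptor PCA
#'
#' Observations on the first two components with the descriptor loading
#' vectors overlaid, optionally coloured by a grouping column (e.g.
#' zone).
#'
#' @param object A `descriptor_pca` ([pca_descriptors()]).
#' @param groups Optional vector (length = number of observations) used
#'   to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.descriptor_pca <- function(object, groups = NULL, ...) {
  sc <- as.data.frame(object$scores[, 1:2, drop = FALSE])
  names(sc) <- c("PC1", "PC2")
  if (!is.null(groups)) sc$group <- groups
  scale_f <- max(abs(sc$PC1), abs(sc$PC2)) * 0.8
  ld <- as.data.frame(object$loadings[, 1:2, drop = FALSE] * scale_f)
  names(ld) <- c("PC1", "PC2")
  ld$descriptor <- rownames(object$loadings)
  pct <- round(100 * object$proportion[1:2], 1)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.5)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6)
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1, yend = .data$PC2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "red3"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(label = .data$descriptor),
      colour = "red3", vjust = -0.5, size = 3
    ) +
    ggplot2::labs(
      x = paste0("PC1 (", pct[1], "%)"),
      y = paste0("PC2 (", pct[2], "%)")
    ) +
    ggplot2::theme_minimal()
}

#' Tile correlogram of the descriptor correlations
#'
#' @param corr Output of [corr_matrix()] (optionally `by_food`).
#' @return A ggplot object.
#' @export
plot_correlogram <- function(corr) {
  p <- ggplot2::ggplot(
    corr,
    ggplot2::aes(x = .data$var1, y = .data$var2, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if ("food" %in% names(corr)) p <- p + ggplot2::facet_wrap(~food)
  p
}

#' Plot the food-sharing networks
#'
#' Draws each per-food directed life-stage network with edge widths
#' proportional to the sharing-incident counts (base graphics, one panel
#' per food).
#'
#' @param networks A `stage_networks` ([build_networks()]).
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot_sharing_networks <- function(networks, ...) {
  stopifnot(inherits(networks, "stage_networks"))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(networks)))
  on.exit(graphics::par(old))
  for (f in names(networks)) {
    g <- networks[[f]]
    igraph::plot.igraph(
      g,
      main = f,
      edge.width = igraph::E(g)$weight,
      edge.curved = 0.2,
      layout = igraph::layout_in_circle(g),
      ...
    )
  }
  invisible(networks)
}
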