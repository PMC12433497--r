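#' Correlation heatmap
#'
#' Tile heatmap of a [correlation_matrix()], with non-significant pairs
#' crossed out. Requires ggplot2.
#'
#' @param cm A `correlation_matrix`.
#' @return A ggplot object.
#' @export
plot_correlations <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_correlations needs the ggplot2 package", call. = FALSE)
  }
  traits <- rownames(cm$r)
  df <- expand.grid(x = traits, y = traits, stringsAsFactors = FALSE)
  df$r <- as.vector(cm$r)
  df$masked <- as.vector(cm$mask)
  df$x <- factor(df$x, levels = traits)
  df$y <- factor(df$y, levels = rev(traits))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r), colour = "white") +
    ggplot2::geom_point(data = df[df$masked, ], shape = 4, size = 4,
                        colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  caption = sprintf("crosses: p >= %g", cm$alpha)) +
    ggplot2::theme_minimal()
}

#' Principal component biplot
#'
#' Scores of the first two dimensions with trait loading arrows, from a
#' [pca_summary()]. Requires ggplot2.
#'
#' @param pc A `pca_summary`.
#' @param dims Two dimensions to display (default 1:2).
#' @return A ggplot object.
#' @export
plot_pca <- function(pc, dims = 1:2) {
  stopifnot(inherits(pc, "pca_summary"), length(dims) == 2)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pca needs the ggplot2 package", call. = FALSE)
  }
  sc <- as.data.frame(pc$prcomp$x[, dims, drop = FALSE])
  names(sc) <- c("d1", "d2")
  ld <- as.data.frame(pc$loadings[, dims, drop = FALSE])
  names(ld) <- c("d1", "d2")
  ld$trait <- rownames(pc$loadings)
  mult <- max(abs(sc$d1), abs(sc$d2)) * 0.9
  labs <- sprintf("Dim %d (%.1f%%)", dims, pc$explained_variance[dims])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$d1, y = .data$d2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$d1 * mult,
                                       yend = .data$d2 * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "#B2182B") +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data$d1 * mult, y = .data$d2 * mult,
                                    label = .data$trait),
                       vjust = -0.5, size = 3, colour = "#B2182B") +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}
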