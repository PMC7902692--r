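#' Plot style for network figures
#'
#' @param layout_seed integer seed for the force-directed layout (identical
#'   seeds give identical coordinates).
#' @param community_palette ordered vector of community colors.
#' @param cna_subnet_color color for subnetwork members in CNA figures.
#' @param positive_color,negative_color edge colors for signed weights
#'   (green = positive, red = negative partial correlation).
#' @return a list of class `plot_style`.
#' @export
plot_style <- function(layout_seed = 42L,
                       community_palette = c("#e41a1c", "#377eb8", "#4daf4a",
                                             "#984ea3", "#ff7f00", "#ffff33",
                                             "#a65628", "#f781bf"),
                       cna_subnet_color = "grey60",
                       positive_color = "darkgreen",
                       negative_color = "red3") {
  structure(list(layout_seed = as.integer(layout_seed),
                 community_palette = community_palette,
                 cna_subnet_color = cna_subnet_color,
                 positive_color = positive_color,
                 negative_color = negative_color),
            class = "plot_style")
}

#' Correlation heatmap
#'
#' Symmetric color-coded correlation matrix with a diverging scale fixed to
#' `[-1, 1]` and the given label order (no implicit clustering), written as
#' an SVG file.
#'
#' @param correlation symmetric correlation matrix with dimnames.
#' @param path output SVG file.
#' @param label_order optional explicit label order.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(correlation, path, label_order = NULL) {
  labels <- colnames(correlation)
  if (!is.null(label_order)) {
    if (!setequal(label_order, labels))
      stop("label_order does not match the correlation matrix labels")
    correlation <- correlation[label_order, label_order]
  }
  breaks <- seq(-1, 1, length.out = 101)
  cols <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(100)
  grDevices::svg(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(correlation, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = breaks, color = cols, border_color = NA,
                     legend = TRUE)
  invisible(path)
}

#' Circular correlation globe
#'
#' Biomarkers are placed as color blocks on a circle; chords join pairs
#' with `|r| >= threshold`, with chord width proportional to `|r|` and
#' color giving the sign.
#'
#' @param correlation symmetric correlation matrix with dimnames.
#' @param path output SVG file.
#' @param threshold minimum absolute correlation for a chord (default 0.3).
#' @param style a [plot_style()].
#' @return `path`, invisibly.
#' @export
plot_circos <- function(correlation, path, threshold = 0.3,
                        style = plot_style()) {
  stopifnot(threshold >= 0, threshold <= 1)
  labels <- colnames(correlation)
  p <- length(labels)
  ang <- seq(0, 2 * pi, length.out = p + 1L)[seq_len(p)]
  x <- cos(ang); y <- sin(ang)
  grDevices::svg(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  block_cols <- grDevices::rainbow(p, s = 0.6)
  idx <- which(upper.tri(correlation), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- correlation[idx[k, 1L], idx[k, 2L]]
    if (abs(r) < threshold) next
    i <- idx[k, 1L]; j <- idx[k, 2L]
    # quadratic Bezier chord through the centre region
    tt <- seq(0, 1, length.out = 50)
    bx <- (1 - tt)^2 * x[i] + tt^2 * x[j]
    by <- (1 - tt)^2 * y[i] + tt^2 * y[j]
    graphics::lines(bx, by, lwd = 0.5 + 4 * abs(r),
                    col = if (r > 0) style$positive_color else style$negative_color)
  }
  graphics::points(x, y, pch = 15, cex = 2.2, col = block_cols)
  graphics::text(1.22 * x, 1.22 * y, labels, cex = 0.7,
                 srt = 0, xpd = NA)
  invisible(path)
}

#' Community-colored network diagram
#'
#' Force-directed (Fruchterman–Reingold) layout seeded by the style's
#' `layout_seed`; nodes are colored by community (white when unassigned),
#' or uniformly gray for subnetwork members in CNA mode. Weighted edges are
#' drawn with thickness proportional to `|weight|` and color giving the
#' sign (green positive, red negative).
#'
#' @param network a `sparse_network`.
#' @param path output SVG file.
#' @param partition optional `community_partition` for node colors.
#' @param style a [plot_style()].
#' @param cna_mode color all subnetwork (non-isolated) members gray and
#'   ignore community colors?
#' @return `path`, invisibly.
#' @export
plot_network <- function(network, path, partition = NULL,
                         style = plot_style(), cna_mode = FALSE) {
  g <- as_igraph(network)
  set.seed(style$layout_seed)
  lw <- if (network_is_weighted(network) && n_edges(network) > 0L)
    abs(network$edges$weight) + 1e-9 else NULL  # FR needs positive weights
  layout <- igraph::layout_with_fr(g, weights = lw)
  labels <- network$labels
  deg <- igraph::degree(g)
  cols <- rep("white", length(labels))
  if (cna_mode) {
    cols[deg > 0] <- style$cna_subnet_color
  } else if (!is.null(partition)) {
    asg <- partition$assignment[labels]
    pal <- style$community_palette
    has <- !is.na(asg)
    cols[has] <- pal[(asg[has] - 1L) %% length(pal) + 1L]
  }
  ew <- rep(1, n_edges(network))
  ecol <- rep("grey40", n_edges(network))
  if (network_is_weighted(network) && n_edges(network) > 0L) {
    w <- network$edges$weight
    ew <- 0.5 + 6 * abs(w)
    ecol <- ifelse(w > 0, style$positive_color, style$negative_color)
  }
  grDevices::svg(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  igraph::plot.igraph(g, layout = layout, vertex.color = cols,
                      vertex.size = 18, vertex.label.cex = 0.7,
                      vertex.label.color = "black",
                      edge.width = ew, edge.color = ecol)
  invisible(path)
}
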