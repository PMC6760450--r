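#' Dendrogram plot
#'
#' ggplot2 rendering of an `hclust` tree with leaves on the x axis in tree
#' order and merge height on y; an optional horizontal line marks the cut
#' distance.
#'
#' @param tree An `hclust` tree.
#' @param cut Optional cut height to draw.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, cut = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- list()
  xh <- function(ref) {
    if (ref < 0) c(leaf_x[-ref], 0) else c(node_x[ref], node_h[ref])
  }
  for (m in seq_len(nrow(tree$merge))) {
    a <- xh(tree$merge[m, 1]); b <- xh(tree$merge[m, 2])
    node_x[m] <- (a[1] + b[1]) / 2
    segs[[m]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_h[m], node_h[m]), yend = c(node_h[m], node_h[m], b[2]))
  }
  segs <- dplyr::bind_rows(segs)
  labels <- tree$labels %||% as.character(seq_len(n))
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = labels[tree$order],
                                guide = ggplot2::guide_axis(angle = 90)) +
    ggplot2::labs(x = NULL, y = "distance") +
    ggplot2::theme_minimal()
  if (!is.null(cut)) {
    p <- p + ggplot2::geom_hline(yintercept = cut, colour = "blue",
                                 linetype = "dashed")
  }
  p
}

#' @rdname plot_dendrogram
#' @param object A `cell_clustering` or `refl_clustering`.
#' @param ... Unused.
#' @method autoplot cell_clustering
#' @export
autoplot.cell_clustering <- function(object, ...) {
  plot_dendrogram(object$tree, cut = object$cut) +
    ggplot2::labs(title = sprintf("Unit-cell clustering (%s metric)",
                                  object$metric))
}

#' @rdname plot_dendrogram
#' @method autoplot refl_clustering
#' @export
autoplot.refl_clustering <- function(object, ...) {
  plot_dendrogram(object$tree, cut = object$cut) +
    ggplot2::labs(title = sprintf("Reflection clustering, cut %.2f (CC = %.2f)",
                                  object$cut,
                                  distance_to_cc(min(object$cut, 1))))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Six-panel lattice-parameter histogram plot
#'
#' Histograms of the six lattice parameters with the fitted normal curve
#' (scaled to the histogram area) and the fit window shaded.
#'
#' @param fits A [fit_cell_histograms()] result.
#' @return A ggplot object, facetted by parameter.
#' @export
plot_cell_histograms <- function(fits) {
  bars <- purrr::pmap_dfr(
    list(fits$parameter, fits$breaks, fits$counts),
    function(p, br, ct) {
      tibble::tibble(parameter = p, lo = br[-length(br)], hi = br[-1],
                     mid = (br[-1] + br[-length(br)]) / 2, count = ct)
    })
  curves <- purrr::pmap_dfr(
    list(fits$parameter, fits$breaks, fits$mean, fits$sigma,
         fits$n_in_window),
    function(p, br, mu, sg, n) {
      x <- seq(min(br), max(br), length.out = 200)
      binw <- mean(diff(br))
      y <- if (sg > 0) n * binw * stats::dnorm(x, mu, sg) else rep(NA, 200)
      tibble::tibble(parameter = p, x = x, y = y)
    })
  ord <- c("a", "b", "c", "alpha", "beta", "gamma")
  bars$parameter <- factor(bars$parameter, levels = ord)
  curves$parameter <- factor(curves$parameter, levels = ord)
  ggplot2::ggplot(bars) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = .data$count),
                       fill = "grey70", colour = "grey40",
                       linewidth = 0.1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red", na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "datasets") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cell_histograms
#' @param object A `cell_histogram_fit` table.
#' @param ... Unused.
#' @method autoplot cell_histogram_fit
#' @export
autoplot.cell_histogram_fit <- function(object, ...) {
  plot_cell_histograms(object)
}

save_figure <- function(plot, path, width = 8, height = 6) {
  grDevices::pdf(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
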