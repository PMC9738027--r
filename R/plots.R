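#' Plot methods
#'
#' `autoplot()` methods render the core objects with ggplot2: an
#' intensity as its rate curve, an NLK partition as the binding sites
#' coloured by cluster with the fitted cluster intensities overlaid,
#' and an NLH dendrogram as a segment tree whose y coordinates are the
#' display heights (each clade is drawn at its own merge's scaled
#' linkage; raw likelihood linkages need not be monotone).
#'
#' @param object the object to plot.
#' @param n_grid evaluation grid size for intensity curves.
#' @param ... unused.
#' @return a ggplot.
#' @name nhppclust-autoplot
NULL

intensity_curve <- function(intensity, n_grid = 401L, label = NULL) {
  grid <- seq(intensity$region[1], intensity$region[2], length.out = n_grid)
  tibble::tibble(position = grid, rate = intensity_at(intensity, grid),
                 curve = label %||% "intensity")
}

#' @rdname nhppclust-autoplot
#' @export
autoplot.nhpp_intensity <- function(object, n_grid = 401L, ...) {
  ggplot2::ggplot(intensity_curve(object, n_grid),
                  ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = "intensity λ(t)") +
    ggplot2::theme_minimal()
}

#' @rdname nhppclust-autoplot
#' @param sites optional sites tibble to draw under a partition's
#'   fitted intensities.
#' @export
autoplot.nlk_partition <- function(object, sites = NULL, n_grid = 401L, ...) {
  curves <- purrr::imap_dfr(object$intensities, function(intensity, ci) {
    dplyr::mutate(intensity_curve(intensity, n_grid), cluster = factor(ci))
  })
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$position, y = .data$rate,
                                            colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = "fitted intensity λ(t)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
  if (!is.null(sites)) {
    pts <- tibble::as_tibble(sites)
    pts$cluster <- factor(object$assignments[as.character(pts$tf)])
    p <- p + ggplot2::geom_rug(
      data = pts, ggplot2::aes(x = .data$position, colour = .data$cluster),
      inherit.aes = FALSE, alpha = 0.5)
  }
  p
}

# x position and subtree segments for each dendrogram node.
dendro_segments <- function(dend) {
  n <- length(dend$labels)
  leaf_x <- numeric(n)
  order <- integer(0)
  walk <- function(id) {
    if (id < 0) { order <<- c(order, -id); return(invisible()) }
    walk(dend$merge[id, 1]); walk(dend$merge[id, 2])
  }
  walk(nrow(dend$merge))
  leaf_x[order] <- seq_len(n)
  node_x <- function(id) {
    if (id < 0) leaf_x[-id] else mean(c(node_x(dend$merge[id, 1]),
                                        node_x(dend$merge[id, 2])))
  }
  node_h <- function(id) if (id < 0) 0 else dend$display_height[id]
  segs <- purrr::map_dfr(seq_len(nrow(dend$merge)), function(step) {
    a <- dend$merge[step, 1]; b <- dend$merge[step, 2]
    h <- dend$display_height[step]
    xa <- node_x(a); xb <- node_x(b)
    tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(node_h(a), node_h(b), h), yend = c(h, h, h))
  })
  list(segments = segs,
       leaves = tibble::tibble(x = leaf_x, label = dend$labels))
}

#' @rdname nhppclust-autoplot
#' @export
autoplot.nlh_dendrogram <- function(object, ...) {
  parts <- dendro_segments(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = parts$segments,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = parts$leaves,
                       ggplot2::aes(x = .data$x, y = -0.2, label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous("likelihood linkage (scaled to [1, 10])") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank())
}

#' Plot an AMCR-vs-parameter tuning curve
#'
#' Renders the `curve` component of [optimal_grid_search()].
#'
#' @param curve tibble with columns `param` and `amcr`.
#' @return a ggplot.
#' @export
plot_grid_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$param, y = .data$amcr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "tuning parameter", y = "AMCR") +
    ggplot2::theme_minimal()
}
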