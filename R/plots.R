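#' Plot a signed interaction network
#'
#' Circular layout with nodes ordered as in the universe; positive links are
#' drawn blue, negative links red, with line width proportional to absolute
#' strength — the conventional rendering of signed co-occurrence graphs.
#'
#' @param object An `interaction_network`.
#' @param label_nodes Label connected nodes with their OTU ids (default TRUE
#'   for networks of up to 80 nodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_network <- function(object,
                                         label_nodes = length(object$nodes) <= 80,
                                         ...) {
  n <- length(object$nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- tibble::tibble(otu_id = object$nodes, x = cos(theta), y = sin(theta),
                        connected = object$nodes %in%
                          c(object$links$from, object$links$to))
  edges <- object$links |>
    dplyr::left_join(dplyr::rename(pos[1:3], from = "otu_id",
                                   x0 = "x", y0 = "y"), by = "from") |>
    dplyr::left_join(dplyr::rename(pos[1:3], to = "otu_id",
                                   x1 = "x", y1 = "y"), by = "to")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign,
                   linewidth = abs(.data$strength)),
      alpha = 0.8) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     alpha = .data$connected), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166ac", negative = "#b2182b")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, title = object$stage)
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = pos[pos$connected, ],
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                   label = .data$otu_id), size = 2.6)
  }
  p
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param grouping Optional per-sample labels used for colour.
#' @param axes Which two axes to draw (default first two).
#' @param ... Unused.
#' @return A ggplot object with percent variation on the axis labels.
#' @export
autoplot.pcoa_result <- function(object, grouping = NULL, axes = c(1, 2), ...) {
  if (ncol(object$coordinates) < max(axes)) {
    stop("not enough positive axes to plot", call. = FALSE)
  }
  df <- tibble::as_tibble(object$coordinates[, axes, drop = FALSE],
                          rownames = "sample_id")
  names(df)[2:3] <- c("a1", "a2")
  if (!is.null(grouping)) df$group <- as.factor(grouping)
  lab <- sprintf("PCo%d (%.1f%%)", axes, 100 * object$explained[axes])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a1, y = .data$a2)) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (is.null(grouping)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::labs(colour = NULL)
  }
}

#' Degree-distribution plot of a network
#'
#' @param network An `interaction_network`.
#' @return A ggplot bar chart of node degrees split by role.
#' @export
plot_degree_distribution <- function(network) {
  roles <- classify_roles(network)
  ggplot2::ggplot(roles,
                  ggplot2::aes(x = .data$degree, fill = .data$role)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "degree", y = "nodes", fill = NULL) +
    ggplot2::theme_minimal()
}
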