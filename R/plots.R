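#' Plot expected rarefaction curves
#'
#' @param curves tibble from [rarefaction_curve()].
#' @return a ggplot.
#' @export
plot_rarefaction <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$depth, .data$expected_richness,
                                       colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads subsampled", y = "expected OTU richness",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn richness_by_group boxplot of richness by group with LSD
#'   letters when available.
#' @param object a `richness_test`.
#' @export
autoplot.richness_test <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$observed_richness)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "observed OTU richness") +
    ggplot2::theme_minimal()
  if (!is.null(object$letters)) {
    lab <- dplyr::mutate(object$letters,
                         y = max(df$observed_richness) * 1.05)
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(.data$group, .data$y,
                                             label = .data$letters))
  }
  p
}

#' @describeIn partition_processes stacked bar of process fractions.
#' @param object a `process_partition`.
#' @export
autoplot.process_partition <- function(object, ...) {
  df <- dplyr::filter(object$summary, .data$n_pairs > 0 | TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = "all pairs", y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_samples dendrogram with SIMPROF-supported groups.
#' @param object a `sample_clustering`.
#' @export
autoplot.sample_clustering <- function(object, ...) {
  hc <- object$hclust
  seg <- dendro_segments(hc)
  leaves <- tibble(x = seq_along(hc$order),
                   label = hc$labels[hc$order])
  leaves <- dplyr::left_join(leaves, object$groups,
                             by = c(label = "sample_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(.data$x, -0.02 * max(seg$y), label = .data$label,
                                    colour = factor(.data$group)),
                       angle = 90, hjust = 1, size = 2.8) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "Aitchison distance", colour = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# segments of an hclust dendrogram in leaf order
dendro_segments <- function(hc) {
  pos <- order(hc$order)          # leaf -> x position
  n <- nrow(hc$merge)
  xc <- numeric(n)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    xs <- vapply(kids, function(k) if (k < 0) pos[-k] else xc[k], numeric(1))
    ys <- vapply(kids, function(k) if (k < 0) 0 else hc$height[k], numeric(1))
    h <- hc$height[i]
    xc[i] <- mean(xs)
    segs[[i]] <- tibble(
      x = c(xs[1], xs[2], xs[1]), y = c(ys[1], ys[2], h),
      xend = c(xs[1], xs[2], xs[2]), yend = c(h, h, h))
  }
  dplyr::bind_rows(segs)
}

#' Plot a sample proportionality network
#'
#' Fruchterman-Reingold layout (seeded), edges weighted by 1 - phi, nodes
#' coloured by a metadata attribute when present.
#'
#' @param g igraph network from [build_network()].
#' @param colour_by vertex attribute for node colour (e.g. `"layer"`).
#' @param seed layout seed.
#' @return a ggplot.
#' @export
plot_network <- function(g, colour_by = "layer", seed = 1) {
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  nodes <- tibble(x = xy[, 1], y = xy[, 2], name = igraph::V(g)$name)
  if (colour_by %in% igraph::vertex_attr_names(g))
    nodes$colour <- igraph::vertex_attr(g, colour_by)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(x = xy[el[, 1], 1], y = xy[el[, 1], 2],
                  xend = xy[el[, 2], 1], yend = xy[el[, 2], 2],
                  weight = if (nrow(el)) igraph::E(g)$weight else numeric(0))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::theme_void()
  if ("colour" %in% names(nodes))
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(.data$x, .data$y,
                                         colour = .data$colour), size = 3) +
      ggplot2::labs(colour = colour_by)
  else
    p + ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                            size = 3)
}
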