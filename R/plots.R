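# ggplot2 presentation layer: autoplot()/plot_*() for the main result
# types, plus broom-style tidiers.

#' @export
tidy.sketch_map <- function(x, ...) {
  xy <- x$landmark_xy
  tibble(id = x$landmark_ids, x = xy[, 1], y = xy[, 2])
}

#' @export
glance.sketch_map <- function(x, ...) {
  tibble(label = x$label, sigma = x$params$sigma,
         n_landmarks = length(x$landmark_ids),
         final_stress = x$final_stress)
}

#' Plot a sketch-map model
#'
#' Landmark scatter in map coordinates.
#'
#' @param object A `"sketch_map"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sketch_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("sketch-map %s", object$label),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an embedding tibble
#'
#' @param embedding Tibble with `x`, `y` and optional property columns
#'   (as returned by [sketchmap()] or read from `embedding.tsv`).
#' @param color Optional column name to color by (e.g. `"energy"`).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, color = NULL) {
  g <- ggplot2::ggplot(embedding, ggplot2::aes(x = .data$x, y = .data$y))
  g <- if (is.null(color)) {
    g + ggplot2::geom_point(alpha = 0.8)
  } else {
    g + ggplot2::geom_point(ggplot2::aes(color = .data[[color]]), alpha = 0.8) +
      ggplot2::scale_color_viridis_c(name = color)
  }
  g + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a cluster tree as a dendrogram
#'
#' Segment-based dendrogram with an optional cut line; heights are the RMS
#' linkage distances.  Below `truncate_below` the merge structure is hidden
#' and cluster extents are drawn as horizontal bars, which keeps large
#' trees readable.
#'
#' @param object A `"cluster_tree"`.
#' @param cut_height Optional horizontal cut line.
#' @param truncate_below Hide merges below this height (default `0`, no
#'   truncation).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_tree <- function(object, cut_height = NULL,
                                  truncate_below = 0, ...) {
  hc <- as.hclust(object)
  n <- length(hc$labels)
  xpos <- numeric(n + nrow(object$merges))   # leaf i -> i, merge k -> n + k
  xpos[hc$order] <- seq_len(n)
  node_x <- function(node) if (node < 0) xpos[-node] else xpos[n + node]
  node_h <- function(node) if (node < 0) 0 else object$merges$delta[node]
  segs <- list()
  for (k in seq_len(nrow(object$merges))) {
    a <- object$merges$node_a[k]; b <- object$merges$node_b[k]
    xa <- node_x(a); xb <- node_x(b)
    ha <- max(node_h(a), truncate_below)
    hb <- max(node_h(b), truncate_below)
    h <- object$merges$delta[k]
    xpos[n + k] <- (xa + xb) / 2
    segs[[k]] <- tibble(
      x = c(xa, xb, min(xa, xb)), xend = c(xa, xb, max(xa, xb)),
      y = c(ha, hb, h), yend = c(h, h, h)
    )
  }
  segs <- dplyr::bind_rows(segs)
  segs <- segs[segs$yend >= truncate_below, , drop = FALSE]
  g <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "linkage distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(cut_height)) {
    g <- g + ggplot2::geom_hline(yintercept = cut_height,
                                 linetype = "dashed", color = "grey40")
  }
  g
}

#' Consistency-screen scatter
#'
#' `sigma_E` against `sigma_D` per cluster on log scales, flagged clusters
#' highlighted — the visual form of the structure/property consistency
#' check.
#'
#' @param screen Output of [consistency_screen()].
#' @return A ggplot.
#' @export
plot_consistency <- function(screen) {
  df <- screen[!is.na(screen$sigma_D) & !is.na(screen$sigma_E), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_D, y = .data$sigma_E,
                                   color = .data$flagged,
                                   size = .data$size)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "darkorange")) +
    ggplot2::labs(x = expression(sigma[D]), y = expression(sigma[E])) +
    ggplot2::theme_minimal()
}
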