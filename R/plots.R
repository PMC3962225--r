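# ggplot2 views of the result types. These are analysis graphics (target
# count distributions, matrix heat views, network sketches), not publication
# layout engines; network drawing uses a deterministic force-directed layout.

#' Plot a target-count distribution
#'
#' Bar chart of the number of compounds per target count.
#'
#' @param object A `promiscuity_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promiscuity_summary
#' @export
autoplot.promiscuity_summary <- function(object, ...) {
  ggplot2::ggplot(object$distribution,
                  ggplot2::aes(x = .data$target_count, y = .data$n_compounds)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "targets per compound (T)", y = "compounds",
                  title = sprintf(
                    "Promiscuity rate %.2f over %d multi-target compounds",
                    object$rate, object$n_multi_target)) +
    ggplot2::theme_minimal()
}

#' Plot a Compound Series Matrix
#'
#' Tile view of the matrix: rows are cores, columns substituents; real cells
#' are shaded by target count (the promiscuity color coding), virtual cells
#' are left hollow.
#'
#' @param object A `csm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csm
#' @export
autoplot.csm <- function(object, ...) {
  cells <- object$cells
  cells$core <- factor(cells$core, levels = rev(object$rows))
  cells$substituent <- factor(cells$substituent, levels = object$columns)
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$substituent, y = .data$core)) +
    ggplot2::geom_tile(data = cells[cells$status == "virtual", ],
                       fill = "white", colour = "grey60", linetype = "dashed") +
    ggplot2::geom_tile(data = cells[cells$status == "real", ],
                       ggplot2::aes(fill = .data$target_count),
                       colour = "grey30") +
    ggplot2::scale_fill_gradient(low = "lightblue", high = "darkblue",
                                 name = "targets") +
    ggplot2::labs(x = "substituent", y = "core") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# shared layout helper for the two unipartite network classes
network_layout <- function(g, seed = 42) {
  withr::with_seed(seed, igraph::layout_with_fr(g))
}

#' Plot a promiscuity-cliff network
#'
#' Nodes are compounds shaded by target count (black = inactive through
#' white = most promiscuous); edges are cliffs; hubs are emphasised.
#'
#' @param object A `cliff_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cliff_network
#' @export
autoplot.cliff_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty cliff network"))
  }
  xy <- network_layout(object$graph)
  ids <- igraph::V(object$graph)$name
  nodes <- object$nodes[match(ids, object$nodes$compound_id), ]
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  el <- igraph::as_edgelist(object$graph)
  segs <- tibble::tibble(x = nodes$x[match(el[, 1], ids)],
                         y = nodes$y[match(el[, 1], ids)],
                         xend = nodes$x[match(el[, 2], ids)],
                         yend = nodes$y[match(el[, 2], ids)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$target_count,
                                     size = .data$is_hub),
                        shape = 21, colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "targets") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 3, `TRUE` = 5),
                               name = "hub") +
    ggplot2::theme_void()
}

#' Plot a target co-activity network
#'
#' Nodes are targets coloured by family; edges connect targets sharing at
#' least the configured number of compounds.
#'
#' @param object A `target_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot target_network
#' @export
autoplot.target_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty target network"))
  }
  xy <- network_layout(object$graph)
  ids <- igraph::V(object$graph)$name
  nodes <- object$nodes[match(ids, object$nodes$target_id), ]
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  el <- igraph::as_edgelist(object$graph)
  segs <- tibble::tibble(x = nodes$x[match(el[, 1], ids)],
                         y = nodes$y[match(el[, 1], ids)],
                         xend = nodes$x[match(el[, 2], ids)],
                         yend = nodes$y[match(el[, 2], ids)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$family), size = 3) +
    ggplot2::theme_void()
}

#' Plot promiscuity rates across molecular-weight bins
#'
#' @param mw_summary Tibble from [summarize_by_mw()].
#' @return A ggplot object.
#' @export
plot_mw_rates <- function(mw_summary) {
  ggplot2::ggplot(mw_summary,
                  ggplot2::aes(x = .data$bin, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "molecular weight bin (Da)",
                  y = "promiscuity rate (mean T | T >= 2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
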