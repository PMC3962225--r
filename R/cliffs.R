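# Promiscuity cliffs: MMPs whose compounds differ strongly in target count,
# and the compound-level cliff network with hub identification.

#' Detect promiscuity cliffs
#'
#' A promiscuity cliff is an MMP whose two compounds differ in target count
#' by at least `delta_threshold` (inclusive, "50 or more" by default): a
#' small structural change coupled to a large-magnitude change in
#' promiscuity.
#'
#' @param mmps MMP tibble from [generate_mmps()].
#' @param profiles Profile tibble with `compound_id` and `target_count`
#'   covering every MMP compound (T = 0 allowed for inactives).
#' @param delta_threshold Minimum absolute target-count difference.
#' @return Tibble of cliffs: MMP columns plus `t_a`, `t_b`, `delta`, and the
#'   `transformation` oriented from the less to the more promiscuous
#'   compound.
#' @export
find_cliffs <- function(mmps, profiles, delta_threshold = 50) {
  stopifnot(is.data.frame(mmps), delta_threshold >= 0)
  lookup <- stats::setNames(profiles$target_count, profiles$compound_id)
  missing <- setdiff(unique(c(mmps$compound_a, mmps$compound_b)), names(lookup))
  if (length(missing) > 0) {
    rlang::abort(paste0("no target profile for compound '", missing[1], "'"),
                 class = "csmtools_input_error")
  }
  t_a <- unname(lookup[mmps$compound_a])
  t_b <- unname(lookup[mmps$compound_b])
  res <- tibble::as_tibble(mmps)
  res$t_a <- as.integer(t_a)
  res$t_b <- as.integer(t_b)
  res$delta <- abs(res$t_a - res$t_b)
  res <- res[res$delta >= delta_threshold, ]
  # orient low-promiscuity side first for transformation accounting
  swap <- res$t_a > res$t_b
  orient <- function(a, b) ifelse(swap, b, a)
  res <- dplyr::mutate(res,
    compound_low = orient(.data$compound_a, .data$compound_b),
    compound_high = orient(.data$compound_b, .data$compound_a),
    substituent_low = orient(.data$substituent_a, .data$substituent_b),
    substituent_high = orient(.data$substituent_b, .data$substituent_a),
    t_low = pmin(.data$t_a, .data$t_b),
    t_high = pmax(.data$t_a, .data$t_b)
  )
  res$transformation <- paste0(res$substituent_low, ">>", res$substituent_high)
  res
}

#' Build the promiscuity-cliff network
#'
#' Nodes are the compounds appearing in at least one cliff (annotated with
#' their target counts, the quantity mapped to a color spectrum when the
#' network is rendered), edges are the cliffs, and hubs are compounds
#' involved in multiple cliffs (degree >= 2).
#'
#' @param cliffs Cliff tibble from [find_cliffs()].
#' @param profiles Optional profile tibble; target counts default to the
#'   `t_a`/`t_b` columns of `cliffs`.
#' @return A `cliff_network`: list with `graph` (igraph), `nodes`
#'   (`compound_id`, `target_count`, `degree`, `is_hub`), `edges` and `hubs`.
#' @export
build_cliff_network <- function(cliffs, profiles = NULL) {
  stopifnot(is.data.frame(cliffs))
  if (nrow(cliffs) == 0) {
    nodes <- tibble::tibble(compound_id = character(0), target_count = integer(0),
                            degree = integer(0), is_hub = logical(0))
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g, nodes = nodes,
                          edges = tibble::as_tibble(cliffs), hubs = character(0)),
                     class = "cliff_network"))
  }
  t_map <- c(stats::setNames(cliffs$t_a, cliffs$compound_a),
             stats::setNames(cliffs$t_b, cliffs$compound_b))
  if (!is.null(profiles)) {
    t_map <- stats::setNames(profiles$target_count, profiles$compound_id)
  }
  ids <- lex_sort(unique(c(cliffs$compound_a, cliffs$compound_b)))
  g <- igraph::graph_from_data_frame(
    cliffs[, c("compound_a", "compound_b")],
    directed = FALSE,
    vertices = data.frame(name = ids, target_count = unname(t_map[ids]))
  )
  deg <- igraph::degree(g)
  nodes <- tibble::tibble(compound_id = ids,
                          target_count = as.integer(unname(t_map[ids])),
                          degree = as.integer(deg[ids]),
                          is_hub = unname(deg[ids]) >= 2)
  structure(list(graph = g, nodes = nodes, edges = tibble::as_tibble(cliffs),
                 hubs = nodes$compound_id[nodes$is_hub]),
            class = "cliff_network")
}

#' @export
print.cliff_network <- function(x, ...) {
  cat("Promiscuity-cliff network: ", nrow(x$nodes), " compounds, ",
      nrow(x$edges), " cliffs, ", length(x$hubs), " hub(s)\n", sep = "")
  invisible(x)
}

#' @rdname build_cliff_network
#' @param x A `cliff_network`.
#' @param ... Unused.
#' @method tidy cliff_network
#' @export
tidy.cliff_network <- function(x, ...) x$nodes

#' @rdname build_cliff_network
#' @method glance cliff_network
#' @export
glance.cliff_network <- function(x, ...) {
  tibble::tibble(n_compounds = nrow(x$nodes), n_cliffs = nrow(x$edges),
                 n_hubs = length(x$hubs),
                 max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else 0L)
}

#' Frequency of chemical transformations across cliffs
#'
#' Counts each transformation oriented from the less to the more promiscuous
#' compound, the bookkeeping behind asking whether any transformation
#' consistently introduces promiscuity cliffs.
#'
#' @param cliffs Cliff tibble from [find_cliffs()].
#' @return Tibble `substituent_low`, `substituent_high`, `transformation`,
#'   `n`, sorted by decreasing count.
#' @export
transformation_frequency <- function(cliffs) {
  if (nrow(cliffs) == 0) {
    return(tibble::tibble(substituent_low = character(0),
                          substituent_high = character(0),
                          transformation = character(0), n = integer(0)))
  }
  res <- dplyr::count(cliffs, .data$substituent_low, .data$substituent_high,
                      .data$transformation, name = "n")
  res[order(-res$n, res$transformation, method = "radix"), ]
}
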