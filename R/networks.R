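# Ligand-based target networks: the shared-compound target co-activity
# network (edge when two targets share at least a minimum number of
# compounds, classified into intra- and inter-family pairs) and the
# compound-target bipartite network with its compound degree distribution.

#' Build the shared-compound target co-activity network
#'
#' For every unordered target pair the number of compounds active against
#' both is counted; pairs sharing at least `min_shared` compounds become
#' edges. Targets not incident to any qualifying edge are excluded from the
#' node set (the network reports targets involved in pairs). Edges are
#' classified as intra-family (both targets from the same family) or
#' inter-family.
#'
#' @param profiles Profile tibble with a `targets` list-column
#'   ([build_profiles()]).
#' @param target_families Mapping target -> family (tibble `target_id`,
#'   `family`, or named character vector). Targets missing from the map are
#'   classified as `"other"` with a warning.
#' @param min_shared Minimum number of shared compounds for an edge.
#' @return A `target_network`: list with `graph` (igraph), `nodes`
#'   (`target_id`, `family`), `edges` (`target_a`, `target_b`,
#'   `shared_compounds`, `intra_family`), `n_intra_family`, `n_inter_family`.
#' @export
build_target_network <- function(profiles, target_families, min_shared = 5) {
  stopifnot(min_shared >= 1)
  fam <- as_family_table(target_families)
  pairs <- shared_compound_counts(profiles)
  edges <- pairs[pairs$shared_compounds >= min_shared, , drop = FALSE]
  all_targets <- unique(c(edges$target_a, edges$target_b))
  unmapped <- setdiff(all_targets, fam$target_id)
  if (length(unmapped) > 0) {
    rlang::warn(paste0(length(unmapped), " target(s) missing a family label, ",
                       "classified as 'other': ",
                       paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  fam_of <- function(t) {
    f <- fam$family[match(t, fam$target_id)]
    ifelse(is.na(f), "other", f)
  }
  edges$intra_family <- fam_of(edges$target_a) == fam_of(edges$target_b)
  nodes <- tibble::tibble(target_id = lex_sort(all_targets))
  nodes$family <- fam_of(nodes$target_id)
  g <- if (nrow(nodes) > 0) {
    igraph::graph_from_data_frame(
      data.frame(from = edges$target_a, to = edges$target_b,
                 shared_compounds = edges$shared_compounds),
      directed = FALSE,
      vertices = data.frame(name = nodes$target_id, family = nodes$family)
    )
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  structure(list(graph = g, nodes = nodes, edges = tibble::as_tibble(edges),
                 n_intra_family = sum(edges$intra_family),
                 n_inter_family = sum(!edges$intra_family),
                 min_shared = min_shared),
            class = "target_network")
}

# Pairwise shared-compound counts via the compound x target incidence
# crossproduct. Returns all pairs with at least one shared compound.
shared_compound_counts <- function(profiles) {
  targets <- lex_sort(unique(unlist(profiles$targets)))
  if (length(targets) < 2) {
    return(tibble::tibble(target_a = character(0), target_b = character(0),
                          shared_compounds = integer(0)))
  }
  inc <- matrix(0L, nrow(profiles), length(targets),
                dimnames = list(NULL, targets))
  for (i in seq_len(nrow(profiles))) {
    inc[i, match(profiles$targets[[i]], targets)] <- 1L
  }
  ct <- crossprod(inc)
  ut <- which(upper.tri(ct) & ct >= 1, arr.ind = TRUE)
  tibble::tibble(target_a = targets[ut[, 1]],
                 target_b = targets[ut[, 2]],
                 shared_compounds = as.integer(ct[ut]))
}

#' @export
print.target_network <- function(x, ...) {
  cat("Target co-activity network (>= ", x$min_shared, " shared compounds): ",
      nrow(x$nodes), " targets, ", nrow(x$edges), " pairs (",
      x$n_intra_family, " intra-family, ", x$n_inter_family,
      " inter-family)\n", sep = "")
  invisible(x)
}

#' @rdname build_target_network
#' @param x A `target_network`.
#' @param ... Unused.
#' @method tidy target_network
#' @export
tidy.target_network <- function(x, ...) x$edges

#' @rdname build_target_network
#' @method glance target_network
#' @export
glance.target_network <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$nodes), n_pairs = nrow(x$edges),
                 n_intra_family = x$n_intra_family,
                 n_inter_family = x$n_inter_family,
                 min_shared = x$min_shared)
}

#' Build a compound-target bipartite network
#'
#' Nodes are compounds and targets; edges are the known compound-target
#' interactions. Duplicate interaction rows are deduplicated and their count
#' reported. The degree distribution of compound nodes (how many targets each
#' compound is active against) is attached.
#'
#' @param interactions Data frame with columns `compound_id` and `target_id`.
#' @return A `bipartite_network`: list with `graph` (igraph, `type` marks the
#'   target side), `compound_nodes`, `target_nodes`, `edges`,
#'   `degree_distribution` (tibble `degree`, `n_compounds`),
#'   `n_duplicates_removed`.
#' @export
build_bipartite_network <- function(interactions) {
  stopifnot(is.data.frame(interactions),
            all(c("compound_id", "target_id") %in% names(interactions)))
  inter <- tibble::as_tibble(interactions[, c("compound_id", "target_id")])
  n_before <- nrow(inter)
  inter <- dplyr::distinct(inter)
  n_dup <- n_before - nrow(inter)
  if (n_dup > 0) {
    rlang::inform(paste0(n_dup, " duplicate interaction row(s) removed"))
  }
  compounds <- lex_sort(unique(inter$compound_id))
  targets <- lex_sort(unique(inter$target_id))
  overlap <- intersect(compounds, targets)
  if (length(overlap) > 0) {
    rlang::abort(paste0("identifier used on both sides of the bipartite network: ",
                        overlap[1]),
                 class = "csmtools_input_error")
  }
  g <- if (nrow(inter) > 0) {
    gg <- igraph::graph_from_data_frame(
      inter, directed = FALSE,
      vertices = data.frame(name = c(compounds, targets),
                            type = c(rep(FALSE, length(compounds)),
                                     rep(TRUE, length(targets))))
    )
    gg
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  deg <- if (length(compounds) > 0) {
    tab <- table(factor(inter$compound_id, levels = compounds))
    dplyr::count(tibble::tibble(degree = as.integer(tab)), .data$degree,
                 name = "n_compounds")
  } else {
    tibble::tibble(degree = integer(0), n_compounds = integer(0))
  }
  structure(list(graph = g,
                 compound_nodes = compounds,
                 target_nodes = targets,
                 edges = inter,
                 degree_distribution = deg,
                 n_duplicates_removed = n_dup),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite compound-target network: ", length(x$compound_nodes),
      " compounds, ", length(x$target_nodes), " targets, ",
      nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

#' @rdname build_bipartite_network
#' @param x A `bipartite_network`.
#' @param ... Unused.
#' @method tidy bipartite_network
#' @export
tidy.bipartite_network <- function(x, ...) x$degree_distribution

#' @rdname build_bipartite_network
#' @method glance bipartite_network
#' @export
glance.bipartite_network <- function(x, ...) {
  tibble::tibble(n_compounds = length(x$compound_nodes),
                 n_targets = length(x$target_nodes),
                 n_interactions = nrow(x$edges),
                 n_duplicates_removed = x$n_duplicates_removed)
}
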