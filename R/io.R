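# Artifact serialization. Every writer has a matching reader that restores
# the in-memory object, so downstream tooling can re-load any artifact
# without recomputation; wide-matrix CSVs are presentation views and restore
# the structural fields only.

#' Write/read activity records
#'
#' Long-CSV serialization of activity-record tibbles, matching the input
#' dialect of [read_activity_table()].
#'
#' @param records Activity-record tibble.
#' @param path Output path.
#' @return `write_activity_table()` returns `path` invisibly.
#' @export
write_activity_table <- function(records, path) {
  out <- tibble::tibble(
    compound_id = records$compound_id,
    smiles = records$smiles,
    target_id = records$target_id,
    target_family = records$target_family,
    measurement_type = records$measurement_type,
    relation = ifelse(is.na(records$relation), "", records$relation),
    value_nM = records$value_nm
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a binary activity matrix
#'
#' @param mat A `binary_matrix` tibble.
#' @param path Output path.
#' @export
write_binary_matrix <- function(mat, path) {
  readr::write_csv(tibble::as_tibble(mat), path)
  invisible(path)
}

#' Write/read MMP tables
#'
#' CSV with columns `compound_a,compound_b,core,substituent_a,substituent_b`;
#' the reader restores the derived `core_heavy_atoms` and `transformation`
#' columns.
#'
#' @param mmps MMP tibble from [generate_mmps()].
#' @param path File path.
#' @export
write_mmps <- function(mmps, path) {
  readr::write_csv(mmps[, c("compound_a", "compound_b", "core",
                            "substituent_a", "substituent_b")], path)
  invisible(path)
}

#' @rdname write_mmps
#' @export
read_mmps <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  needed <- c("compound_a", "compound_b", "core", "substituent_a", "substituent_b")
  stopifnot(all(needed %in% names(df)))
  res <- tibble::as_tibble(df[, needed])
  sizes <- fragment_heavy_atoms(unique(res$core))
  res$core_heavy_atoms <- as.integer(sizes[res$core])
  res$transformation <- paste0(res$substituent_a, ">>", res$substituent_b)
  res
}

#' Write/read promiscuity-cliff tables
#'
#' CSV with columns
#' `compound_a,compound_b,t_a,t_b,delta,core,substituent_a,substituent_b`;
#' the reader restores the low/high orientation and transformation columns.
#'
#' @param cliffs Cliff tibble from [find_cliffs()].
#' @param path File path.
#' @export
write_cliffs <- function(cliffs, path) {
  readr::write_csv(cliffs[, c("compound_a", "compound_b", "t_a", "t_b",
                              "delta", "core", "substituent_a",
                              "substituent_b")], path)
  invisible(path)
}

#' @rdname write_cliffs
#' @export
read_cliffs <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t_a = readr::col_integer(), t_b = readr::col_integer(),
    delta = readr::col_integer(), .default = readr::col_character()),
    progress = FALSE)
  res <- tibble::as_tibble(df)
  swap <- res$t_a > res$t_b
  orient <- function(a, b) ifelse(swap, b, a)
  res$compound_low <- orient(res$compound_a, res$compound_b)
  res$compound_high <- orient(res$compound_b, res$compound_a)
  res$substituent_low <- orient(res$substituent_a, res$substituent_b)
  res$substituent_high <- orient(res$substituent_b, res$substituent_a)
  res$t_low <- pmin(res$t_a, res$t_b)
  res$t_high <- pmax(res$t_a, res$t_b)
  res$transformation <- paste0(res$substituent_low, ">>", res$substituent_high)
  res
}

#' Write/read a promiscuity summary as JSON
#'
#' @param summary A `promiscuity_summary`.
#' @param path File path.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "promiscuity_summary"))
  jsonlite::write_json(list(
    n_compounds_total = summary$n_compounds_total,
    n_multi_target = summary$n_multi_target,
    rate = summary$rate,
    p_at_least_2 = summary$p_at_least_2,
    p_more_than_5 = summary$p_more_than_5,
    distribution = summary$distribution
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dist <- tibble::as_tibble(x$distribution)
  dist$target_count <- as.integer(dist$target_count)
  dist$n_compounds <- as.integer(dist$n_compounds)
  structure(list(
    n_compounds_total = as.integer(x$n_compounds_total),
    n_multi_target = as.integer(x$n_multi_target),
    rate = if (is.null(x$rate)) NA_real_ else as.numeric(x$rate),
    p_at_least_2 = as.numeric(x$p_at_least_2),
    p_more_than_5 = as.numeric(x$p_more_than_5),
    distribution = dist
  ), class = "promiscuity_summary")
}

#' Write a target-count distribution as CSV
#'
#' Two columns, `target_count` and `n_compounds`.
#'
#' @param summary A `promiscuity_summary`.
#' @param path File path.
#' @export
write_distribution_csv <- function(summary, path) {
  readr::write_csv(summary$distribution, path)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    target_count = readr::col_integer(), n_compounds = readr::col_integer()),
    progress = FALSE)
}

#' Write/read a CSM as JSON
#'
#' Serializes rows, columns, the full cell table (`compound_id`,
#' `target_count`, `status`, plus structures and per-cell target sets) and
#' the core-level MMPs of the matrix.
#'
#' @param csm A `csm` object.
#' @param path File path.
#' @export
write_csm_json <- function(csm, path) {
  stopifnot(inherits(csm, "csm"))
  cells <- csm$cells
  jsonlite::write_json(list(
    rows = csm$rows,
    columns = csm$columns,
    cells = lapply(seq_len(nrow(cells)), function(i) {
      list(core = cells$core[i], substituent = cells$substituent[i],
           status = cells$status[i],
           compound_id = cells$compound_id[i],
           smiles = cells$smiles[i],
           target_count = cells$target_count[i],
           targets = as.list(cells$targets[[i]]))
    }),
    core_mmps = csm$core_mmps
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_csm_json
#' @export
read_csm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr1 <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  int1 <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  cells <- tibble::tibble(
    core = vapply(x$cells, function(c) chr1(c$core), character(1)),
    substituent = vapply(x$cells, function(c) chr1(c$substituent), character(1)),
    compound_id = vapply(x$cells, function(c) chr1(c$compound_id), character(1)),
    smiles = vapply(x$cells, function(c) chr1(c$smiles), character(1)),
    status = vapply(x$cells, function(c) chr1(c$status), character(1)),
    target_count = vapply(x$cells, function(c) int1(c$target_count), integer(1)),
    targets = lapply(x$cells, function(c) as.character(unlist(c$targets)))
  )
  cm <- x$core_mmps
  core_mmps <- if (length(cm) == 0) {
    tibble::tibble(core_a = character(0), core_b = character(0),
                   shared_core = character(0), substituent_a = character(0),
                   substituent_b = character(0), transformation = character(0))
  } else {
    tibble::tibble(
      core_a = vapply(cm, function(r) chr1(r$core_a), character(1)),
      core_b = vapply(cm, function(r) chr1(r$core_b), character(1)),
      shared_core = vapply(cm, function(r) chr1(r$shared_core), character(1)),
      substituent_a = vapply(cm, function(r) chr1(r$substituent_a), character(1)),
      substituent_b = vapply(cm, function(r) chr1(r$substituent_b), character(1)),
      transformation = vapply(cm, function(r) chr1(r$transformation), character(1))
    )
  }
  cells$targets[cells$status == "virtual"] <- list(character(0))
  structure(list(rows = as.character(unlist(x$rows)),
                 columns = as.character(unlist(x$columns)),
                 cells = cells, core_mmps = core_mmps),
            class = "csm")
}

#' Write/read the wide CSM view
#'
#' Rows x columns CSV; real cells are `compound_id:T`, empty cells
#' `VIRTUAL`. The reader restores rows, columns and the structural cell
#' fields (`compound_id`, `target_count`, `status`); structures and target
#' sets are not part of this view.
#'
#' @param csm A `csm` object.
#' @param path File path.
#' @export
write_csm_csv <- function(csm, path) {
  stopifnot(inherits(csm, "csm"))
  cells <- csm$cells
  wide <- matrix("VIRTUAL", length(csm$rows), length(csm$columns),
                 dimnames = list(csm$rows, csm$columns))
  real <- cells[cells$status == "real", ]
  wide[cbind(match(real$core, csm$rows), match(real$substituent, csm$columns))] <-
    paste0(real$compound_id, ":", real$target_count)
  df <- tibble::as_tibble(wide)
  df <- tibble::add_column(df, core = csm$rows, .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_csm_csv
#' @export
read_csm_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  rows <- df$core
  cols <- setdiff(names(df), "core")
  grid <- tidyr::expand_grid(core = rows, substituent = cols)
  vals <- as.matrix(df[, cols])
  flat <- as.vector(t(vals))  # row-major to match expand_grid order
  is_virtual <- flat == "VIRTUAL"
  grid$compound_id <- ifelse(is_virtual, NA_character_,
                             sub(":[0-9]+$", "", flat))
  tc <- rep(NA_integer_, length(flat))
  tc[!is_virtual] <- as.integer(sub("^.*:", "", flat[!is_virtual]))
  grid$target_count <- tc
  grid$status <- ifelse(is_virtual, "virtual", "real")
  structure(list(rows = rows, columns = cols, cells = grid,
                 core_mmps = NULL), class = "csm")
}

#' Write design candidates as a SMILES file
#'
#' One candidate per line (`smiles<TAB>id`), preceded by provenance comment
#' lines recording the core and substituent of each virtual cell.
#'
#' @param candidates Tibble from [design_candidates()].
#' @param path File path.
#' @export
write_candidates_smi <- function(candidates, path) {
  lines <- character(0)
  for (i in seq_len(nrow(candidates))) {
    lines <- c(lines,
               paste0("# core=", candidates$core[i],
                      " substituent=", candidates$substituent[i]),
               paste0(candidates$smiles[i], "\tCAND-", i))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_candidates_smi
#' @export
read_candidates_smi <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  entries <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(entries, "\t", fixed = TRUE)
  tibble::tibble(
    core = sub("^# core=(.*) substituent=.*$", "\\1", comments),
    substituent = sub("^.* substituent=", "", comments),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}

# --- network exports ---------------------------------------------------------

#' Export networks as GraphML or SIF
#'
#' GraphML keeps node attributes (`target_count` for cliff networks,
#' `family` for target networks, `side` for bipartite networks), edge
#' attributes (`shared_compounds`) and the construction parameters as graph
#' attributes, so the matching readers restore the full objects. SIF is the
#' conventional `node <tab> relation <tab> node` interaction view.
#'
#' @param network A `cliff_network`, `target_network` or `bipartite_network`.
#' @param path File path.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  if (inherits(network, "target_network")) {
    g <- igraph::set_graph_attr(g, "kind", "target_network")
    g <- igraph::set_graph_attr(g, "min_shared", network$min_shared)
  } else if (inherits(network, "cliff_network")) {
    g <- igraph::set_graph_attr(g, "kind", "cliff_network")
  } else if (inherits(network, "bipartite_network")) {
    g <- igraph::set_graph_attr(g, "kind", "bipartite_network")
    igraph::V(g)$side <- ifelse(igraph::V(g)$type, "target", "compound")
  } else {
    rlang::abort("unsupported network object", class = "csmtools_input_error")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  kind <- igraph::graph_attr(g, "kind")
  if (identical(kind, "target_network")) {
    el <- igraph::as_edgelist(g)
    fam <- stats::setNames(igraph::V(g)$family, igraph::V(g)$name)
    edges <- tibble::tibble(
      target_a = el[, 1], target_b = el[, 2],
      shared_compounds = as.integer(igraph::E(g)$shared_compounds)
    )
    edges$intra_family <- unname(fam[edges$target_a] == fam[edges$target_b])
    nodes <- tibble::tibble(target_id = igraph::V(g)$name,
                            family = igraph::V(g)$family)
    ord <- lex_order(nodes$target_id)
    return(structure(list(graph = g, nodes = nodes[ord, ],
                          edges = edges,
                          n_intra_family = sum(edges$intra_family),
                          n_inter_family = sum(!edges$intra_family),
                          min_shared = as.numeric(igraph::graph_attr(g, "min_shared"))),
                     class = "target_network"))
  }
  if (identical(kind, "cliff_network")) {
    ids <- igraph::V(g)$name
    deg <- igraph::degree(g)
    nodes <- tibble::tibble(compound_id = ids,
                            target_count = as.integer(igraph::V(g)$target_count),
                            degree = as.integer(deg),
                            is_hub = unname(deg >= 2))
    nodes <- nodes[lex_order(nodes$compound_id), ]
    el <- igraph::as_edgelist(g)
    return(structure(list(graph = g, nodes = nodes,
                          edges = tibble::tibble(compound_a = el[, 1],
                                                 compound_b = el[, 2]),
                          hubs = nodes$compound_id[nodes$is_hub]),
                     class = "cliff_network"))
  }
  if (identical(kind, "bipartite_network")) {
    side <- igraph::V(g)$side
    ids <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    compound_first <- ids[match(el[, 1], ids)] %in% ids[side == "compound"]
    inter <- tibble::tibble(
      compound_id = ifelse(compound_first, el[, 1], el[, 2]),
      target_id = ifelse(compound_first, el[, 2], el[, 1])
    )
    compounds <- lex_sort(ids[side == "compound"])
    deg <- table(factor(inter$compound_id, levels = compounds))
    return(structure(list(graph = g,
                          compound_nodes = compounds,
                          target_nodes = lex_sort(ids[side == "target"]),
                          edges = inter,
                          degree_distribution = dplyr::count(
                            tibble::tibble(degree = as.integer(deg)),
                            .data$degree, name = "n_compounds"),
                          n_duplicates_removed = 0L),
                     class = "bipartite_network"))
  }
  rlang::abort("GraphML file does not carry a recognised 'kind' attribute",
               class = "csmtools_input_error")
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  rel <- if (inherits(network, "cliff_network")) "cliff"
  else if (inherits(network, "target_network")) "shares_compounds"
  else "interacts"
  el <- igraph::as_edgelist(network$graph)
  writeLines(if (nrow(el) > 0) paste(el[, 1], rel, el[, 2], sep = "\t")
             else character(0), path)
  invisible(path)
}

#' Write/read a compound degree distribution
#'
#' CSV with columns `degree` and `n_compounds`.
#'
#' @param network A `bipartite_network`.
#' @param path File path.
#' @export
write_degree_distribution_csv <- function(network, path) {
  readr::write_csv(network$degree_distribution, path)
  invisible(path)
}

#' @rdname write_degree_distribution_csv
#' @export
read_degree_distribution_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    degree = readr::col_integer(), n_compounds = readr::col_integer()),
    progress = FALSE)
}
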