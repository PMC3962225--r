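# Compound Series Matrices (CSMs).
#
# Two-step construction: (1) compound-level MMPs group compounds into analog
# series, one per core; (2) MMPs computed over the core fragments themselves
# relate series whose cores differ by a structural change at a single site.
# Each connected component of the core-level MMP graph with at least two
# cores becomes one CSM: rows are the related cores, columns the union of
# their substituents, filled cells are real compounds annotated with target
# counts, and empty cells are virtual compounds — enumerable candidates for
# design. No fragmentation rounds beyond these two are applied.

#' Group compounds into analog series
#'
#' Computes compound-level MMPs and, for every core that occurs in at least
#' one MMP, collects all compounds fragmenting to that core under the size
#' restrictions, keyed by their substituent. An analog series is an
#' MMP-derived grouping, so it always has at least two members; a compound
#' may belong to several series via different cores.
#'
#' @param dataset A `curated_dataset` or a data frame with `compound_id` and
#'   `smiles`.
#' @param limits A [size_limits()] object.
#' @return A tibble of class `analog_series`, one row per series: `core`,
#'   `n_members`, `members` (list of tibbles `substituent`, `compound_id`,
#'   `smiles`).
#' @export
build_series <- function(dataset, limits = size_limits()) {
  structures <- compound_structures(dataset)
  mmps <- generate_mmps(structures, limits)
  out <- tibble::tibble(core = character(0), n_members = integer(0),
                        members = list())
  class(out) <- c("analog_series", class(out))
  if (nrow(mmps) == 0) return(out)
  frags <- fragment_molecules(structures$smiles, ids = structures$compound_id)
  frags <- frags[passes_size_restrictions(frags, limits), ]
  frags <- frags[frags$core %in% unique(mmps$core), ]
  smiles_of <- stats::setNames(structures$smiles, structures$compound_id)
  dup <- dplyr::count(frags, .data$core, .data$substituent, name = "n")
  dup <- dup[dup$n > 1, ]
  if (nrow(dup) > 0) {
    rlang::abort(paste0("two distinct compounds share core '", dup$core[1],
                        "' with identical substituent '", dup$substituent[1],
                        "'; upstream structure deduplication failed"),
                 class = "csmtools_integrity_error")
  }
  series <- lapply(split(frags, frags$core), function(df) {
    members <- tibble::tibble(substituent = df$substituent,
                              compound_id = df$parent_id,
                              smiles = unname(smiles_of[df$parent_id]))
    members[lex_order(members$substituent), ]
  })
  keep <- vapply(series, nrow, integer(1)) >= 2
  series <- series[keep]
  out <- tibble::tibble(core = lex_sort(names(series)),
                        n_members = NA_integer_, members = list(NULL))
  out$members <- series[out$core]
  out$n_members <- vapply(out$members, nrow, integer(1))
  class(out) <- c("analog_series", class(out))
  out
}

#' Assemble Compound Series Matrices
#'
#' Builds the core-level MMP graph over the series cores; each connected
#' component with at least two cores becomes one CSM. Rows are the component
#' cores (sorted by heavy-atom count, then lexicographically), columns the
#' union of substituents across member series (same ordering). A cell is
#' real when its (core, substituent) combination exists in the data — then it
#' holds exactly one compound, annotated with its target count — and virtual
#' otherwise. A compound fragmenting into several cells of one CSM is placed
#' once, at the cell with the largest core.
#'
#' @param series `analog_series` tibble from [build_series()].
#' @param profiles Optional profile tibble ([build_profiles()]); real cells
#'   are annotated with `target_count` (and `targets` when available).
#'   Compounds absent from `profiles` get a target count of 0.
#' @param limits A [size_limits()] object.
#' @return A list of `csm` objects: each a list with `rows`, `columns`,
#'   `cells` (tibble `core`, `substituent`, `status`, `compound_id`,
#'   `smiles`, `target_count`, `targets`), and `core_mmps`.
#' @export
build_csms <- function(series, profiles = NULL, limits = size_limits()) {
  stopifnot(is.data.frame(series))
  if (nrow(series) == 0) return(list())
  core_mmps <- core_level_mmps(series$core, limits)
  if (nrow(core_mmps) == 0) return(list())
  g <- igraph::graph_from_data_frame(core_mmps[, c("core_a", "core_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = series$core))
  comp <- igraph::components(g)
  t_of <- function(ids) {
    if (is.null(profiles)) return(rep(0L, length(ids)))
    tc <- profiles$target_count[match(ids, profiles$compound_id)]
    as.integer(ifelse(is.na(tc), 0L, tc))
  }
  targets_of <- function(ids) {
    if (is.null(profiles) || !("targets" %in% names(profiles))) {
      return(rep(list(character(0)), length(ids)))
    }
    idx <- match(ids, profiles$compound_id)
    lapply(idx, function(i) if (is.na(i)) character(0) else profiles$targets[[i]])
  }
  csms <- list()
  for (ci in seq_len(comp$no)) {
    cores <- names(comp$membership)[comp$membership == ci]
    if (length(cores) < 2) next
    sel <- series[series$core %in% cores, ]
    cells_real <- dplyr::bind_rows(lapply(seq_len(nrow(sel)), function(i) {
      m <- sel$members[[i]]
      tibble::tibble(core = sel$core[i], substituent = m$substituent,
                     compound_id = m$compound_id, smiles = m$smiles)
    }))
    # one cell per compound within a CSM: keep the largest core
    core_sizes <- fragment_heavy_atoms(unique(cells_real$core))
    cells_real$core_heavy <- core_sizes[cells_real$core]
    cells_real <- cells_real[order(-cells_real$core_heavy,
                                   cells_real$core, cells_real$substituent,
                                   method = "radix"), ]
    cells_real <- dplyr::distinct(cells_real, .data$compound_id, .keep_all = TRUE)
    rows <- order_fragments(unique(cells_real$core))
    cols <- order_fragments(unique(cells_real$substituent))
    grid <- tidyr::expand_grid(core = rows, substituent = cols)
    grid <- dplyr::left_join(grid,
                             cells_real[, c("core", "substituent",
                                            "compound_id", "smiles")],
                             by = c("core", "substituent"))
    grid$status <- ifelse(is.na(grid$compound_id), "virtual", "real")
    grid$target_count <- ifelse(grid$status == "real", t_of(grid$compound_id), NA)
    grid$target_count <- as.integer(grid$target_count)
    grid$targets <- targets_of(grid$compound_id)
    grid$targets[grid$status == "virtual"] <- list(character(0))
    csm <- structure(list(
      rows = rows, columns = cols, cells = grid,
      core_mmps = core_mmps[core_mmps$core_a %in% cores &
                              core_mmps$core_b %in% cores, ]
    ), class = "csm")
    csms[[length(csms) + 1]] <- csm
  }
  # deterministic order: by first row core
  if (length(csms) > 1) {
    csms <- csms[lex_order(vapply(csms, function(x) x$rows[1], character(1)))]
  }
  csms
}

# Heavy-atom counts for fragment SMILES, as a named vector.
fragment_heavy_atoms <- function(frags) {
  res <- integer(length(frags))
  h <- frags == H_SUBSTITUENT
  res[h] <- 0L
  if (any(!h)) {
    mols <- parse_molecules(frags[!h])
    res[!h] <- vapply(mols, function(m) {
      if (is.null(m)) NA_integer_ else as.integer(n_heavy(m$atoms))
    }, integer(1))
  }
  stats::setNames(res, frags)
}

# Sort fragments by heavy-atom count, then lexicographically.
order_fragments <- function(frags) {
  sizes <- fragment_heavy_atoms(frags)
  frags[order(sizes, frags, method = "radix")]
}

#' @export
print.csm <- function(x, ...) {
  n_real <- sum(x$cells$status == "real")
  cat("Compound Series Matrix: ", length(x$rows), " cores x ",
      length(x$columns), " substituents; ", n_real, " real, ",
      nrow(x$cells) - n_real, " virtual cells\n", sep = "")
  invisible(x)
}

#' @rdname build_csms
#' @param x A `csm` object.
#' @param ... Unused.
#' @method tidy csm
#' @export
tidy.csm <- function(x, ...) x$cells

#' @rdname build_csms
#' @method glance csm
#' @export
glance.csm <- function(x, ...) {
  real <- x$cells[x$cells$status == "real", ]
  tibble::tibble(
    n_rows = length(x$rows), n_columns = length(x$columns),
    n_real = nrow(real), n_virtual = nrow(x$cells) - nrow(real),
    n_multi_target = sum(real$target_count >= 2),
    max_target_count = if (nrow(real)) max(real$target_count) else NA_integer_
  )
}

#' Collection-level CSM statistics
#'
#' A CSM is multi-target when it contains at least one compound active
#' against two or more targets. The family span of a CSM is the number of
#' distinct target families covered by the targets of its real-cell
#' compounds; multi-target CSMs either stay within a single family or span
#' several.
#'
#' @param csms List of `csm` objects from [build_csms()].
#' @param target_families Mapping target -> family (tibble or named vector).
#' @return A `csm_statistics` object: `n_csms`, `n_multi_target_csms`,
#'   `n_single_family`, `n_multi_family`, `family_span_histogram` (tibble
#'   `n_families`, `n_csms`).
#' @export
csm_statistics <- function(csms, target_families = NULL) {
  fam <- if (is.null(target_families)) NULL else as_family_table(target_families)
  span <- vapply(csms, function(x) {
    real <- x$cells[x$cells$status == "real", ]
    targets <- unique(unlist(real$targets))
    if (length(targets) == 0) return(0L)
    if (is.null(fam)) return(NA_integer_)
    f <- fam$family[match(targets, fam$target_id)]
    length(unique(ifelse(is.na(f), "other", f)))
  }, integer(1))
  multi <- vapply(csms, function(x) {
    any(x$cells$target_count[x$cells$status == "real"] >= 2)
  }, logical(1))
  hist <- if (length(span[multi]) > 0 && !anyNA(span[multi])) {
    dplyr::count(tibble::tibble(n_families = span[multi]), .data$n_families,
                 name = "n_csms")
  } else {
    tibble::tibble(n_families = integer(0), n_csms = integer(0))
  }
  structure(list(
    n_csms = length(csms),
    n_multi_target_csms = sum(multi),
    n_single_family = sum(multi & !is.na(span) & span <= 1),
    n_multi_family = sum(multi & !is.na(span) & span > 1),
    family_span_histogram = hist
  ), class = "csm_statistics")
}

#' @export
print.csm_statistics <- function(x, ...) {
  cat("CSM collection: ", x$n_csms, " matrices, ", x$n_multi_target_csms,
      " multi-target (", x$n_single_family, " single-family, ",
      x$n_multi_family, " multi-family)\n", sep = "")
  invisible(x)
}

#' @rdname csm_statistics
#' @param x A `csm_statistics` object.
#' @param ... Unused.
#' @method tidy csm_statistics
#' @export
tidy.csm_statistics <- function(x, ...) x$family_span_histogram

#' @rdname csm_statistics
#' @method glance csm_statistics
#' @export
glance.csm_statistics <- function(x, ...) {
  tibble::tibble(n_csms = x$n_csms,
                 n_multi_target_csms = x$n_multi_target_csms,
                 n_single_family = x$n_single_family,
                 n_multi_family = x$n_multi_family)
}

#' Extract the promiscuous submatrix of a CSM
#'
#' Retains the real cells with `target_count >= min_target_count`, drops rows
#' and columns left without any surviving real cell, and recomputes virtual
#' cells on the reduced grid (real cells below the threshold become virtual
#' if their row and column survive).
#'
#' @param csm A `csm` object.
#' @param min_target_count Minimum per-compound target count to retain.
#' @return A reduced `csm` object.
#' @export
extract_promiscuous_submatrix <- function(csm, min_target_count) {
  stopifnot(inherits(csm, "csm"), min_target_count >= 1)
  real <- csm$cells[csm$cells$status == "real" &
                      csm$cells$target_count >= min_target_count, ]
  if (nrow(real) == 0) {
    rlang::abort(paste0("empty submatrix: no real cell with target count >= ",
                        min_target_count),
                 class = "csmtools_empty_result")
  }
  rows <- csm$rows[csm$rows %in% real$core]
  cols <- csm$columns[csm$columns %in% real$substituent]
  grid <- tidyr::expand_grid(core = rows, substituent = cols)
  grid <- dplyr::left_join(grid,
                           real[, c("core", "substituent", "compound_id",
                                    "smiles", "target_count", "targets")],
                           by = c("core", "substituent"))
  grid$status <- ifelse(is.na(grid$compound_id), "virtual", "real")
  grid$targets[grid$status == "virtual"] <- list(character(0))
  structure(list(rows = rows, columns = cols, cells = grid,
                 core_mmps = csm$core_mmps[csm$core_mmps$core_a %in% rows &
                                             csm$core_mmps$core_b %in% rows, ]),
            class = "csm")
}

#' Enumerate virtual design candidates in a CSM column
#'
#' Compounds in a column share a substituent; when a column contains a
#' promiscuous compound, the virtual cells of that column are core +
#' substituent combinations absent from the data set and suggest candidates
#' with potentially similar promiscuity profiles. Each virtual cell is
#' reassembled into a full structure; chemically invalid reassemblies are
#' skipped with a warning.
#'
#' @param csm A `csm` object.
#' @param column Substituent (column label) to enumerate.
#' @return Tibble `core`, `substituent`, `smiles` (canonical assembled
#'   structure), one row per virtual cell of the column.
#' @export
design_candidates <- function(csm, column) {
  stopifnot(inherits(csm, "csm"))
  if (!column %in% csm$columns) {
    rlang::abort(paste0("column '", column, "' not present in the CSM"),
                 class = "csmtools_input_error")
  }
  virt <- csm$cells[csm$cells$substituent == column &
                      csm$cells$status == "virtual", ]
  if (nrow(virt) == 0) {
    return(tibble::tibble(core = character(0), substituent = character(0),
                          smiles = character(0)))
  }
  smi <- reassemble_fragments(virt$core, virt$substituent)
  bad <- is.na(smi)
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " candidate(s) skipped: core/substituent ",
                       "combination could not be assembled (e.g. core '",
                       virt$core[which(bad)[1]], "')"))
  }
  tibble::tibble(core = virt$core[!bad], substituent = virt$substituent[!bad],
                 smiles = smi[!bad])
}
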