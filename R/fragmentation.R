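# Single-cut fragmentation, fragment indexing and matched molecular pair
# (MMP) assembly.
#
# A fragmentation cuts one acyclic single bond between two heavy atoms and
# yields a (core, substituent) pair of fragments, each carrying exactly one
# wildcard attachment point. Both orientations of a cut are emitted, so a
# fragment can serve as core in one pairing and substituent in another.
# Indexing fragmentations by canonical core string makes MMP generation a
# grouped self-join instead of an all-pairs comparison.

#' Transformation size restrictions
#'
#' Heavy-atom limits that keep MMP substructure exchanges small, chemically
#' meaningful replacements: the substituent may have at most
#' `max_substituent` heavy atoms, the core must have at least
#' `core_to_substituent_ratio` times as many heavy atoms as the substituent,
#' and the two exchanged substituents may differ by at most
#' `max_exchange_delta` heavy atoms.
#'
#' @param max_substituent Maximum substituent size in heavy atoms.
#' @param core_to_substituent_ratio Minimum core/substituent heavy-atom ratio.
#' @param max_exchange_delta Maximum heavy-atom difference between exchanged
#'   substituents.
#' @return An object of class `size_limits`.
#' @export
size_limits <- function(max_substituent = 13,
                        core_to_substituent_ratio = 2,
                        max_exchange_delta = 8) {
  stopifnot(max_substituent >= 1, core_to_substituent_ratio >= 0,
            max_exchange_delta >= 0)
  structure(list(max_substituent = max_substituent,
                 core_to_substituent_ratio = core_to_substituent_ratio,
                 max_exchange_delta = max_exchange_delta),
            class = "size_limits")
}

#' @export
print.size_limits <- function(x, ...) {
  cat("Transformation size restrictions:\n",
      "  max substituent heavy atoms: ", x$max_substituent, "\n",
      "  min core/substituent ratio:  ", x$core_to_substituent_ratio, "\n",
      "  max exchange size delta:     ", x$max_exchange_delta, "\n", sep = "")
  invisible(x)
}

# Fragment a batch of structures. Returns one tibble with columns
# parent_id, core, substituent, core_heavy_atoms, substituent_heavy_atoms.
# Results are cached per (SMILES string, hydrogen_cuts) so repeated calls on
# overlapping compound sets are cheap.
fragment_molecules <- function(smiles, ids = smiles, hydrogen_cuts = FALSE) {
  stopifnot(length(smiles) == length(ids))
  if (length(smiles) == 0) return(empty_fragmentation_tbl())
  uniq <- unique(smiles)
  keys <- paste0("frag:", as.integer(hydrogen_cuts), ":", uniq)
  todo <- uniq[!vapply(keys, exists, logical(1), envir = .chem_cache)]
  if (length(todo) > 0) {
    computed <- fragment_uncached(todo, hydrogen_cuts)
    for (i in seq_along(todo)) {
      assign(paste0("frag:", as.integer(hydrogen_cuts), ":", todo[i]),
             computed[[i]], envir = .chem_cache)
    }
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    tbl <- get(paste0("frag:", as.integer(hydrogen_cuts), ":", smiles[i]),
               envir = .chem_cache)
    if (is.null(tbl)) {
      rlang::abort(paste0("unparseable structure for compound '", ids[i], "'"),
                   class = "csmtools_parse_error")
    }
    if (nrow(tbl) > 0) tbl$parent_id <- ids[i]
    out[[i]] <- tbl
  }
  dplyr::bind_rows(out)
}

empty_fragmentation_tbl <- function() {
  tibble::tibble(parent_id = character(0), core = character(0),
                 substituent = character(0), core_heavy_atoms = integer(0),
                 substituent_heavy_atoms = integer(0))
}

# Worker: fragment a set of distinct SMILES, no caching. Returns a list
# parallel to `smiles`; NULL elements mark unparseable structures.
fragment_uncached <- function(smiles, hydrogen_cuts) {
  mols <- parse_molecules(smiles, add_h = hydrogen_cuts)
  blocks <- character(0)     # fragment MOL blocks, canonicalized in one batch
  rows <- list()             # bookkeeping per emitted fragmentation
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    if (is.null(mol)) next
    heavy <- which(mol$atoms != "H")
    inert <- mol$atoms %in% c(ATTACHMENT, CORE_MARKER)
    bb <- mol$bonds
    heavy_bonds <- which(bb[, 1] %in% heavy & bb[, 2] %in% heavy &
                           !inert[bb[, 1]] & !inert[bb[, 2]] & bb[, 3] == 1L)
    if (length(heavy_bonds) > 0) {
      g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2])[bb[, 1] %in% heavy &
                                                                 bb[, 2] %in% heavy, ,
                                                               drop = FALSE],
                                       directed = FALSE)
      br <- igraph::bridges(g)
      bridge_pairs <- igraph::as_edgelist(g)[br, , drop = FALSE]
      bridge_key <- paste(pmin(bridge_pairs[, 1], bridge_pairs[, 2]),
                          pmax(bridge_pairs[, 1], bridge_pairs[, 2]))
      for (e in heavy_bonds) {
        a <- bb[e, 1]; b <- bb[e, 2]
        if (!(paste(min(a, b), max(a, b)) %in% bridge_key)) next
        sides <- split_sides(mol, heavy, a, b)
        blk_a <- mol_block(mol, keep = sides$a,
                           extra_atoms = ATTACHMENT,
                           extra_bonds = rbind(c(match(a, sides$a),
                                                 length(sides$a) + 1L, 1L)),
                           title = as.character(length(blocks) + 1))
        blocks <- c(blocks, blk_a)
        ia <- length(blocks)
        blk_b <- mol_block(mol, keep = sides$b,
                           extra_atoms = ATTACHMENT,
                           extra_bonds = rbind(c(match(b, sides$b),
                                                 length(sides$b) + 1L, 1L)),
                           title = as.character(length(blocks) + 1))
        blocks <- c(blocks, blk_b)
        ib <- length(blocks)
        na_ <- n_heavy(mol$atoms[sides$a]); nb_ <- n_heavy(mol$atoms[sides$b])
        rows[[length(rows) + 1]] <- list(m = m, core_i = ia, sub_i = ib,
                                         core_n = na_, sub_n = nb_)
        rows[[length(rows) + 1]] <- list(m = m, core_i = ib, sub_i = ia,
                                         core_n = nb_, sub_n = na_)
      }
    }
    if (hydrogen_cuts) {
      hpos <- which(mol$hcount > 0 & mol$atoms != "H" & !inert)
      for (a in hpos) {
        blk <- mol_block(mol, keep = heavy,
                         extra_atoms = ATTACHMENT,
                         extra_bonds = rbind(c(match(a, heavy),
                                               length(heavy) + 1L, 1L)),
                         title = as.character(length(blocks) + 1))
        blocks <- c(blocks, blk)
        rows[[length(rows) + 1]] <- list(m = m, core_i = length(blocks), sub_i = 0L,
                                         core_n = n_heavy(mol$atoms[heavy]), sub_n = 0L)
      }
    }
  }
  frag_smiles <- canonicalize_mol_blocks(blocks)
  out <- lapply(mols, function(m) if (is.null(m)) NULL else empty_fragmentation_tbl())
  if (length(rows) > 0) {
    df <- tibble::tibble(
      m = vapply(rows, `[[`, integer(1), "m"),
      core = frag_smiles[vapply(rows, `[[`, integer(1), "core_i")],
      substituent = ifelse(vapply(rows, `[[`, integer(1), "sub_i") == 0L,
                           H_SUBSTITUENT,
                           frag_smiles[pmax(1L, vapply(rows, `[[`, integer(1), "sub_i"))]),
      core_heavy_atoms = vapply(rows, function(r) as.integer(r$core_n), integer(1)),
      substituent_heavy_atoms = vapply(rows, function(r) as.integer(r$sub_n), integer(1))
    )
    df <- df[!is.na(df$core) & !is.na(df$substituent), ]
    for (m in unique(df$m)) {
      sub <- df[df$m == m, c("core", "substituent",
                             "core_heavy_atoms", "substituent_heavy_atoms")]
      sub <- dplyr::distinct(sub, .data$core, .data$substituent, .keep_all = TRUE)
      sub <- tibble::add_column(sub, parent_id = NA_character_, .before = 1)
      out[[m]] <- sub
    }
  }
  out
}

# Atom indices (within `heavy`) of the two sides of the cut bond a-b.
split_sides <- function(mol, heavy, a, b) {
  bb <- mol$bonds
  sel <- bb[, 1] %in% heavy & bb[, 2] %in% heavy &
    !(bb[, 1] == a & bb[, 2] == b) & !(bb[, 1] == b & bb[, 2] == a)
  adj <- bb[sel, , drop = FALSE]
  visit <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- unique(c(adj[adj[, 1] %in% frontier, 2],
                      adj[adj[, 2] %in% frontier, 1]))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    sort(seen)
  }
  list(a = visit(a), b = visit(b))
}

#' Enumerate single-cut fragmentations of one structure
#'
#' Cuts every acyclic single bond between two heavy atoms and returns each
#' resulting (core, substituent) fragment pair in both orientations, with
#' fragments as canonical SMILES carrying one `*` attachment point. Ring
#' bonds are never cut; molecules with a single heavy atom have no
#' fragmentations.
#'
#' @param structure A single SMILES string.
#' @param id Identifier used in error messages (defaults to the structure).
#' @param hydrogen_cuts Also emit hydrogen-replacement fragmentations (core =
#'   molecule with an attachment point at a hydrogen position, substituent =
#'   `"[*H]"`)? Used by the core-level MMP round, off for compound-level
#'   fragmentation.
#' @return A tibble with columns `parent_id`, `core`, `substituent`,
#'   `core_heavy_atoms`, `substituent_heavy_atoms`, deduplicated.
#' @export
#' @examples
#' \donttest{
#' enumerate_fragmentations("CCc1ccccc1")  # ethylbenzene: 2 cuts, 4 rows
#' }
enumerate_fragmentations <- function(structure, id = structure,
                                     hydrogen_cuts = FALSE) {
  stopifnot(is.character(structure), length(structure) == 1)
  fragment_molecules(structure, ids = id, hydrogen_cuts = hydrogen_cuts)
}

#' Apply transformation size restrictions to fragmentations
#'
#' @param fragmentations A fragmentation tibble as returned by
#'   [enumerate_fragmentations()].
#' @param limits A [size_limits()] object.
#' @return Logical vector, `TRUE` where the fragmentation passes.
#' @export
passes_size_restrictions <- function(fragmentations, limits = size_limits()) {
  stopifnot(inherits(limits, "size_limits"))
  fragmentations$substituent_heavy_atoms <= limits$max_substituent &
    fragmentations$core_heavy_atoms >=
      limits$core_to_substituent_ratio * fragmentations$substituent_heavy_atoms
}

#' Generate matched molecular pairs
#'
#' Indexes size-restricted fragmentations by canonical core and pairs
#' compounds that share a core with distinct substituents. Every unordered
#' compound pair yields at most one MMP: when a pair shares several cores the
#' MMP with the largest core is kept (most conservative transformation; ties
#' broken lexicographically). The transformation is oriented so that
#' `substituent_a` sorts before `substituent_b`.
#'
#' @param x A `curated_dataset` (see [curate_activities()]) or a data frame
#'   with columns `compound_id` and `smiles`.
#' @param limits A [size_limits()] object.
#' @return A tibble with one row per MMP: `compound_a`, `compound_b`, `core`,
#'   `substituent_a`, `substituent_b`, `core_heavy_atoms`, `transformation`.
#' @export
generate_mmps <- function(x, limits = size_limits()) {
  structures <- compound_structures(x)
  if (nrow(structures) < 2) return(empty_mmp_tbl())
  frags <- fragment_molecules(structures$smiles, ids = structures$compound_id)
  frags <- frags[passes_size_restrictions(frags, limits), ]
  mmps_from_fragments(frags, limits)
}

empty_mmp_tbl <- function() {
  tibble::tibble(compound_a = character(0), compound_b = character(0),
                 core = character(0), substituent_a = character(0),
                 substituent_b = character(0), core_heavy_atoms = integer(0),
                 transformation = character(0))
}

# Shared pairing logic: `frags` already size-restricted.
mmps_from_fragments <- function(frags, limits) {
  if (nrow(frags) == 0) return(empty_mmp_tbl())
  pairs <- dplyr::inner_join(
    frags, frags,
    by = c("core", "core_heavy_atoms"),
    suffix = c("_a", "_b"),
    relationship = "many-to-many"
  )
  pairs <- dplyr::filter(
    pairs,
    .data$parent_id_a < .data$parent_id_b,
    .data$substituent_a != .data$substituent_b,
    abs(.data$substituent_heavy_atoms_a - .data$substituent_heavy_atoms_b) <=
      limits$max_exchange_delta
  )
  if (nrow(pairs) == 0) return(empty_mmp_tbl())
  # one MMP per compound pair: largest core, then lexicographic tie-breaks
  pairs <- dplyr::arrange(
    pairs,
    .data$parent_id_a, .data$parent_id_b,
    dplyr::desc(.data$core_heavy_atoms),
    .data$core, .data$substituent_a, .data$substituent_b,
    .by_group = FALSE
  )
  pairs <- dplyr::distinct(pairs, .data$parent_id_a, .data$parent_id_b,
                           .keep_all = TRUE)
  # orient the transformation: substituent_a lexicographically first
  swap <- lex_lt(pairs$substituent_b, pairs$substituent_a)
  res <- tibble::tibble(
    compound_a = ifelse(swap, pairs$parent_id_b, pairs$parent_id_a),
    compound_b = ifelse(swap, pairs$parent_id_a, pairs$parent_id_b),
    core = pairs$core,
    substituent_a = ifelse(swap, pairs$substituent_b, pairs$substituent_a),
    substituent_b = ifelse(swap, pairs$substituent_a, pairs$substituent_b),
    core_heavy_atoms = as.integer(pairs$core_heavy_atoms)
  )
  res$transformation <- paste0(res$substituent_a, ">>", res$substituent_b)
  dplyr::arrange(res, .data$compound_a, .data$compound_b)
}

#' Matched molecular pairs between core fragments
#'
#' The second round of the two-step CSM scheme: core fragments from
#' compound-level MMPs are treated as molecules whose attachment point is
#' preserved as an inert marker atom that is never cut, and single-cut MMP
#' generation is applied to them. Hydrogen-replacement fragmentations are
#' included here so that cores differing by an H-to-substituent change at one
#' site (e.g. phenyl vs. 4-methylphenyl) are recognized as related. No further
#' fragmentation rounds are applied beyond this one.
#'
#' @param cores Character vector of canonical core SMILES, each with exactly
#'   one `*` attachment point.
#' @param limits A [size_limits()] object.
#' @return A tibble with one row per related core pair: `core_a`, `core_b`,
#'   `shared_core`, `substituent_a`, `substituent_b`, `transformation`.
#' @export
core_level_mmps <- function(cores, limits = size_limits()) {
  cores <- unique(cores)
  if (length(cores) < 2) {
    return(tibble::tibble(core_a = character(0), core_b = character(0),
                          shared_core = character(0),
                          substituent_a = character(0),
                          substituent_b = character(0),
                          transformation = character(0)))
  }
  marked <- core_to_marker(cores)
  frags <- fragment_molecules(marked, ids = cores, hydrogen_cuts = TRUE)
  frags <- frags[passes_size_restrictions(frags, limits), ]
  res <- mmps_from_fragments(frags, limits)
  tibble::tibble(core_a = res$compound_a, core_b = res$compound_b,
                 shared_core = res$core,
                 substituent_a = res$substituent_a,
                 substituent_b = res$substituent_b,
                 transformation = res$transformation)
}

# Extract a compound_id/smiles tibble from the accepted input forms.
compound_structures <- function(x) {
  if (inherits(x, "curated_dataset")) return(x$compounds[, c("compound_id", "smiles")])
  if (is.data.frame(x)) {
    if (!all(c("compound_id", "smiles") %in% names(x))) {
      rlang::abort("need columns 'compound_id' and 'smiles'",
                   class = "csmtools_input_error")
    }
    return(dplyr::distinct(tibble::as_tibble(x[, c("compound_id", "smiles")])))
  }
  if (is.character(x) && !is.null(names(x))) {
    return(tibble::tibble(compound_id = names(x), smiles = unname(x)))
  }
  rlang::abort("unsupported input; pass a curated_dataset or a compound/smiles table",
               class = "csmtools_input_error")
}
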