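# Synthetic ground-truth fixtures.
#
# Two generators exercise the whole pipeline without any external database:
#
# * generate_analog_grid() plants a full cores x substituents analog grid
#   (with seeded random deletions) whose expected MMPs, series, CSM layout
#   and virtual cells are known exactly by construction. Cores are a
#   fluorine-decoration chain on a benzene scaffold — consecutive cores
#   differ by one H->F change at a single site, so core-level relatedness is
#   guaranteed — and substituents are single heavy atoms disjoint from
#   fluorine, which provably rules out accidental alternative shared cores
#   between grid compounds under the default size restrictions.
#
# * generate_binary_matrix() emulates a profiling microarray readout: a
#   binary compound x target matrix with background activity sampled at a
#   fixed rate over structurally inert cycloalkanes (no acyclic bonds, hence
#   provably MMP-free) and planted promiscuity-cliff pairs built as true
#   structural MMP partners with an exact target-count difference.

# ring positions that can carry a fluorine decoration, in the order they are
# added; position 6 is avoided so the SMILES template stays simple
F_POSITIONS <- c(4, 3, 5, 2)

# single-heavy-atom substituents available to the grid (disjoint from F)
GRID_SUBSTITUENTS <- c(C = "C", N = "N", O = "O", Cl = "Cl", Br = "Br",
                       S = "S", I = "I")

#' Specification for a planted analog grid
#'
#' @param n_series Number of cores (2 to 5): core k carries k-1 fluorine
#'   decorations, so consecutive cores are related by a single H->F change.
#' @param substituents Substituent atoms for the columns (subset of
#'   C, N, O, Cl, Br, S, I).
#' @param deletion_fraction Fraction of grid cells deleted at random; every
#'   core keeps at least two compounds.
#' @param n_targets Number of targets activities are sampled over.
#' @param families Named integer vector of family sizes summing to
#'   `n_targets`.
#' @param t_geom_prob Success probability of the zero-truncated geometric
#'   target-count sampler (heavier single-target skew for larger values).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_series = 4,
                         substituents = c("C", "N", "O", "Cl", "Br"),
                         deletion_fraction = 0.25,
                         n_targets = 20,
                         families = c("GPCR-A" = 8, "kinase" = 6,
                                      "protease" = 3, "ion channel" = 2,
                                      "NHR" = 1),
                         t_geom_prob = 0.6,
                         seed = 1) {
  stopifnot(n_series >= 2, n_series <= length(F_POSITIONS) + 1,
            all(substituents %in% GRID_SUBSTITUENTS),
            length(substituents) >= 2,
            deletion_fraction >= 0, deletion_fraction < 1,
            n_targets >= 1, sum(families) == n_targets,
            t_geom_prob > 0, t_geom_prob < 1,
            is.numeric(seed))
  structure(list(n_series = as.integer(n_series),
                 substituents = substituents,
                 deletion_fraction = deletion_fraction,
                 n_targets = as.integer(n_targets),
                 families = families,
                 t_geom_prob = t_geom_prob,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Benzene core with fluorines at the first (k-1) decoration positions and a
# wildcard attachment at position 1.
grid_core_smiles <- function(k) {
  pos <- F_POSITIONS[seq_len(k - 1)]
  ring <- rep("c", 5)  # ring positions 2..6
  ring[pos - 1] <- "c(F)"
  paste0("*c1", paste(ring, collapse = ""), "1")
}

# target id helper
target_ids <- function(n) sprintf("T%02d", seq_len(n))

family_table_from_sizes <- function(families, n_targets) {
  tibble::tibble(target_id = target_ids(n_targets),
                 family = rep(names(families), times = families))
}

# zero-truncated geometric sampler capped at n_targets
sample_target_counts <- function(n, prob, cap) {
  t <- stats::rgeom(n, prob) + 1L
  pmin(t, cap)
}

#' Generate a planted analog grid with ground truth
#'
#' Assembles the full cores x substituents grid, deletes a seeded random
#' subset of cells (each core keeps at least two compounds), samples
#' per-compound target profiles from a zero-truncated geometric distribution
#' with family structure, and emits Ki activity records plus an exact
#' ground-truth record of the planted layout.
#'
#' @param spec A [fixture_spec()].
#' @return A list with:
#'   * `records`: activity-record tibble (round-trips through
#'     [curate_activities()]),
#'   * `dataset`: the curated dataset,
#'   * `profiles`: target profiles of the curated dataset,
#'   * `ground_truth`: list with `grid` (tibble `core`, `substituent`,
#'     `compound_id`, `smiles`, `present`, `targets`, `target_count`),
#'     `cores`, `substituents`, `families`, `expected_mmps`,
#'     `expected_series` and `expected_virtual_cells`.
#' @export
generate_analog_grid <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    cores <- vapply(seq_len(spec$n_series), grid_core_smiles, character(1))
    cores_can <- canonical_smiles(cores, strict = TRUE)
    subs <- GRID_SUBSTITUENTS[spec$substituents]
    sub_frag <- canonical_smiles(paste0("*", unname(subs)), strict = TRUE)
    grid <- tidyr::expand_grid(row = seq_along(cores), col = seq_along(subs))
    grid$core <- cores_can[grid$row]
    grid$substituent <- sub_frag[grid$col]
    # compound structure: substituent atom replaces the attachment wildcard
    grid$smiles <- canonical_smiles(
      paste0(unname(subs)[grid$col], substring(cores[grid$row], 2)),
      strict = TRUE
    )
    grid$compound_id <- sprintf("CMP-%d-%s", grid$row, names(subs)[grid$col])
    # seeded deletions, each core keeping >= 2 members
    n_cells <- nrow(grid)
    n_delete <- floor(spec$deletion_fraction * n_cells)
    deletable <- seq_len(n_cells)
    deleted <- integer(0)
    if (n_delete > 0) {
      for (cand in sample(deletable, n_cells)) {
        if (length(deleted) >= n_delete) break
        left <- table(grid$row[setdiff(seq_len(n_cells), c(deleted, cand))])
        if (all(left >= 2) && length(left) == length(cores)) {
          deleted <- c(deleted, cand)
        }
      }
    }
    grid$present <- !(seq_len(n_cells) %in% deleted)
    # planted target profiles over present compounds
    tids <- target_ids(spec$n_targets)
    tc <- sample_target_counts(n_cells, spec$t_geom_prob, spec$n_targets)
    grid$targets <- lapply(seq_len(n_cells), function(i) {
      if (!grid$present[i]) return(character(0))
      lex_sort(sample(tids, tc[i]))
    })
    grid$target_count <- vapply(grid$targets, length, integer(1))
    fam <- family_table_from_sizes(spec$families, spec$n_targets)
    # activity records: one Ki measurement per compound-target pair
    present <- grid[grid$present, ]
    records <- dplyr::bind_rows(lapply(seq_len(nrow(present)), function(i) {
      tg <- present$targets[[i]]
      tibble::tibble(
        compound_id = present$compound_id[i],
        smiles = present$smiles[i],
        target_id = tg,
        target_family = fam$family[match(tg, fam$target_id)],
        measurement_type = "Ki",
        relation = "=",
        value_nm = round(10^stats::runif(length(tg), 0, 4), 3),
        active_flag = NA
      )
    }))
    ground_truth <- list(
      grid = grid[, c("core", "substituent", "compound_id", "smiles",
                      "present", "targets", "target_count")],
      cores = cores_can,
      substituents = sub_frag,
      families = fam,
      expected_mmps = expected_grid_mmps(grid),
      expected_series = expected_grid_series(grid),
      expected_virtual_cells = expected_virtual_cells(grid)
    )
    dataset <- curate_activities(records, "Ki")
    list(records = records, dataset = dataset,
         profiles = build_profiles(dataset), ground_truth = ground_truth)
  })
}

# All unordered pairs of present compounds within a row are MMPs (and, by
# construction, nothing else is).
expected_grid_mmps <- function(grid) {
  present <- grid[grid$present, ]
  rows <- split(present, present$core)
  out <- dplyr::bind_rows(lapply(rows, function(df) {
    if (nrow(df) < 2) return(NULL)
    idx <- utils::combn(seq_len(nrow(df)), 2)
    tibble::tibble(core = df$core[1],
                   compound_1 = df$compound_id[idx[1, ]],
                   compound_2 = df$compound_id[idx[2, ]],
                   substituent_1 = df$substituent[idx[1, ]],
                   substituent_2 = df$substituent[idx[2, ]])
  }))
  if (nrow(out) == 0) return(out)
  swap <- lex_lt(out$substituent_2, out$substituent_1)
  tibble::tibble(
    compound_a = ifelse(swap, out$compound_2, out$compound_1),
    compound_b = ifelse(swap, out$compound_1, out$compound_2),
    core = out$core,
    substituent_a = ifelse(swap, out$substituent_2, out$substituent_1),
    substituent_b = ifelse(swap, out$substituent_1, out$substituent_2)
  )
}

expected_grid_series <- function(grid) {
  present <- grid[grid$present, ]
  counts <- table(present$core)
  cores <- names(counts)[counts >= 2]
  lapply(stats::setNames(cores, cores), function(co) {
    df <- present[present$core == co, c("substituent", "compound_id", "smiles")]
    df[lex_order(df$substituent), ]
  })
}

# Virtual cells of the expected single CSM: deleted cells plus nothing else,
# restricted to columns that still have at least one present compound.
expected_virtual_cells <- function(grid) {
  live_cols <- unique(grid$substituent[grid$present])
  live_rows <- names(which(table(grid$core[grid$present]) >= 2))
  virt <- grid[!grid$present & grid$substituent %in% live_cols &
                 grid$core %in% live_rows, ]
  tibble::tibble(core = virt$core, substituent = virt$substituent,
                 smiles = virt$smiles)
}

#' Generate a binary profiling matrix with planted promiscuity cliffs
#'
#' Background compounds are unsubstituted cycloalkanes of distinct ring
#' sizes: they contain no acyclic bond, form no fragmentations and hence no
#' MMPs, so any cliff reported among them is a false positive. Planted cliff
#' pairs are substituted cycloalkanes differing only in the substituent
#' (methyl vs. chloro on the same ring), i.e. true structural MMP partners,
#' with target counts differing by exactly `delta`.
#'
#' @param n_compounds Number of background compounds.
#' @param n_targets Number of targets (columns).
#' @param base_activity_rate Per-cell activity probability of the background.
#' @param n_planted_cliff_pairs Number of planted MMP cliff pairs.
#' @param delta Exact target-count difference of each planted pair; must not
#'   exceed `n_targets`.
#' @param seed Integer seed.
#' @return A list with `matrix` (a `binary_matrix` tibble) and
#'   `ground_truth` (list with `planted_cliffs` tibble `compound_low`,
#'   `compound_high`, `t_low`, `t_high`, `delta`, and `background_ids`).
#' @export
generate_binary_matrix <- function(n_compounds = 200, n_targets = 100,
                                   base_activity_rate = 0.03,
                                   n_planted_cliff_pairs = 5,
                                   delta = 55, seed = 1) {
  stopifnot(n_compounds >= 1, n_targets >= 1,
            base_activity_rate >= 0, base_activity_rate <= 1,
            n_planted_cliff_pairs >= 0)
  if (n_planted_cliff_pairs > 0 && delta > n_targets) {
    rlang::abort(paste0("infeasible plant: delta (", delta,
                        ") exceeds n_targets (", n_targets, ")"),
                 class = "csmtools_input_error")
  }
  withr::with_seed(seed, {
    tids <- target_ids(n_targets)
    ring <- function(k) paste0("C1", strrep("C", k - 1), "1")
    bg <- tibble::tibble(
      compound_id = sprintf("BG-%03d", seq_len(n_compounds)),
      smiles = canonical_smiles(vapply(seq_len(n_compounds) + 2, ring,
                                       character(1)), strict = TRUE)
    )
    bg_cells <- matrix(stats::rbinom(n_compounds * n_targets, 1,
                                     base_activity_rate),
                       nrow = n_compounds)
    planted <- NULL
    pl_cells <- NULL
    if (n_planted_cliff_pairs > 0) {
      scaffold <- function(k, sub) {
        paste0(sub, "C1", strrep("C", k + 2), "1")  # substituted (k+3)-ring
      }
      t_low <- sample(0:min(10, n_targets - delta), n_planted_cliff_pairs,
                      replace = TRUE)
      t_high <- t_low + delta
      planted <- tibble::tibble(
        compound_low = sprintf("PC-%02d-lo", seq_len(n_planted_cliff_pairs)),
        compound_high = sprintf("PC-%02d-hi", seq_len(n_planted_cliff_pairs)),
        smiles_low = canonical_smiles(
          vapply(seq_len(n_planted_cliff_pairs),
                 function(k) scaffold(k, "C"), character(1)), strict = TRUE),
        smiles_high = canonical_smiles(
          vapply(seq_len(n_planted_cliff_pairs),
                 function(k) scaffold(k, "Cl"), character(1)), strict = TRUE),
        t_low = as.integer(t_low),
        t_high = as.integer(t_high),
        delta = as.integer(delta)
      )
      pl_cells <- t(vapply(c(rbind(t_low, t_high)), function(t) {
        cells <- integer(n_targets)
        if (t > 0) cells[sample(n_targets, t)] <- 1L
        cells
      }, integer(n_targets)))
    }
    ids <- c(bg$compound_id, if (!is.null(planted))
      c(rbind(planted$compound_low, planted$compound_high)))
    smis <- c(bg$smiles, if (!is.null(planted))
      c(rbind(planted$smiles_low, planted$smiles_high)))
    cells <- rbind(bg_cells, pl_cells)
    mat <- tibble::as_tibble(as.data.frame(cells))
    names(mat) <- tids
    mat <- dplyr::bind_cols(tibble::tibble(compound_id = ids, smiles = smis),
                            mat)
    mat <- structure(mat, class = c("binary_matrix", class(tibble::tibble())))
    list(matrix = mat,
         ground_truth = list(
           planted_cliffs = if (is.null(planted)) {
             tibble::tibble(compound_low = character(0),
                            compound_high = character(0),
                            t_low = integer(0), t_high = integer(0),
                            delta = integer(0))
           } else {
             planted[, c("compound_low", "compound_high", "t_low", "t_high",
                         "delta")]
           },
           background_ids = bg$compound_id
         ))
  })
}
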