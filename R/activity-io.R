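# Reading, validation, curation and deduplication of compound activity data,
# and construction of per-compound target profiles.
#
# Two potency measurement types (Ki and IC50) are handled separately, the way
# equilibrium constants and assay-dependent IC50 readouts are kept apart in
# curated database subsets; binary profiling matrices are a third input kind.

LONG_HEADER <- c("compound_id", "smiles", "target_id", "target_family",
                 "measurement_type", "relation", "value_nM")
MEASUREMENT_TYPES <- c("Ki", "IC50", "binary")
RELATIONS <- c("=", ">", "<", "~")

#' Read a compound activity table
#'
#' Reads activity records from one of the supported dialects:
#' * `long_csv`: one measurement per row with header
#'   `compound_id,smiles,target_id,target_family,measurement_type,relation,value_nM`.
#' * `wide_binary_csv`: a binary compound x target matrix (first column
#'   `compound_id`, second `smiles`, one 0/1 column per target); one binary
#'   record is emitted per 1-cell. The full compound roster (including
#'   all-inactive rows) is attached as attribute `"roster"`.
#' * `sdf`: an SDF structure file whose records carry a `compound_id`
#'   property; returns a compound/smiles table (activities come from CSV).
#'
#' @param path Path to the input file.
#' @param format One of `"long_csv"`, `"wide_binary_csv"`, `"sdf"`.
#' @return A tibble of activity records (`compound_id`, `smiles`, `target_id`,
#'   `target_family`, `measurement_type`, `relation`, `value_nm`,
#'   `active_flag`), or a structure table for `format = "sdf"`.
#' @export
read_activity_table <- function(path, format = c("long_csv", "wide_binary_csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("input file not found: ", path), class = "csmtools_input_error")
  }
  switch(format,
         long_csv = read_long_csv(path),
         wide_binary_csv = binary_records(read_binary_matrix(path)),
         sdf = read_structures_sdf(path))
}

read_long_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(LONG_HEADER, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("malformed activity table: missing column(s) ",
                        paste(missing_cols, collapse = ", ")),
                 class = "csmtools_input_error")
  }
  bad_type <- which(!(df$measurement_type %in% MEASUREMENT_TYPES))
  if (length(bad_type) > 0) {
    rlang::abort(paste0("row ", bad_type[1] + 1, ": unknown measurement_type '",
                        df$measurement_type[bad_type[1]], "'"),
                 class = "csmtools_input_error")
  }
  is_binary <- df$measurement_type == "binary"
  bad_rel <- which(!is_binary & !(df$relation %in% RELATIONS))
  if (length(bad_rel) > 0) {
    rlang::abort(paste0("row ", bad_rel[1] + 1, ": invalid relation '",
                        df$relation[bad_rel[1]], "'"),
                 class = "csmtools_input_error")
  }
  value <- suppressWarnings(as.numeric(df$value_nM))
  bad_val <- which(!is_binary & (is.na(value) | value <= 0))
  if (length(bad_val) > 0) {
    rlang::abort(paste0("row ", bad_val[1] + 1, ": field value_nM must be a ",
                        "positive potency in nM, got '", df$value_nM[bad_val[1]], "'"),
                 class = "csmtools_input_error")
  }
  bad_field <- which(!nzchar(df$compound_id) | !nzchar(df$target_id) | !nzchar(df$smiles))
  if (length(bad_field) > 0) {
    rlang::abort(paste0("row ", bad_field[1] + 1,
                        ": empty compound_id, smiles or target_id"),
                 class = "csmtools_input_error")
  }
  tibble::tibble(
    compound_id = df$compound_id,
    smiles = df$smiles,
    target_id = df$target_id,
    target_family = df$target_family,
    measurement_type = df$measurement_type,
    relation = ifelse(is_binary, NA_character_, df$relation),
    value_nm = ifelse(is_binary, NA_real_, value),
    active_flag = ifelse(is_binary, TRUE, NA)
  )
}

#' Read a wide binary activity matrix
#'
#' @param path CSV with columns `compound_id`, `smiles`, then one 0/1 column
#'   per target.
#' @return A wide tibble (class `binary_matrix`), one row per compound.
#' @export
read_binary_matrix <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("input file not found: ", path), class = "csmtools_input_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(), smiles = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  if (!identical(names(df)[1:2], c("compound_id", "smiles"))) {
    rlang::abort("wide binary matrix must start with columns compound_id, smiles",
                 class = "csmtools_input_error")
  }
  cells <- as.matrix(df[, -(1:2)])
  if (ncol(cells) == 0 || !all(cells %in% c(0, 1))) {
    bad <- which(!(cells %in% c(0, 1)))[1]
    rlang::abort(paste0("binary matrix cells must be 0 or 1",
                        if (!is.na(bad)) paste0("; offending cell value '",
                                                cells[bad], "'")),
                 class = "csmtools_input_error")
  }
  structure(tibble::as_tibble(df), class = c("binary_matrix", class(tibble::tibble())))
}

#' Long binary records from a wide matrix
#'
#' @param mat A `binary_matrix` tibble from [read_binary_matrix()].
#' @return Activity-record tibble with one row per active (1) cell; the full
#'   compound roster is attached as attribute `"roster"`.
#' @export
binary_records <- function(mat) {
  targets <- setdiff(names(mat), c("compound_id", "smiles"))
  long <- tidyr::pivot_longer(tibble::as_tibble(mat), cols = dplyr::all_of(targets),
                              names_to = "target_id", values_to = "active")
  long <- dplyr::filter(long, .data$active == 1)
  rec <- tibble::tibble(
    compound_id = long$compound_id,
    smiles = long$smiles,
    target_id = long$target_id,
    target_family = NA_character_,
    measurement_type = "binary",
    relation = NA_character_,
    value_nm = NA_real_,
    active_flag = TRUE
  )
  attr(rec, "roster") <- tibble::tibble(compound_id = mat$compound_id,
                                        smiles = mat$smiles)
  rec
}

read_structures_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  smi <- canonicalize_mol_blocks(
    vapply(seq_along(ChemmineR::sdfid(sdfset)), function(i) {
      lines <- ChemmineR::sdf2str(sdfset[[i]])
      lines[1] <- as.character(i)
      paste(lines, collapse = "\n")
    }, character(1))
  )
  ids <- vapply(seq_along(ChemmineR::sdfid(sdfset)), function(i) {
    db <- ChemmineR::datablock(sdfset[[i]])
    if ("compound_id" %in% names(db)) db[["compound_id"]] else NA_character_
  }, character(1))
  if (anyNA(ids)) {
    rlang::abort("SDF records must carry a 'compound_id' property",
                 class = "csmtools_input_error")
  }
  tibble::tibble(compound_id = ids, smiles = smi)
}

#' Curate an activity record set
#'
#' Applies the curation rules used for potency-based promiscuity analyses:
#' only records of the requested measurement type are kept, records with
#' approximate potency annotations (relations `>`, `<`, `~`) are excluded,
#' and potencies must be at or below `potency_threshold_nm` (10 uM by
#' default) to qualify as active. Structures are salt-stripped and
#' canonicalized; compounds whose canonical structures coincide are merged
#' (union of their activities, the lexicographically smallest identifier is
#' retained as representative). Replicate measurements for one
#' compound-target pair are aggregated by geometric mean.
#'
#' @param records Activity-record tibble from [read_activity_table()].
#' @param measurement_type `"Ki"` or `"IC50"`: the single type retained.
#' @param potency_threshold_nm Maximum potency (nM) to qualify as active.
#' @return A `curated_dataset`: list with `compounds` (tibble `compound_id`,
#'   `smiles`, `merged_ids`), `activities` (tibble `compound_id`, `target_id`,
#'   `target_family`, `value_nm`), `measurement_type`, `potency_threshold_nm`.
#' @export
curate_activities <- function(records, measurement_type = c("Ki", "IC50"),
                              potency_threshold_nm = 10000) {
  measurement_type <- match.arg(measurement_type)
  stopifnot(is.data.frame(records), nrow(records) > 0,
            potency_threshold_nm > 0)
  keep <- records$measurement_type == measurement_type &
    !is.na(records$relation) & records$relation == "=" &
    !is.na(records$value_nm) & records$value_nm > 0 &
    records$value_nm <= potency_threshold_nm
  kept <- tibble::as_tibble(records[keep, ])
  if (nrow(kept) == 0) {
    rlang::abort(paste0("empty dataset: no ", measurement_type,
                        " records with relation '=' at or below ",
                        potency_threshold_nm, " nM"),
                 class = "csmtools_empty_result")
  }
  kept$canonical <- desalt_smiles(kept$smiles)
  # merge compound ids mapping to the same canonical structure
  id_map <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(kept, .data$compound_id, .data$canonical),
                    .data$canonical),
    representative = lex_sort(.data$compound_id)[1],
    merged_ids = list(lex_sort(.data$compound_id)),
    .groups = "drop"
  )
  kept <- dplyr::left_join(kept, id_map, by = "canonical")
  activities <- dplyr::summarise(
    dplyr::group_by(kept, compound_id = .data$representative,
                    target_id = .data$target_id),
    target_family = dplyr::first(.data$target_family),
    value_nm = exp(mean(log(.data$value_nm))),
    .groups = "drop"
  )
  compounds <- tibble::tibble(compound_id = id_map$representative,
                              smiles = id_map$canonical,
                              merged_ids = id_map$merged_ids)
  compounds <- compounds[lex_order(compounds$compound_id), ]
  activities <- activities[lex_order(activities$compound_id, activities$target_id), ]
  structure(list(compounds = compounds,
                 activities = activities,
                 measurement_type = measurement_type,
                 potency_threshold_nm = potency_threshold_nm),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated ", x$measurement_type, " dataset: ",
      nrow(x$compounds), " compounds, ",
      nrow(x$activities), " compound-target activities, ",
      length(unique(x$activities$target_id)), " targets (potency <= ",
      x$potency_threshold_nm, " nM)\n", sep = "")
  invisible(x)
}

#' @rdname curate_activities
#' @param x A `curated_dataset`.
#' @param ... Unused.
#' @method tidy curated_dataset
#' @export
tidy.curated_dataset <- function(x, ...) {
  act <- dplyr::left_join(x$activities, x$compounds[, c("compound_id", "smiles")],
                          by = "compound_id")
  tibble::tibble(
    compound_id = act$compound_id,
    smiles = act$smiles,
    target_id = act$target_id,
    target_family = act$target_family,
    measurement_type = x$measurement_type,
    relation = "=",
    value_nm = act$value_nm,
    active_flag = NA
  )
}

#' @rdname curate_activities
#' @method glance curated_dataset
#' @export
glance.curated_dataset <- function(x, ...) {
  tibble::tibble(
    measurement_type = x$measurement_type,
    potency_threshold_nm = x$potency_threshold_nm,
    n_compounds = nrow(x$compounds),
    n_targets = length(unique(x$activities$target_id)),
    n_activities = nrow(x$activities)
  )
}

#' Per-compound target profiles
#'
#' One profile per curated compound with its set of distinct active targets
#' and the target count T, the per-compound promiscuity measure.
#'
#' @param dataset A `curated_dataset` from [curate_activities()], or an
#'   activity tibble with columns `compound_id` and `target_id`.
#' @return A tibble with columns `compound_id`, `targets` (list of character
#'   vectors) and `target_count`.
#' @export
build_profiles <- function(dataset) {
  act <- if (inherits(dataset, "curated_dataset")) dataset$activities else {
    stopifnot(is.data.frame(dataset),
              all(c("compound_id", "target_id") %in% names(dataset)))
    tibble::as_tibble(dataset)
  }
  prof <- dplyr::summarise(
    dplyr::group_by(act, .data$compound_id),
    targets = list(lex_sort(unique(.data$target_id))),
    .groups = "drop"
  )
  prof$target_count <- vapply(prof$targets, length, integer(1))
  prof[lex_order(prof$compound_id), ]
}

#' Profiles from a binary matrix, keeping inactive compounds
#'
#' Unlike [build_profiles()], all-zero rows are kept with `target_count = 0`;
#' inactive compounds stay in probability denominators and distributions of
#' binary profiling analyses but are excluded from promiscuity rates.
#'
#' @param mat A `binary_matrix` from [read_binary_matrix()].
#' @return Profile tibble with columns `compound_id`, `targets`,
#'   `target_count` (zero allowed).
#' @export
binary_profiles <- function(mat) {
  targets <- setdiff(names(mat), c("compound_id", "smiles"))
  cells <- as.matrix(mat[, targets, drop = FALSE])
  tibble::tibble(
    compound_id = mat$compound_id,
    targets = lapply(seq_len(nrow(cells)), function(i) {
      lex_sort(targets[cells[i, ] == 1])
    }),
    target_count = as.integer(rowSums(cells))
  )
}
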