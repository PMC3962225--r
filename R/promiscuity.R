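# Promiscuity summary statistics over target profiles: global rates,
# threshold probabilities, target-count distributions, and stratification by
# target family and molecular-weight bin.
#
# A promiscuity rate is the mean target count over MULTI-target compounds
# only; including single-target compounds would depress the rate, so they are
# excluded from the mean but kept in probability denominators and in the
# distribution. Inactive compounds (T = 0, binary matrices) likewise stay in
# denominators and distributions but never enter the rate.

#' Summarize compound promiscuity
#'
#' @param profiles Profile tibble (`compound_id`, `target_count`; see
#'   [build_profiles()] and [binary_profiles()]).
#' @return A `promiscuity_summary` object with fields `n_compounds_total`,
#'   `n_multi_target`, `rate` (mean T over compounds with T >= 2; `NA` when
#'   no compound is multi-target), `p_at_least_2`, `p_more_than_5` (fractions
#'   of all compounds) and `distribution` (tibble `target_count`,
#'   `n_compounds`).
#' @export
#' @examples
#' prof <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
#'                        target_count = c(1L, 1L, 2L, 6L))
#' summarize_promiscuity(prof)
summarize_promiscuity <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0,
            "target_count" %in% names(profiles))
  t <- as.integer(profiles$target_count)
  stopifnot(all(t >= 0))
  multi <- t[t >= 2]
  dist <- dplyr::count(tibble::tibble(target_count = t), .data$target_count,
                       name = "n_compounds")
  structure(list(
    n_compounds_total = length(t),
    n_multi_target = length(multi),
    rate = if (length(multi) > 0) mean(multi) else NA_real_,
    p_at_least_2 = mean(t >= 2),
    p_more_than_5 = mean(t > 5),
    distribution = dist
  ), class = "promiscuity_summary")
}

#' @export
print.promiscuity_summary <- function(x, ...) {
  cat("Promiscuity summary over ", x$n_compounds_total, " compounds\n",
      "  multi-target compounds: ", x$n_multi_target, "\n",
      "  promiscuity rate (mean T | T >= 2): ",
      if (is.na(x$rate)) "undefined (no multi-target compound)" else
        formatC(x$rate, digits = 3, format = "fg"), "\n",
      "  P(T >= 2): ", formatC(x$p_at_least_2, digits = 3, format = "fg"), "\n",
      "  P(T > 5):  ", formatC(x$p_more_than_5, digits = 3, format = "fg"), "\n",
      sep = "")
  invisible(x)
}

#' @rdname summarize_promiscuity
#' @param x A `promiscuity_summary`.
#' @param ... Unused.
#' @method tidy promiscuity_summary
#' @export
tidy.promiscuity_summary <- function(x, ...) x$distribution

#' @rdname summarize_promiscuity
#' @method glance promiscuity_summary
#' @export
glance.promiscuity_summary <- function(x, ...) {
  tibble::tibble(n_compounds_total = x$n_compounds_total,
                 n_multi_target = x$n_multi_target,
                 rate = x$rate,
                 p_at_least_2 = x$p_at_least_2,
                 p_more_than_5 = x$p_more_than_5)
}

# Normalize a target->family mapping to a tibble(target_id, family).
as_family_table <- function(target_families) {
  if (is.data.frame(target_families)) {
    stopifnot(all(c("target_id", "family") %in% names(target_families)))
    return(dplyr::distinct(tibble::as_tibble(target_families[, c("target_id", "family")])))
  }
  if (is.character(target_families) && !is.null(names(target_families))) {
    return(tibble::tibble(target_id = names(target_families),
                          family = unname(target_families)))
  }
  rlang::abort("target families must be a data frame (target_id, family) or a named vector",
               class = "csmtools_input_error")
}

#' Promiscuity within one target family
#'
#' Restricts every compound's target set to targets of the given family and
#' summarizes the restricted profiles; the multi-target condition of the rate
#' applies within the family, so a compound active against one family target
#' and many others contributes to the family's denominator but not its rate.
#' Compounds with no target in the family are not active against the family
#' and are dropped.
#'
#' @param profiles Profile tibble with a `targets` list-column.
#' @param target_families Mapping target -> family (tibble with `target_id`,
#'   `family`, or a named character vector).
#' @param family Family label to summarize.
#' @return A `promiscuity_summary` over the family-restricted profiles.
#' @export
summarize_by_family <- function(profiles, target_families, family) {
  fam <- as_family_table(target_families)
  if (!family %in% fam$family) {
    rlang::abort(paste0("family '", family, "' absent from the family map"),
                 class = "csmtools_input_error")
  }
  fam_targets <- fam$target_id[fam$family == family]
  restricted <- vapply(profiles$targets, function(tg) {
    length(intersect(tg, fam_targets))
  }, integer(1))
  keep <- restricted >= 1
  if (!any(keep)) {
    rlang::abort(paste0("no compound is active against family '", family, "'"),
                 class = "csmtools_empty_result")
  }
  summarize_promiscuity(tibble::tibble(
    compound_id = profiles$compound_id[keep],
    target_count = restricted[keep]
  ))
}

#' Molecular-weight bin specification
#'
#' Left-open bins in Da; the default follows a 100-Da progression from the
#' 200-Da boundary of the smallest-compound subset up to 700 Da, with an open
#' last bin.
#'
#' @param edges Strictly increasing bin edges in Da; bins are
#'   `(edges[i], edges[i+1]]` plus an open last bin `(max(edges), Inf)`.
#' @return An object of class `mw_bins`.
#' @export
mw_bins <- function(edges = c(0, 200, 300, 400, 500, 600, 700)) {
  stopifnot(is.numeric(edges), length(edges) >= 2, all(diff(edges) > 0))
  structure(list(edges = edges), class = "mw_bins")
}

mw_bin_labels <- function(bins) {
  e <- bins$edges
  inner <- paste0("(", e[-length(e)], ",", e[-1], "]")
  c(inner, paste0("(", e[length(e)], ",Inf)"))
}

#' Promiscuity stratified by molecular weight
#'
#' Assigns each profiled compound to exactly one MW bin (weights computed
#' from the desalted structure; values at a bin edge fall in the lower bin;
#' values beyond the last edge go to the open last bin, never dropped) and
#' summarizes promiscuity per bin.
#'
#' @param profiles Profile tibble.
#' @param structures Tibble with `compound_id` and `smiles` covering every
#'   profiled compound.
#' @param bins An [mw_bins()] specification.
#' @return A tibble with one row per populated bin: `bin`, `mw_lo`, `mw_hi`,
#'   `n_compounds`, `n_multi_target`, `rate`, `p_at_least_2`, `p_more_than_5`
#'   and a `summary` list-column of `promiscuity_summary` objects.
#' @export
summarize_by_mw <- function(profiles, structures, bins = mw_bins()) {
  stopifnot(is.data.frame(structures),
            all(c("compound_id", "smiles") %in% names(structures)))
  idx <- match(profiles$compound_id, structures$compound_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("no structure for compound '",
                        profiles$compound_id[which(is.na(idx))[1]], "'"),
                 class = "csmtools_input_error")
  }
  mw <- molecular_weight(structures$smiles[idx])
  if (anyNA(mw)) {
    rlang::abort(paste0("unparseable structure for compound '",
                        profiles$compound_id[which(is.na(mw))[1]], "'"),
                 class = "csmtools_parse_error")
  }
  edges <- c(bins$edges, Inf)
  labels <- mw_bin_labels(bins)
  assignment <- cut(mw, breaks = edges, labels = labels, right = TRUE)
  # weights at or below the first edge belong to the first bin
  assignment[is.na(assignment) & mw <= bins$edges[1]] <- labels[1]
  per_bin <- lapply(split(seq_len(nrow(profiles)), assignment), function(i) {
    if (length(i) == 0) return(NULL)
    summarize_promiscuity(profiles[i, ])
  })
  keep <- !vapply(per_bin, is.null, logical(1))
  res <- tibble::tibble(
    bin = factor(names(per_bin)[keep], levels = labels),
    summary = unname(per_bin[keep])
  )
  res$mw_lo <- edges[as.integer(res$bin)]
  res$mw_hi <- edges[as.integer(res$bin) + 1]
  g <- dplyr::bind_rows(lapply(res$summary, glance))
  res <- dplyr::bind_cols(res[, c("bin", "mw_lo", "mw_hi")],
                          g[, c("n_compounds_total", "n_multi_target", "rate",
                                "p_at_least_2", "p_more_than_5")],
                          res[, "summary"])
  dplyr::rename(res, n_compounds = "n_compounds_total")
}

#' Fraction of highly promiscuous compounds
#'
#' Fraction of all profiles (including inactive, T = 0 compounds of binary
#' matrices) with a target count strictly above `threshold`.
#'
#' @param profiles Profile tibble.
#' @param threshold Positive integer target-count threshold.
#' @return A single fraction in `[0, 1]`.
#' @export
high_promiscuity_fraction <- function(profiles, threshold) {
  stopifnot(threshold >= 1)
  mean(profiles$target_count > threshold)
}
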