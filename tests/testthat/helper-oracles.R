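# Test helpers: a deterministic compound library, independent brute-force
# oracles for MMP and target-network construction, and an alternative-SMILES
# re-encoder based on the OpenBabel command-line tool.

# Deterministic library of valid drug-like SMILES: substituted benzenes and
# branched chains assembled from templates. `min_heavy` filters to molecules
# with at least that many heavy atoms (so any first-atom index up to
# `min_heavy` is a valid re-encoding seed).
compound_library <- function(n, seed = 1, min_heavy = 0) {
  subs <- c("CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCN", "OCC", "OC(C)C",
            "CCCl", "CC(C)O", "CCOC", "CCSC")
  chains <- c("CCCCCCCCCC", "CCCC(C)CCCCC", "CCC(CC)CCCCC", "CCCCOCCCCC",
              "CCCCNCCCCC", "CCC(C)CC(C)CCC", "CCCCC(O)CCCC", "CCCCSCCCCC")
  pairs <- expand.grid(a = subs, b = subs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, ]
  pool <- c(paste0(subs, "c1ccccc1"),
            paste0(pairs$a, "c1ccc(", pairs$b, ")cc1"),
            paste0(pairs$a, "c1cccc(", pairs$b, ")c1"),
            chains)
  withr::with_seed(seed, {
    can <- unique(canonical_smiles(pool, strict = TRUE))
    if (min_heavy > 0) {
      can <- can[csmtools:::fragment_heavy_atoms(can) >= min_heavy]
    }
    stopifnot(length(can) >= n)
    sample(can, n)
  })
}

# Brute-force MMP oracle: compares the fragmentation sets of every compound
# pair directly (O(n^2) over fragmentations), applying the same size
# restrictions, per-pair largest-core selection and transformation
# orientation as the spec of the indexed generator, but without any core
# index.
oracle_mmps <- function(structures, limits = size_limits()) {
  ids <- structures$compound_id
  frags <- lapply(seq_len(nrow(structures)), function(i) {
    f <- enumerate_fragmentations(structures$smiles[i], id = ids[i])
    f[passes_size_restrictions(f, limits), ]
  })
  rows <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fi <- frags[[i]]; fj <- frags[[j]]
      if (nrow(fi) == 0 || nrow(fj) == 0) next
      cand <- NULL
      for (k in seq_len(nrow(fi))) {
        match_rows <- which(fj$core == fi$core[k] &
                              fj$substituent != fi$substituent[k])
        for (l in match_rows) {
          if (abs(fi$substituent_heavy_atoms[k] -
                    fj$substituent_heavy_atoms[l]) > limits$max_exchange_delta) next
          cand <- rbind(cand, data.frame(
            core = fi$core[k], core_heavy_atoms = fi$core_heavy_atoms[k],
            sub_i = fi$substituent[k], sub_j = fj$substituent[l],
            stringsAsFactors = FALSE))
        }
      }
      if (is.null(cand)) next
      cand <- cand[order(-cand$core_heavy_atoms, cand$core, cand$sub_i,
                         cand$sub_j, method = "radix"), ]
      best <- cand[1, ]
      first <- sort(c(best$sub_i, best$sub_j), method = "radix")[1]
      if (first == best$sub_i) {
        rows[[length(rows) + 1]] <- data.frame(
          compound_a = ids[i], compound_b = ids[j], core = best$core,
          substituent_a = best$sub_i, substituent_b = best$sub_j,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          compound_a = ids[j], compound_b = ids[i], core = best$core,
          substituent_a = best$sub_j, substituent_b = best$sub_i,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(compound_a = character(0), compound_b = character(0),
                      core = character(0), substituent_a = character(0),
                      substituent_b = character(0)))
  }
  do.call(rbind, rows)
}

mmp_key <- function(df) {
  sort(paste(df$compound_a, df$compound_b, df$core,
             df$substituent_a, df$substituent_b, sep = "|"))
}

# Brute-force target network oracle: explicit pairwise set intersections.
oracle_target_edges <- function(profiles, min_shared) {
  targets <- sort(unique(unlist(profiles$targets)))
  rows <- list()
  if (length(targets) >= 2) {
    for (i in seq_len(length(targets) - 1)) {
      for (j in (i + 1):length(targets)) {
        shared <- sum(vapply(profiles$targets, function(tg) {
          targets[i] %in% tg && targets[j] %in% tg
        }, logical(1)))
        if (shared >= min_shared) {
          rows[[length(rows) + 1]] <- data.frame(
            target_a = targets[i], target_b = targets[j],
            shared_compounds = shared, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target_a = character(0), target_b = character(0),
                      shared_compounds = integer(0)))
  }
  do.call(rbind, rows)
}

# Alternative (non-canonical) SMILES encodings of the same molecules, using
# the OpenBabel CLI first-atom output option. `first_atom` must not exceed
# the smallest heavy-atom count in `smiles`.
reencode_smiles <- function(smiles, first_atom) {
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".smi")
  writeLines(paste0(smiles, "\t", seq_along(smiles)), inp)
  res <- suppressWarnings(system2("obabel",
                                  c("-ismi", inp, "-osmi", "-O", out,
                                    "-xf", first_atom),
                                  stdout = FALSE, stderr = FALSE))
  stopifnot(res == 0)
  lines <- readLines(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- rep(NA_character_, length(smiles))
  for (p in parts) {
    idx <- suppressWarnings(as.integer(trimws(p[2])))
    if (!is.na(idx)) got[idx] <- p[1]
  }
  got
}

# random sparse profile set for network tests
random_profiles <- function(n_compounds, n_targets, rate, seed) {
  withr::with_seed(seed, {
    tids <- sprintf("T%02d", seq_len(n_targets))
    tibble::tibble(
      compound_id = sprintf("c%03d", seq_len(n_compounds)),
      targets = lapply(seq_len(n_compounds), function(i) {
        sort(tids[stats::runif(n_targets) < rate])
      })
    ) -> prof
    prof$target_count <- vapply(prof$targets, length, integer(1))
    prof[prof$target_count >= 1, ]
  })
}

# tiny long-CSV activity fixture written to a temp file
write_toy_activity_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "compound_id,smiles,target_id,target_family,measurement_type,relation,value_nM"
  writeLines(c(header, rows), path)
  path
}
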