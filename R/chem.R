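# Molecular structure backend.
#
# All structure handling runs through OpenBabel (via ChemmineOB) and ChemmineR:
# SMILES parsing, canonical SMILES, SDF construction and molecular weights.
# Molecules are held internally as plain molecular graphs (atom symbol vector +
# bond matrix) extracted from ChemmineR SDF objects, which is the form the
# fragmentation machinery operates on.
#
# Supported chemistry: neutral organic molecules without stereo annotations.
# Attachment points are wildcard atoms ("*"); the inert core-level attachment
# marker is astatine ("At"), an element that never occurs in drug-like inputs.

# Conversion cache: canonical SMILES and fragmentation results are memoised
# per input string for the lifetime of the session.
.chem_cache <- new.env(parent = emptyenv())

ATTACHMENT <- "*"
CORE_MARKER <- "At"
# canonical token OpenBabel assigns to the hydrogen substituent [*][H]
H_SUBSTITUENT <- "[*H]"

ob_options <- function(...) {
  opts <- c(...)
  data.frame(names = names(opts), args = unname(opts), stringsAsFactors = FALSE)
}

ob_convert <- function(text, from, to, options = NULL) {
  if (is.null(options)) {
    ChemmineOB::convertFormat(from, to, text)
  } else {
    ChemmineOB::convertFormat(from, to, text, options = options)
  }
}

#' Canonical SMILES
#'
#' Converts SMILES strings to OpenBabel canonical SMILES. Invalid structures
#' yield `NA` unless `strict = TRUE`, in which case an error naming the
#' offending input is raised.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict Error on unparseable input instead of returning `NA`?
#' @return Character vector of canonical SMILES, same length as `smiles`.
#' @export
#' @examples
#' \donttest{
#' canonical_smiles(c("OCC", "c1ccccc1C"))
#' }
canonical_smiles <- function(smiles, strict = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  key <- paste0("can:", smiles)
  out <- vapply(key, function(k) {
    if (exists(k, envir = .chem_cache)) get(k, envir = .chem_cache) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  todo <- which(is.na(out) & !is.na(smiles))
  if (length(todo) > 0) {
    uniq <- unique(smiles[todo])
    inp <- paste0(uniq, "\t", seq_along(uniq), "\n", collapse = "")
    res <- ob_convert(inp, "SMI", "CAN")
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got <- rep(NA_character_, length(uniq))
    for (p in parts) {
      idx <- suppressWarnings(as.integer(p[2]))
      if (!is.na(idx)) got[idx] <- p[1]
    }
    for (i in seq_along(uniq)) {
      assign(paste0("can:", uniq[i]), got[i], envir = .chem_cache)
    }
    out[todo] <- got[match(smiles[todo], uniq)]
  }
  if (strict && anyNA(out[!is.na(smiles)])) {
    bad <- smiles[is.na(out) & !is.na(smiles)]
    rlang::abort(
      paste0("unparseable structure(s): ", paste(utils::head(bad, 5), collapse = ", ")),
      class = "csmtools_parse_error"
    )
  }
  out
}

#' Strip salts and counterions
#'
#' Keeps the largest covalent component of each (possibly multi-component)
#' SMILES, the conventional preprocessing step before structure
#' deduplication of database exports. Ties are broken by taking the
#' lexicographically smallest canonical component.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of desalted canonical SMILES.
#' @export
desalt_smiles <- function(smiles) {
  can <- canonical_smiles(smiles, strict = TRUE)
  vapply(can, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    comp <- strsplit(s, ".", fixed = TRUE)[[1]]
    sizes <- vapply(comp, count_heavy_atoms_smiles, numeric(1))
    comp <- comp[order(-sizes, comp, method = "radix")]
    canonical_smiles(comp[1], strict = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

# Heavy atom count straight off a SMILES string: count element tokens,
# excluding H, the wildcard and the core marker. Used only for desalting
# tie-breaks; graph-derived counts are used everywhere else.
count_heavy_atoms_smiles <- function(s) {
  toks <- gregexpr("Cl|Br|Si|Se|At|\\[[^]]+\\]|[BCNOPSFI]|[bcnops]", s)[[1]]
  if (toks[1] == -1) return(0)
  m <- regmatches(s, gregexpr("Cl|Br|Si|Se|At|\\[[^]]+\\]|[BCNOPSFI]|[bcnops]", s))[[1]]
  sum(!grepl("^\\[?\\*|At|^\\[H", m))
}

# --- molecular graphs --------------------------------------------------------

# Parse SMILES into molecular graphs. Returns a list (one element per input,
# NULL where unparseable) of lists with fields:
#   atoms: character vector of element symbols ("C", "N", "*", "At", "H", ...)
#   bonds: integer matrix with columns a, b, order (1-based atom indices)
#   hcount: integer vector of attached explicit hydrogens (only if add_h)
# Atom coordinates are irrelevant and discarded; bond orders come kekulized
# from OpenBabel so fragment SDF blocks stay valid.
parse_molecules <- function(smiles, add_h = FALSE) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0) return(list())
  opts <- if (add_h) ob_options(h = "", gen2D = "") else NULL
  inp <- paste0(smiles, "\t", seq_len(n), "\n", collapse = "")
  sdfstr <- ob_convert(inp, "SMI", "SDF", options = opts)
  out <- vector("list", n)
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(out)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines)))
  for (i in seq_along(ChemmineR::sdfid(sdfset))) {
    sdf <- sdfset[[i]]
    idx <- suppressWarnings(as.integer(ChemmineR::sdfid(sdfset)[i]))
    if (is.na(idx)) next
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    atoms <- sub("_\\d+$", "", rownames(ab))
    bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
      cbind(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]), order = as.integer(bb[, 3]))
    } else {
      bb <- matrix(0, 0, 7)
      cbind(a = integer(0), b = integer(0), order = integer(0))
    }
    mol <- list(atoms = atoms, bonds = bonds,
                atomblock = ab, bondblock = bb)
    if (add_h) {
      hc <- integer(length(atoms))
      if (nrow(bonds) > 0) {
        for (k in seq_len(nrow(bonds))) {
          a <- bonds[k, 1]; b <- bonds[k, 2]
          if (atoms[b] == "H") hc[a] <- hc[a] + 1L
          if (atoms[a] == "H") hc[b] <- hc[b] + 1L
        }
      }
      mol$hcount <- hc
    }
    out[[idx]] <- mol
  }
  out
}

# Build a V2000 MOL block (as a single string, $$$$-terminated) for a subset
# of atoms of a parsed molecule plus optional extra atoms/bonds. `keep` is an
# integer vector of original atom indices; `extra_atoms` a character vector of
# symbols appended after them; `extra_bonds` a matrix (a, b, order) in the NEW
# (local) indexing.
mol_block <- function(mol, keep, extra_atoms = character(0), extra_bonds = NULL,
                      title = "frag", relabel = NULL) {
  ab <- mol$atomblock[keep, , drop = FALSE]
  if (!is.null(relabel)) {
    rn <- rownames(ab)
    for (j in seq_along(relabel$at)) {
      rn[relabel$at[j]] <- relabel$sym[j]
    }
    rownames(ab) <- rn
  }
  if (length(extra_atoms) > 0) {
    pad <- matrix(0, length(extra_atoms), ncol(ab),
                  dimnames = list(extra_atoms, colnames(ab)))
    ab <- rbind(ab, pad)
  }
  # row names carry the element symbols; re-suffix them uniquely
  rownames(ab) <- paste0(sub("_\\d+$", "", rownames(ab)), "_", seq_len(nrow(ab)))
  # remap bonds among kept atoms
  map <- integer(length(mol$atoms))
  map[keep] <- seq_along(keep)
  bb <- mol$bonds
  sel <- bb[, 1] %in% keep & bb[, 2] %in% keep
  bb <- bb[sel, , drop = FALSE]
  nb <- cbind(map[bb[, 1]], map[bb[, 2]], bb[, 3])
  if (!is.null(extra_bonds)) nb <- rbind(nb, extra_bonds)
  zeros <- matrix(0, nrow(nb), max(0, ncol(mol$bondblock) - 3))
  bbm <- cbind(nb, zeros)
  colnames(bbm) <- colnames(mol$bondblock)[seq_len(ncol(bbm))]
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(ab), nrow(bbm))
  sdf <- methods::new("SDF",
                      header = c(Molecule_Name = title, Source = "", Comment = "",
                                 Counts_Line = counts),
                      atomblock = ab, bondblock = bbm, datablock = character(0))
  paste(ChemmineR::sdf2str(sdf), collapse = "\n")
}

# Canonicalize a batch of MOL blocks (each a $$$$-terminated string whose
# title is its 1-based index). Returns canonical SMILES, NA where conversion
# failed.
canonicalize_mol_blocks <- function(blocks, n_out = length(blocks)) {
  if (length(blocks) == 0) return(rep(NA_character_, n_out))
  res <- ob_convert(paste(blocks, collapse = "\n"), "SDF", "CAN")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- rep(NA_character_, n_out)
  for (p in parts) {
    idx <- suppressWarnings(as.integer(p[2]))
    if (!is.na(idx) && idx <= length(out)) out[idx] <- p[1]
  }
  out
}

# Number of heavy atoms in a parsed fragment graph, excluding hydrogens,
# wildcards and the core marker.
n_heavy <- function(atoms) sum(!(atoms %in% c("H", ATTACHMENT, CORE_MARKER)))

#' Molecular weight from SMILES
#'
#' Computes the molecular weight (Da) of each structure after salt stripping,
#' including implicit hydrogens.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of molecular weights in Da.
#' @export
molecular_weight <- function(smiles) {
  if (length(smiles) == 0) return(numeric(0))
  des <- desalt_smiles(smiles)
  uniq <- unique(des)
  inp <- paste0(uniq, "\t", seq_along(uniq), "\n", collapse = "")
  sdfstr <- ob_convert(inp, "SMI", "SDF", options = ob_options(h = "", gen2D = ""))
  sdfset <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))
  )
  mw <- suppressWarnings(ChemmineR::MW(sdfset))
  idx <- as.integer(ChemmineR::sdfid(sdfset))
  vals <- rep(NA_real_, length(uniq))
  vals[idx] <- unname(mw)
  vals[match(des, uniq)]
}

# Convert fragment cores (wildcard attachment) to standalone molecules with
# the inert [At] marker in place of the wildcard, and back. Used by the
# second, core-level MMP round: the marker is a real atom OpenBabel keeps
# through canonicalization but that the fragmenter never cuts.
core_to_marker <- function(cores) {
  mols <- parse_molecules(cores)
  blocks <- character(length(cores))
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    if (is.null(mol)) rlang::abort(paste0("unparseable core: ", cores[i]),
                                   class = "csmtools_parse_error")
    star <- which(mol$atoms == ATTACHMENT)
    if (length(star) != 1) {
      rlang::abort(paste0("core must have exactly one attachment point: ", cores[i]),
                   class = "csmtools_input_error")
    }
    blocks[i] <- mol_block(mol, keep = seq_along(mol$atoms), title = as.character(i),
                           relabel = list(at = star, sym = CORE_MARKER))
  }
  canonicalize_mol_blocks(blocks)
}

marker_to_core <- function(marked) {
  mols <- parse_molecules(marked)
  blocks <- character(length(marked))
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    if (is.null(mol)) rlang::abort(paste0("unparseable structure: ", marked[i]),
                                   class = "csmtools_parse_error")
    at <- which(mol$atoms == CORE_MARKER)
    blocks[i] <- mol_block(mol, keep = seq_along(mol$atoms), title = as.character(i),
                           relabel = list(at = at, sym = ATTACHMENT))
  }
  canonicalize_mol_blocks(blocks)
}

#' Reassemble a core and a substituent into a full structure
#'
#' Joins two single-attachment-point fragments with a single bond at their
#' attachment points, the inverse of a single-cut fragmentation. The hydrogen
#' substituent (`"[*H]"`) caps the core's attachment point with an implicit
#' hydrogen.
#'
#' @param core,substituent Character vectors of fragment SMILES, each with
#'   exactly one `*` attachment point. Recycled against each other.
#' @return Character vector of canonical SMILES of the assembled molecules;
#'   `NA` where assembly was not chemically possible.
#' @export
#' @examples
#' \donttest{
#' reassemble_fragments("*c1ccccc1", "*CC")  # ethylbenzene
#' }
reassemble_fragments <- function(core, substituent) {
  n <- max(length(core), length(substituent))
  core <- rep_len(core, n)
  substituent <- rep_len(substituent, n)
  cores <- parse_molecules(core)
  subs_h <- substituent == H_SUBSTITUENT
  subs <- vector("list", n)
  if (any(!subs_h)) subs[!subs_h] <- parse_molecules(substituent[!subs_h])
  blocks <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cm <- cores[[i]]
    if (is.null(cm)) next
    cstar <- which(cm$atoms == ATTACHMENT)
    if (length(cstar) != 1) next
    cnb <- bond_neighbors(cm, cstar)
    if (length(cnb) != 1) next
    keep_c <- setdiff(seq_along(cm$atoms), cstar)
    if (subs_h[i]) {
      # capping with hydrogen: drop the wildcard, implicit valence fills in
      blocks[i] <- mol_block(cm, keep = keep_c, title = as.character(i))
      next
    }
    sm <- subs[[i]]
    if (is.null(sm)) next
    sstar <- which(sm$atoms == ATTACHMENT)
    if (length(sstar) != 1) next
    snb <- bond_neighbors(sm, sstar)
    if (length(snb) != 1) next
    # merged graph: core heavy part, then substituent heavy part
    merged <- merge_graphs(cm, keep_c, sm, setdiff(seq_along(sm$atoms), sstar))
    a_local <- match(cnb, keep_c)
    b_local <- length(keep_c) + match(snb, setdiff(seq_along(sm$atoms), sstar))
    merged$extra_bonds <- rbind(c(a_local, b_local, 1L))
    blocks[i] <- merged_block(merged, title = as.character(i))
  }
  ok <- !is.na(blocks)
  canonicalize_mol_blocks(blocks[ok], n_out = n)
}

bond_neighbors <- function(mol, idx) {
  bb <- mol$bonds
  c(bb[bb[, 1] == idx, 2], bb[bb[, 2] == idx, 1])
}

# Combine two molecules' kept-atom subgraphs into one block-buildable object.
merge_graphs <- function(m1, keep1, m2, keep2) {
  ab <- rbind(m1$atomblock[keep1, , drop = FALSE],
              m2$atomblock[keep2, , drop = FALSE])
  rownames(ab) <- paste0(sub("_\\d+$", "", rownames(ab)), "_", seq_len(nrow(ab)))
  map1 <- integer(length(m1$atoms)); map1[keep1] <- seq_along(keep1)
  map2 <- integer(length(m2$atoms)); map2[keep2] <- length(keep1) + seq_along(keep2)
  b1 <- m1$bonds[m1$bonds[, 1] %in% keep1 & m1$bonds[, 2] %in% keep1, , drop = FALSE]
  b2 <- m2$bonds[m2$bonds[, 1] %in% keep2 & m2$bonds[, 2] %in% keep2, , drop = FALSE]
  nb <- rbind(cbind(map1[b1[, 1]], map1[b1[, 2]], b1[, 3]),
              cbind(map2[b2[, 1]], map2[b2[, 2]], b2[, 3]))
  list(atomblock = ab, bonds = nb, ncol_bb = ncol(m1$bondblock))
}

merged_block <- function(merged, title) {
  nb <- rbind(merged$bonds, merged$extra_bonds)
  zeros <- matrix(0, nrow(nb), max(0, merged$ncol_bb - 3))
  bbm <- cbind(nb, zeros)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(merged$atomblock), nrow(bbm))
  sdf <- methods::new("SDF",
                      header = c(Molecule_Name = title, Source = "", Comment = "",
                                 Counts_Line = counts),
                      atomblock = merged$atomblock, bondblock = bbm,
                      datablock = character(0))
  paste(ChemmineR::sdf2str(sdf), collapse = "\n")
}

# Locale-independent lexicographic helpers used for all deterministic
# orderings (transformation direction, row/column sorting, tie-breaks).
lex_sort <- function(x) sort(x, method = "radix")
lex_order <- function(...) order(..., method = "radix")
lex_lt <- function(a, b) {
  # TRUE where a sorts strictly before b under C-locale byte order
  vapply(seq_along(a), function(i) {
    a[i] != b[i] && lex_sort(c(a[i], b[i]))[1] == a[i]
  }, logical(1))
}
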