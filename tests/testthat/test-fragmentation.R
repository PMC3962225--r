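# single-cut fragmentation, size restrictions, compound- and core-level MMPs

test_that("eligible cuts are exactly the acyclic heavy-atom single bonds", {
  # ethylbenzene: 2 eligible cuts, both orientations emitted
  f <- enumerate_fragmentations("CCc1ccccc1")
  expect_equal(nrow(f), 4)
  expect_true(all(c("*c1ccccc1", "*CC") %in% f$core) ||
                any(f$core == "*c1ccccc1" & f$substituent == "*CC"))
  phenyl_cut <- f[f$core == "*c1ccccc1", ]
  expect_equal(phenyl_cut$substituent, "*CC")
  expect_equal(phenyl_cut$core_heavy_atoms, 6L)
  expect_equal(phenyl_cut$substituent_heavy_atoms, 2L)
  # single heavy atom: nothing to cut
  expect_equal(nrow(enumerate_fragmentations("C")), 0)
  # rings are never cut
  expect_equal(nrow(enumerate_fragmentations("c1ccccc1")), 0)
  expect_equal(nrow(enumerate_fragmentations("C1CCCCC1")), 0)
  # double bonds are not cut: acrylate ester has only single-bond cuts
  f2 <- enumerate_fragmentations("C=CC(=O)OC")
  expect_false(any(f2$core == "*C" & f2$substituent == "*C=C"  &
                     f2$core_heavy_atoms == 1))
  expect_error(enumerate_fragmentations("C1CC", id = "bad-input"),
               "bad-input", class = "csmtools_parse_error")
})

test_that("fragmentation sets are invariant to the input encoding", {
  mols <- compound_library(12, seed = 11)
  frag_key <- function(s) {
    f <- enumerate_fragmentations(s)
    sort(paste(f$core, f$substituent, sep = "|"))
  }
  ref <- lapply(mols, frag_key)
  for (fa in c(2, 5, 9)) {
    alt <- reencode_smiles(mols, fa)
    expect_false(anyNA(alt))
    for (i in seq_along(mols)) {
      expect_identical(frag_key(alt[i]), ref[[i]],
                       label = paste("encoding", fa, "of", mols[i]))
    }
  }
})

test_that("size restrictions implement the substituent and ratio limits", {
  f <- tibble::tibble(core_heavy_atoms = c(10L, 4L, 30L, 26L),
                      substituent_heavy_atoms = c(3L, 5L, 14L, 13L))
  expect_equal(passes_size_restrictions(f, size_limits()),
               c(TRUE, FALSE, FALSE, TRUE))
  loose <- size_limits(max_substituent = 14, core_to_substituent_ratio = 1)
  expect_equal(passes_size_restrictions(f, loose), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("MMP generation matches hand-derived toy cases", {
  trio <- tibble::tibble(compound_id = c("tol", "eb", "pb"),
                         smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"))
  m <- generate_mmps(trio)
  expect_equal(nrow(m), 3)  # every pair is an MMP
  expect_setequal(paste(m$compound_a, m$compound_b),
                  c("tol eb", "tol pb", "eb pb"))
  # the ethyl/propyl pair shares the larger benzyl core, which wins dedup
  eb_pb <- m[m$compound_a %in% c("eb", "pb") & m$compound_b %in% c("eb", "pb"), ]
  expect_equal(eb_pb$core, "*Cc1ccccc1")
  # transformation is oriented lexicographically
  expect_true(all(m$substituent_a < m$substituent_b |
                    m$transformation == paste0(m$substituent_a, ">>",
                                               m$substituent_b)))
  # no fragmentations, no MMPs
  none <- generate_mmps(tibble::tibble(compound_id = c("bz", "py"),
                                       smiles = c("c1ccccc1", "c1ccncc1")))
  expect_equal(nrow(none), 0)
})

test_that("MMP output is independent of compound order and deduplicated", {
  mols <- compound_library(15, seed = 4)
  tbl <- tibble::tibble(compound_id = sprintf("m%02d", seq_along(mols)),
                        smiles = mols)
  m1 <- generate_mmps(tbl)
  m2 <- generate_mmps(tbl[rev(seq_len(nrow(tbl))), ])
  expect_identical(mmp_key(m1), mmp_key(m2))
  # at most one MMP per unordered compound pair
  pair_ids <- paste(pmin(m1$compound_a, m1$compound_b),
                    pmax(m1$compound_a, m1$compound_b))
  expect_equal(anyDuplicated(pair_ids), 0L)
})

test_that("core-level MMPs relate cores differing at a single site", {
  # H -> methyl
  cm <- core_level_mmps(c("*c1ccccc1", "*c1ccc(C)cc1"))
  expect_equal(nrow(cm), 1)
  expect_setequal(c(cm$substituent_a, cm$substituent_b), c("*C", "[*H]"))
  # unrelated ring systems share no sub-core
  expect_equal(nrow(core_level_mmps(c("*c1ccccc1", "*C1CCCCC1"))), 0)
  # a single core has no partner
  expect_equal(nrow(core_level_mmps("*c1ccccc1")), 0)
  # F -> Cl at the same position
  cm2 <- core_level_mmps(c("*c1ccc(F)cc1", "*c1ccc(Cl)cc1"))
  expect_equal(nrow(cm2), 1)
  expect_setequal(c(cm2$substituent_a, cm2$substituent_b), c("*F", "*Cl"))
  # the attachment marker itself is never treated as a cuttable substituent:
  # two copies of the same core yield nothing
  expect_equal(nrow(core_level_mmps(c("*c1ccccc1", "*c1ccccc1"))), 0)
})
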