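# analog series and Compound Series Matrix assembly

test_that("analog series collect all compounds sharing an MMP core", {
  tbl <- tibble::tibble(compound_id = c("tol", "eb"),
                        smiles = c("Cc1ccccc1", "CCc1ccccc1"))
  ser <- build_series(tbl)
  expect_equal(nrow(ser), 1)
  expect_equal(ser$core, "*c1ccccc1")
  expect_setequal(ser$members[[1]]$substituent, c("*C", "*CC"))
  # compounds with no MMP form no series
  none <- build_series(tibble::tibble(compound_id = c("bz", "py"),
                                      smiles = c("c1ccccc1", "c1ccncc1")))
  expect_equal(nrow(none), 0)
})

test_that("CSMs lay out related cores x substituent union with virtual cells", {
  # 2 related cores (phenyl, 4-F-phenyl), substituents Me/Et/Pr, 2 deletions
  tbl <- tibble::tibble(
    compound_id = c("a-me", "a-et", "a-pr", "b-me", "b-et"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
               "Cc1ccc(F)cc1", "CCc1ccc(F)cc1")
  )
  prof <- tibble::tibble(compound_id = tbl$compound_id,
                         targets = list("T1", c("T1", "T2"), "T1",
                                        c("T1", "T2", "T3"), "T1"),
                         target_count = c(1L, 2L, 1L, 3L, 1L))
  csms <- build_csms(build_series(tbl), prof)
  expect_equal(length(csms), 1)
  csm <- csms[[1]]
  expect_equal(length(csm$rows), 2)
  expect_equal(length(csm$columns), 3)
  expect_equal(sum(csm$cells$status == "real"), 5)
  expect_equal(sum(csm$cells$status == "virtual"), 1)
  virt <- csm$cells[csm$cells$status == "virtual", ]
  expect_equal(virt$substituent, "*CCC")   # b-pr is the missing analog
  # every real cell reassembles to its compound (canonical comparison)
  real <- csm$cells[csm$cells$status == "real", ]
  expect_equal(reassemble_fragments(real$core, real$substituent),
               canonical_smiles(real$smiles))
  # real + virtual = rows x columns
  expect_equal(nrow(csm$cells), length(csm$rows) * length(csm$columns))
  # per-cell target counts carried over
  expect_equal(real$target_count[real$compound_id == "b-me"], 3L)
})

test_that("unrelated series stay in separate components", {
  tbl <- tibble::tibble(
    compound_id = c("a1", "a2", "r1", "r2"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1",           # phenyl series
               "CC1CCCCC1C(=O)OC", "CCC1CCCCC1C(=O)OC")  # ester ring series
  )
  ser <- build_series(tbl)
  csms <- build_csms(ser)
  # phenyl and the substituted cyclohexane core are unrelated: each component
  # has one core, so no CSM is formed
  expect_equal(length(csms), 0)
})

test_that("promiscuous submatrix extraction prunes rows and columns", {
  tbl <- tibble::tibble(
    compound_id = c("a-me", "a-et", "a-pr", "b-me", "b-et", "b-pr"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
               "Cc1ccc(F)cc1", "CCc1ccc(F)cc1", "CCCc1ccc(F)cc1")
  )
  prof <- tibble::tibble(
    compound_id = tbl$compound_id,
    targets = lapply(c(12, 1, 1, 1, 1, 1), function(k) sprintf("T%02d", 1:k)),
    target_count = c(12L, 1L, 1L, 1L, 1L, 1L)
  )
  csms <- build_csms(build_series(tbl), prof)
  # ethyl/propyl analogs also relate through benzyl-type cores, giving a
  # second matrix; pick the phenyl-core one
  csm <- csms[[which(vapply(csms, function(x) "*c1ccccc1" %in% x$rows,
                            logical(1)))]]
  sub <- extract_promiscuous_submatrix(csm, 5)
  expect_equal(length(sub$rows), 1)
  expect_equal(length(sub$columns), 1)
  expect_equal(sub$cells$compound_id, "a-me")
  # threshold 1 keeps every real cell
  ident <- extract_promiscuous_submatrix(csm, 1)
  expect_equal(sum(ident$cells$status == "real"),
               sum(csm$cells$status == "real"))
  expect_error(extract_promiscuous_submatrix(csm, 100),
               class = "csmtools_empty_result")
})

test_that("design candidates reassemble the virtual cells of a column", {
  tbl <- tibble::tibble(
    compound_id = c("a-me", "a-et", "b-me", "b-cl"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccc(F)cc1", "Clc1ccc(F)cc1")
  )
  csm <- build_csms(build_series(tbl))[[1]]
  # the ethyl column has one virtual cell: 4-F-phenyl + ethyl
  cand <- design_candidates(csm, "*CC")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$smiles, canonical_smiles("CCc1ccc(F)cc1"))
  # a fully populated column yields nothing
  expect_equal(nrow(design_candidates(csm, "*C")), 0)
  expect_error(design_candidates(csm, "*CCCC"),
               class = "csmtools_input_error")
})

test_that("CSM statistics classify family spans of multi-target matrices", {
  fix <- generate_analog_grid(fixture_spec(seed = 12))
  csms <- build_csms(build_series(fix$dataset), fix$profiles)
  stats <- csm_statistics(csms, fix$ground_truth$families)
  expect_equal(stats$n_csms, length(csms))
  expect_equal(stats$n_single_family + stats$n_multi_family,
               stats$n_multi_target_csms)
  # recompute the span of the first CSM by hand
  real <- csms[[1]]$cells[csms[[1]]$cells$status == "real", ]
  fam <- fix$ground_truth$families
  span <- length(unique(fam$family[fam$target_id %in% unlist(real$targets)]))
  hist <- stats$family_span_histogram
  if (any(real$target_count >= 2)) {
    expect_true(span %in% hist$n_families)
  }
})
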