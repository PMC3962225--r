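# promiscuity rates, probabilities, and stratified summaries

toy_profiles <- function(counts) {
  tibble::tibble(compound_id = sprintf("c%d", seq_along(counts)),
                 target_count = as.integer(counts))
}

test_that("rates average multi-target compounds; probabilities use all", {
  s <- summarize_promiscuity(toy_profiles(c(1, 1, 2, 6)))
  expect_equal(s$rate, 4)
  expect_equal(s$p_at_least_2, 0.5)
  expect_equal(s$p_more_than_5, 0.25)
  expect_equal(s$n_multi_target, 2)
  s2 <- summarize_promiscuity(toy_profiles(c(2, 3, 5)))
  expect_equal(s2$rate, 10 / 3)
  # no multi-target compound: rate undefined, not zero
  s3 <- summarize_promiscuity(toy_profiles(c(1, 1, 1)))
  expect_true(is.na(s3$rate))
  expect_equal(s3$p_at_least_2, 0)
  # distribution accounts for every compound
  expect_equal(sum(s$distribution$n_compounds), 4)
  expect_true(s$p_more_than_5 <= s$p_at_least_2)
})

test_that("removing a single-target compound shifts probabilities, not rate", {
  counts <- c(1, 1, 2, 4, 8)
  s_all <- summarize_promiscuity(toy_profiles(counts))
  s_less <- summarize_promiscuity(toy_profiles(counts[-1]))
  expect_equal(s_all$rate, s_less$rate)
  expect_lt(s_all$p_at_least_2, s_less$p_at_least_2)
})

test_that("family summaries restrict target sets within the family", {
  fam <- tibble::tibble(target_id = c("G1", "G2", "K1", "K2", "K3", "K4"),
                        family = c("GPCR-A", "GPCR-A", rep("kinase", 4)))
  prof <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    targets = list(c("G1", "G2", "K1", "K2", "K3"),  # 2 GPCR + 3 kinase
                   c("G1", "K1", "K2", "K3", "K4"),  # 1 GPCR + 4 kinase
                   c("G1", "G2")),                   # 2 GPCR
    target_count = c(5L, 5L, 2L)
  )
  g <- summarize_by_family(prof, fam, "GPCR-A")
  # compound b is single-target within the family: counted, not rated
  expect_equal(g$n_compounds_total, 3)
  expect_equal(g$n_multi_target, 2)
  expect_equal(g$rate, 2)
  k <- summarize_by_family(prof, fam, "kinase")
  expect_equal(k$n_compounds_total, 2)
  expect_equal(k$rate, (3 + 4) / 2)
  expect_error(summarize_by_family(prof, fam, "protease"),
               class = "csmtools_input_error")
  # family-restricted multi-target compounds never exceed the global count
  glob <- summarize_promiscuity(prof)
  expect_lte(g$n_multi_target + k$n_multi_target - 1, glob$n_compounds_total)
})

test_that("molecular-weight bins are left-open with an open last bin", {
  prof <- tibble::tibble(compound_id = c("bz", "big"),
                         targets = list(c("T1", "T2"), c("T1", "T2", "T3")),
                         target_count = c(2L, 3L))
  structures <- tibble::tibble(
    compound_id = c("bz", "big"),
    smiles = c("c1ccccc1",                       # 78 Da -> (0,200]
               paste0("C", strrep("C", 60)))     # ~860 Da -> open last bin
  )
  res <- summarize_by_mw(prof, structures)
  expect_equal(as.character(res$bin), c("(0,200]", "(700,Inf)"))
  expect_equal(res$rate, c(2, 3))
  # a compound exactly at a bin edge falls in the lower bin
  edges <- mw_bins(c(0, 78.11184, 200))
  res2 <- summarize_by_mw(prof[1, ], structures[1, ], edges)
  expect_equal(as.character(res2$bin), "(0,78.11184]")
})

test_that("high-promiscuity fractions keep inactives in the denominator", {
  prof <- toy_profiles(c(0, 0, 11, 3))
  expect_equal(high_promiscuity_fraction(prof, 10), 0.25)
  expect_equal(high_promiscuity_fraction(prof, 100), 0)
})

test_that("summary statistics match generator ground truth exactly", {
  fix <- generate_analog_grid(fixture_spec(seed = 9))
  gt <- fix$ground_truth$grid[fix$ground_truth$grid$present, ]
  s <- summarize_promiscuity(fix$profiles)
  tt <- gt$target_count
  expect_equal(s$n_compounds_total, nrow(gt))
  expect_equal(s$rate, mean(tt[tt >= 2]))
  expect_equal(s$p_at_least_2, mean(tt >= 2))
  expect_equal(s$p_more_than_5, mean(tt > 5))
  # per-family agreement
  fam <- fix$ground_truth$families
  for (f in unique(fam$family)) {
    in_fam <- vapply(gt$targets, function(tg) {
      length(intersect(tg, fam$target_id[fam$family == f]))
    }, integer(1))
    if (!any(in_fam >= 1)) next
    sf <- summarize_by_family(fix$profiles, fam, f)
    expect_equal(sf$n_compounds_total, sum(in_fam >= 1))
    if (any(in_fam >= 2)) {
      expect_equal(sf$rate, mean(in_fam[in_fam >= 2]))
    }
  }
})
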