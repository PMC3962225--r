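# shared-compound target networks and the bipartite interaction network

profiles_from_sets <- function(sets) {
  tibble::tibble(compound_id = sprintf("c%02d", seq_along(sets)),
                 targets = lapply(sets, sort),
                 target_count = lengths(sets))
}

test_that("target pairs need the minimum number of shared compounds", {
  # five compounds hit T1+T2; four hit T1+T3
  sets <- c(rep(list(c("T1", "T2")), 5), rep(list(c("T1", "T3")), 4))
  prof <- profiles_from_sets(sets)
  fam <- c(T1 = "GPCR-A", T2 = "GPCR-A", T3 = "kinase")
  net <- build_target_network(prof, fam, min_shared = 5)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$target_a, net$edges$target_b), c("T1", "T2"))
  expect_equal(net$edges$shared_compounds, 5L)
  expect_equal(net$n_intra_family, 1)
  expect_equal(net$n_inter_family, 0)
  # isolated targets (T3) are not nodes
  expect_setequal(net$nodes$target_id, c("T1", "T2"))
  # all single-target compounds: no pairs at all
  singles <- profiles_from_sets(rep(list("T1"), 10))
  empty <- build_target_network(singles, fam, 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("unlabelled targets warn and classify as other", {
  sets <- rep(list(c("T1", "TX")), 5)
  prof <- profiles_from_sets(sets)
  expect_warning(net <- build_target_network(prof, c(T1 = "GPCR-A"), 5),
                 "other")
  expect_equal(net$nodes$family[net$nodes$target_id == "TX"], "other")
  expect_equal(net$n_inter_family, 1)
})

test_that("edge sets equal the pairwise-intersection oracle", {
  for (seed in c(2, 8, 21)) {
    prof <- random_profiles(35, 10, 0.3, seed)
    net <- build_target_network(prof, stats::setNames(rep("f", 10),
                                                      sprintf("T%02d", 1:10)),
                                min_shared = 4)
    oracle <- oracle_target_edges(prof, 4)
    got <- paste(net$edges$target_a, net$edges$target_b,
                 net$edges$shared_compounds)
    want <- paste(oracle$target_a, oracle$target_b, oracle$shared_compounds)
    expect_setequal(got, want)
  }
})

test_that("raising min_shared never adds edges or nodes", {
  prof <- random_profiles(40, 8, 0.35, seed = 5)
  fam <- stats::setNames(rep("f", 8), sprintf("T%02d", 1:8))
  prev_edges <- Inf
  prev_nodes <- Inf
  for (ms in c(1, 3, 5, 8)) {
    net <- build_target_network(prof, fam, ms)
    expect_lte(nrow(net$edges), prev_edges)
    expect_lte(nrow(net$nodes), prev_nodes)
    prev_edges <- nrow(net$edges)
    prev_nodes <- nrow(net$nodes)
  }
})

test_that("bipartite networks mirror the interaction set", {
  inter <- tibble::tibble(compound_id = c("d1", "d1", "d2"),
                          target_id = c("t1", "t2", "t1"))
  net <- build_bipartite_network(inter)
  expect_equal(length(net$compound_nodes), 2)
  expect_equal(length(net$target_nodes), 2)
  expect_equal(nrow(net$edges), 3)
  dd <- net$degree_distribution
  expect_equal(dd$n_compounds[dd$degree == 1], 1L)
  expect_equal(dd$n_compounds[dd$degree == 2], 1L)
  # duplicates are removed and reported
  expect_message(net2 <- build_bipartite_network(inter[c(1, 1, 2, 3), ]),
                 "duplicate")
  expect_equal(nrow(net2$edges), 3)
  expect_equal(net2$n_duplicates_removed, 1L)
  # empty input
  empty <- build_bipartite_network(inter[0, ])
  expect_equal(nrow(empty$edges), 0)
})

test_that("degree sums balance on both bipartite sides", {
  withr::with_seed(3, {
    inter <- tibble::tibble(
      compound_id = sample(sprintf("d%02d", 1:25), 120, replace = TRUE),
      target_id = sample(sprintf("t%02d", 1:12), 120, replace = TRUE)
    )
  })
  inter <- dplyr::distinct(inter)
  net <- build_bipartite_network(inter)
  expect_equal(sum(net$degree_distribution$degree *
                     net$degree_distribution$n_compounds),
               nrow(net$edges))
  target_deg <- table(net$edges$target_id)
  expect_equal(sum(target_deg), nrow(net$edges))
})
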