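# promiscuity-cliff detection, cliff networks and transformation counts

toy_mmps <- function(...) {
  rows <- list(...)
  tibble::tibble(
    compound_a = vapply(rows, `[[`, character(1), 1),
    compound_b = vapply(rows, `[[`, character(1), 2),
    core = "*c1ccccc1",
    substituent_a = vapply(rows, function(r) r[[3]], character(1)),
    substituent_b = vapply(rows, function(r) r[[4]], character(1)),
    core_heavy_atoms = 6L,
    transformation = paste0(vapply(rows, function(r) r[[3]], character(1)),
                            ">>", vapply(rows, function(r) r[[4]], character(1)))
  )
}

test_that("cliff threshold is inclusive and missing profiles are named", {
  mm <- toy_mmps(list("a", "b", "*C", "*CC"),
                 list("c", "d", "*C", "*Cl"),
                 list("e", "f", "*C", "*O"))
  prof <- tibble::tibble(compound_id = letters[1:6],
                         target_count = c(2L, 60L, 10L, 40L, 0L, 50L))
  cl <- find_cliffs(mm, prof, 50)
  expect_equal(nrow(cl), 2)
  ab <- cl[cl$compound_a == "a", ]
  expect_equal(ab$delta, 58L)
  # delta exactly at threshold qualifies ("50 or more")
  expect_true("e" %in% cl$compound_a)
  # (10, 40) misses the threshold
  expect_false("c" %in% cl$compound_a)
  expect_error(find_cliffs(mm, prof[-2, ], 50), "'b'",
               class = "csmtools_input_error")
})

test_that("cliff sets are symmetric and monotone in the threshold", {
  mm <- toy_mmps(list("a", "b", "*C", "*CC"), list("c", "d", "*C", "*Cl"))
  prof <- tibble::tibble(compound_id = letters[1:4],
                         target_count = c(5L, 30L, 1L, 80L))
  swapped <- mm
  swapped$compound_a <- mm$compound_b
  swapped$compound_b <- mm$compound_a
  key <- function(cl) sort(paste(pmin(cl$compound_a, cl$compound_b),
                                 pmax(cl$compound_a, cl$compound_b)))
  expect_equal(key(find_cliffs(mm, prof, 20)),
               key(find_cliffs(swapped, prof, 20)))
  # threshold zero returns every MMP with distinct counts; raising it only
  # ever removes cliffs
  sizes <- vapply(c(0, 10, 25, 50, 80, 200), function(th) {
    nrow(find_cliffs(mm, prof, th))
  }, numeric(1))
  expect_equal(sizes[1], 2)
  expect_true(all(diff(sizes) <= 0))
})

test_that("cliff networks identify hubs by degree", {
  mm <- toy_mmps(list("a", "b", "*C", "*CC"),
                 list("a", "c", "*C", "*Cl"),
                 list("d", "e", "*C", "*O"))
  prof <- tibble::tibble(compound_id = letters[1:5],
                         target_count = c(0L, 60L, 70L, 2L, 90L))
  net <- build_cliff_network(find_cliffs(mm, prof, 50))
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$hubs, "a")
  # hub set equals a direct degree count over the edge list
  ends <- c(net$edges$compound_a, net$edges$compound_b)
  expect_setequal(net$hubs, names(which(table(ends) >= 2)))
  # empty input gives an empty network
  empty <- build_cliff_network(find_cliffs(mm, prof, 1000))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(length(empty$hubs), 0)
})

test_that("a planted cliff star yields one hub of the planted degree", {
  k <- 6
  mm <- do.call(toy_mmps, lapply(seq_len(k), function(i) {
    list("hub", paste0("s", i), "*C", paste0("*", strrep("C", i + 1)))
  }))
  prof <- tibble::tibble(compound_id = c("hub", paste0("s", seq_len(k))),
                         target_count = c(90L, rep(3L, k)))
  net <- build_cliff_network(find_cliffs(mm, prof, 50))
  expect_equal(net$hubs, "hub")
  expect_equal(net$nodes$degree[net$nodes$compound_id == "hub"], k)
})

test_that("transformation frequencies count oriented exchanges", {
  mm <- toy_mmps(list("a", "b", "*C", "*Cl"),
                 list("c", "d", "*C", "*Cl"),
                 list("e", "f", "*C", "*O"))
  prof <- tibble::tibble(compound_id = letters[1:6],
                         target_count = c(1L, 60L, 2L, 80L, 0L, 70L))
  tf <- transformation_frequency(find_cliffs(mm, prof, 50))
  # both *C>>*Cl cliffs point from low to high T regardless of input order
  expect_equal(tf$n[tf$transformation == "*C>>*Cl"], 2L)
  expect_equal(tf$n[tf$transformation == "*C>>*O"], 1L)
  expect_equal(nrow(transformation_frequency(
    find_cliffs(mm, prof, 1000))), 0)
})
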