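# reading, validation, curation and profile construction

test_that("long CSV rows map to records and malformed rows are named", {
  path <- write_toy_activity_csv(c(
    "c1,CCO,T1,GPCR-A,Ki,=,500",
    "c2,CCN,T2,kinase,IC50,>,1000",
    "c3,CCC,T3,other,binary,,"
  ))
  rec <- read_activity_table(path, "long_csv")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$value_nm[1], 500)
  expect_equal(rec$measurement_type, c("Ki", "IC50", "binary"))
  expect_true(rec$active_flag[3])
  expect_true(is.na(rec$value_nm[3]))

  bad_value <- write_toy_activity_csv("c1,CCO,T1,GPCR-A,Ki,=,-3")
  expect_error(read_activity_table(bad_value, "long_csv"),
               "value_nM", class = "csmtools_input_error")
  bad_type <- write_toy_activity_csv("c1,CCO,T1,GPCR-A,EC50,=,10")
  expect_error(read_activity_table(bad_type, "long_csv"),
               "measurement_type", class = "csmtools_input_error")
  expect_error(read_activity_table("no/such/file.csv", "long_csv"),
               "no/such/file.csv", class = "csmtools_input_error")
})

test_that("wide binary matrices emit one record per active cell", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,T1,T2,T3",
               "c1,CCO,1,0,1",
               "c2,CCN,0,0,0"), path)
  rec <- read_activity_table(path, "wide_binary_csv")
  expect_equal(nrow(rec), 2)
  expect_setequal(paste(rec$compound_id, rec$target_id), c("c1 T1", "c1 T3"))
  expect_true(all(rec$measurement_type == "binary"))
  # the all-zero compound survives in the roster and in binary profiles
  roster <- attr(rec, "roster")
  expect_equal(roster$compound_id, c("c1", "c2"))
  prof <- binary_profiles(read_binary_matrix(path))
  expect_equal(prof$target_count, c(2L, 0L))
})

test_that("curation drops approximate and weak records and merges duplicates", {
  rows <- c(
    "a,CCO,T1,GPCR-A,Ki,=,500",       # kept
    "b,CCO.Cl,T2,GPCR-A,Ki,=,900",    # same structure after desalting -> merged
    "c,CCN,T1,GPCR-A,Ki,>,100",       # approximate -> excluded
    "d,CCN,T1,GPCR-A,Ki,~,100",       # approximate -> excluded
    "e,CCN,T1,GPCR-A,Ki,=,20000",     # above 10 uM -> excluded
    "f,CCN,T1,GPCR-A,IC50,=,100",     # wrong measurement type
    "g,CCCC,T3,kinase,Ki,=,100"       # kept
  )
  rec <- read_activity_table(write_toy_activity_csv(rows), "long_csv")
  ds <- curate_activities(rec, "Ki")
  expect_s3_class(ds, "curated_dataset")
  expect_equal(nrow(ds$compounds), 2)
  merged <- ds$activities[ds$activities$compound_id == "a", ]
  expect_setequal(merged$target_id, c("T1", "T2"))
  expect_setequal(ds$compounds$merged_ids[[1]], c("a", "b"))
  # empty result is an explicit signal
  expect_error(curate_activities(rec[3:6, ], "Ki"),
               "empty dataset", class = "csmtools_empty_result")
})

test_that("replicate potencies aggregate by geometric mean", {
  rows <- c("a,CCO,T1,GPCR-A,Ki,=,100",
            "a,CCO,T1,GPCR-A,Ki,=,10000")
  rec <- read_activity_table(write_toy_activity_csv(rows), "long_csv")
  ds <- curate_activities(rec, "Ki")
  expect_equal(ds$activities$value_nm, sqrt(100 * 10000))
})

test_that("curation is idempotent and order-invariant", {
  fix <- generate_analog_grid(fixture_spec(seed = 5))
  ds1 <- fix$dataset
  ds2 <- curate_activities(tidy(ds1), ds1$measurement_type,
                           ds1$potency_threshold_nm)
  expect_equal(ds1$activities, ds2$activities)
  expect_equal(ds1$compounds$compound_id, ds2$compounds$compound_id)
  expect_equal(ds1$compounds$smiles, ds2$compounds$smiles)
  shuffled <- withr::with_seed(1, fix$records[sample(nrow(fix$records)), ])
  ds3 <- curate_activities(shuffled, "Ki")
  expect_equal(ds1$activities, ds3$activities)
})

test_that("profiles count distinct targets and match hand-planted counts", {
  act <- tibble::tibble(
    compound_id = c("x", "x", "x", "y", rep("z", 3), rep("w", 5)),
    target_id = c("T1", "T1", "T2", "T1", "T1", "T2", "T3",
                  paste0("T", 1:5))
  )
  prof <- build_profiles(act)
  counts <- stats::setNames(prof$target_count, prof$compound_id)
  expect_equal(unname(counts[c("y", "x", "z", "w")]), c(1L, 2L, 3L, 5L))
  # sum of target counts equals distinct compound-target pairs
  expect_equal(sum(prof$target_count),
               nrow(dplyr::distinct(act, compound_id, target_id)))
  # order invariance
  prof2 <- build_profiles(act[rev(seq_len(nrow(act))), ])
  expect_equal(prof, prof2)
})
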