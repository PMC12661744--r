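test_that("constructor validates the arm-level data model and names offenders", {
  good <- data.frame(study = c("s1", "s1", "s2", "s2"),
                     treatment = c("A", "B", "A", "C"),
                     events = c(12, 15, 10, 19), sample_size = rep(50, 4))
  ds <- nma_data(good)
  expect_s3_class(ds, "nma_data")
  expect_equal(ds$treatments, c("A", "B", "C"))

  bad <- good; bad$events[2] <- 60
  expect_error(nma_data(bad), "s1")

  single_arm <- good[-2, ]
  expect_error(nma_data(single_arm), ">= 2 arms")

  dup <- good; dup$treatment[2] <- "A"
  expect_error(nma_data(dup), "duplicate")

  expect_error(nma_data(data.frame(study = c("s1", "s1"),
                                   treatment = c("A", "B"),
                                   events = c(1, 2),
                                   sample_size = c(0, 10))), "positive integer")
})

test_that("row order never affects the canonical dataset or downstream results", {
  base <- data.frame(study = c("s1", "s1", "s2", "s2", "s2"),
                     treatment = c("B", "A", "C", "A", "B"),
                     events = c(15, 12, 19, 10, 14), sample_size = rep(50, 5))
  shuffled <- base[c(4, 2, 5, 1, 3), ]
  expect_identical(nma_data(base), nma_data(shuffled))
  expect_identical(build_network(nma_data(base)),
                   build_network(nma_data(shuffled)))
})

test_that("reference treatment re-orders the coding", {
  ds <- triangle_ds()
  ds_b <- nma_data(ds$arms, reference = "B")
  expect_equal(ds_b$treatments, c("B", "A", "C"))
  expect_error(nma_data(ds$arms, reference = "Z"), "not present")
})

test_that("long-format reader round-trips and reports malformed input", {
  ds <- triangle_ds()
  path <- withr::local_tempfile(fileext = ".csv")
  write_nma_data(ds, path)
  ds2 <- read_nma_data(path)
  expect_identical(ds$arms, ds2$arms)

  # custom column mapping
  path2 <- withr::local_tempfile(fileext = ".csv")
  renamed <- ds$arms
  names(renamed) <- c("trial", "arm", "r", "n")
  write.csv(renamed, path2, row.names = FALSE, quote = FALSE)
  ds3 <- read_nma_data(path2, mapping = list(study = "trial",
                                             treatment = "arm",
                                             events = "r",
                                             sample_size = "n"))
  expect_identical(ds$arms, ds3$arms)

  # malformed numeric cell: error names the line
  txt <- c("study,treatment,events,sample_size",
           "s1,A,10,50", "s1,B,xx,50", "s2,A,10,50", "s2,B,12,50")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, path3)
  expect_error(read_nma_data(path3), "row\\(s\\) 3")

  # invariant violation names the study
  txt[3] <- "s1,B,60,50"
  writeLines(txt, path3)
  expect_error(read_nma_data(path3), "s1")

  expect_error(read_nma_data("no/such/file.csv"), "not found")
})

test_that("wide reader normalises to the long data model", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,t1,r1,n1,t2,r2,n2,t3,r3,n3",
               "s1,A,20,80,B,24,80,C,28,80",
               "s2,A,22,80,B,26,80,,,"), path)
  ds <- read_nma_wide(path)
  expect_equal(sort(unique(ds$arms$study)), c("s1", "s2"))
  expect_equal(nrow(ds$arms), 5L)
  expect_equal(ds$arms$events[ds$arms$study == "s1" &
                                ds$arms$treatment == "C"], 28)
})

test_that("event-risk filter removes studies with any extreme arm, strictly", {
  ds <- nma_data(data.frame(
    study = rep(c("low", "edge"), each = 2),
    treatment = rep(c("A", "B"), 2),
    events = c(10, 50, 20, 80), sample_size = rep(100, 4)))
  rep_ <- filter_event_risk(ds)
  expect_equal(rep_$removed_studies$study, "low")       # 0.10 < 0.15
  expect_match(rep_$removed_studies$reason, "below 0.15")
  # arms at exactly 0.15 / 0.85 would be kept; 0.20 and 0.80 clearly are
  expect_equal(unique(rep_$retained$arms$study), "edge")

  boundary <- nma_data(data.frame(
    study = c("b", "b"), treatment = c("A", "B"),
    events = c(15, 85), sample_size = c(100, 100)))
  expect_equal(nrow(filter_event_risk(boundary)$removed_studies), 0L)
})

test_that("filter reports broken connectivity and total exclusion", {
  rep_ <- filter_event_risk(line_extreme_ds())
  expect_equal(rep_$removed_studies$study, "ab1")
  expect_false(rep_$connectivity_intact)
  expect_false(rep_$all_removed)

  all_bad <- nma_data(data.frame(
    study = c("s1", "s1"), treatment = c("A", "B"),
    events = c(5, 95), sample_size = c(100, 100)))
  rep2 <- filter_event_risk(all_bad)
  expect_true(rep2$all_removed)
  expect_null(rep2$retained)
})

test_that("filter is idempotent and the unit interval removes nothing", {
  ds <- triangle_ds()
  once <- filter_event_risk(ds)
  twice <- filter_event_risk(once$retained)
  expect_identical(once$retained$arms, twice$retained$arms)
  expect_equal(nrow(twice$removed_studies), 0L)

  open <- filter_event_risk(line_extreme_ds(), lo = 0, hi = 1)
  expect_equal(nrow(open$removed_studies), 0L)
  expect_error(filter_event_risk(ds, lo = 0.5, hi = 0.2), "lo < hi")
})

test_that("eligibility applies the four criteria and is configurable", {
  tri <- check_eligibility(triangle_ds())
  expect_true(tri$overall_eligible)
  expect_true(all(tri$criteria))

  # loop from a single three-arm design only
  abc <- nma_data(data.frame(study = rep("t1", 3),
                             treatment = c("A", "B", "C"),
                             events = c(20, 24, 28), sample_size = rep(80, 3)))
  e1 <- check_eligibility(abc)
  expect_false(e1$criteria[["valid_loop"]])
  expect_false(e1$overall_eligible)

  e2 <- check_eligibility(star_ds())
  expect_false(e2$criteria[["valid_loop"]])

  two <- nma_data(data.frame(study = rep(c("s1", "s2", "s3"), each = 2),
                             treatment = rep(c("A", "B"), 3),
                             events = rep(c(20, 24), 3),
                             sample_size = rep(80, 6)))
  e3 <- check_eligibility(two)
  expect_false(e3$criteria[["enough_treatments"]])
  e4 <- check_eligibility(two, rules = list(min_treatments = 2))
  expect_true(e4$criteria[["enough_treatments"]])

  # overall eligibility is the conjunction of the criteria
  for (e in list(tri, e1, e2, e3)) {
    expect_identical(e$overall_eligible, all(e$criteria))
  }
})

test_that("results tables round-trip and refuse empty input", {
  df <- as.data.frame(fake_result(0.5, -0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(df, path)
  back <- read_results_table(path)
  expect_equal(back$index, df$index, tolerance = 1e-12)
  expect_equal(names(back), names(df))
  expect_error(write_results_table(df[0, ], path), "no results")
})

test_that("filter and eligibility reports serialise to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(filter_event_risk(line_extreme_ds()), path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$type, "filter_report")
  expect_equal(parsed$removed_studies$study, "ab1")
  write_report_json(check_eligibility(triangle_ds()), path)
  parsed2 <- jsonlite::fromJSON(path)
  expect_true(parsed2$overall_eligible)
})
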