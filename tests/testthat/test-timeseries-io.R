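test_that("protocol invariants are enforced", {
  p <- ifsigtt_protocol()
  expect_s3_class(p, "ifsigtt_protocol")
  expect_length(p$sample_times, 20)
  expect_error(ifsigtt_protocol(sample_times = c(0, 0, 10)),
               "strictly increasing")
  expect_error(ifsigtt_protocol(insulin_time = -5), "after dextrose")
  expect_error(ifsigtt_protocol(sample_times = c(2, 5, 10)),
               "two pre-dextrose")
})

test_that("subject_series validates its invariants", {
  expect_error(subject_series("a", "foal", c(0, 0), c(1, 1), c(1, 1)),
               "strictly increasing")
  expect_error(subject_series("a", "foal", c(0, 5), c(-1, 100), c(1, 1)),
               "positive")
  expect_error(subject_series("a", "foal", c(0, 5), c(100, 100), c(-2, 1)),
               "non-negative")
  expect_error(subject_series("a", "foal", c(0, 5), c(100), c(1, 1)),
               "one value per time")
  s <- subject_series("a", "horse", c(0, 5), c(100, NA), c(1, NA))
  expect_true(is.na(s$glucose[2]))   # missing kept, never imputed
})

test_that("CSV round trip preserves values at full precision", {
  co <- generate_cohort(3, 2, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  co2 <- read_cohort_csv(path)
  expect_equal(length(co2), 5)
  for (i in seq_along(co$subjects)) {
    expect_identical(co$subjects[[i]]$subject_id,
                     co2$subjects[[i]]$subject_id)
    expect_equal(co2$subjects[[i]]$glucose, co$subjects[[i]]$glucose,
                 tolerance = 0)
    expect_equal(co2$subjects[[i]]$insulin, co$subjects[[i]]$insulin,
                 tolerance = 0)
    expect_equal(co2$subjects[[i]]$times, co$subjects[[i]]$times,
                 tolerance = 0)
  }
})

test_that("reader rejects malformed input with named errors", {
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_cohort_csv(empty), "schema error")

  no_col <- write_tmp_csv(data.frame(subject_id = "a", group = "foal",
                                     time_min = 0))
  expect_error(read_cohort_csv(no_col), "missing column")

  dup <- write_tmp_csv(data.frame(
    subject_id = "a", group = "foal", time_min = c(0, 0),
    glucose_mg_dl = c(100, 100), insulin_uIU_ml = c(5, 5)))
  expect_error(read_cohort_csv(dup), "integrity error")

  bad <- write_tmp_csv(data.frame(
    subject_id = "a", group = "foal", time_min = c(0, 2),
    glucose_mg_dl = c("100", "oops"), insulin_uIU_ml = c(5, 5)))
  expect_error(read_cohort_csv(bad), "non-numeric glucose_mg_dl in row 3")
})

test_that("a small single-subject file parses, sorted by time", {
  path <- write_tmp_csv(data.frame(
    subject_id = "f1", group = "foal", time_min = c(5, 0, 2),
    glucose_mg_dl = c(280, 166, 320), insulin_uIU_ml = c(60, 8, 90)))
  co <- read_cohort_csv(path)
  expect_equal(length(co), 1)
  s <- co$subjects[[1]]
  expect_equal(s$times, c(0, 2, 5))
  expect_equal(s$glucose, c(166, 320, 280))
  expect_equal(nrow(attr(co, "parse_report")), 0)
})

test_that("missing cells are reported, not imputed", {
  path <- write_tmp_csv(data.frame(
    subject_id = "f1", group = "foal", time_min = c(0, 2, 5),
    glucose_mg_dl = c(166, NA, 280), insulin_uIU_ml = c(8, 90, 60)))
  co <- read_cohort_csv(path)
  rep <- attr(co, "parse_report")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$time_min, 2)
  expect_equal(rep$variable, "glucose_mg_dl")
  expect_true(is.na(co$subjects[[1]]$glucose[2]))
})

test_that("enrollment filter excludes strictly above 20 uIU/mL", {
  mk <- function(id, ins0) subject_series(id, "foal", c(-60, 0),
                                          c(160, 166), c(ins0, ins0))
  co <- ifsigtt_cohort(lapply(
    seq_along(c(4, 8, 20, 21, 30)),
    function(i) mk(paste0("s", i), c(4, 8, 20, 21, 30)[i])))
  res <- apply_enrollment_filter(co)
  expect_equal(length(res$cohort), 3)          # 20.0 exactly is retained
  expect_setequal(res$excluded, c("s4", "s5")) # 21 and 30 excluded

  # idempotence
  res2 <- apply_enrollment_filter(res$cohort)
  expect_equal(cohort_ids_for_test(res2$cohort),
               cohort_ids_for_test(res$cohort))
  expect_length(res2$excluded, 0)

  # a single subject at 25 is excluded
  res3 <- apply_enrollment_filter(ifsigtt_cohort(list(mk("x", 25))))
  expect_equal(res3$excluded, "x")

  # missing time-0 insulin is a validation error
  bad <- subject_series("y", "foal", c(-60, 0), c(160, 166), c(8, NA))
  expect_error(apply_enrollment_filter(ifsigtt_cohort(list(bad))),
               "time-0 insulin")
})

test_that("series validation reports schedule deviations without mutating", {
  p <- ifsigtt_protocol()
  full <- toy_series()
  expect_equal(nrow(validate_series(full, p)), 0)

  times <- p$sample_times
  miss150 <- toy_series(times = setdiff(times, 150),
                        glucose = rep(100, 19), insulin = rep(10, 19))
  iss <- validate_series(miss150, p)
  expect_equal(iss$issue, "missing_time")
  expect_equal(iss$time_min, 150)

  extra45 <- toy_series(times = sort(c(times, 45)),
                        glucose = rep(100, 21), insulin = rep(10, 21))
  iss2 <- validate_series(extra45, p)
  expect_equal(iss2$issue, "unscheduled_time")
  expect_equal(iss2$time_min, 45)
})
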