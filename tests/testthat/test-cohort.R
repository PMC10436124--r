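test_that("read_cohort reads a small fixture back and validates it", {
  schema <- cohort_schema(covariates = list(sex = c("male", "female")),
                          exposures = c("pm25", "o3", "temp"))
  d <- tibble::tibble(
    subject_id = c(1, 1, 1, 2, 2, 2),
    start = c(0, 1, 2, 0, 1, 2),
    stop = c(1, 2, 2.6, 1, 2, 3),
    event = c(0, 0, 1, 0, 0, 0),
    pm25 = c(40, 42, 44, 30, 31, 32),
    o3 = c(90, 91, 92, 95, 96, 97),
    temp = c(14, 15, 16, 13, 14, 15),
    sex = c("male", "male", "male", "female", "female", "female")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  cohort <- read_cohort(path, schema)
  expect_equal(nrow(cohort), 6)
  expect_equal(person_years(cohort), (1 + 1 + 0.6) + 3)
  expect_s3_class(cohort$sex, "factor")

  # stop < start on row 3 is rejected with the row index
  bad <- d
  bad$stop[3] <- 1.5
  readr::write_csv(bad, path)
  expect_error(read_cohort(path, schema), "row\\(s\\) 3")

  # missing required column is named
  readr::write_csv(d[, setdiff(names(d), "o3")], path)
  expect_error(read_cohort(path, schema), "o3")

  # non-binary event
  bad <- d
  bad$event[1] <- 2
  readr::write_csv(bad, path)
  expect_error(read_cohort(path, schema), "event")
})

test_that("write_cohort / read_cohort round trip is exact for a generated cohort", {
  cohort <- make_cohort(generator_config(n_subjects = 100), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path, attr(cohort, "schema"))
  for (v in c("start", "stop", "event", "pm25", "o3", "temp")) {
    expect_identical(as.numeric(back[[v]]), as.numeric(cohort[[v]]), label = v)
  }
  expect_identical(as.character(back$subject_id), as.character(cohort$subject_id))
  for (v in names(attr(cohort, "schema")$covariates)) {
    expect_identical(as.character(back[[v]]), as.character(cohort[[v]]))
  }
})

test_that("validate_cohort enforces the counting-process contract", {
  base <- tibble::tibble(subject_id = c(1, 1), start = c(0, 1),
                         stop = c(1, 2), event = c(0, 1))
  expect_silent(validate_cohort(base))
  overlap <- base
  overlap$start[2] <- 0.5
  expect_error(validate_cohort(overlap), "overlap")
  midev <- tibble::tibble(subject_id = c(1, 1), start = c(0, 1),
                          stop = c(1, 2), event = c(1, 0))
  expect_error(validate_cohort(midev), "non-final")
  schema <- cohort_schema(covariates = list(sex = c("male", "female")))
  badlab <- base
  badlab$sex <- c("male", "other")
  expect_error(validate_cohort(badlab, schema), "other")
})

test_that("expand_counting_process splits follow-up at year boundaries", {
  fu <- tibble::tibble(subject_id = 1L, time = 2.5, event = 1L)
  ex <- tidyr::expand_grid(subject_id = 1L, year = 2008:2010)
  ex$pm25 <- c(40, 45, 50)
  out <- expand_counting_process(fu, ex, baseline_year = 2008)
  expect_equal(nrow(out), 3)
  expect_equal(out$stop - out$start, c(1, 1, 0.5))
  expect_equal(out$event, c(0, 0, 1))
  expect_equal(out$pm25, c(40, 45, 50))

  # censoring exactly at a year boundary emits no zero-length record
  fu2 <- tibble::tibble(subject_id = 1L, time = 2, event = 0L)
  out2 <- expand_counting_process(fu2, ex, baseline_year = 2008)
  expect_equal(nrow(out2), 2)
  expect_true(all(out2$stop > out2$start))

  # missing subject-year exposure is reported with subject and year
  fu3 <- tibble::tibble(subject_id = 1L, time = 4, event = 0L)
  expect_error(expand_counting_process(fu3, ex, baseline_year = 2008), "2011")
})

test_that("expand_counting_process conserves person-time and events", {
  set.seed(5)
  n <- 50
  fu <- tibble::tibble(subject_id = seq_len(n),
                       time = runif(n, 0.5, 9.5),
                       event = rbinom(n, 1, 0.3))
  ex <- tidyr::expand_grid(subject_id = seq_len(n), year = 2008:2017)
  ex$pm25 <- rnorm(nrow(ex), 40, 5)
  out <- expand_counting_process(fu, ex, baseline_year = 2008)
  expect_equal(person_years(out), sum(fu$time), tolerance = 1e-9)
  expect_equal(sum(out$event), sum(fu$event))
  expect_silent(validate_cohort(out))
})

test_that("quantize codes quartiles with right-closed bins", {
  d <- tibble::tibble(pm25 = c(1, 2, 3, 4))
  q <- quantize(d, "pm25")
  expect_equal(q$pm25_q, c(0, 1, 2, 3))

  # boundary values fall in the lower category; checked by direct enumeration
  spec <- quantile_spec("pm25", c(10, 20, 30))
  x <- c(5, 10, 10.01, 20, 25, 30, 31)
  expected <- vapply(x, function(v) {
    if (v <= 10) 0 else if (v <= 20) 1 else if (v <= 30) 2 else 3
  }, numeric(1))
  got <- quantize(tibble::tibble(pm25 = x), "pm25", spec)$pm25_q
  expect_equal(got, expected)

  expect_error(quantize(tibble::tibble(pm25 = rep(7, 10)), "pm25"),
               "degenerate")
})

test_that("quantization is monotone and balanced on the deriving data", {
  set.seed(21)
  x <- rnorm(2000, 50, 10)
  d <- quantize(tibble::tibble(pm25 = x), "pm25")
  ord <- order(x)
  expect_true(all(diff(d$pm25_q[ord]) >= 0))
  props <- as.numeric(table(factor(d$pm25_q, levels = 0:3))) / length(x)
  expect_true(all(abs(props - 0.25) <= 2 / sqrt(length(x))))
})

test_that("quantile_spec JSON serialization round trips", {
  spec <- quantile_spec("pm25", c(31.7, 41.3, 53.1), source = "fixed")
  path <- withr::local_tempfile(fileext = ".json")
  write_quantile_spec(spec, path)
  back <- read_quantile_spec(path)
  expect_equal(back$cuts, spec$cuts)
  expect_equal(back$exposure, "pm25")
  expect_error(quantile_spec("x", c(1, 1, 2)), "increasing")
})
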