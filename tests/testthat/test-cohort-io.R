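# Cohort reading, validation, eligibility filtering and staging.

test_that("read_cohort parses, sorts and groups visits", {
  df <- data.frame(
    participant_id = c("B", "B", "B", "A", "A", "A"),
    age = c(72, 70.5, 69, 66, 64.5, 63),    # deliberately out of order
    cdr_sb = c(2, 1.5, 1, 0.5, 0.5, 0),
    diagnosis = c("MCI", "MCI", "MCI", "MCI", "mci", "CN"),
    sex = "F", hypertension = c("TRUE", "", "", "FALSE", "", "")
  )
  co <- read_cohort(write_visits_csv(df))
  expect_s3_class(co, "fdi_cohort")
  expect_equal(n_participants(co), 2)
  ser <- cohort_series(co)
  expect_equal(vapply(ser, nrow, integer(1)), c(A = 3L, B = 3L))
  expect_true(all(vapply(ser, function(s) all(diff(s$age) > 0), logical(1))))
  # diagnosis normalisation: CN alias and case-insensitive labels
  expect_equal(ser$A$diagnosis, c("CU", "MCI", "MCI"))
  # covariates: first non-missing value per participant
  expect_equal(co$covariates$hypertension[co$covariates$participant_id == "A"],
               FALSE)
  expect_equal(nrow(co$rejects), 0)
})

test_that("read_cohort rejects bad rows with reasons instead of dropping them", {
  df <- data.frame(
    participant_id = c("A", "A", "A", "A", "B", "B", ""),
    age = c("65", "66.5", "old", "66.5", "70", "71", "72"),
    cdr_sb = c("0", "19", "1", "0.5", "1", "x", "2"),
    stringsAsFactors = FALSE
  )
  co <- read_cohort(write_visits_csv(df))
  expect_equal(sort(unique(co$rejects$reason)),
               sort(c("score out of range [0,18]", "non-numeric or missing age",
                      "non-numeric or missing cdr_sb", "missing participant_id",
                      "duplicate visit age within participant")))
  # surviving rows: A@65 and B@70 (the second A@66.5 row duplicates the age
  # of the score-rejected first one, so it is flagged too)
  expect_equal(nrow(co$visits), 2)
  expect_error(read_cohort(write_visits_csv(df), fdi_schema(cdr_sb = "CDRSB")),
               "missing required column")
})

test_that("off-grid CDR-SB values are accepted with a warning", {
  df <- data.frame(participant_id = "A", age = c(65, 66), cdr_sb = c(0.3, 1))
  expect_warning(co <- read_cohort(write_visits_csv(df)), "0.5-point grid")
  expect_equal(nrow(co$visits), 2)
})

test_that("cohort CSV round trip preserves visits and covariates", {
  sim <- simulate_cohort(sim_config(n = 12, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$visits$age, sim$cohort$visits$age, tolerance = 1e-12)
  expect_equal(back$visits$cdr_sb, sim$cohort$visits$cdr_sb)
  expect_equal(back$visits$diagnosis, sim$cohort$visits$diagnosis)
  expect_equal(back$covariates$sex, sim$cohort$covariates$sex)
})

test_that("eligibility rules exclude by age, visit count and etiology", {
  visits <- rbind(
    data.frame(participant_id = "young", age = c(58, 60), cdr_sb = c(0, 0.5)),
    data.frame(participant_id = "single", age = 65, cdr_sb = 1),
    data.frame(participant_id = "nonad", age = c(66, 68), cdr_sb = c(1, 2)),
    data.frame(participant_id = "ok", age = c(61, 63), cdr_sb = c(0, 0.5))
  )
  visits$diagnosis <- NA_character_
  cov <- data.frame(participant_id = c("young", "single", "nonad", "ok"),
                    non_ad_etiology = c(FALSE, FALSE, TRUE, FALSE))
  co <- fdindex:::new_cohort(visits, cov)
  el <- apply_eligibility(co)
  expect_equal(sort(unique(el$cohort$visits$participant_id)), "ok")
  expect_equal(el$report$n_excluded[el$report$rule == "min_age"], 1)
  expect_equal(el$report$n_excluded[el$report$rule == "min_visits"], 1)
  expect_equal(el$report$n_excluded[el$report$rule == "non_ad_etiology"], 1)
  # keeps non-AD cases when exclusion is off
  el2 <- apply_eligibility(co, exclude_non_ad = FALSE)
  expect_setequal(unique(el2$cohort$visits$participant_id), c("ok", "nonad"))
})

test_that("apply_eligibility is idempotent", {
  sim <- simulate_cohort(sim_config(n = 30, seed = 3))
  once <- apply_eligibility(sim$cohort)
  twice <- apply_eligibility(once$cohort)
  expect_equal(twice$cohort$visits, once$cohort$visits)
  expect_true(all(twice$report$n_excluded == 0))
})

test_that("staging is a total monotone step function with cuts 0.5 and 4.5", {
  grid <- seq(0, 18, by = 0.25)
  st <- stage_from_cdrsb(grid)
  expect_equal(st[grid < 0.5], rep("CU", 2))
  expect_equal(unique(st[grid >= 0.5 & grid <= 4.5]), "MCI")
  expect_equal(unique(st[grid > 4.5]), "AD")
  # monotone: stage index never decreases with score
  idx <- match(st, c("CU", "MCI", "AD"))
  expect_true(all(diff(idx) >= 0))
  expect_error(stage_from_cdrsb(18.5), "outside")
  expect_error(stage_from_cdrsb(-0.5), "outside")
})

test_that("model JSON serialization round-trips exactly and rejects corrupt files", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$curve$k, m$curve$k, tolerance = 1e-12)
  expect_equal(m2$curve$t0, m$curve$t0, tolerance = 1e-12)
  expect_equal(m2$thresholds$threshold, m$thresholds$threshold)
  expect_equal(m2$provenance$source, "reference")
  # byte-identical re-serialization
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
  # truncated file fails loudly, no partial model
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = "\n"), 1, 80), trunc)
  expect_error(read_model(trunc), "malformed")
  # unknown schema version rejected
  bad <- withr::local_tempfile(fileext = ".json")
  js <- jsonlite::read_json(path)
  js$schema_version <- "99.0"
  jsonlite::write_json(js, bad, auto_unbox = TRUE)
  expect_error(read_model(bad), "schema version")
})
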