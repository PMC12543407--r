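# Onset-event extraction, Kaplan-Meier estimation and threshold extraction.

# cohort with hand-chosen diagnoses; zero shifts keep FDI = age
toy_diag_cohort <- function() {
  mk <- function(id, ages, diags, scores = NULL) {
    data.frame(participant_id = id, age = ages,
               cdr_sb = scores %||% rep(1, length(ages)),
               diagnosis = diags, stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  visits <- rbind(
    mk("conv",  c(76, 77.5, 79),   c("CU", "CU", "MCI")),
    mk("cens",  c(76, 78, 81),     c("CU", "CU", "CU")),
    mk("jump",  c(75, 78),         c("CU", "AD")),
    mk("prev",  c(80, 82),         c("MCI", "AD"))
  )
  fdindex:::new_cohort(visits,
                       data.frame(participant_id = unique(visits$participant_id)))
}

zero_shifts <- function(cohort) {
  ids <- unique(cohort$visits$participant_id)
  data.frame(participant_id = ids, delta = 0, sse = 0, identifiable = TRUE,
             n_visits = 2, stringsAsFactors = FALSE)
}

test_that("extract_onset_events takes first qualifying visit, censors, and excludes prevalent cases", {
  co <- toy_diag_cohort()
  sh <- zero_shifts(co)
  ev <- extract_onset_events(co, sh, "MCI")
  ev <- ev[order(ev$participant_id), ]
  # conv: MCI event at 79; cens: censored at 81; jump (CU -> AD): counts as
  # MCI event at the AD visit; prev: prevalent, excluded
  expect_equal(ev$participant_id, c("cens", "conv", "jump"))
  expect_equal(ev$fdi_time, c(81, 79, 78))
  expect_equal(ev$status, c(0L, 1L, 1L))
  expect_equal(attr(ev, "n_prevalent"), 1L)

  # direct converters can instead be dropped from the MCI analysis
  ev2 <- suppressWarnings(
    extract_onset_events(co, sh, "MCI", cu_to_ad_counts_mci = FALSE))
  expect_false("jump" %in% ev2$participant_id)

  # AD endpoint: conv has no AD visit -> censored at last FDI; prev was
  # MCI (not AD) at entry, so it is at risk for AD and converts at 82
  sh0 <- zero_shifts(co)
  eva <- extract_onset_events(co, sh0, "AD")
  eva <- eva[order(eva$participant_id), ]
  expect_equal(eva$participant_id, c("cens", "conv", "jump", "prev"))
  expect_equal(eva$status, c(0L, 0L, 1L, 1L))
  expect_equal(eva$fdi_time[eva$participant_id == "prev"], 82)

  # shifts change event times one-for-one
  sh$delta <- 2.5
  ev3 <- extract_onset_events(co, sh, "MCI")
  expect_equal(sort(ev3$fdi_time), sort(ev$fdi_time) + 2.5)
})

test_that("staging fallback supplies diagnoses when the column is missing", {
  visits <- data.frame(participant_id = "A", age = c(76, 78, 80),
                       cdr_sb = c(0, 1, 5), diagnosis = NA_character_)
  co <- fdindex:::new_cohort(visits, data.frame(participant_id = "A"))
  ev <- extract_onset_events(co, zero_shifts(co), "MCI")
  expect_equal(ev$fdi_time, 78)
  expect_warning(
    out <- extract_onset_events(co, zero_shifts(co), "MCI",
                                use_staging_fallback = FALSE),
    "without usable diagnosis")
  expect_equal(nrow(out), 0)
})

test_that("km_estimate matches the hand-computed product-limit values", {
  # three events, no censoring: S = 2/3, 1/3, 0
  ev <- data.frame(fdi_time = c(77, 79, 81), status = 1L, endpoint = "MCI")
  km <- km_estimate(ev)
  expect_equal(km$surv, c(2, 1, 0) / 3, tolerance = 1e-12)
  expect_equal(km$time, c(77, 79, 81))

  # event 70, censored 72, event 75: S = 2/3 at 70, 0 at 75
  ev2 <- data.frame(fdi_time = c(70, 72, 75), status = c(1L, 0L, 1L),
                    endpoint = "AD")
  km2 <- km_estimate(ev2)
  expect_equal(km2$surv[km2$time == 70], 2 / 3, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 75], 0, tolerance = 1e-12)

  # single event among censorings: exactly one drop
  ev3 <- data.frame(fdi_time = c(70, 71, 73, 76), status = c(0L, 0L, 1L, 0L))
  km3 <- km_estimate(ev3)
  expect_equal(sum(diff(c(1, km3$surv)) < 0), 1)

  expect_error(km_estimate(data.frame(fdi_time = c(70, 75), status = 0L)),
               "no events")
})

test_that("km_estimate agrees with the product-limit oracle on all small configurations", {
  # every event/censor pattern for 1-6 subjects, distinct and tied times
  for (n in 1:6) {
    times_sets <- list(seq_len(n), ceiling(seq_len(n) / 2))
    for (times in times_sets) {
      for (mask in seq_len(2^n) - 1L) {
        status <- as.integer(intToBits(mask)[1:n])
        if (sum(status) == 0) next
        ev <- data.frame(fdi_time = times, status = status)
        km <- km_estimate(ev)
        oracle <- km_oracle(times, status)
        got <- km$surv[match(oracle$time, km$time)]
        expect_equal(got, oracle$surv, tolerance = 1e-12)
      }
    }
  }
})

test_that("survival curve is a non-increasing step function bounded by [0, 1]", {
  sim <- simulate_cohort(sim_config(n = 150, seed = 4))
  al <- suppressWarnings(fit_alignment_model(sim$cohort))
  ev <- extract_onset_events(sim$cohort, al, "MCI")
  km <- km_estimate(ev)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_true(all(km$surv[km$time < min(ev$fdi_time[ev$status == 1])] == 1))
  # with no censoring, S(t) = 1 - ECDF of the event times
  evc <- ev[ev$status == 1, ]
  kmc <- km_estimate(evc)
  ec <- stats::ecdf(evc$fdi_time)
  expect_equal(kmc$surv, 1 - ec(kmc$time), tolerance = 1e-12)
})

test_that("threshold is the first time S reaches 1 - p, without extrapolation", {
  km <- km_estimate(data.frame(fdi_time = c(77, 79, 81), status = 1L))
  expect_equal(threshold_from_curve(km), 79)       # first S <= 0.5

  # first-crossing contract at a near-tie
  curve <- structure(list(endpoint = "MCI", time = c(80, 80.5),
                          surv = c(0.51, 0.49)), class = "fdi_surv")
  expect_equal(threshold_from_curve(curve), 80.5)

  # non-crossing curve: undefined, not extrapolated
  high <- structure(list(endpoint = "MCI", time = c(80, 82),
                         surv = c(0.8, 0.6)), class = "fdi_surv")
  expect_error(threshold_from_curve(high), "threshold undefined")

  # theta is non-decreasing in the onset probability p
  km6 <- km_estimate(data.frame(fdi_time = 70 + (1:8), status = 1L))
  ths <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), threshold_from_curve,
                numeric(1), curve = km6)
  expect_true(all(diff(ths) >= 0))
})

test_that("stratified thresholds recover a designed between-group onset offset", {
  cfg <- sim_config(n = 300, seed = 9,
                    covariate_effects = list(
                      hypertension = list(prob = 0.5, mci_offset = 3,
                                          ad_offset = 3)))
  sim <- simulate_cohort(cfg)
  al <- suppressWarnings(fit_alignment_model(sim$cohort))
  th <- stratified_thresholds(sim$cohort, al, "MCI",
                              stratify_by = "hypertension")
  t_true <- th$threshold[th$stratum_level == "TRUE"]
  t_false <- th$threshold[th$stratum_level == "FALSE"]
  expect_equal(t_true - t_false, 3, tolerance = 1)

  # a null covariate (sex) gives closely matching thresholds
  th_sex <- stratified_thresholds(sim$cohort, al, "MCI", stratify_by = "sex")
  expect_lt(abs(diff(th_sex$threshold)), 1)

  expect_error(stratified_thresholds(sim$cohort, al, "MCI",
                                     stratify_by = "nope"),
               "unknown covariate")
})

test_that("small strata are reported undefined with a warning", {
  sim <- simulate_cohort(sim_config(n = 40, seed = 10))
  al <- suppressWarnings(fit_alignment_model(sim$cohort))
  co <- sim$cohort
  co$covariates$rare <- rep(c(TRUE, rep(FALSE, 7)), length.out =
                              nrow(co$covariates))
  expect_warning(
    th <- stratified_thresholds(co, al, "MCI", stratify_by = "rare",
                                min_per_stratum = 20),
    "fewer than")
  expect_true(is.na(th$threshold[th$stratum_level == "TRUE"]))
})
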