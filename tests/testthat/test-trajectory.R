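# Mean-curve evaluation and fitting, per-participant alignment, and the
# joint alternating estimation.

test_that("eval_curve is the logistic with midpoint C/2 and known calibration", {
  cv <- ref_curve()
  expect_equal(eval_curve(cv, cv$t0), 9)            # C/2 at the midpoint
  expect_equal(eval_curve(cv, 79), 0.5, tolerance = 1e-12)
  expect_equal(eval_curve(cv, 85), 4.5, tolerance = 1e-12)
  t <- seq(40, 120, by = 0.5)
  expect_true(all(diff(eval_curve(cv, t)) > 0))     # strictly increasing
  expect_true(all(eval_curve(cv, t) > 0 & eval_curve(cv, t) < 18))
  expect_equal(invert_curve(cv, eval_curve(cv, 83.2)), 83.2, tolerance = 1e-9)
})

test_that("bin_mean_trajectory averages within bins and flags empty bins", {
  visits <- data.frame(
    participant_id = c("A", "A", "B", "B"),
    age = c(70.2, 72.4, 70.7, 96.5),
    cdr_sb = c(1, 3, 2, 10), diagnosis = NA_character_
  )
  co <- fdindex:::new_cohort(visits, data.frame(participant_id = c("A", "B")))
  b <- bin_mean_trajectory(co)
  expect_equal(nrow(b), 40)                          # all bins present
  expect_equal(b$mean_cdr_sb[b$bin == 70], 1.5)      # (1 + 2) / 2
  expect_equal(b$n[b$bin == 70], 2)
  expect_true(is.na(b$mean_cdr_sb[b$bin == 95]))     # empty bin, not zero
  expect_equal(b$n[b$bin == 95], 0)
})

test_that("bin means of a noise-free on-curve cohort match the curve", {
  sim <- simulate_cohort(sim_config(n = 400, noise_sd = 0, round_scores = FALSE,
                                    delta_sd = 0, seed = 2))
  b <- bin_mean_trajectory(sim$cohort)
  busy <- !is.na(b$mean_cdr_sb) & b$n >= 20
  expect_gt(sum(busy), 5)
  # bin means vs the curve at the mean observed age within each bin (the
  # midpoint comparison would pick up the within-bin age distribution, not
  # a fitting error)
  expect_lt(max(abs(b$mean_cdr_sb[busy] - logistic(b$mean_age[busy]))), 0.1)
})

test_that("fit_mean_curve recovers exact and noisy logistic bins", {
  t <- seq(60.5, 99.5, by = 1)
  exact <- data.frame(age_mid = t, mean_cdr_sb = logistic(t), n = 50)
  fit <- fit_mean_curve(exact)
  expect_equal(fit$k, log(35 / 3) / 6, tolerance = 1e-3)
  expect_equal(fit$t0, 85 + log(3) / (log(35 / 3) / 6), tolerance = 1e-3)

  withr::with_seed(11, {
    noisy <- exact
    noisy$mean_cdr_sb <- pmax(noisy$mean_cdr_sb + rnorm(nrow(noisy), 0, 0.2), 0)
    fitn <- fit_mean_curve(noisy)
    expect_lt(abs(fitn$t0 - (85 + log(3) / (log(35 / 3) / 6))), 0.5)
  })

  flat <- data.frame(age_mid = t, mean_cdr_sb = 0, n = 50)
  expect_error(fit_mean_curve(flat), "no rising signal")
  expect_error(fit_mean_curve(exact[1:2, ]), "at least 3")
})

test_that("free-ceiling fit stays within (0, 18] and recovers a lower ceiling", {
  t <- seq(60.5, 99.5, by = 1)
  b <- data.frame(age_mid = t,
                  mean_cdr_sb = 12 / (1 + exp(-0.4 * (t - 86))), n = 30)
  fit <- fit_mean_curve(b, fix_ceiling = FALSE)
  expect_equal(fit$C, 12, tolerance = 0.05)
  expect_lte(fit$C, 18)
})

test_that("align_participant recovers an exact shift on the rising region", {
  cv <- ref_curve()
  s <- on_curve_series(fdi = c(80, 81.5, 83, 84.5), delta_true = 5)
  a <- align_participant(s, cv)
  expect_equal(a$delta, 5, tolerance = 1e-2)
  expect_true(a$identifiable)
  expect_lt(a$sse, 1e-6)
})

test_that("flat floor trajectories are unidentifiable with delta pulled to zero", {
  cv <- ref_curve()
  s <- data.frame(age = seq(62, 68, by = 1.5), cdr_sb = 0)
  a <- align_participant(s, cv)
  expect_false(a$identifiable)
  expect_equal(a$censor_side, "floor")
  expect_lt(abs(a$delta), 0.5)
  # ceiling case mirrors it
  s18 <- data.frame(age = seq(96, 102, by = 1.5), cdr_sb = 18)
  a18 <- align_participant(s18, cv)
  expect_false(a18$identifiable)
  expect_equal(a18$censor_side, "ceiling")
  expect_error(align_participant(data.frame(age = 70, cdr_sb = 1), cv),
               "at least 2 visits")
})

test_that("alignment is translation equivariant", {
  cv <- ref_curve()
  withr::with_seed(21, {
    for (i in 1:5) {
      fdi <- sort(runif(4, 76, 92))
      s <- on_curve_series(fdi, delta_true = runif(1, -8, 8))
      s$cdr_sb <- pmin(pmax(s$cdr_sb + rnorm(4, 0, 0.3), 0), 18)
      base <- align_participant(s, cv)$delta
      for (shift in c(-5, 3, 10)) {
        s2 <- s
        s2$age <- s$age + shift
        expect_equal(align_participant(s2, cv)$delta, base - shift,
                     tolerance = 1e-2)
      }
    }
  })
})

test_that("to_fdi shifts ages and preserves spacing exactly", {
  expect_equal(to_fdi(c(70, 71.5), 8), c(78, 79.5))
  s <- data.frame(age = c(70, 71.5, 74.5), cdr_sb = 1)
  out <- to_fdi(s, 0)
  expect_equal(out$fdi, s$age)
  out2 <- to_fdi(s, -3.25)
  expect_equal(diff(out2$fdi), diff(s$age))
})

test_that("alternating fit sends identical participants to zero shift", {
  visits <- do.call(rbind, lapply(sprintf("P%02d", 1:8), function(id)
    on_curve_series(c(80, 81.5, 83), delta_true = 0, id = id)))
  visits$diagnosis <- NA_character_
  co <- fdindex:::new_cohort(visits,
                             data.frame(participant_id = unique(visits$participant_id)))
  al <- fit_alignment_model(co)
  expect_true(all(abs(al$shifts$delta) < 1e-6))
  expect_true(all(al$shifts$identifiable))
})

test_that("alternating fit recovers curve and shifts on a noise-free cohort", {
  sim <- simulate_cohort(sim_config(n = 200, noise_sd = 0, round_scores = FALSE,
                                    seed = 1))
  al <- suppressWarnings(fit_alignment_model(sim$cohort))
  expect_true(al$convergence$converged)
  k_true <- log(35 / 3) / 6
  t0_true <- 85 + log(3) / k_true
  expect_lt(abs(al$curve$k - k_true) / k_true, 1e-2)
  expect_lt(abs(al$curve$t0 - t0_true) / t0_true, 1e-2)

  m <- merge(al$shifts, sim$truth, by = "participant_id")
  idf <- m$identifiable
  expect_gt(sum(idf), 80)
  # anchoring fixes the scale origin; compare shifts after centring both
  # vectors the same way (visit-weighted over identifiable subjects)
  ctr <- function(x) x - stats::weighted.mean(x[idf], m$n_visits[idf])
  expect_lt(max(abs(ctr(m$delta)[idf] - ctr(m$delta_true)[idf])), 0.25)

  # anchored objective decreased over the run
  obj <- al$convergence$objective
  expect_lt(obj[length(obj)], obj[1])
})

test_that("whole-model fit is translation equivariant in the age scale", {
  sim <- simulate_cohort(sim_config(n = 60, seed = 5))
  al1 <- suppressWarnings(fit_alignment_model(sim$cohort))
  shifted <- sim$cohort
  shifted$visits$age <- shifted$visits$age + 4
  al2 <- suppressWarnings(fit_alignment_model(shifted))
  expect_equal(al2$curve$t0 - al1$curve$t0, 4, tolerance = 0.05)
  expect_equal(al2$curve$k, al1$curve$k, tolerance = 1e-3)
  expect_equal(al2$shifts$delta, al1$shifts$delta, tolerance = 0.05)
})
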