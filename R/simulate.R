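# Synthetic longitudinal cohort generator with known ground truth.
#
# Emulates the structure of observational Alzheimer disease cohorts:
# enrolment after age 60, ~1.5-year visit spacing, 3-10 years of follow-up,
# CDR-SB on the 0.5-point grid in [0, 18], a mixture of cognitively
# unimpaired / MCI / AD outcomes. Ground truth is defined on the latent
# (noise-free) trajectory, so true onset ages are exact real numbers while
# observed scores carry measurement noise and rounding — the separation of
# measurement error from estimand that real cohorts cannot provide.

#' Simulation configuration
#'
#' Defaults reflect the cohorts the generator emulates: baseline age normal
#' with mean 72 and SD 7 (truncated to (60, 95]), 1.5-year visit interval,
#' follow-up uniform on 3-10 years, shift SD 6 years (spreading onset ages
#' with an SD comparable to observed onset-age SDs of ~6.5-7 years),
#' observation noise SD 0.5 score units, scores rounded to the 0.5 grid.
#' The latent curve is the calibration logistic (ceiling 18) crossing the
#' MCI cut (0.5) at FDI 79 and the AD cut (4.5) at FDI 85, so the designed
#' onset FDIs are exactly 79 and 85.
#'
#' @param n number of participants.
#' @param curve latent mean trajectory, an [fdi_curve()].
#' @param delta_sd SD of the true time shifts (years).
#' @param baseline_age_mean,baseline_age_sd,baseline_age_range truncated
#'   normal for age at first visit; the lower bound is exclusive so every
#'   participant enrols after 60.
#' @param visit_interval years between visits.
#' @param followup_range uniform range of follow-up length (years).
#' @param noise_sd SD of the observation noise (score units).
#' @param round_scores round observed scores to the 0.5-point grid.
#' @param staging_cuts MCI and AD staging cuts on the score scale.
#' @param covariate_effects optional named list, one entry per covariate,
#'   each a list with `prob` (carrier probability) and `mci_offset` /
#'   `ad_offset` (years added to the carrier group's onset FDIs; the
#'   diagnosis rule shifts, scores do not).
#' @param label_delay_prob probability that a participant's onset labels are
#'   delayed by one visit (diagnosis lag noise; default 0 = clean labels).
#' @param seed RNG seed; everything downstream is deterministic given it.
#' @return A `fdi_sim_config` list.
#' @export
sim_config <- function(n = 500,
                       curve = fdi_curve(k = log(35/3)/6,
                                         t0 = 85 + log(3)/(log(35/3)/6)),
                       delta_sd = 6,
                       baseline_age_mean = 72, baseline_age_sd = 7,
                       baseline_age_range = c(60, 95),
                       visit_interval = 1.5, followup_range = c(3, 10),
                       noise_sd = 0.5, round_scores = TRUE,
                       staging_cuts = c(0.5, 4.5),
                       covariate_effects = NULL,
                       label_delay_prob = 0, seed = 1) {
  stopifnot(n >= 1, inherits(curve, "fdi_curve"), delta_sd >= 0,
            noise_sd >= 0, visit_interval > 0,
            followup_range[1] <= followup_range[2],
            staging_cuts[1] < staging_cuts[2],
            label_delay_prob >= 0, label_delay_prob <= 1)
  structure(
    list(n = n, curve = curve, delta_sd = delta_sd,
         baseline_age_mean = baseline_age_mean,
         baseline_age_sd = baseline_age_sd,
         baseline_age_range = baseline_age_range,
         visit_interval = visit_interval, followup_range = followup_range,
         noise_sd = noise_sd, round_scores = round_scores,
         staging_cuts = staging_cuts, covariate_effects = covariate_effects,
         label_delay_prob = label_delay_prob, seed = seed),
    class = "fdi_sim_config"
  )
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  # exclusive lower bound; rejection sampling is exact and deterministic
  # under the ambient RNG stream
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x <= hi) return(x)
  }
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Per participant: a true shift `delta* ~ N(0, delta_sd)` and baseline age
#' are drawn; the latent trajectory is `m(age + delta*)` on the
#' configuration's curve; visits run from baseline every `visit_interval`
#' years to the end of follow-up; the observed score is the latent value
#' plus `N(0, noise_sd)` noise, rounded to the 0.5 grid and clamped to
#' \[0, 18\]; the diagnosis label at a visit follows the latent stage
#' (CU/MCI/AD), with any configured covariate offsets shifting the carrier
#' group's diagnosis rule along the FDI axis. True onset ages solve the
#' latent crossing exactly: `onset_age = invert_curve(cut) + offset - delta*`.
#'
#' @param config an [sim_config()].
#' @return An `fdi_sim`: `cohort` (an `fdi_cohort`), `truth` (data.frame
#'   `participant_id`, `delta_true`, `onset_mci_age`, `onset_ad_age`,
#'   `onset_mci_fdi`, `onset_ad_fdi`, covariate columns), `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n = 20, seed = 42))
#' head(sim$truth)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "fdi_sim_config"))
  cv <- config$curve
  f_mci <- invert_curve(cv, config$staging_cuts[1])
  f_ad <- invert_curve(cv, config$staging_cuts[2])
  covs <- config$covariate_effects
  cov_names <- names(covs)

  with_seed(config$seed, {
    visits_list <- vector("list", config$n)
    truth_list <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      id <- sprintf("S%04d", i)
      delta <- stats::rnorm(1, 0, config$delta_sd)
      b_age <- rtruncnorm1(config$baseline_age_mean, config$baseline_age_sd,
                           config$baseline_age_range[1],
                           config$baseline_age_range[2])
      fu <- stats::runif(1, config$followup_range[1], config$followup_range[2])
      ages <- b_age + seq(0, fu, by = config$visit_interval)

      o_mci <- 0; o_ad <- 0
      carrier <- stats::setNames(logical(length(cov_names)), cov_names)
      for (nm in cov_names) {
        carrier[nm] <- stats::runif(1) < (covs[[nm]]$prob %||% 0.5)
        if (carrier[nm]) {
          o_mci <- o_mci + (covs[[nm]]$mci_offset %||% 0)
          o_ad <- o_ad + (covs[[nm]]$ad_offset %||% 0)
        }
      }
      sex <- if (stats::runif(1) < 0.5) "F" else "M"

      latent_fdi <- ages + delta
      latent <- eval_curve(cv, latent_fdi)
      noise <- if (config$noise_sd > 0)
        stats::rnorm(length(ages), 0, config$noise_sd) else 0
      obs <- latent + noise
      if (config$round_scores) obs <- round(obs * 2) / 2
      obs <- clamp(obs, 0, cv$C)

      diag <- ifelse(latent_fdi >= f_ad + o_ad, "AD",
                     ifelse(latent_fdi >= f_mci + o_mci, "MCI", "CU"))
      if (config$label_delay_prob > 0 && stats::runif(1) < config$label_delay_prob) {
        # diagnosis lags the latent stage by one visit
        diag <- c("CU", diag[-length(diag)])
      }

      row_cov <- as.list(carrier)
      visits_list[[i]] <- data.frame(
        participant_id = id, age = ages, cdr_sb = obs, mmse = NA_real_,
        diagnosis = diag, stringsAsFactors = FALSE
      )
      truth_list[[i]] <- data.frame(
        participant_id = id, delta_true = delta,
        onset_mci_age = f_mci + o_mci - delta,
        onset_ad_age = f_ad + o_ad - delta,
        onset_mci_fdi = f_mci + o_mci, onset_ad_fdi = f_ad + o_ad,
        sex = sex, stringsAsFactors = FALSE
      )
      for (nm in cov_names) truth_list[[i]][[nm]] <- carrier[[nm]]
    }

    visits <- do.call(rbind, visits_list)
    truth <- do.call(rbind, truth_list)
    cov_df <- truth[, c("participant_id", "sex", cov_names), drop = FALSE]
    cohort <- new_cohort(visits, cov_df,
                         provenance = sprintf("synthetic cohort (n=%d, seed=%d)",
                                              config$n, config$seed))
    structure(list(cohort = cohort, truth = truth, config = config),
              class = "fdi_sim")
  })
}

#' @export
print.fdi_sim <- function(x, ...) {
  cat(sprintf("<fdi_sim> n = %d (seed %d)\n", x$config$n, x$config$seed))
  print(x$cohort)
  invisible(x)
}

#' Summary of a simulated cohort's ground truth
#'
#' @param sim an `fdi_sim`.
#' @return List with `median_onset_mci_fdi`, `median_onset_ad_fdi`,
#'   `shift_sd`, and (when covariate effects are configured) per-stratum
#'   median onset FDIs; strata with no members are omitted.
#' @export
truth_report <- function(sim) {
  stopifnot(inherits(sim, "fdi_sim"))
  tr <- sim$truth
  out <- list(
    median_onset_mci_fdi = stats::median(tr$onset_mci_fdi),
    median_onset_ad_fdi = stats::median(tr$onset_ad_fdi),
    shift_sd = stats::sd(tr$delta_true)
  )
  for (nm in names(sim$config$covariate_effects)) {
    for (lv in c(TRUE, FALSE)) {
      sel <- tr[[nm]] == lv
      if (!any(sel)) next
      out[[sprintf("median_onset_mci_fdi_%s_%s", nm, lv)]] <-
        stats::median(tr$onset_mci_fdi[sel])
      out[[sprintf("median_onset_ad_fdi_%s_%s", nm, lv)]] <-
        stats::median(tr$onset_ad_fdi[sel])
    }
  }
  out
}
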