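# Onset events on the FDI scale, Kaplan-Meier survival and onset thresholds.
#
# An MCI (or AD) onset event is the FDI of the first visit at which the
# participant carries a qualifying diagnosis; participants never reaching the
# endpoint are right-censored at their last-visit FDI. The FDI threshold for
# an endpoint is the first time the onset-free survival curve reaches 0.5.

#' Extract onset events on the FDI scale
#'
#' For endpoint `"MCI"` the qualifying diagnoses are MCI and AD (a
#' participant who converts straight from cognitively unimpaired to AD has a
#' latent MCI onset no later than the AD visit; set
#' `cu_to_ad_counts_mci = FALSE` to exclude such converters from the MCI
#' analysis instead). For endpoint `"AD"` only an AD diagnosis qualifies.
#' The clinician diagnosis column is authoritative; when a visit has no
#' diagnosis and `use_staging_fallback` is `TRUE`, the CDR-SB staging rule
#' ([stage_from_cdrsb()]) fills in. Participants already at or past the
#' endpoint at their first visit (prevalent cases) are excluded and counted.
#'
#' @param cohort an `fdi_cohort`.
#' @param alignment an `fdi_alignment` (or its `shifts` data.frame) covering
#'   every participant to be analysed.
#' @param endpoint `"MCI"` or `"AD"`.
#' @param use_staging_fallback stage visits without a diagnosis from CDR-SB.
#' @param cu_to_ad_counts_mci count direct CU-to-AD converters as MCI events
#'   at the AD visit.
#' @return data.frame of class `fdi_events` with `participant_id`,
#'   `endpoint`, `fdi_time`, `status` (1 = event, 0 = censored); attributes
#'   `n_prevalent` and `n_skipped` carry the exclusion counts.
#' @export
extract_onset_events <- function(cohort, alignment,
                                 endpoint = c("MCI", "AD"),
                                 use_staging_fallback = TRUE,
                                 cu_to_ad_counts_mci = TRUE) {
  endpoint <- match.arg(endpoint)
  shifts <- if (inherits(alignment, "fdi_alignment")) alignment$shifts else alignment
  series <- cohort_series(cohort)
  ids <- names(series)
  missing_shift <- setdiff(ids, shifts$participant_id)
  if (length(missing_shift))
    stop_fdi(paste0("no shift for participant(s): ",
                    paste(utils::head(missing_shift, 5), collapse = ", ")),
             "fdi_precondition_error")

  out <- vector("list", length(ids))
  n_prevalent <- 0L
  n_skipped <- 0L
  for (j in seq_along(ids)) {
    s <- series[[j]]
    delta <- shifts$delta[match(ids[j], shifts$participant_id)]
    diag <- s$diagnosis %||% rep(NA_character_, nrow(s))
    if (use_staging_fallback) {
      fill <- is.na(diag) & !is.na(s$cdr_sb)
      diag[fill] <- stage_from_cdrsb(s$cdr_sb[fill])
    }
    usable <- !is.na(diag) & diag != "OTHER"
    if (!any(usable)) { n_skipped <- n_skipped + 1L; next }
    dg <- diag[usable]
    fdi <- s$age[usable] + delta

    qualifying <- if (endpoint == "AD") dg == "AD" else dg %in% c("MCI", "AD")
    first_q <- if (any(qualifying)) which(qualifying)[1] else NA_integer_

    if (endpoint == "MCI" && !cu_to_ad_counts_mci &&
        !is.na(first_q) && dg[first_q] == "AD") {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!is.na(first_q) && first_q == 1L) { n_prevalent <- n_prevalent + 1L; next }

    if (is.na(first_q)) {
      out[[j]] <- data.frame(participant_id = ids[j], endpoint = endpoint,
                             fdi_time = fdi[length(fdi)], status = 0L,
                             stringsAsFactors = FALSE)
    } else {
      out[[j]] <- data.frame(participant_id = ids[j], endpoint = endpoint,
                             fdi_time = fdi[first_q], status = 1L,
                             stringsAsFactors = FALSE)
    }
  }
  if (n_skipped)
    warning(sprintf("%d participant(s) without usable diagnosis skipped", n_skipped))
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(participant_id = character(), endpoint = character(),
                     fdi_time = numeric(), status = integer(),
                     stringsAsFactors = FALSE)
  structure(ev, n_prevalent = n_prevalent, n_skipped = n_skipped,
            class = c("fdi_events", "data.frame"))
}

#' Kaplan-Meier estimate of onset-free survival on the FDI scale
#'
#' Product-limit estimator with right censoring (events precede censorings
#' at tied times, the standard convention) and 95% confidence limits on the
#' log-log scale, computed with the survival package.
#'
#' @param events an `fdi_events` data.frame (or any data.frame with
#'   `fdi_time` and `status`).
#' @return An `fdi_surv`: `endpoint`, and vectors `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lower`, `upper` over the observed times.
#' @export
km_estimate <- function(events) {
  stopifnot(is.data.frame(events), all(c("fdi_time", "status") %in% names(events)))
  if (!nrow(events) || sum(events$status) == 0)
    stop_fdi("no events for endpoint; cannot estimate a survival curve",
             "fdi_precondition_error")
  sf <- survival::survfit(
    survival::Surv(events$fdi_time, events$status) ~ 1,
    conf.type = "log-log", conf.int = 0.95
  )
  structure(
    list(endpoint = if (nrow(events) && "endpoint" %in% names(events))
                      events$endpoint[[1]] else NA_character_,
         time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
         n_censor = sf$n.censor, surv = sf$surv,
         lower = sf$lower, upper = sf$upper),
    class = "fdi_surv"
  )
}

#' @export
print.fdi_surv <- function(x, ...) {
  cat(sprintf("<fdi_surv> endpoint %s: %d times, %d events, S range [%.3f, 1]\n",
              x$endpoint, length(x$time), sum(x$n_event), min(x$surv)))
  invisible(x)
}

#' Export a survival curve as a data.frame
#'
#' @param x an `fdi_surv`.
#' @param ... unused.
#' @return data.frame with the time grid, risk table and confidence limits,
#'   suitable for CSV export and plotting.
#' @export
as.data.frame.fdi_surv <- function(x, ...) {
  data.frame(endpoint = x$endpoint, fdi = x$time, n_risk = x$n_risk,
             n_event = x$n_event, n_censor = x$n_censor, surv = x$surv,
             lower = x$lower, upper = x$upper, stringsAsFactors = FALSE)
}

#' FDI threshold at a given onset probability
#'
#' The threshold is the smallest observed FDI time at which the survival
#' estimate has dropped to `1 - p` or below (for the default `p = 0.5`, the
#' first time S reaches 0.5). The KM curve is a step function, so no
#' interpolation or extrapolation is performed; if the curve never reaches
#' `1 - p` the threshold is undefined and an error is raised.
#'
#' @param curve an `fdi_surv`.
#' @param p onset probability defining the threshold (default 0.5).
#' @return The FDI threshold (years).
#' @export
threshold_from_curve <- function(curve, p = 0.5) {
  stopifnot(inherits(curve, "fdi_surv"), p > 0, p < 1)
  hit <- which(curve$surv <= 1 - p + 1e-12)
  if (!length(hit))
    stop_fdi(sprintf("threshold undefined: survival never reaches %.3g (min S = %.3g)",
                     1 - p, min(curve$surv)),
             "fdi_threshold_error")
  curve$time[hit[1]]
}

threshold_row <- function(endpoint, stratum_var, stratum_level, events, p = 0.5) {
  theta <- tryCatch(threshold_from_curve(km_estimate(events), p = p),
                    fdi_error = function(e) NA_real_)
  data.frame(endpoint = endpoint,
             stratum_var = stratum_var, stratum_level = stratum_level,
             threshold = theta,
             n_events = sum(events$status == 1L),
             n_censored = sum(events$status == 0L),
             stringsAsFactors = FALSE)
}

#' Overall onset thresholds for both endpoints
#'
#' @param cohort an `fdi_cohort`.
#' @param alignment an `fdi_alignment` for the cohort.
#' @param p onset probability (default 0.5).
#' @param ... passed to [extract_onset_events()].
#' @return An `fdi_thresholds` data.frame (endpoint, stratum_var,
#'   stratum_level, threshold, n_events, n_censored) with overall rows for
#'   MCI and AD.
#' @export
overall_thresholds <- function(cohort, alignment, p = 0.5, ...) {
  rows <- lapply(c("MCI", "AD"), function(ep) {
    ev <- extract_onset_events(cohort, alignment, endpoint = ep, ...)
    threshold_row(ep, NA_character_, NA_character_, ev, p = p)
  })
  structure(do.call(rbind, rows), class = c("fdi_thresholds", "data.frame"))
}

#' Per-stratum onset thresholds
#'
#' Splits the cohort by a covariate (e.g. `"sex"` or a comorbidity flag),
#' runs the extract-events / Kaplan-Meier / threshold pipeline in each
#' stratum, and reports one threshold per stratum. Strata smaller than
#' `min_per_stratum` participants are reported with a missing threshold and
#' a small-sample warning rather than an unstable estimate.
#'
#' @param cohort an `fdi_cohort` with the covariate in `cohort$covariates`.
#' @param alignment an `fdi_alignment`.
#' @param endpoint `"MCI"` or `"AD"`.
#' @param stratify_by covariate column name.
#' @param min_per_stratum minimum participants per stratum (default 20).
#' @param p onset probability (default 0.5).
#' @param ... passed to [extract_onset_events()].
#' @return An `fdi_thresholds` data.frame, one row per stratum level.
#' @export
stratified_thresholds <- function(cohort, alignment, endpoint = c("MCI", "AD"),
                                  stratify_by, min_per_stratum = 20, p = 0.5,
                                  ...) {
  endpoint <- match.arg(endpoint)
  cov <- cohort$covariates
  if (is.null(cov) || !(stratify_by %in% names(cov)))
    stop_fdi(paste0("unknown covariate: ", stratify_by), "fdi_config_error")
  levels_present <- sort(unique(stats::na.omit(as.character(cov[[stratify_by]]))))
  if (!length(levels_present))
    stop_fdi(paste0("covariate has no non-missing values: ", stratify_by),
             "fdi_config_error")
  rows <- lapply(levels_present, function(lv) {
    ids <- cov$participant_id[!is.na(cov[[stratify_by]]) &
                                as.character(cov[[stratify_by]]) == lv]
    sub_visits <- cohort$visits[cohort$visits$participant_id %in% ids, , drop = FALSE]
    sub <- new_cohort(sub_visits, cov[cov$participant_id %in% ids, , drop = FALSE],
                      cohort$provenance)
    if (length(unique(sub_visits$participant_id)) < min_per_stratum) {
      warning(sprintf("stratum %s=%s has fewer than %d participants; threshold undefined",
                      stratify_by, lv, min_per_stratum))
      return(data.frame(endpoint = endpoint, stratum_var = stratify_by,
                        stratum_level = lv, threshold = NA_real_,
                        n_events = NA_integer_, n_censored = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    ev <- extract_onset_events(sub, alignment, endpoint = endpoint, ...)
    threshold_row(endpoint, stratify_by, lv, ev, p = p)
  })
  structure(do.call(rbind, rows), class = c("fdi_thresholds", "data.frame"))
}
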