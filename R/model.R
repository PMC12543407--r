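# FDI model bundle: mean curve + threshold table, serialization, and
# prediction of chronological age at MCI/AD onset.
#
# Prediction logic: a participant's shift delta places them on the FDI scale
# (FDI = age + delta); their predicted age at endpoint e is theta_e - delta,
# the chronological age at which their FDI reaches the endpoint threshold.

MODEL_SCHEMA_VERSION <- "1.0"

validate_thresholds <- function(thresholds) {
  req <- c("endpoint", "stratum_var", "stratum_level", "threshold",
           "n_events", "n_censored")
  if (!is.data.frame(thresholds) || !all(req %in% names(thresholds)))
    stop_fdi("threshold table must have columns endpoint, stratum_var, stratum_level, threshold, n_events, n_censored",
             "fdi_model_error")
  overall <- is.na(thresholds$stratum_var)
  for (ep in c("MCI", "AD"))
    if (!any(overall & thresholds$endpoint == ep & !is.na(thresholds$threshold)))
      stop_fdi(paste0("missing overall ", ep, " threshold"), "fdi_model_error")
  # theta_MCI <= theta_AD wherever both endpoints exist for a stratum pairing
  key <- paste(thresholds$stratum_var, thresholds$stratum_level, sep = "\r")
  for (kk in unique(key)) {
    mci <- thresholds$threshold[key == kk & thresholds$endpoint == "MCI"]
    ad <- thresholds$threshold[key == kk & thresholds$endpoint == "AD"]
    if (length(mci) && length(ad) && !is.na(mci[1]) && !is.na(ad[1]) &&
        mci[1] > ad[1])
      stop_fdi(sprintf("threshold ordering violated (MCI %.3g > AD %.3g) in stratum %s",
                       mci[1], ad[1], gsub("\r", "=", kk)),
               "fdi_model_error")
  }
  invisible(thresholds)
}

new_fdi_model <- function(curve, thresholds, provenance) {
  stopifnot(inherits(curve, "fdi_curve"))
  validate_thresholds(thresholds)
  if (!inherits(thresholds, "fdi_thresholds"))
    class(thresholds) <- c("fdi_thresholds", class(thresholds))
  structure(list(curve = curve, thresholds = thresholds,
                 provenance = provenance),
            class = "fdi_model")
}

#' Assemble an FDI model from a fitted alignment and threshold table
#'
#' @param alignment an `fdi_alignment` (supplies the mean curve).
#' @param thresholds an `fdi_thresholds` table containing at least the
#'   overall MCI and AD rows; `rbind` the output of [overall_thresholds()]
#'   and any [stratified_thresholds()] calls.
#' @param metadata optional named list stored in the provenance block.
#' @return An `fdi_model` with `provenance$source = "fitted"`.
#' @export
build_model <- function(alignment, thresholds, metadata = list()) {
  stopifnot(inherits(alignment, "fdi_alignment"))
  prov <- c(list(source = "fitted",
                 n_participants = nrow(alignment$shifts),
                 lambda = alignment$lambda,
                 converged = alignment$convergence$converged),
            metadata)
  new_fdi_model(alignment$curve, thresholds, prov)
}

#' The packaged reference FDI model
#'
#' Carries the published Florey Dementia Index onset thresholds: overall
#' MCI 79 and AD 85; sex-specific AD thresholds 84.7 (male) and 85.5
#' (female); and per-comorbidity thresholds for hypertension, stroke, other
#' neurologic disorders and psychiatric disorders (disease / disease-free
#' groups). The mean curve is a logistic with ceiling 18 whose rate and
#' midpoint are reconstructed so the curve crosses the MCI staging cut (0.5)
#' at FDI 79 and the AD cut (4.5) at FDI 85 — consistent with the reference
#' thresholds, but not itself a published fit; the provenance note records
#' this.
#'
#' @return An `fdi_model` with `provenance$source = "reference"`.
#' @export
#' @examples
#' m <- default_model()
#' get_threshold(m, "MCI")               # 79
#' get_threshold(m, "AD", "sex", "M")    # 84.7
default_model <- function() {
  k <- log(35 / 3) / 6
  t0 <- 85 + log(3) / k
  curve <- fdi_curve(k = k, t0 = t0, C = 18, fit_domain = c(60, 100))
  th <- function(ep, var, lev, theta)
    data.frame(endpoint = ep, stratum_var = var, stratum_level = lev,
               threshold = theta, n_events = NA_integer_,
               n_censored = NA_integer_, stringsAsFactors = FALSE)
  thresholds <- rbind(
    th("MCI", NA, NA, 79),
    th("AD",  NA, NA, 85),
    th("AD",  "sex", "M", 84.7),
    th("AD",  "sex", "F", 85.5),
    th("MCI", "hypertension", "TRUE", 78.2),
    th("MCI", "hypertension", "FALSE", 79),
    th("AD",  "hypertension", "TRUE", 85.3),
    th("AD",  "hypertension", "FALSE", 84.8),
    th("MCI", "stroke", "TRUE", 77.5),
    th("MCI", "stroke", "FALSE", 78.9),
    th("AD",  "stroke", "TRUE", 88.1),
    th("AD",  "stroke", "FALSE", 84.8),
    th("MCI", "neurologic", "TRUE", 77.8),
    th("MCI", "neurologic", "FALSE", 79),
    th("AD",  "neurologic", "TRUE", 86.4),
    th("AD",  "neurologic", "FALSE", 84.7),
    th("MCI", "psychiatric", "TRUE", 74.9),
    th("MCI", "psychiatric", "FALSE", 78.9),
    th("AD",  "psychiatric", "TRUE", 89.2),
    th("AD",  "psychiatric", "FALSE", 84.8)
  )
  new_fdi_model(curve, thresholds, list(
    source = "reference",
    note = paste("curve coefficients reconstructed from the reference",
                 "thresholds (crosses 0.5 at FDI 79 and 4.5 at FDI 85);",
                 "not a published cohort fit")
  ))
}

#' @export
print.fdi_model <- function(x, ...) {
  cat(sprintf("<fdi_model> source: %s\n", x$provenance$source %||% "?"))
  print(x$curve)
  cat(sprintf("  thresholds: MCI %.4g / AD %.4g overall; %d stratum rows\n",
              get_threshold(x, "MCI"), get_threshold(x, "AD"),
              sum(!is.na(x$thresholds$stratum_var))))
  invisible(x)
}

#' Look up an FDI onset threshold
#'
#' @param model an `fdi_model` (or an `fdi_thresholds` table).
#' @param endpoint `"MCI"` or `"AD"`.
#' @param stratum_var,stratum_level optional stratum; omit for the overall
#'   threshold.
#' @return The threshold (years), or `NA` if the requested entry is absent.
#' @export
get_threshold <- function(model, endpoint, stratum_var = NULL,
                          stratum_level = NULL) {
  tab <- if (inherits(model, "fdi_model")) model$thresholds else model
  sel <- tab$endpoint == endpoint
  sel <- sel & if (is.null(stratum_var)) is.na(tab$stratum_var)
               else !is.na(tab$stratum_var) & tab$stratum_var == stratum_var &
                    tab$stratum_level == as.character(stratum_level)
  if (!any(sel)) return(NA_real_)
  tab$threshold[which(sel)[1]]
}

#' Serialize an FDI model to JSON
#'
#' The file carries an explicit schema version; [read_model()] rejects
#' unknown versions. Numeric values are written at full precision so a
#' write/read round trip reproduces the model to 1e-12 and re-serialization
#' is byte-identical.
#'
#' @param model an `fdi_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fdi_model"))
  validate_thresholds(model$thresholds)
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    curve = list(family = model$curve$family, C = model$curve$C,
                 k = model$curve$k, t0 = model$curve$t0,
                 fit_domain = model$curve$fit_domain,
                 resid_sd = model$curve$resid_sd,
                 n_points = model$curve$n_points),
    thresholds = as.data.frame(unclass(model$thresholds),
                               stringsAsFactors = FALSE),
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load an FDI model from JSON
#'
#' @param path file written by [write_model()].
#' @return An `fdi_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_fdi(paste0("file not found: ", path), "fdi_io_error")
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop_fdi(paste0("malformed model file: ",
                                        conditionMessage(e)), "fdi_model_error"))
  if (!is.list(payload) || is.null(payload$schema_version))
    stop_fdi("malformed model file: no schema_version", "fdi_model_error")
  if (!identical(payload$schema_version, MODEL_SCHEMA_VERSION))
    stop_fdi(paste0("unsupported model schema version: ", payload$schema_version),
             "fdi_model_error")
  cv <- payload$curve
  if (is.null(cv$k) || is.null(cv$t0) || is.null(payload$thresholds))
    stop_fdi("malformed model file: missing curve or thresholds", "fdi_model_error")
  curve <- fdi_curve(k = cv$k, t0 = cv$t0, C = cv$C %||% 18,
                     family = cv$family %||% "logistic",
                     fit_domain = cv$fit_domain %||% c(60, 100),
                     resid_sd = cv$resid_sd %||% NA_real_,
                     n_points = cv$n_points %||% NA_real_)
  th <- as.data.frame(payload$thresholds, stringsAsFactors = FALSE)
  th$stratum_var <- as.character(th$stratum_var)
  th$stratum_level <- as.character(th$stratum_level)
  th$n_events <- as.integer(th$n_events)
  th$n_censored <- as.integer(th$n_censored)
  new_fdi_model(curve, th, as.list(payload$provenance))
}

#' Predict chronological age at MCI and AD onset for one participant
#'
#' Aligns the participant's visits to the model's mean curve to obtain their
#' time shift delta, then predicts onset age for each endpoint as
#' `theta_endpoint - delta`. Predictions that fall at or before the last
#' observed visit are flagged (`onset_at_or_before_last_visit`), not
#' clamped: the raw value is still reported. With `stratify_by`, the
#' threshold for the participant's stratum is used when present, falling
#' back to the overall threshold with a warning.
#'
#' @param series per-participant visit data.frame (columns `age`, `cdr_sb`).
#' @param model an `fdi_model`.
#' @param stratify_by optional covariate name for stratum-specific
#'   thresholds.
#' @param covariates optional named list/one-row data.frame giving the
#'   participant's covariate values (used with `stratify_by`).
#' @param ... passed to [align_participant()].
#' @return An `fdi_prediction` list: `participant_id`, `delta`,
#'   `current_fdi`, `pred_age_mci`, `pred_age_ad`, `flags` (per-endpoint
#'   onset-in-past flags and `identifiable`), `stratum`.
#' @export
#' @examples
#' m <- default_model()
#' visits <- data.frame(age = c(78, 80), cdr_sb = eval_curve(m$curve, c(78, 80)))
#' predict_onset(visits, m)  # delta = 0: onsets at 79 and 85
predict_onset <- function(series, model, stratify_by = NULL,
                          covariates = NULL, ...) {
  stopifnot(inherits(model, "fdi_model"))
  al <- align_participant(series, model$curve, ...)
  last_age <- max(series$age[!is.na(series$cdr_sb)])

  stratum <- NA_character_
  theta <- function(ep) {
    if (!is.null(stratify_by)) {
      lev <- if (!is.null(covariates)) covariates[[stratify_by]] else NULL
      if (!is.null(lev) && !is.na(lev)) {
        th <- get_threshold(model, ep, stratify_by, lev)
        if (!is.na(th)) {
          stratum <<- paste0(stratify_by, "=", lev)
          return(th)
        }
        warning(sprintf("no %s threshold for stratum %s=%s; using overall",
                        ep, stratify_by, lev))
      }
    }
    get_threshold(model, ep)
  }
  th_mci <- theta("MCI")
  th_ad <- theta("AD")
  pred_mci <- th_mci - al$delta
  pred_ad <- th_ad - al$delta
  structure(
    list(participant_id = al$participant_id, delta = al$delta,
         current_fdi = last_age + al$delta,
         pred_age_mci = pred_mci, pred_age_ad = pred_ad,
         flags = list(mci_onset_at_or_before_last_visit = pred_mci <= last_age,
                      ad_onset_at_or_before_last_visit = pred_ad <= last_age,
                      identifiable = al$identifiable),
         stratum = stratum),
    class = "fdi_prediction"
  )
}

#' @export
print.fdi_prediction <- function(x, ...) {
  cat(sprintf("<fdi_prediction> %s: delta %+.2f y, current FDI %.1f\n",
              x$participant_id %||% "?", x$delta, x$current_fdi))
  cat(sprintf("  predicted onset age: MCI %.1f%s, AD %.1f%s%s\n",
              x$pred_age_mci,
              if (x$flags$mci_onset_at_or_before_last_visit) " (at/before last visit)" else "",
              x$pred_age_ad,
              if (x$flags$ad_onset_at_or_before_last_visit) " (at/before last visit)" else "",
              if (x$flags$identifiable) "" else "  [shift not identifiable]"))
  invisible(x)
}

#' Predict onset ages for every eligible participant in a cohort
#'
#' @param cohort an `fdi_cohort`.
#' @param model an `fdi_model`.
#' @param stratify_by optional covariate name (see [predict_onset()]).
#' @param ... passed to [align_participant()].
#' @return data.frame with one row per participant with >= 2 scored visits:
#'   `participant_id`, `delta`, `current_fdi`, `pred_age_mci`,
#'   `pred_age_ad`, flag columns and `stratum`; participants with too few
#'   visits are listed in the `rejects` attribute.
#' @export
predict_cohort <- function(cohort, model, stratify_by = NULL, ...) {
  series <- cohort_series(cohort)
  cov <- cohort$covariates
  rows <- list()
  rejects <- character(0)
  for (id in names(series)) {
    s <- series[[id]]
    if (sum(!is.na(s$cdr_sb)) < 2) { rejects <- c(rejects, id); next }
    cv <- if (!is.null(cov)) cov[match(id, cov$participant_id), , drop = FALSE]
          else NULL
    p <- predict_onset(s, model, stratify_by = stratify_by, covariates = cv, ...)
    rows[[id]] <- data.frame(
      participant_id = id, delta = p$delta, current_fdi = p$current_fdi,
      pred_age_mci = p$pred_age_mci, pred_age_ad = p$pred_age_ad,
      mci_onset_at_or_before_last_visit = p$flags$mci_onset_at_or_before_last_visit,
      ad_onset_at_or_before_last_visit = p$flags$ad_onset_at_or_before_last_visit,
      identifiable = p$flags$identifiable,
      stratum = p$stratum, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_fdi("no participant has >= 2 scored visits",
                             "fdi_precondition_error")
  rownames(out) <- NULL
  structure(out, rejects = rejects)
}
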