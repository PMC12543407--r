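# Scoring predicted against observed onset ages: MAE and RMSE with
# percentile-bootstrap confidence intervals.
#
# Error convention throughout: error = predicted - observed, so positive
# errors are late predictions.

#' Signed onset-age errors (predicted - observed)
#'
#' @param predictions data.frame with `participant_id` and a predicted-age
#'   column (`pred_age`, or `pred_age_mci`/`pred_age_ad` selected via
#'   `endpoint`).
#' @param observed data.frame with `participant_id` and `onset_age`.
#' @param endpoint used to pick `pred_age_mci` or `pred_age_ad` when no
#'   plain `pred_age` column exists.
#' @return data.frame `participant_id`, `predicted`, `observed`, `error`;
#'   ids present on only one side are reported in the `unmatched` attribute.
#' @export
onset_errors <- function(predictions, observed, endpoint = NULL) {
  pcol <- if ("pred_age" %in% names(predictions)) "pred_age"
          else if (!is.null(endpoint)) paste0("pred_age_", tolower(endpoint))
          else stop_fdi("no pred_age column and no endpoint given", "fdi_config_error")
  stopifnot(pcol %in% names(predictions),
            all(c("participant_id", "onset_age") %in% names(observed)))
  obs <- observed[!is.na(observed$onset_age), , drop = FALSE]
  common <- intersect(predictions$participant_id, obs$participant_id)
  unmatched <- list(
    prediction_only = setdiff(predictions$participant_id, obs$participant_id),
    observed_only = setdiff(obs$participant_id, predictions$participant_id)
  )
  if (!length(common))
    stop_fdi("no participants have both a prediction and an observed onset",
             "fdi_precondition_error")
  pred <- predictions[[pcol]][match(common, predictions$participant_id)]
  o <- obs$onset_age[match(common, obs$participant_id)]
  structure(
    data.frame(participant_id = common, predicted = pred, observed = o,
               error = pred - o, stringsAsFactors = FALSE),
    unmatched = unmatched
  )
}

#' Mean absolute and root mean square error
#'
#' @param errors numeric vector of signed errors (years).
#' @return Named numeric vector `c(mae = , rmse = )`; `mae <= rmse` always.
#' @export
#' @examples
#' mae_rmse(c(1, -1, 2))  # 4/3 and sqrt(2)
mae_rmse <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stop_fdi("no errors to summarize", "fdi_precondition_error")
  c(mae = mean(abs(errors)), rmse = sqrt(mean(errors^2)))
}

#' Percentile bootstrap confidence interval for MAE or RMSE
#'
#' Resamples the error vector with replacement `B` times and takes the
#' percentile interval of the statistic. Deterministic for a fixed `seed`
#' (the caller's RNG state is untouched).
#'
#' @param errors numeric vector of signed errors; length >= 2.
#' @param statistic `"mae"` or `"rmse"`.
#' @param B number of bootstrap resamples (default 1000; < 100 warns).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(errors, statistic = c("mae", "rmse"), B = 1000,
                         level = 0.95, seed = 1) {
  statistic <- match.arg(statistic)
  errors <- errors[!is.na(errors)]
  n <- length(errors)
  if (n < 2) stop_fdi("bootstrap needs at least 2 errors", "fdi_precondition_error")
  if (B < 100) warning("fewer than 100 bootstrap resamples; interval is unstable")
  stat_fun <- if (statistic == "mae") function(e) mean(abs(e))
              else function(e) sqrt(mean(e^2))
  stats_b <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    if (statistic == "mae") rowMeans(abs(matrix(errors[idx], nrow = B)))
    else sqrt(rowMeans(matrix(errors[idx]^2, nrow = B)))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], upper = q[2])
}

new_eval_report <- function(endpoint, errors_df, mae, mae_ci, rmse, rmse_ci,
                            exclusions) {
  if (mae > rmse + 1e-12)
    stop_fdi("internal inconsistency: MAE exceeds RMSE", "fdi_internal_error")
  structure(
    list(endpoint = endpoint, n = nrow(errors_df),
         mae = mae, mae_ci = mae_ci, rmse = rmse, rmse_ci = rmse_ci,
         predicted_mean = mean(errors_df$predicted),
         predicted_sd = stats::sd(errors_df$predicted),
         observed_mean = mean(errors_df$observed),
         observed_sd = stats::sd(errors_df$observed),
         errors = errors_df, exclusions = exclusions),
    class = "fdi_eval"
  )
}

#' @export
print.fdi_eval <- function(x, ...) {
  cat(sprintf("<fdi_eval> endpoint %s, n = %d\n", x$endpoint, x$n))
  cat(sprintf("  MAE  %.3f y (95%% CI %.3f-%.3f)\n", x$mae, x$mae_ci[1], x$mae_ci[2]))
  cat(sprintf("  RMSE %.3f y (95%% CI %.3f-%.3f)\n", x$rmse, x$rmse_ci[1], x$rmse_ci[2]))
  cat(sprintf("  predicted onset %.1f (SD %.1f), observed %.1f (SD %.1f)\n",
              x$predicted_mean, x$predicted_sd, x$observed_mean, x$observed_sd))
  ex <- unlist(x$exclusions)
  if (any(ex > 0))
    cat("  excluded: ", paste(names(ex)[ex > 0], ex[ex > 0], sep = "=",
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Observed onset ages from recorded diagnoses: age at the first visit with a
# qualifying diagnosis. Prevalent participants (qualifying at first visit)
# get NA with prevalent = TRUE.
observed_onsets <- function(cohort, endpoint = c("MCI", "AD"),
                            use_staging_fallback = TRUE) {
  endpoint <- match.arg(endpoint)
  series <- cohort_series(cohort)
  out <- lapply(names(series), function(id) {
    s <- series[[id]]
    diag <- s$diagnosis %||% rep(NA_character_, nrow(s))
    if (use_staging_fallback) {
      fill <- is.na(diag) & !is.na(s$cdr_sb)
      diag[fill] <- stage_from_cdrsb(s$cdr_sb[fill])
    }
    qual <- if (endpoint == "AD") !is.na(diag) & diag == "AD"
            else !is.na(diag) & diag %in% c("MCI", "AD")
    first_q <- if (any(qual)) which(qual)[1] else NA_integer_
    data.frame(participant_id = id,
               onset_age = if (is.na(first_q) || first_q == 1L) NA_real_
                           else s$age[first_q],
               prevalent = !is.na(first_q) && first_q == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate onset-age prediction on a cohort with observed onsets
#'
#' For each participant with an observed onset, prediction uses only the
#' visits strictly before the observed onset age (no leakage of post-onset
#' scores); at least `min_pre_visits` scored visits must remain.
#' Participants whose pre-onset alignment is flagged non-identifiable are
#' still scored — pre-onset CDR-SB trajectories sit low on the curve by
#' construction, so the flag marks weak rather than absent information —
#' and their number is reported as `weakly_identified` in the exclusion
#' counts. Observed onsets are taken from the recorded
#' diagnoses (first qualifying visit) unless an explicit `onsets` table —
#' e.g. a simulator's exact ground truth — is supplied.
#'
#' @param model an `fdi_model`.
#' @param cohort an `fdi_cohort`.
#' @param endpoint `"MCI"` or `"AD"`.
#' @param onsets optional data.frame `participant_id`, `onset_age`
#'   overriding diagnosis-derived onsets.
#' @param min_pre_visits minimum scored visits before onset (default 2).
#' @param B,seed,level bootstrap settings for the MAE/RMSE intervals.
#' @param ... passed to [align_participant()].
#' @return An `fdi_eval` report.
#' @export
evaluate_cohort <- function(model, cohort, endpoint = c("MCI", "AD"),
                            onsets = NULL, min_pre_visits = 2, B = 1000,
                            seed = 1, level = 0.95, ...) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(model, "fdi_model"))
  if (is.null(onsets)) {
    ob <- observed_onsets(cohort, endpoint)
    n_prevalent <- sum(ob$prevalent)
    onsets <- ob[!is.na(ob$onset_age), c("participant_id", "onset_age")]
  } else {
    stopifnot(all(c("participant_id", "onset_age") %in% names(onsets)))
    n_prevalent <- 0L
    onsets <- onsets[!is.na(onsets$onset_age), c("participant_id", "onset_age")]
  }
  series <- cohort_series(cohort)
  exclusions <- list(no_observed_onset = length(series) - nrow(onsets) - n_prevalent,
                     prevalent = n_prevalent, too_few_pre_onset_visits = 0L,
                     weakly_identified = 0L)
  rows <- list()
  for (i in seq_len(nrow(onsets))) {
    id <- onsets$participant_id[i]
    s <- series[[id]]
    if (is.null(s)) next
    pre <- s[s$age < onsets$onset_age[i] & !is.na(s$cdr_sb), , drop = FALSE]
    if (nrow(pre) < min_pre_visits) {
      exclusions$too_few_pre_onset_visits <- exclusions$too_few_pre_onset_visits + 1L
      next
    }
    al <- align_participant(pre, model$curve, ...)
    if (!al$identifiable)
      exclusions$weakly_identified <- exclusions$weakly_identified + 1L
    rows[[id]] <- data.frame(
      participant_id = id,
      pred_age = get_threshold(model, endpoint) - al$delta,
      onset_age = onsets$onset_age[i], stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    stop_fdi(paste0("no evaluable participants (",
                    paste(names(exclusions), unlist(exclusions), sep = "=",
                          collapse = ", "), ")"),
             "fdi_precondition_error", data = exclusions)
  preds <- do.call(rbind, rows)
  err <- onset_errors(preds, preds[c("participant_id", "onset_age")],
                      endpoint = endpoint)
  mr <- mae_rmse(err$error)
  mae_ci <- if (nrow(err) >= 2)
    bootstrap_ci(err$error, "mae", B = B, level = level, seed = seed)
  else c(lower = NA_real_, upper = NA_real_)
  rmse_ci <- if (nrow(err) >= 2)
    bootstrap_ci(err$error, "rmse", B = B, level = level, seed = seed)
  else c(lower = NA_real_, upper = NA_real_)
  new_eval_report(endpoint, err, mr[["mae"]], mae_ci, mr[["rmse"]], rmse_ci,
                  exclusions)
}
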