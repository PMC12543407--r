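# Per-participant time-shift alignment: the age -> FDI transformation.
#
# Each participant's trajectory is shifted along the time axis until it sits
# on the population mean curve; the shift delta defines their FDI scale
# (FDI = age + delta). Shifts are estimated by penalized least squares with
# a small noise-scaled ridge term (lambda * sigma^2 * delta^2) standing in
# for Gaussian random-effect shrinkage, searched on a coarse grid and refined by
# golden-section. The population curve and the shifts are estimated jointly
# by alternating the two steps, with the shift mean anchored to zero so the
# FDI scale stays numerically comparable to chronological age.

golden_section <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (b - a > tol) {
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d_; fc <- fd; d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

#' Align one participant's trajectory to the mean curve
#'
#' Finds the time shift delta minimising the penalized squared distance
#' between the participant's observed CDR-SB values and the mean curve
#' evaluated at `age + delta`:
#' `sum_j (y_j - m(age_j + delta))^2 + lambda * sigma^2 * delta^2`,
#' the Gaussian-posterior form in which the shrinkage strength follows the
#' residual noise variance. `sigma` is floored at 0.25 — the maximum
#' rounding error of the score's 0.5-point grid, below which differences in
#' fit carry no information — so that on exact data a flat plateau of
#' optima still resolves toward `delta = 0`.
#' The search is a grid at `grid_step` resolution over `bounds` followed by
#' golden-section refinement to `tol`.
#'
#' A shift is flagged non-identifiable when the trajectory does not pin it
#' down: sliding the participant onto the saturated part of the curve (the
#' floor, fitted values near 0, or the ceiling, fitted values near C)
#' explains the data essentially as well as the optimum. Concretely, the
#' shift is identifiable only when
#' `min(sum(y^2), sum((y - C)^2)) - SSE(delta_hat) > 10 * sigma2`, where
#' `sigma2` is the squared residual noise scale: `sigma^2` when the caller
#' supplies a noise SD (as [fit_alignment_model()] does, from the pooled
#' curve fit), else the subject's own `SSE(delta_hat) / (n - 1)`; in both
#' cases floored at `0.25^2` (the score grid's maximum rounding error). A
#' trajectory that never leaves the floor (or ceiling) of the curve is
#' therefore unidentifiable, and on noisy data the rule additionally flags
#' flat trajectories whose apparent fit to the rising part of the curve is
#' indistinguishable from noise. For unidentifiable participants the ridge
#' pulls the reported delta toward zero, and the flag warns the caller that
#' the value carries no information.
#'
#' @param series per-participant visit data.frame (columns `age`, `cdr_sb`;
#'   `participant_id` optional) or a list with numeric `age` and `cdr_sb`.
#' @param curve an `fdi_curve`.
#' @param bounds search interval for delta in years.
#' @param lambda ridge penalty weight (dimensionless); default 1e-3.
#' @param grid_step coarse grid resolution in years.
#' @param tol refinement tolerance in years.
#' @param sigma residual noise SD used by the identifiability test; `NULL`
#'   (the default) estimates it from the subject's own residuals.
#' @return An `fdi_align` list: `participant_id`, `delta`, `sse`
#'   (unpenalized, at the optimum), `identifiable`, `n_visits_used`,
#'   `delta_lower`/`delta_upper` (the range of shifts whose SSE lies within
#'   the identifiability margin of the optimum), and `censor_side`
#'   (`"none"` for identifiable shifts; `"floor"`/`"ceiling"` says which
#'   saturated fit makes an unidentifiable shift one-sided — the true shift
#'   is then bounded by `delta_upper` / `delta_lower` respectively).
#' @export
align_participant <- function(series, curve, bounds = c(-30, 30),
                              lambda = 1e-3, grid_step = 0.25, tol = 1e-3,
                              sigma = NULL) {
  stopifnot(inherits(curve, "fdi_curve"))
  age <- series$age
  y <- series$cdr_sb
  id <- if (!is.null(series$participant_id)) as.character(series$participant_id[[1]])
        else NA_character_
  ok <- !is.na(age) & !is.na(y)
  age <- age[ok]; y <- y[ok]
  if (length(age) < 2)
    stop_fdi("alignment needs at least 2 visits with a CDR-SB score",
             "fdi_precondition_error")

  grid <- seq(bounds[1], bounds[2], by = grid_step)
  # unpenalized SSE for all grid deltas at once: rows = deltas, cols = visits
  tt <- outer(grid, age, `+`)
  m <- curve$C / (1 + exp(-curve$k * (tt - curve$t0)))
  sse_grid <- rowSums((m - matrix(y, nrow = length(grid), ncol = length(y),
                                  byrow = TRUE))^2)

  # shrinkage scales with the residual noise (Gaussian-posterior form): on
  # exact data the penalty vanishes up to a tie-break floor that still
  # pulls plateau optima toward delta = 0
  sigma2 <- if (!is.null(sigma) && is.finite(sigma)) sigma^2
            else min(sse_grid) / max(length(y) - 1, 1)
  sigma2 <- max(sigma2, 0.25^2)   # floor: max rounding error of the 0.5 grid
  lam_eff <- lambda * sigma2
  pen_grid <- sse_grid + lam_eff * grid^2

  i <- which.min(pen_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  pen <- function(d) {
    mm <- curve$C / (1 + exp(-curve$k * (age + d - curve$t0)))
    sum((y - mm)^2) + lam_eff * d^2
  }
  ref <- golden_section(pen, lo, hi, tol = tol)
  delta <- ref$minimum
  sse_min <- min(ref$objective - lam_eff * delta^2, min(sse_grid))

  # identifiability: the optimum must beat the saturated (floor/ceiling)
  # fits by more than residual noise could produce
  sse_floor <- sum(y^2)
  sse_ceiling <- sum((y - curve$C)^2)
  margin <- 10 * sigma2
  identifiable <- (min(sse_floor, sse_ceiling) - sse_min) > margin

  # range of shifts compatible with the data (SSE within the margin of the
  # optimum); for unidentifiable subjects the finite edge is a censoring
  # bound on the true shift
  compat <- grid[sse_grid <= sse_min + margin]
  structure(
    list(participant_id = id, delta = delta,
         sse = max(ref$objective - lam_eff * delta^2, 0),
         identifiable = identifiable, n_visits_used = length(age),
         delta_lower = min(compat, delta), delta_upper = max(compat, delta),
         censor_side = if (identifiable) "none"
                       else if (sse_floor <= sse_ceiling) "floor" else "ceiling"),
    class = "fdi_align"
  )
}

#' @export
print.fdi_align <- function(x, ...) {
  cat(sprintf("<fdi_align> %s: delta = %+.3f y (SSE %.4g, %d visits%s)\n",
              x$participant_id %||% "?", x$delta, x$sse, x$n_visits_used,
              if (x$identifiable) "" else ", NOT identifiable"))
  invisible(x)
}

#' Transform a participant's visit ages to the FDI scale
#'
#' @param series visit data.frame with an `age` column, or a numeric vector
#'   of ages.
#' @param delta the participant's time shift in years.
#' @return For a data.frame input, the same data.frame with an `fdi` column
#'   appended; for a numeric input, the shifted numeric vector.
#' @export
#' @examples
#' to_fdi(c(70, 71.5), delta = 8)
to_fdi <- function(series, delta) {
  stopifnot(is.finite(delta))
  if (is.numeric(series)) return(series + delta)
  series$fdi <- series$age + delta
  series
}

# Location of the shift distribution, treating unidentifiable shifts as
# censored observations: a trajectory stuck on the curve floor only bounds
# its shift from above (left-censored at the edge of its data-compatible
# range), one stuck at the ceiling bounds it from below. Censored-Gaussian
# MLE via survreg; falls back to the visit-weighted mean of identifiable
# shifts when the censored fit is not feasible.
shift_location <- function(delta, identifiable, cens_side, cens_bound,
                           n_visits) {
  if (!any(identifiable))
    return(stats::weighted.mean(delta, n_visits))
  fallback <- stats::weighted.mean(delta[identifiable], n_visits[identifiable])
  cens <- !identifiable & is.finite(cens_bound)
  if (sum(cens) < 3 || sum(identifiable) < 3) return(fallback)
  lower <- ifelse(identifiable, delta,
                  ifelse(cens_side == "ceiling", cens_bound, NA_real_))
  upper <- ifelse(identifiable, delta,
                  ifelse(cens_side == "floor", cens_bound, NA_real_))
  keep <- identifiable | cens
  fit <- tryCatch(
    suppressWarnings(survival::survreg(
      survival::Surv(lower[keep], upper[keep], type = "interval2") ~ 1,
      weights = n_visits[keep], dist = "gaussian"
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(stats::coef(fit)[1])) return(fallback)
  unname(stats::coef(fit)[1])
}

#' Jointly estimate the mean curve and all participant shifts
#'
#' Alternating least squares: (i) all shifts start at zero; (ii) the logistic
#' curve is fitted to the pooled shifted points `(age + delta, cdr_sb)` of
#' the subjects whose shift is currently identifiable (all subjects on the
#' first pass) — trajectories whose placement on the curve is arbitrary
#' would otherwise distort it; (iii) every shift is re-estimated against the
#' current curve by [align_participant()]; (iv) the shift distribution is
#' re-centred at zero — its location is estimated by a censored-Gaussian MLE
#' in which identifiable shifts are exact observations and unidentifiable
#' ones are censored at the edge of their data-compatible range (a flat
#' trajectory on the curve floor only bounds its shift from above), falling
#' back to the visit-weighted mean of identifiable shifts when too few
#' subjects are censored — with the curve midpoint `t0` adjusted in
#' compensation so fitted values are unchanged. This keeps the FDI scale
#' anchored to chronological age for the cohort as a whole rather than for
#' the (selectively more progressed) identifiable subset. After convergence,
#' each unidentifiable shift is reported as the conditional mean of the
#' fitted shift distribution given its censoring bound instead of the
#' arbitrary ridge optimum. Steps (ii)-(iv) repeat until the largest shift
#' change is below
#' `delta_tol` and the relative curve-parameter change is below
#' `curve_rel_tol`, or `max_iter` is reached (then `converged = FALSE` with a
#' warning).
#'
#' @param cohort an eligible `fdi_cohort` (see [apply_eligibility()]).
#' @param fix_ceiling keep the curve ceiling at 18.
#' @param bounds,lambda,grid_step,tol passed to [align_participant()].
#' @param delta_tol convergence tolerance on the largest shift change (years).
#' @param curve_rel_tol convergence tolerance on relative change in (k, t0).
#' @param max_iter iteration cap.
#' @return An `fdi_alignment`: `curve` (`fdi_curve`), `shifts` (data.frame
#'   with `participant_id`, `delta`, `sse`, `identifiable`, `n_visits`),
#'   `lambda`, `convergence` (list: `iterations`, `max_delta_change`,
#'   `converged`, `objective` trace of SSE + lambda*sum(delta^2)).
#' @export
fit_alignment_model <- function(cohort, fix_ceiling = TRUE,
                                bounds = c(-30, 30), lambda = 1e-3,
                                grid_step = 0.25, tol = 1e-3,
                                delta_tol = 0.01, curve_rel_tol = 1e-4,
                                max_iter = 100) {
  series <- cohort_series(cohort)
  series <- lapply(series, function(s) s[!is.na(s$cdr_sb), , drop = FALSE])
  usable <- vapply(series, nrow, integer(1)) >= 2
  if (!all(usable)) {
    warning(sprintf("%d participant(s) with < 2 scored visits skipped",
                    sum(!usable)))
    series <- series[usable]
  }
  if (!length(series)) stop_fdi("no alignable participants", "fdi_precondition_error")
  ids <- names(series)
  n_visits <- vapply(series, nrow, integer(1))
  ages <- lapply(series, `[[`, "age")
  ys <- lapply(series, `[[`, "cdr_sb")
  all_age <- unlist(ages, use.names = FALSE)
  all_y <- unlist(ys, use.names = FALSE)
  subj <- rep(seq_along(series), n_visits)

  delta <- rep(0, length(series))
  identifiable <- rep(TRUE, length(series))
  sse <- rep(NA_real_, length(series))
  cens_side <- rep("none", length(series))
  cens_bound <- rep(NA_real_, length(series))
  prev_par <- c(NA_real_, NA_real_)
  objective <- numeric(0)
  curve <- NULL
  converged <- FALSE
  max_change <- Inf

  for (iter in seq_len(max_iter)) {
    # curve step pools only subjects whose shift is currently identifiable:
    # the placement of unidentifiable trajectories is arbitrary and would
    # contaminate the curve (all subjects enter the first fit)
    use <- identifiable[subj]
    fit <- fit_logistic_wls(all_age[use] + delta[subj][use], all_y[use],
                            fix_ceiling = fix_ceiling)
    curve <- fdi_curve(k = fit$k, t0 = fit$t0, C = fit$C,
                       fit_domain = c(60, 100),
                       resid_sd = fit$resid_sd, n_points = fit$n_points)

    old_delta <- delta
    for (i in seq_along(series)) {
      a <- align_participant(list(age = ages[[i]], cdr_sb = ys[[i]]),
                             curve, bounds = bounds, lambda = lambda,
                             grid_step = grid_step, tol = tol,
                             sigma = curve$resid_sd)
      delta[i] <- a$delta
      identifiable[i] <- a$identifiable
      sse[i] <- a$sse
      cens_side[i] <- a$censor_side
      cens_bound[i] <- switch(a$censor_side, floor = a$delta_upper,
                              ceiling = a$delta_lower, NA_real_)
    }
    sig2 <- if (is.finite(curve$resid_sd)) curve$resid_sd^2 else 0.25^2
    objective <- c(objective, sum(sse) + lambda * max(sig2, 0.25^2) * sum(delta^2))

    # anchor: centre the estimated shift *distribution* at zero and shift
    # t0 in compensation (fitted values unchanged). Unidentifiable subjects
    # enter the location estimate as censored observations at the edge of
    # their data-compatible shift range; with none (or too few subjects for
    # the censored MLE) this reduces to the identifiable-shift mean.
    anchor <- shift_location(delta, identifiable, cens_side, cens_bound,
                             n_visits)
    delta <- delta - anchor
    cens_bound <- cens_bound - anchor
    curve$t0 <- curve$t0 - anchor

    max_change <- max(abs(delta - old_delta))
    par_now <- c(curve$k, curve$t0)
    rel_par <- if (anyNA(prev_par)) Inf
               else max(abs(par_now - prev_par) / pmax(abs(prev_par), 1e-8))
    prev_par <- par_now
    if (iter > 1 && max_change < delta_tol && rel_par < curve_rel_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("alignment did not converge in %d iterations (max shift change %.4f)",
                    max_iter, max_change))

  # reported shift for an unidentifiable subject: the conditional mean of
  # the fitted (zero-centred) shift distribution given its censoring bound,
  # rather than the arbitrary within-plateau ridge optimum
  if (any(!identifiable) && sum(identifiable) >= 3) {
    sd_delta <- stats::sd(delta[identifiable])
    if (is.finite(sd_delta) && sd_delta > 1e-8) {
      for (i in which(!identifiable)) {
        b <- cens_bound[i]
        if (!is.finite(b)) next
        z <- b / sd_delta
        # E[X | X < b] (floor side) / E[X | X > b] (ceiling) for X~N(0, sd^2)
        hr <- exp(stats::dnorm(z, log = TRUE) -
                    stats::pnorm(if (cens_side[i] == "floor") z else -z,
                                 log.p = TRUE))
        delta[i] <- if (cens_side[i] == "floor") -sd_delta * hr else sd_delta * hr
      }
    }
  }

  shifts <- data.frame(
    participant_id = ids, delta = delta, sse = sse,
    identifiable = identifiable, n_visits = n_visits,
    censor_side = cens_side, censor_bound = cens_bound,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(curve = curve, shifts = shifts, lambda = lambda,
         convergence = list(iterations = iter, max_delta_change = max_change,
                            converged = converged, objective = objective)),
    class = "fdi_alignment"
  )
}

#' @export
print.fdi_alignment <- function(x, ...) {
  cat(sprintf("<fdi_alignment> %d participants (%d identifiable), lambda = %g\n",
              nrow(x$shifts), sum(x$shifts$identifiable), x$lambda))
  print(x$curve)
  cv <- x$convergence
  cat(sprintf("  %s after %d iteration(s), max shift change %.4g y\n",
              if (cv$converged) "converged" else "NOT converged",
              cv$iterations, cv$max_delta_change))
  invisible(x)
}
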