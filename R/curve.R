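# Population mean CDR-SB trajectory on the FDI scale.
#
# The mean trajectory is a 3-parameter logistic m(t) = C / (1 + exp(-k (t -
# t0))) with the ceiling C normally fixed at 18, the CDR-SB maximum. It is
# strictly increasing, bounded by the valid score range, and matches the
# qualitative shape of population CDR-SB means: flat below an FDI of ~75,
# rising sharply between 75 and 100.

#' Construct a mean-trajectory curve
#'
#' @param k logistic rate (1/years), must be positive.
#' @param t0 logistic midpoint on the FDI scale (years); `m(t0) = C/2`.
#' @param C ceiling in score units (default 18, the CDR-SB maximum; use 30
#'   for an inverted-MMSE curve).
#' @param family curve family; only `"logistic"` is implemented.
#' @param fit_domain FDI range the curve was fitted on; evaluation outside it
#'   is extrapolation.
#' @param resid_sd residual SD from the fit (NA if not fitted).
#' @param n_points number of points (or total bin weight) used in the fit.
#' @return An object of class `fdi_curve`.
#' @export
fdi_curve <- function(k, t0, C = 18, family = "logistic",
                      fit_domain = c(60, 100), resid_sd = NA_real_,
                      n_points = NA_real_) {
  family <- match.arg(family, "logistic")
  stopifnot(is.numeric(k), length(k) == 1, k > 0,
            is.numeric(t0), length(t0) == 1, is.finite(t0),
            is.numeric(C), length(C) == 1, C > 0, is.finite(C))
  structure(
    list(family = family, C = C, k = k, t0 = t0,
         fit_domain = as.numeric(fit_domain),
         resid_sd = resid_sd, n_points = n_points),
    class = "fdi_curve"
  )
}

#' @export
print.fdi_curve <- function(x, ...) {
  cat(sprintf("<fdi_curve> %s: C = %.4g, k = %.4f /y, t0 = %.2f (FDI domain %g-%g)\n",
              x$family, x$C, x$k, x$t0, x$fit_domain[1], x$fit_domain[2]))
  if (!is.na(x$resid_sd))
    cat(sprintf("  fit: residual SD %.3f over %g points\n", x$resid_sd, x$n_points))
  invisible(x)
}

#' Evaluate the mean trajectory
#'
#' @param curve an `fdi_curve`.
#' @param t FDI value(s) in years.
#' @param warn_extrapolation warn when `t` falls outside the fit domain.
#' @return Expected CDR-SB score(s), in (0, C).
#' @export
#' @examples
#' cv <- fdi_curve(k = log(35/3)/6, t0 = 85 + log(3)/(log(35/3)/6))
#' eval_curve(cv, c(79, 85))  # 0.5 and 4.5 by calibration
eval_curve <- function(curve, t, warn_extrapolation = FALSE) {
  stopifnot(inherits(curve, "fdi_curve"))
  if (warn_extrapolation &&
      any(t < curve$fit_domain[1] | t > curve$fit_domain[2], na.rm = TRUE))
    warning("evaluating the mean trajectory outside its fit domain")
  curve$C / (1 + exp(-curve$k * (t - curve$t0)))
}

#' Invert the mean trajectory
#'
#' @param curve an `fdi_curve`.
#' @param y score value(s) strictly inside (0, C).
#' @return FDI value(s) t with `eval_curve(curve, t) = y`.
#' @export
invert_curve <- function(curve, y) {
  stopifnot(inherits(curve, "fdi_curve"))
  if (any(y <= 0 | y >= curve$C))
    stop_fdi("score must lie strictly inside (0, C) to invert the curve",
             "fdi_domain_error")
  curve$t0 - log(curve$C / y - 1) / curve$k
}

#' Bin mean CDR-SB scores by age (or FDI)
#'
#' Averages all visit scores falling in fixed-width age bins across the
#' cohort. Bins with no observations are kept as rows with `n = 0` and a
#' missing mean, so gaps are visible rather than imputed as zero.
#'
#' @param cohort an `fdi_cohort`.
#' @param ages two-element range covered by the bins (default 60-100 years).
#' @param width bin width in years.
#' @return data.frame with `bin` (left edge), `age_mid` (bin midpoint),
#'   `mean_age` (mean observed age within the bin), `mean_cdr_sb`, `n`.
#' @export
bin_mean_trajectory <- function(cohort, ages = c(60, 100), width = 1) {
  stopifnot(inherits(cohort, "fdi_cohort"), nrow(cohort$visits) > 0)
  edges <- seq(ages[1], ages[2], by = width)
  lefts <- edges[-length(edges)]
  v <- cohort$visits[!is.na(cohort$visits$cdr_sb), , drop = FALSE]
  # right-closed top bin so the range endpoint is not dropped
  idx <- findInterval(v$age, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= length(lefts)
  if (!any(inside))
    warning("no visits fall inside the binning range; table is empty")
  idx <- idx[inside]
  sc <- v$cdr_sb[inside]
  n <- tabulate(idx, nbins = length(lefts))
  s <- vapply(seq_along(lefts), function(i) sum(sc[idx == i]), numeric(1))
  a <- vapply(seq_along(lefts), function(i) sum(v$age[inside][idx == i]),
              numeric(1))
  data.frame(
    bin = lefts, age_mid = lefts + width / 2,
    mean_age = ifelse(n > 0, a / pmax(n, 1), NA_real_),
    mean_cdr_sb = ifelse(n > 0, s / pmax(n, 1), NA_real_), n = n
  )
}

# Weighted least-squares logistic fit; the workhorse behind fit_mean_curve
# and the curve step of fit_alignment_model. Start values from a logit
# linearisation of points away from the bounds.
fit_logistic_wls <- function(t, y, w = rep(1, length(t)), fix_ceiling = TRUE,
                             C = 18) {
  ok <- is.finite(t) & is.finite(y) & is.finite(w) & w > 0
  t <- t[ok]; y <- y[ok]; w <- w[ok]
  if (length(t) < 3) stop_fdi("need at least 3 points to fit the curve",
                              "fdi_fit_error")
  rng <- range(y)
  if (diff(rng) < 1e-8 || stats::weighted.mean(y, w) < 1e-8)
    stop_fdi("no rising signal in the data; cannot fit a logistic",
             "fdi_fit_error", data = list(range = rng))

  # start values: logit-linearise interior points, else crude fallback
  interior <- y > 0.02 * C & y < 0.98 * C
  k0 <- 0.3
  t00 <- stats::weighted.mean(t, w * pmax(y, 1e-6))
  if (sum(interior) >= 2) {
    z <- log(y[interior] / (C - y[interior]))
    fit0 <- stats::lm.wfit(cbind(1, t[interior]), z, w[interior])
    if (is.finite(fit0$coefficients[2]) && fit0$coefficients[2] > 0) {
      k0 <- fit0$coefficients[2]
      t00 <- -fit0$coefficients[1] / k0
    }
  }
  k0 <- clamp(k0, 0.05, 2)
  t00 <- clamp(t00, min(t) - 30, max(t) + 30)

  obj <- function(par) {
    kk <- par[1]; tt <- par[2]
    CC <- if (fix_ceiling) C else par[3]
    m <- CC / (1 + exp(-kk * (t - tt)))
    sum(w * (y - m)^2)
  }
  par0 <- if (fix_ceiling) c(k0, t00) else c(k0, t00, max(C * 0.9, rng[2]))
  lower <- if (fix_ceiling) c(1e-4, -1e3) else c(1e-4, -1e3, rng[2] + 1e-6)
  upper <- if (fix_ceiling) c(10, 1e3) else c(10, 1e3, C)
  fit <- tryCatch(
    stats::optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) list(convergence = 99L, message = conditionMessage(e),
                             par = par0, value = obj(par0))
  )
  if (fit$convergence != 0) {
    # line-search failures near flat directions: retry with Nelder-Mead on a
    # log-rate parametrization (keeps k > 0), polish with a bounded pass
    obj_nm <- function(par) {
      p <- c(exp(par[1]), par[2], if (!fix_ceiling) clamp(par[3], lower[3], C))
      obj(p)
    }
    par0_nm <- c(log(par0[1]), par0[-1])
    nm <- stats::optim(par0_nm, obj_nm, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    fit <- list(par = c(clamp(exp(nm$par[1]), lower[1], upper[1]), nm$par[2],
                        if (!fix_ceiling) clamp(nm$par[3], lower[3], C)),
                value = nm$value, convergence = nm$convergence,
                message = nm$message)
    if (fit$convergence != 0)
      stop_fdi(paste0("curve optimizer failed to converge: ",
                      fit$message %||% ""),
               "fdi_fit_error",
               data = list(par = fit$par, value = fit$value,
                           convergence = fit$convergence))
  }
  k <- unname(fit$par[1]); t0 <- unname(fit$par[2])
  CC <- if (fix_ceiling) C else unname(fit$par[3])
  dof <- max(length(t) - length(par0), 1)
  list(k = k, t0 = t0, C = CC, sse = fit$value,
       resid_sd = sqrt(fit$value / sum(w) * length(t) / dof),
       n_points = sum(w))
}

#' Fit the mean trajectory to binned cohort means
#'
#' Weighted least squares (weights = bin counts) of the logistic mean curve
#' to the output of [bin_mean_trajectory()]. The ceiling is fixed at the
#' CDR-SB maximum of 18 unless `fix_ceiling = FALSE`, in which case it is
#' estimated within (0, 18].
#'
#' @param binned data.frame from [bin_mean_trajectory()] (columns `age_mid`
#'   or `bin`, `mean_cdr_sb`, `n`).
#' @param fix_ceiling keep `C = 18` fixed.
#' @param fit_domain stored as the curve's fit domain; defaults to the range
#'   of non-empty bins.
#' @param C score ceiling: the fixed value when `fix_ceiling`, else the
#'   upper bound of the estimated ceiling (default 18, the CDR-SB maximum).
#' @return An `fdi_curve` with fit diagnostics.
#' @export
fit_mean_curve <- function(binned, fix_ceiling = TRUE, fit_domain = NULL,
                           C = 18) {
  stopifnot(is.data.frame(binned))
  tcol <- if ("age_mid" %in% names(binned)) "age_mid" else "bin"
  ok <- !is.na(binned$mean_cdr_sb) & binned$n > 0
  if (sum(ok) < 3)
    stop_fdi("need at least 3 non-empty bins to fit the mean curve",
             "fdi_fit_error")
  t <- binned[[tcol]][ok]; y <- binned$mean_cdr_sb[ok]; w <- binned$n[ok]
  fit <- fit_logistic_wls(t, y, w, fix_ceiling = fix_ceiling, C = C)
  fdi_curve(k = fit$k, t0 = fit$t0, C = fit$C,
            fit_domain = fit_domain %||% range(t),
            resid_sd = fit$resid_sd, n_points = fit$n_points)
}
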