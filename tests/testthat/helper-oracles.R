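# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results from first principles (fine-grid
# search, hand product-limit formula) rather than calling package internals.

# reference logistic used throughout: crosses 0.5 at t=79 and 4.5 at t=85
ref_curve <- function() {
  k <- log(35 / 3) / 6
  fdi_curve(k = k, t0 = 85 + log(3) / k)
}

logistic <- function(t, C = 18, k = log(35 / 3) / 6,
                     t0 = 85 + log(3) / (log(35 / 3) / 6)) {
  C / (1 + exp(-k * (t - t0)))
}

# Brute-force fine-grid minimiser of the alignment objective
#   SSE(delta) + lambda * max(sigma2, 0.25^2) * delta^2,
# with sigma2 = min SSE / (n - 1) when no noise SD is given (mirrors the
# documented objective, computed independently).
align_oracle <- function(age, y, curve, bounds = c(-30, 30), lambda = 1e-3,
                         sigma = NULL, step = 0.001) {
  deltas <- seq(bounds[1], bounds[2], by = step)
  sse <- vapply(deltas, function(d) {
    m <- curve$C / (1 + exp(-curve$k * (age + d - curve$t0)))
    sum((y - m)^2)
  }, numeric(1))
  sigma2 <- if (is.null(sigma)) min(sse) / max(length(y) - 1, 1) else sigma^2
  pen <- sse + lambda * max(sigma2, 0.25^2) * deltas^2
  deltas[which.min(pen)]
}

# Hand product-limit estimator: S(t) = prod over event times u <= t of
# (1 - d_u / n_u), censored subjects at a tied time still at risk for that
# time's events. Returns survival at each unique observed time.
km_oracle <- function(time, status) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & status == 1)
    if (d > 0) s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# write a small visit table to a temporary CSV and return the path
write_visits_csv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# visits exactly on the reference curve at the given FDI positions,
# reported at ages fdi - delta_true
on_curve_series <- function(fdi, delta_true = 0, id = "P1") {
  data.frame(participant_id = id, age = fdi - delta_true,
             cdr_sb = logistic(fdi), stringsAsFactors = FALSE)
}
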