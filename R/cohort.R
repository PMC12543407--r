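# Cohort input/output, validation, eligibility filtering and CDR-SB staging.
#
# A cohort is stored long-format, as collected: one row per visit, plus a
# per-participant covariate table. Visit ages are strictly increasing within
# participant; CDR-SB lives on [0, 18] (0.5-point granularity in practice,
# accepted off-grid with a warning).

#' Default column-name schema for cohort CSV files
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in an input file. Override individual entries to read files
#' with different headers, e.g. `fdi_schema(participant_id = "RID")`.
#'
#' @param ... named character overrides of the defaults.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' fdi_schema(participant_id = "subject", cdr_sb = "CDRSB")
fdi_schema <- function(...) {
  schema <- c(
    participant_id = "participant_id", age = "age", cdr_sb = "cdr_sb",
    mmse = "mmse", diagnosis = "diagnosis", sex = "sex",
    apoe_e4 = "apoe_e4", hypertension = "hypertension", stroke = "stroke",
    neurologic = "neurologic", psychiatric = "psychiatric",
    education_years = "education_years", non_ad_etiology = "non_ad_etiology"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(over)] <- over
  }
  schema
}

covariate_fields <- function() {
  c("sex", "apoe_e4", "hypertension", "stroke", "neurologic", "psychiatric",
    "education_years", "non_ad_etiology")
}

new_cohort <- function(visits, covariates, provenance = "", rejects = NULL) {
  visits <- visits[order(visits$participant_id, visits$age), , drop = FALSE]
  rownames(visits) <- NULL
  if (is.null(rejects))
    rejects <- data.frame(row = integer(), participant_id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  structure(
    list(visits = visits, covariates = covariates,
         provenance = provenance, rejects = rejects),
    class = "fdi_cohort"
  )
}

#' @export
print.fdi_cohort <- function(x, ...) {
  cat(sprintf("<fdi_cohort> %d participants, %d visits", n_participants(x),
              nrow(x$visits)))
  if (nrow(x$rejects)) cat(sprintf(" (%d rejected rows)", nrow(x$rejects)))
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of participants in a cohort
#' @param cohort an `fdi_cohort`.
#' @return Integer count of distinct participants.
#' @export
n_participants <- function(cohort) length(unique(cohort$visits$participant_id))

#' Split a cohort into per-participant visit tables
#' @param cohort an `fdi_cohort`.
#' @return Named list of visit `data.frame`s, ages ascending, one per participant.
#' @export
cohort_series <- function(cohort) {
  split(cohort$visits, cohort$visits$participant_id)
}

normalize_diagnosis <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA")] <- NA_character_
  known <- c("CU", "MCI", "AD")
  alias <- c("CN" = "CU", "NL" = "CU", "NORMAL" = "CU",
             "DEMENTIA" = "AD", "ALZHEIMER" = "AD")
  hit <- !is.na(x) & x %in% names(alias)
  x[hit] <- alias[x[hit]]
  x[!is.na(x) & !(x %in% known)] <- "OTHER"
  x
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a long-format longitudinal cohort from CSV
#'
#' One row per visit. Required columns (after schema mapping):
#' `participant_id`, `age`, `cdr_sb`. Optional: `mmse`, `diagnosis`
#' (CU/MCI/AD; anything else becomes OTHER), and the covariate columns of
#' [fdi_schema()]. Rows that cannot be used (non-numeric or out-of-range age
#' or score, missing id, duplicated visit age within a participant) are
#' collected in the returned object's `rejects` table with a reason — never
#' silently dropped. Visits are sorted by age within participant.
#'
#' @param path CSV file path.
#' @param schema column mapping from [fdi_schema()].
#' @return An `fdi_cohort`: list with `visits`, `covariates`, `provenance`,
#'   `rejects`.
#' @export
read_cohort <- function(path, schema = fdi_schema()) {
  if (!file.exists(path)) stop_fdi(paste0("file not found: ", path), "fdi_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("participant_id", "age", "cdr_sb")
  missing_cols <- required[!(schema[required] %in% names(raw))]
  if (length(missing_cols))
    stop_fdi(paste0("missing required column(s): ",
                    paste(schema[missing_cols], collapse = ", ")),
             "fdi_schema_error")

  col <- function(field) {
    nm <- schema[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }

  id <- trimws(col("participant_id"))
  age <- suppressWarnings(as.numeric(col("age")))
  cdr <- suppressWarnings(as.numeric(col("cdr_sb")))
  mmse <- suppressWarnings(as.numeric(col("mmse")))
  diag <- normalize_diagnosis(col("diagnosis"))

  reason <- rep(NA_character_, nrow(raw))
  mark <- function(bad, why) reason[is.na(reason) & bad] <<- why
  mark(is.na(id) | id == "", "missing participant_id")
  mark(is.na(age), "non-numeric or missing age")
  mark(age <= 0, "age out of range (must be > 0)")
  mark(is.na(cdr), "non-numeric or missing cdr_sb")
  mark(!is.na(cdr) & (cdr < 0 | cdr > 18), "score out of range [0,18]")
  mark(!is.na(mmse) & (mmse < 0 | mmse > 30), "mmse out of range [0,30]")

  # duplicate visit ages within a participant: keep the first occurrence
  keep <- is.na(reason)
  key <- paste(id, age, sep = "\r")
  dup <- keep & duplicated(key)
  reason[dup] <- "duplicate visit age within participant"
  keep <- is.na(reason)

  off_grid <- keep & !is.na(cdr) & abs(cdr * 2 - round(cdr * 2)) > 1e-9
  if (any(off_grid))
    warning(sprintf("%d CDR-SB value(s) not on the 0.5-point grid; accepted as-is",
                    sum(off_grid)))

  visits <- data.frame(
    participant_id = id[keep], age = age[keep], cdr_sb = cdr[keep],
    mmse = mmse[keep], diagnosis = diag[keep], stringsAsFactors = FALSE
  )
  rejects <- data.frame(
    row = which(!keep), participant_id = id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )

  # covariates: first non-missing value per participant
  cov <- data.frame(participant_id = unique(visits$participant_id),
                    stringsAsFactors = FALSE)
  logical_fields <- c("apoe_e4", "hypertension", "stroke", "neurologic",
                      "psychiatric", "non_ad_etiology")
  for (f in covariate_fields()) {
    v <- col(f)[keep]
    if (all(is.na(v) | v == "")) next
    if (f %in% logical_fields) v <- parse_logical(v)
    else if (f == "education_years") v <- suppressWarnings(as.numeric(v))
    else v <- trimws(v)
    first_val <- tapply(v, visits$participant_id, function(z) {
      z <- z[!is.na(z)]
      if (length(z)) z[[1]] else if (is.logical(v)) NA else NA
    })
    cov[[f]] <- as.vector(unname(first_val[cov$participant_id]))
    if (is.logical(v)) cov[[f]] <- as.logical(cov[[f]])
    if (f == "education_years") cov[[f]] <- as.numeric(cov[[f]])
  }

  new_cohort(visits, cov, provenance = paste0("read from ", basename(path)),
             rejects = rejects)
}

#' Write a cohort to CSV (inverse of [read_cohort()])
#'
#' @param cohort an `fdi_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$visits
  cov <- cohort$covariates
  if (!is.null(cov) && ncol(cov) > 1)
    out <- merge(out, cov, by = "participant_id", all.x = TRUE, sort = FALSE)
  out <- out[order(out$participant_id, out$age), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Filter a cohort by the FDI eligibility rules
#'
#' Retains participants whose first visit is after `min_age`, who have at
#' least `min_visits` visits with a non-missing CDR-SB score, and (when
#' `exclude_non_ad`) whose `non_ad_etiology` flag is absent or `FALSE`.
#' Each excluded participant is counted once, under the first rule that
#' excludes them (order: `min_age`, `min_visits`, `non_ad_etiology`).
#'
#' @param cohort an `fdi_cohort`.
#' @param min_age years; first-visit age must exceed this (strict).
#' @param min_visits minimum number of visits with a CDR-SB score.
#' @param exclude_non_ad drop participants flagged with a non-Alzheimer
#'   etiology for their impairment.
#' @return List with `cohort` (the filtered `fdi_cohort`) and `report`
#'   (data.frame of rule, n_excluded).
#' @export
apply_eligibility <- function(cohort, min_age = 60, min_visits = 2,
                              exclude_non_ad = TRUE) {
  series <- cohort_series(cohort)
  ids <- names(series)
  first_age <- vapply(series, function(s) s$age[[1]], numeric(1))
  n_scored <- vapply(series, function(s) sum(!is.na(s$cdr_sb)), integer(1))

  non_ad <- rep(FALSE, length(ids))
  if (exclude_non_ad && !is.null(cohort$covariates$non_ad_etiology)) {
    flag <- cohort$covariates$non_ad_etiology[
      match(ids, cohort$covariates$participant_id)]
    non_ad <- !is.na(flag) & flag
  }

  rule <- rep(NA_character_, length(ids))
  rule[is.na(rule) & first_age <= min_age] <- "min_age"
  rule[is.na(rule) & n_scored < min_visits] <- "min_visits"
  rule[is.na(rule) & non_ad] <- "non_ad_etiology"
  keep_ids <- ids[is.na(rule)]

  visits <- cohort$visits[cohort$visits$participant_id %in% keep_ids, , drop = FALSE]
  cov <- cohort$covariates[cohort$covariates$participant_id %in% keep_ids, , drop = FALSE]
  report <- data.frame(
    rule = c("min_age", "min_visits", "non_ad_etiology"),
    n_excluded = c(sum(rule == "min_age", na.rm = TRUE),
                   sum(rule == "min_visits", na.rm = TRUE),
                   sum(rule == "non_ad_etiology", na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  if (!length(keep_ids)) warning("no participants satisfy the eligibility rules")
  list(cohort = new_cohort(visits, cov, cohort$provenance, cohort$rejects),
       report = report)
}

#' Stage cognition from a CDR-SB score
#'
#' Piecewise-constant staging rule: scores below 0.5 are cognitively
#' unimpaired (CU), 0.5 to 4.5 inclusive is mild cognitive impairment (MCI),
#' and above 4.5 is Alzheimer dementia (AD).
#'
#' @param score numeric CDR-SB value(s) in \[0, 18\].
#' @return Character vector of stages among `"CU"`, `"MCI"`, `"AD"`.
#' @export
#' @examples
#' stage_from_cdrsb(c(0, 2, 6))
stage_from_cdrsb <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 18))
    stop_fdi("CDR-SB score outside [0, 18]", "fdi_domain_error")
  ifelse(score < 0.5, "CU", ifelse(score <= 4.5, "MCI", "AD"))
}
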