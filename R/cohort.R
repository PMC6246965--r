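ENCOUNTER_CLASSES <- c("inpatient", "ed", "outpatient", "other")
HOSPITAL_CLASSES  <- c("inpatient", "ed")
AGE_GROUPS <- c("18-<30", "30-<65", ">=65")
DEMOGRAPHIC_COLS <- c("age_group", "gender", "race", "ethnicity", "insurance")

#' Study design windows
#'
#' The index date splits time into constraint-evaluation lookbacks and the
#' capture-measurement follow-up. All intervals are half-open: lookbacks are
#' `[index - L, index)` and the follow-up is `[index, index + F)`, so the
#' index date itself opens the follow-up and no encounter can fall in both.
#'
#' @param index_date Index date (`Date` or ISO-8601 string).
#' @param lookback_short Short lookback in days (default 365, "the past year").
#' @param lookback_long Long lookback in days (default 730, "the past 2 years").
#' @param followup Follow-up in days (default 183, roughly 6 months).
#' @return An object of class `study_design`.
#' @export
study_design <- function(index_date = "2017-04-01",
                         lookback_short = 365, lookback_long = 730,
                         followup = 183) {
  index_date <- as.Date(index_date)
  if (is.na(index_date)) abort_validation("index_date is not a valid date")
  for (nm in c("lookback_short", "lookback_long", "followup")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort_validation(paste0(nm, " must be a single positive number of days"))
    }
  }
  if (lookback_long < lookback_short) {
    abort_validation("lookback_long must be >= lookback_short")
  }
  structure(list(index_date = index_date,
                 lookback_short = as.integer(lookback_short),
                 lookback_long = as.integer(lookback_long),
                 followup = as.integer(followup)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> index %s | lookbacks %d/%d d | follow-up %d d\n",
              format(x$index_date), x$lookback_short, x$lookback_long,
              x$followup))
  invisible(x)
}

#' Window membership predicate
#'
#' @param dates Vector of `Date`s.
#' @param design A [study_design()].
#' @param window One of `"short_lookback"`, `"long_lookback"`, `"followup"`.
#' @return Logical vector; half-open intervals (see [study_design()]).
#' @export
in_window <- function(dates, design,
                      window = c("short_lookback", "long_lookback",
                                 "followup")) {
  stopifnot(inherits(design, "study_design"))
  window <- match.arg(window)
  idx <- design$index_date
  switch(window,
    short_lookback = dates >= idx - design$lookback_short & dates < idx,
    long_lookback  = dates >= idx - design$lookback_long  & dates < idx,
    followup       = dates >= idx & dates < idx + design$followup
  )
}

#' Read and validate a patient table
#'
#' Required columns: `id`, `zip`, `has_system_pcp`. Optional demographics:
#' `age_group`, `gender`, `race`, `ethnicity`, `insurance`. Validation errors
#' name the offending row or id.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_patients <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_patients(x)
}

#' Validate an in-memory patient table
#' @param x Data frame with the patient CSV columns.
#' @return Validated tibble with typed columns.
#' @export
validate_patients <- function(x) {
  need <- c("id", "zip", "has_system_pcp")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_validation(paste0("patient table missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$id <- as.character(x$id)
  if (anyNA(x$id) || any(x$id == "")) {
    abort_validation("patient id must be non-missing")
  }
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) {
    abort_validation(paste0("duplicate patient id: ", dup[1]))
  }
  x$zip <- as.character(x$zip)
  x$zip[x$zip %in% c("", "NA")] <- NA_character_
  bad <- which(!is.na(x$zip) & !grepl("^[0-9]{5}$", x$zip))
  if (length(bad)) {
    abort_validation(sprintf("patient row %d (id %s): malformed zip '%s'",
                             bad[1], x$id[bad[1]], x$zip[bad[1]]))
  }
  x$has_system_pcp <- parse_logical_col(x$has_system_pcp, "has_system_pcp")
  if ("age_group" %in% names(x)) {
    bad <- which(!is.na(x$age_group) & !(x$age_group %in% AGE_GROUPS))
    if (length(bad)) {
      abort_validation(sprintf(
        "patient row %d: age_group '%s' not one of %s",
        bad[1], x$age_group[bad[1]], paste(AGE_GROUPS, collapse = ", ")))
    }
  }
  x
}

parse_logical_col <- function(v, name) {
  if (is.logical(v)) return(v)
  s <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[s %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(is.na(out) & !is.na(v) & s != "NA")
  if (length(bad)) {
    abort_validation(sprintf("row %d: cannot parse %s value '%s' as logical",
                             bad[1], name, v[bad[1]]))
  }
  if (anyNA(out)) {
    abort_validation(paste0(name, " must be non-missing"))
  }
  out
}

#' Read and validate an encounter table
#'
#' Required columns: `patient_id`, `date` (ISO-8601), `klass` (one of
#' inpatient, ed, outpatient, other), `in_system`; optional `facility_id`.
#'
#' @param path CSV path.
#' @param patients Optional validated patient table; when supplied, every
#'   `patient_id` must refer to a known patient.
#' @return Validated tibble.
#' @export
read_encounters <- function(path, patients = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_encounters(x, patients = patients)
}

#' Validate an in-memory encounter table
#' @param x Data frame with the encounter CSV columns.
#' @param patients Optional validated patient table for referential checks.
#' @return Validated tibble with typed columns.
#' @export
validate_encounters <- function(x, patients = NULL) {
  need <- c("patient_id", "date", "klass", "in_system")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_validation(paste0("encounter table missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$patient_id <- as.character(x$patient_id)
  d <- as.Date(as.character(x$date), format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad)) {
    abort_validation(sprintf("encounter row %d: unparsable date '%s'",
                             bad[1], x$date[bad[1]]))
  }
  x$date <- d
  x$klass <- as.character(x$klass)
  bad <- which(!(x$klass %in% ENCOUNTER_CLASSES))
  if (length(bad)) {
    abort_validation(sprintf(
      "encounter row %d: klass '%s' not one of %s", bad[1], x$klass[bad[1]],
      paste(ENCOUNTER_CLASSES, collapse = ", ")))
  }
  x$in_system <- parse_logical_col(x$in_system, "in_system")
  if (!"facility_id" %in% names(x)) x$facility_id <- NA_character_
  x$facility_id <- as.character(x$facility_id)
  x$facility_id[x$facility_id %in% c("", "NA")] <- NA_character_
  if (!is.null(patients)) {
    unknown <- setdiff(unique(x$patient_id), patients$id)
    if (length(unknown)) {
      abort_validation(paste0("encounter refers to unknown patient id: ",
                              unknown[1]))
    }
  }
  x
}

#' Write patient / encounter tables
#'
#' Round-trip companions to [read_patients()] and [read_encounters()].
#' @param x Table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
write_encounters <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Demographic summary of a cohort
#'
#' Count and percentage of the cohort per category, for each demographic
#' dimension present in the table. Missing values are tabulated as
#' `"Unknown or not reported"`, so counts within a dimension always sum to
#' the cohort size. Percentages are rendered to 2 decimals, round half up.
#'
#' @param patients Validated patient table.
#' @return Tibble `dimension`, `category`, `n`, `pct`.
#' @export
summarize_demographics <- function(patients) {
  if (nrow(patients) == 0) abort_validation("cohort is empty")
  dims <- intersect(DEMOGRAPHIC_COLS, names(patients))
  if (length(dims) == 0) {
    abort_validation("patient table carries no demographic columns")
  }
  n_total <- nrow(patients)
  rows <- lapply(dims, function(dim) {
    v <- patients[[dim]]
    v[is.na(v)] <- "Unknown or not reported"
    tab <- table(v)
    tibble::tibble(dimension = dim,
                   category = names(tab),
                   n = as.integer(tab),
                   pct = round_half_up(100 * as.integer(tab) / n_total))
  })
  dplyr::bind_rows(rows)
}
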