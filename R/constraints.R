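#' The ten candidate constraint families
#'
#' Each family combines a utilization / primary-care clause with the distance
#' clause "lives within r miles of at least one system hospital":
#'
#' * `DISTANCE_ONLY` — distance clause only.
#' * `PCP` — has an in-system primary care physician.
#' * `ENC2_1Y` / `ENC2_2Y` — >=2 in-system encounters (any class) in the
#'   short / long lookback.
#' * `HOSP1_1Y` — >=1 in-system hospital encounter (inpatient or ED) in the
#'   short lookback; `HOSP2_1Y` / `HOSP2_2Y` — >=2 in the short / long
#'   lookback.
#' * `OUTPT1_1Y` — >=1 in-system outpatient visit in the short lookback;
#'   `OUTPT2_1Y` / `OUTPT2_2Y` — >=2 in the short / long lookback.
#'
#' @return Character vector of the ten family names.
#' @export
constraint_families <- function() {
  c("DISTANCE_ONLY", "PCP", "ENC2_1Y", "ENC2_2Y",
    "HOSP1_1Y", "HOSP2_1Y", "HOSP2_2Y",
    "OUTPT1_1Y", "OUTPT2_1Y", "OUTPT2_2Y")
}

# family -> (encounter classes counted, lookback window, count threshold);
# DISTANCE_ONLY and PCP have no utilization clause
family_clause <- function(family) {
  switch(family,
    DISTANCE_ONLY = NULL,
    PCP       = NULL,
    ENC2_1Y   = list(classes = ENCOUNTER_CLASSES, window = "short_lookback", min = 2L),
    ENC2_2Y   = list(classes = ENCOUNTER_CLASSES, window = "long_lookback",  min = 2L),
    HOSP1_1Y  = list(classes = HOSPITAL_CLASSES,  window = "short_lookback", min = 1L),
    HOSP2_1Y  = list(classes = HOSPITAL_CLASSES,  window = "short_lookback", min = 2L),
    HOSP2_2Y  = list(classes = HOSPITAL_CLASSES,  window = "long_lookback",  min = 2L),
    OUTPT1_1Y = list(classes = "outpatient",      window = "short_lookback", min = 1L),
    OUTPT2_1Y = list(classes = "outpatient",      window = "short_lookback", min = 2L),
    OUTPT2_2Y = list(classes = "outpatient",      window = "long_lookback",  min = 2L),
    abort_validation(paste0("unknown constraint family: ", family))
  )
}

#' Constraint specification
#'
#' @param family One of [constraint_families()].
#' @param r Radius in miles, positive; `Inf` disables the distance clause
#'   (for patients with a known home zip).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(family, r) {
  family <- as.character(family)
  if (!family %in% constraint_families()) {
    abort_validation(paste0("unknown constraint family: ", family))
  }
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0) {
    abort_validation("r must be a single positive number of miles (Inf allowed)")
  }
  structure(list(family = family, r = as.numeric(r)),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat(sprintf("<constraint_spec> %s, r = %s miles\n", x$family,
              if (is.infinite(x$r)) "Inf" else format(x$r)))
  invisible(x)
}

#' Does one patient satisfy a constraint?
#'
#' Conjunction of the family's utilization/PCP clause, evaluated over the
#' patient's pre-index encounter history, and the distance clause
#' `dist_miles <= r` ("within" is boundary-inclusive). With `r = Inf` the
#' distance clause is vacuous for located patients. A patient with unknown
#' distance (`NA`) fails every constraint, including `r = Inf`: an
#' unlocatable patient cannot be given a geography-based capture claim.
#'
#' @param patient One-row patient table (needs `has_system_pcp`).
#' @param history Encounter table restricted to this patient's pre-index
#'   encounters.
#' @param spec A [constraint_spec()].
#' @param design A [study_design()].
#' @param dist_miles Distance to nearest system hospital in miles, or `NA`.
#' @return Single logical.
#' @export
satisfies_constraint <- function(patient, history, spec, design, dist_miles) {
  stopifnot(inherits(spec, "constraint_spec"), inherits(design, "study_design"))
  if (is.na(dist_miles) || dist_miles > spec$r) return(FALSE)
  if (spec$family == "PCP" && !isTRUE(patient$has_system_pcp)) return(FALSE)
  clause <- family_clause(spec$family)
  if (is.null(clause)) return(TRUE)
  keep <- history$in_system &
    history$klass %in% clause$classes &
    in_window(history$date, design, clause$window)
  sum(keep) >= clause$min
}

# per-patient utilization counts for every clause the ten families need;
# one pass over the encounter table, reused across the whole (family, r) grid
clause_counts <- function(patients, encounters, design) {
  enc <- encounters[encounters$in_system, , drop = FALSE]
  win_s <- in_window(enc$date, design, "short_lookback")
  win_l <- in_window(enc$date, design, "long_lookback")
  hosp <- enc$klass %in% HOSPITAL_CLASSES
  outp <- enc$klass == "outpatient"
  count_by <- function(keep) {
    t <- table(factor(enc$patient_id[keep], levels = patients$id))
    as.integer(t)
  }
  tibble::tibble(
    id = patients$id,
    n_enc_1y   = count_by(win_s),
    n_enc_2y   = count_by(win_l),
    n_hosp_1y  = count_by(win_s & hosp),
    n_hosp_2y  = count_by(win_l & hosp),
    n_outpt_1y = count_by(win_s & outp),
    n_outpt_2y = count_by(win_l & outp)
  )
}

clause_satisfied <- function(family, patients, counts) {
  switch(family,
    DISTANCE_ONLY = rep(TRUE, nrow(patients)),
    PCP       = patients$has_system_pcp,
    ENC2_1Y   = counts$n_enc_1y >= 2L,
    ENC2_2Y   = counts$n_enc_2y >= 2L,
    HOSP1_1Y  = counts$n_hosp_1y >= 1L,
    HOSP2_1Y  = counts$n_hosp_1y >= 2L,
    HOSP2_2Y  = counts$n_hosp_2y >= 2L,
    OUTPT1_1Y = counts$n_outpt_1y >= 1L,
    OUTPT2_1Y = counts$n_outpt_1y >= 2L,
    OUTPT2_2Y = counts$n_outpt_2y >= 2L
  )
}

#' Filter a cohort by a constraint
#'
#' Returns exactly the patient ids for which [satisfies_constraint()] holds,
#' computed vectorised over the cohort.
#'
#' @param patients Validated patient table.
#' @param encounters Validated encounter table (all patients; only pre-index
#'   in-system encounters matter to the clauses).
#' @param spec A [constraint_spec()].
#' @param design A [study_design()].
#' @param distances Per-patient distance table from [patient_distances()]
#'   (columns `id`, `dist_miles`).
#' @return Character vector of satisfying patient ids, in cohort order.
#' @export
cohort_filter <- function(patients, encounters, spec, design, distances) {
  stopifnot(inherits(spec, "constraint_spec"))
  counts <- clause_counts(patients, encounters, design)
  d <- distances$dist_miles[match(patients$id, distances$id)]
  ok <- !is.na(d) & d <= spec$r & clause_satisfied(spec$family, patients, counts)
  patients$id[ok]
}
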