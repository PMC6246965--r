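#' Criterion 1: cohort share satisfying a constraint
#'
#' The percentage of the full patient cohort that satisfies a candidate
#' constraint — the cohort-size side of the capture trade-off.
#'
#' @param n_satisfying Count of satisfying patients.
#' @param n_cohort Total cohort size (> 0).
#' @return Percentage on the 0-100 scale, 2 decimals, round half up.
#' @examples
#' criterion1(55707, 348054) # 16.01
#' @export
criterion1 <- function(n_satisfying, n_cohort) {
  if (!is.numeric(n_cohort) || n_cohort <= 0) {
    abort_validation("n_cohort must be positive")
  }
  if (n_satisfying < 0 || n_satisfying > n_cohort) {
    abort_validation("n_satisfying must be in [0, n_cohort]")
  }
  round_half_up(100 * n_satisfying / n_cohort)
}

#' Restrict encounters to follow-up hospital encounters
#'
#' Keeps inpatient and ED encounters dated inside the follow-up window —
#' the encounter universe on which capture (Criterion 2) is measured.
#'
#' @param encounters Validated encounter table.
#' @param design A [study_design()].
#' @return Filtered encounter tibble.
#' @export
followup_hospital_encounters <- function(encounters, design) {
  keep <- encounters$klass %in% HOSPITAL_CLASSES &
    in_window(encounters$date, design, "followup")
  encounters[keep, , drop = FALSE]
}

#' Criterion 2: pooled in-system share of follow-up hospital encounters
#'
#' For the patients satisfying a constraint, the percentage of their
#' follow-up hospital encounters (inpatient stays and ED visits) that
#' occurred in-system. The denominator is pooled at the encounter level over
#' every satisfying patient: patients with zero follow-up hospital
#' encounters remain cohort members but contribute nothing to numerator or
#' denominator. This is not a mean of per-patient ratios.
#'
#' @param followup_encounters Encounter table already restricted to
#'   follow-up hospital encounters (see [followup_hospital_encounters()]).
#' @param satisfying Character vector of satisfying patient ids.
#' @return List with `enc_within`, `enc_total`, and `pct` (2 decimals, round
#'   half up; `NA` when the pooled denominator is empty — undefined, which
#'   is distinct from 0).
#' @examples
#' # 10,501 of 15,135 pooled encounters in-system -> 69.38
#' @export
criterion2 <- function(followup_encounters, satisfying) {
  e <- followup_encounters[followup_encounters$patient_id %in% satisfying, ,
                           drop = FALSE]
  enc_total <- nrow(e)
  enc_within <- sum(e$in_system)
  pct <- if (enc_total > 0) round_half_up(100 * enc_within / enc_total) else NA_real_
  list(enc_within = as.integer(enc_within),
       enc_total = as.integer(enc_total),
       pct = pct)
}

#' Sweep the evaluation criteria over a (family, r) grid
#'
#' One evaluation point per combination of constraint family and radius:
#' satisfying count, Criterion-1 percentage, pooled follow-up hospital
#' encounter tallies, and Criterion-2 percentage. The `c1_pct`/`c2_pct`
#' columns carry the exact ratios (doubles); [write_results()] renders them
#' to the 2-decimal display convention.
#'
#' @param patients,encounters Validated tables.
#' @param design A [study_design()].
#' @param distances Per-patient distance table ([patient_distances()]).
#' @param families Subset of [constraint_families()] (default all ten).
#' @param r_grid Radii in miles; default 1-10 by 1, 15-60 by 5, plus `Inf`.
#' @return Tibble with one row per (family, r): `family`, `r`, `n_cohort`,
#'   `n_satisfying`, `c1_pct`, `enc_total`, `enc_within`, `c2_pct`.
#' @export
sweep_constraints <- function(patients, encounters, design, distances,
                              families = constraint_families(),
                              r_grid = default_r_grid()) {
  if (length(r_grid) == 0) abort_validation("r_grid must be non-empty")
  if (any(is.na(r_grid) | r_grid <= 0)) {
    abort_validation("r_grid values must be positive (Inf allowed)")
  }
  bad <- setdiff(families, constraint_families())
  if (length(bad)) {
    abort_validation(paste0("unknown constraint family: ", bad[1]))
  }
  r_grid <- sort(unique(as.numeric(r_grid)))
  n_cohort <- nrow(patients)
  if (n_cohort == 0) abort_validation("cohort is empty")

  counts <- clause_counts(patients, encounters, design)
  d <- distances$dist_miles[match(patients$id, distances$id)]
  fu <- followup_hospital_encounters(encounters, design)
  # pooled tallies reduce to per-patient totals summed over the satisfying set
  fu_tot <- as.integer(table(factor(fu$patient_id, levels = patients$id)))
  fu_in  <- as.integer(table(factor(fu$patient_id[fu$in_system],
                                    levels = patients$id)))

  rows <- list()
  for (family in families) {
    clause_ok <- clause_satisfied(family, patients, counts)
    for (r in r_grid) {
      ok <- !is.na(d) & d <= r & clause_ok
      enc_total <- sum(fu_tot[ok])
      enc_within <- sum(fu_in[ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = family, r = r,
        n_cohort = n_cohort, n_satisfying = sum(ok),
        c1_pct = 100 * sum(ok) / n_cohort,
        enc_total = enc_total, enc_within = enc_within,
        c2_pct = if (enc_total > 0) 100 * enc_within / enc_total else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Default radius grid
#'
#' 1-10 miles by 1, 15-60 by 5, plus `Inf`: fine resolution where the
#' capture curves move fastest, coarse where they flatten, and the
#' distance-free limit.
#' @return Numeric vector of radii in miles.
#' @export
default_r_grid <- function() c(1:10, seq(15, 60, by = 5), Inf)

#' Per-hospital breakdown of captured encounters
#'
#' Splits the pooled in-system follow-up hospital encounters of a satisfying
#' cohort across the system's hospitals, as a percentage of *all* the
#' cohort's follow-up hospital encounters (the same pooled denominator as
#' Criterion 2). In-system encounters whose facility is missing or not a
#' known hospital are reported in an `"unattributed"` row, so the shares sum
#' exactly to the Criterion-2 percentage.
#'
#' @param followup_encounters Follow-up hospital encounter table.
#' @param satisfying Satisfying patient ids.
#' @param hospitals Hospital table (or character vector of hospital ids).
#' @return Tibble `hospital_id`, `enc_at_hospital`, `enc_total`, `pct`
#'   (exact double); empty when no satisfying patient has encounters.
#' @export
hospital_breakdown <- function(followup_encounters, satisfying, hospitals) {
  ids <- if (is.character(hospitals)) hospitals else hospitals$id
  e <- followup_encounters[followup_encounters$patient_id %in% satisfying, ,
                           drop = FALSE]
  enc_total <- nrow(e)
  if (enc_total == 0) {
    return(tibble::tibble(hospital_id = character(), enc_at_hospital = integer(),
                          enc_total = integer(), pct = numeric()))
  }
  ins <- e[e$in_system, , drop = FALSE]
  fac <- ifelse(is.na(ins$facility_id) | !(ins$facility_id %in% ids),
                "unattributed", ins$facility_id)
  tab <- table(factor(fac, levels = c(ids, "unattributed")))
  out <- tibble::tibble(
    hospital_id = names(tab),
    enc_at_hospital = as.integer(tab),
    enc_total = enc_total,
    pct = 100 * as.integer(tab) / enc_total
  )
  if (out$enc_at_hospital[out$hospital_id == "unattributed"] == 0) {
    out <- out[out$hospital_id != "unattributed", , drop = FALSE]
  }
  out
}

#' Selection policy
#'
#' Formalisation of "strike a balance" between the two criteria: maximise
#' the Criterion-2 capture percentage subject to the Criterion-1 cohort
#' share meeting a floor. The floor is a tunable knob, not an empirical
#' fact; the default of 15% keeps selected cohorts large enough for
#' downstream modeling.
#'
#' @param min_c1 Minimum Criterion-1 percentage in \[0, 100\] (default 15).
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(min_c1 = 15) {
  if (!is.numeric(min_c1) || length(min_c1) != 1 ||
      is.na(min_c1) || min_c1 < 0 || min_c1 > 100) {
    abort_validation("min_c1 must be a single percentage in [0, 100]")
  }
  structure(list(min_c1 = as.numeric(min_c1),
                 objective = "max_c2_subject_to_c1"),
            class = "selection_policy")
}

#' Select the constraint that balances the two criteria
#'
#' Among evaluation points with a defined Criterion-2 value and
#' `c1_pct >= min_c1`, returns the point maximising `c2_pct`. Ties break by
#' larger `c1_pct`, then smaller `r`; the result is deterministic. Points
#' with an undefined Criterion 2 (empty pooled denominator) carry no
#' evidence and are excluded.
#'
#' @param points Evaluation-point tibble from [sweep_constraints()].
#' @param policy A [selection_policy()].
#' @return One-row tibble (the selected evaluation point).
#' @export
select_constraint <- function(points, policy = selection_policy()) {
  stopifnot(inherits(policy, "selection_policy"))
  feasible <- points[!is.na(points$c2_pct) &
                       points$c1_pct >= policy$min_c1, , drop = FALSE]
  if (nrow(feasible) == 0) {
    abort_validation(sprintf(
      "no feasible constraint: no evaluation point with defined Criterion 2 has c1_pct >= %g",
      policy$min_c1))
  }
  ord <- order(-feasible$c2_pct, -feasible$c1_pct, feasible$r)
  feasible[ord[1], , drop = FALSE]
}

#' Write an evaluation-point table to CSV
#'
#' Renders `c1_pct`/`c2_pct` to the 2-decimal round-half-up display
#' convention; counts stay exact integers.
#'
#' @param points Tibble from [sweep_constraints()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(points, path) {
  out <- points
  out$c1_pct <- format_pct(out$c1_pct)
  out$c2_pct <- format_pct(out$c2_pct)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Plot capture curves from an evaluation-point table
#'
#' Criterion-1 or Criterion-2 percentage against the radius r, one line per
#' constraint family (the finite-r part of the sweep). Requires ggplot2.
#'
#' @param points Tibble from [sweep_constraints()].
#' @param criterion `"c1"` or `"c2"`.
#' @param r_max Optional upper limit on r for the fine-resolution view.
#' @return A ggplot object.
#' @export
plot_capture_curves <- function(points, criterion = c("c1", "c2"),
                                r_max = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_capture_curves() requires the ggplot2 package")
  }
  criterion <- match.arg(criterion)
  ycol <- paste0(criterion, "_pct")
  dat <- points[is.finite(points$r), , drop = FALSE]
  if (!is.null(r_max)) dat <- dat[dat$r <= r_max, , drop = FALSE]
  ylab <- if (criterion == "c1") {
    "% of cohort satisfying constraint"
  } else {
    "% of follow-up hospital encounters in-system"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, y = .data[[ycol]],
                                    colour = .data$family)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "r (miles)", y = ylab, colour = "Constraint") +
    ggplot2::theme_minimal()
}
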