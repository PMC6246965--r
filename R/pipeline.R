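#' Run the full capture analysis pipeline
#'
#' Orchestrates the whole method: validate inputs, compute per-patient
#' distances, sweep the constraint families over the radius grid, select the
#' balancing constraint, break its captured encounters down per hospital,
#' and summarise cohort demographics. Writes `results.csv`,
#' `breakdown.csv`, `demographics.csv`, `selection.csv` and `run_log.txt`
#' to `out_dir` (when given) and returns everything invisibly. Outputs are
#' deterministic for identical inputs.
#'
#' @param patients,encounters,centroids,hospitals Validated input tables
#'   (from the `read_*` functions or [generate_study()]).
#' @param design A [study_design()].
#' @param families Constraint families to sweep (default all ten).
#' @param r_grid Radius grid in miles (default [default_r_grid()]).
#' @param policy A [selection_policy()].
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Print the stage log to the console.
#' @return (Invisibly) list with `results`, `selected`, `breakdown`,
#'   `demographics`, `distances`, `log` (character vector of stage counts).
#' @export
run_study <- function(patients, encounters, centroids, hospitals,
                      design = study_design(),
                      families = constraint_families(),
                      r_grid = default_r_grid(),
                      policy = selection_policy(),
                      out_dir = NULL, verbose = FALSE) {
  patients <- validate_patients(patients)
  encounters <- validate_encounters(encounters, patients)
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message(msg)
    invisible(NULL)
  }
  say("cohort: %d patients, %d encounters", nrow(patients), nrow(encounters))

  distances <- patient_distances(patients, centroids, hospitals)
  say("distances: %d patients unlocatable (missing or unknown zip), excluded from all distance-gated constraints",
      attr(distances, "n_unlocatable"))

  fu <- followup_hospital_encounters(encounters, design)
  say("follow-up: %d hospital encounters (%d in-system) in [%s, %s)",
      nrow(fu), sum(fu$in_system), format(design$index_date),
      format(design$index_date + design$followup))

  results <- sweep_constraints(patients, encounters, design, distances,
                               families = families, r_grid = r_grid)
  say("sweep: %d evaluation points (%d families x %d radii)",
      nrow(results), length(families), length(unique(results$r)))

  selected <- select_constraint(results, policy)
  say("selected: %s at r = %s miles (C1 = %s%%, C2 = %s%%; %d/%d patients, %d/%d encounters)",
      selected$family,
      if (is.infinite(selected$r)) "Inf" else format(selected$r),
      format_pct(selected$c1_pct), format_pct(selected$c2_pct),
      selected$n_satisfying, selected$n_cohort,
      selected$enc_within, selected$enc_total)

  sel_spec <- constraint_spec(selected$family, selected$r)
  satisfying <- cohort_filter(patients, encounters, sel_spec, design,
                              distances)
  breakdown <- hospital_breakdown(fu, satisfying, hospitals)
  say("breakdown: %d hospital rows for the selected constraint",
      nrow(breakdown))

  demographics <- tryCatch(summarize_demographics(patients),
                           carecapture_validation_error = function(e) NULL)
  if (is.null(demographics)) say("demographics: none available")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(results, file.path(out_dir, "results.csv"))
    sel_out <- selected
    sel_out$c1_pct <- format_pct(sel_out$c1_pct)
    sel_out$c2_pct <- format_pct(sel_out$c2_pct)
    readr::write_csv(sel_out, file.path(out_dir, "selection.csv"), na = "")
    bd <- breakdown
    if (nrow(bd)) bd$pct <- format_pct(bd$pct)
    readr::write_csv(bd, file.path(out_dir, "breakdown.csv"), na = "")
    if (!is.null(demographics)) {
      dm <- demographics
      dm$pct <- format_pct(dm$pct)
      readr::write_csv(dm, file.path(out_dir, "demographics.csv"), na = "")
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }

  invisible(list(results = results, selected = selected,
                 breakdown = breakdown, demographics = demographics,
                 distances = distances, log = log))
}
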