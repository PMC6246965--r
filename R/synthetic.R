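#' Synthetic fragmented-care study configuration
#'
#' Parameterises the generator of a complete synthetic study: hospitals,
#' a zip-centroid grid, patients scattered around the hospitals, 2-year
#' encounter histories, and 6-month follow-up hospital encounters whose
#' probability of occurring in-system decays with distance and rises with
#' in-system PCP attribution.
#'
#' The default configuration emulates an urban academic health system: about
#' half the patients live in a dense core a few miles from the hospitals and
#' the rest are scattered tens of miles out; PCP attribution is likeliest
#' near the hospitals; and loyalty (the per-encounter probability of staying
#' in-system) follows a logistic model in distance and PCP status.
#'
#' @param seed Integer RNG seed; a fixed seed makes the output reproducible.
#' @param n_patients Cohort size.
#' @param n_hospitals Number of system hospitals.
#' @param center Named vector `c(lat=, lon=)`, the system's urban center.
#' @param hospital_spread_miles Radial spread of the hospitals around the
#'   center, in miles.
#' @param zip_spacing_deg Zip-grid spacing in degrees; patient locations are
#'   snapped to this grid and the occupied cells become synthetic zips.
#' @param patient_mix Two-component distance mixture: `weights` (sum to 1)
#'   and exponential `scales_miles` for the urban-core and scattered
#'   components of home-to-center distance.
#' @param missing_zip_prob Probability a patient's home zip is unrecorded.
#' @param pcp_model `base_prob` (PCP probability at distance 0) and
#'   `distance_decay` (logit decrease per mile).
#' @param history_model Per-class encounter `rates_per_year` over the
#'   lookback, and an `in_system` logistic (`b0`, `b_dist`, `b_pcp`) for the
#'   probability a history encounter is in-system.
#' @param followup_model `rate`: expected follow-up hospital encounters per
#'   patient over the follow-up window; `p_inpatient`: share of those that
#'   are inpatient stays (the rest are ED visits).
#' @param loyalty_model Logistic coefficients (`b0`, `b_dist`, `b_pcp`)
#'   giving each follow-up hospital encounter's probability of being
#'   in-system: `plogis(b0 - b_dist * dist_miles + b_pcp * has_pcp)`.
#' @param facility_weights In-system facility assignment weights across the
#'   hospitals (recycled/normalised to `n_hospitals`).
#' @param design A [study_design()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_patients = 5000L,
    n_hospitals = 3L,
    center = c(lat = 47.61, lon = -122.33),
    hospital_spread_miles = 3,
    zip_spacing_deg = 0.05,
    patient_mix = list(weights = c(0.47, 0.53), scales_miles = c(5, 45)),
    missing_zip_prob = 0.01,
    pcp_model = list(base_prob = 0.44, distance_decay = 0.055),
    history_model = list(
      rates_per_year = c(outpatient = 1.1, inpatient = 0.06,
                         ed = 0.15, other = 0.35),
      in_system = list(b0 = 0.3, b_dist = 0.05, b_pcp = 1.0)),
    followup_model = list(rate = 0.35, p_inpatient = 0.3),
    loyalty_model = list(b0 = -0.55, b_dist = 0.06, b_pcp = 1.5),
    facility_weights = c(0.5, 0.35, 0.15),
    design = study_design()) {
  cfg <- structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    n_hospitals = as.integer(n_hospitals), center = center,
    hospital_spread_miles = hospital_spread_miles,
    zip_spacing_deg = zip_spacing_deg, patient_mix = patient_mix,
    missing_zip_prob = missing_zip_prob, pcp_model = pcp_model,
    history_model = history_model, followup_model = followup_model,
    loyalty_model = loyalty_model,
    facility_weights = rep_len(facility_weights, n_hospitals),
    design = design), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  chk_prob <- function(p, nm) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
      abort_validation(paste0(nm, " must be probability(ies) in [0, 1]"))
    }
  }
  chk_pos <- function(v, nm, strict = TRUE) {
    if (!is.numeric(v) || any(is.na(v)) ||
        any(if (strict) v <= 0 else v < 0)) {
      abort_validation(paste0(nm, " must be ",
                              if (strict) "positive" else "non-negative"))
    }
  }
  if (cfg$n_patients < 1) abort_validation("n_patients must be >= 1")
  if (cfg$n_hospitals < 1) abort_validation("n_hospitals must be >= 1")
  check_latlon(cfg$center[["lat"]], cfg$center[["lon"]], "center")
  chk_pos(cfg$hospital_spread_miles, "hospital_spread_miles", strict = FALSE)
  chk_pos(cfg$zip_spacing_deg, "zip_spacing_deg")
  w <- cfg$patient_mix$weights
  chk_prob(w, "patient_mix$weights")
  if (abs(sum(w) - 1) > 1e-8) {
    abort_validation("patient_mix$weights must sum to 1")
  }
  chk_pos(cfg$patient_mix$scales_miles, "patient_mix$scales_miles")
  chk_prob(cfg$missing_zip_prob, "missing_zip_prob")
  chk_prob(cfg$pcp_model$base_prob, "pcp_model$base_prob")
  chk_pos(cfg$history_model$rates_per_year, "history rates", strict = FALSE)
  chk_pos(cfg$followup_model$rate, "followup_model$rate", strict = FALSE)
  chk_prob(cfg$followup_model$p_inpatient, "followup_model$p_inpatient")
  chk_pos(cfg$facility_weights, "facility_weights", strict = FALSE)
  if (sum(cfg$facility_weights) <= 0) {
    abort_validation("facility_weights must have positive sum")
  }
  stopifnot(inherits(cfg$design, "study_design"))
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> seed %d | %d patients, %d hospitals | loyalty b0=%.2f b_dist=%.3f b_pcp=%.2f\n",
    x$seed, x$n_patients, x$n_hospitals, x$loyalty_model$b0,
    x$loyalty_model$b_dist, x$loyalty_model$b_pcp))
  invisible(x)
}

# approximate miles-per-degree used only to place synthetic points; the
# pipeline re-measures every distance with the Vincenty geodesic
MILES_PER_DEG_LAT <- 69.05

loyalty_prob <- function(loyalty_model, dist_miles, has_pcp) {
  stats::plogis(loyalty_model$b0 - loyalty_model$b_dist * dist_miles +
                  loyalty_model$b_pcp * as.numeric(has_pcp))
}

#' Generate a synthetic fragmented-care study
#'
#' Draws hospitals, a zip grid, patients, 2-year encounter histories and
#' 6-month follow-up hospital encounters from a [synthetic_config()]. All
#' randomness flows from `config$seed`: the same config yields identical
#' tables. The distances that drive PCP attribution and loyalty are the
#' same zip-centroid-to-nearest-hospital Vincenty distances the analysis
#' pipeline later measures, so the analytic oracle
#' [expected_in_system_share()] applies exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with validated `patients`, `encounters`, `centroids`,
#'   `hospitals` tables, the `design`, and `truth` (per-patient `id`,
#'   `dist_miles`, `has_system_pcp`, `p_loyalty` — generator-side ground
#'   truth for oracle checks; `dist_miles` is kept even when the emitted zip
#'   is masked as missing).
#' @export
generate_study <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(config$seed)
  design <- config$design

  # hospitals on a deterministic ring around the center
  nh <- config$n_hospitals
  ang <- 2 * pi * (seq_len(nh) - 1) / max(nh, 1)
  rad <- if (nh == 1) 0 else config$hospital_spread_miles
  hlat <- config$center[["lat"]] + rad * cos(ang) / MILES_PER_DEG_LAT
  hlon <- config$center[["lon"]] + rad * sin(ang) /
    (MILES_PER_DEG_LAT * cos(config$center[["lat"]] * pi / 180))
  hospitals <- tibble::tibble(
    id = sprintf("H%02d", seq_len(nh)),
    name = sprintf("System Hospital %d", seq_len(nh)),
    lat = hlat, lon = hlon)

  # patient locations: anchor hospital + exponential-mixture radial offset
  n <- config$n_patients
  anchor <- sample.int(nh, n, replace = TRUE,
                       prob = config$facility_weights)
  comp <- sample.int(length(config$patient_mix$weights), n, replace = TRUE,
                     prob = config$patient_mix$weights)
  dist_draw <- stats::rexp(n, rate = 1 / config$patient_mix$scales_miles[comp])
  bearing <- stats::runif(n, 0, 2 * pi)
  plat <- hlat[anchor] + dist_draw * cos(bearing) / MILES_PER_DEG_LAT
  plon <- hlon[anchor] + dist_draw * sin(bearing) /
    (MILES_PER_DEG_LAT * cos(config$center[["lat"]] * pi / 180))

  # snap to the zip grid; occupied cells become the synthetic zips
  gi <- round((plat - config$center[["lat"]]) / config$zip_spacing_deg)
  gj <- round((plon - config$center[["lon"]]) / config$zip_spacing_deg)
  cell <- paste(gi, gj, sep = ":")
  ucell <- sort(unique(cell))
  if (length(ucell) > 89999) abort_validation("zip grid overflow: too many occupied cells")
  zip_of_cell <- stats::setNames(sprintf("%05d", 10000 + seq_along(ucell)),
                                 ucell)
  uk <- match(ucell, cell)
  centroids <- tibble::tibble(
    zip = unname(zip_of_cell),
    lat = config$center[["lat"]] + gi[uk] * config$zip_spacing_deg,
    lon = config$center[["lon"]] + gj[uk] * config$zip_spacing_deg)
  zip <- unname(zip_of_cell[cell])

  # the distance the pipeline will see: zip centroid -> nearest hospital
  dist_miles <- min_hospital_distance_miles(zip, centroids, hospitals)

  pm <- config$pcp_model
  p_pcp <- stats::plogis(stats::qlogis(pm$base_prob) -
                           pm$distance_decay * dist_miles)
  has_pcp <- stats::runif(n) < p_pcp

  patients <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    zip = zip,
    has_system_pcp = has_pcp,
    age_group = sample(AGE_GROUPS, n, replace = TRUE,
                       prob = c(0.185, 0.60, 0.215)),
    gender = sample(c("Female", "Male"), n, replace = TRUE,
                    prob = c(0.556, 0.444)),
    insurance = sample(c("Private", "Public", "Self-paid or charity"), n,
                       replace = TRUE, prob = c(0.48, 0.44, 0.08)))

  p_loyal <- loyalty_prob(config$loyalty_model, dist_miles, has_pcp)
  hm <- config$history_model
  p_hist_in <- stats::plogis(hm$in_system$b0 -
                               hm$in_system$b_dist * dist_miles +
                               hm$in_system$b_pcp * as.numeric(has_pcp))

  # 2-year histories: per-class Poisson counts, uniform dates in the lookback
  lb_years <- design$lookback_long / 365
  hist_list <- lapply(names(hm$rates_per_year), function(kl) {
    cnt <- stats::rpois(n, hm$rates_per_year[[kl]] * lb_years)
    pid <- rep(seq_len(n), cnt)
    m <- length(pid)
    if (m == 0) return(NULL)
    ins <- stats::runif(m) < p_hist_in[pid]
    fac <- rep(NA_character_, m)
    if (kl %in% HOSPITAL_CLASSES) {
      k <- which(ins)
      if (length(k)) {
        fac[k] <- hospitals$id[sample.int(nh, length(k), replace = TRUE,
                                          prob = config$facility_weights)]
      }
    }
    tibble::tibble(
      patient_id = patients$id[pid],
      date = design$index_date - 1 -
        floor(stats::runif(m) * design$lookback_long),
      klass = kl, in_system = ins, facility_id = fac)
  })

  # 6-month follow-up hospital encounters with logistic loyalty
  fu_cnt <- stats::rpois(n, config$followup_model$rate)
  pid <- rep(seq_len(n), fu_cnt)
  m <- length(pid)
  fu <- NULL
  if (m > 0) {
    ins <- stats::runif(m) < p_loyal[pid]
    fac <- rep(NA_character_, m)
    k <- which(ins)
    if (length(k)) {
      fac[k] <- hospitals$id[sample.int(nh, length(k), replace = TRUE,
                                        prob = config$facility_weights)]
    }
    fu <- tibble::tibble(
      patient_id = patients$id[pid],
      date = design$index_date + floor(stats::runif(m) * design$followup),
      klass = ifelse(stats::runif(m) < config$followup_model$p_inpatient,
                     "inpatient", "ed"),
      in_system = ins, facility_id = fac)
  }
  encounters <- dplyr::bind_rows(c(hist_list, list(fu)))
  encounters <- encounters[order(encounters$patient_id, encounters$date,
                                 encounters$klass), , drop = FALSE]

  # mask some zips as unrecorded (after all models have used the distance)
  drop_zip <- stats::runif(n) < config$missing_zip_prob
  patients$zip[drop_zip] <- NA_character_

  list(patients = validate_patients(patients),
       encounters = validate_encounters(encounters, patients),
       centroids = centroids,
       hospitals = hospitals,
       design = design,
       truth = tibble::tibble(id = patients$id, dist_miles = dist_miles,
                              has_system_pcp = has_pcp,
                              p_loyalty = p_loyal))
}

#' Analytic expected pooled in-system share
#'
#' Closed-form expectation of the pooled in-system share of follow-up
#' hospital encounters for a sub-population, under the generator's loyalty
#' model: each patient contributes encounters at rate `rates` (uniform by
#' default) with per-encounter in-system probability
#' `plogis(b0 - b_dist * dist + b_pcp * pcp)`, so the pooled share is the
#' rate-weighted mean of those probabilities. Used as the oracle that the
#' empirical Criterion-2 value must approach as the cohort grows.
#'
#' @param config A [synthetic_config()] (only `loyalty_model` is used).
#' @param dist_miles Distances of the sub-population's patients.
#' @param has_pcp Logical (or 0/1) PCP flags, recycled against `dist_miles`.
#' @param rates Optional per-patient encounter rates (default uniform).
#' @return Expected pooled in-system share, percent on the 0-100 scale.
#' @export
expected_in_system_share <- function(config, dist_miles, has_pcp,
                                     rates = NULL) {
  n <- max(length(dist_miles), length(has_pcp))
  dist_miles <- rep_len(dist_miles, n)
  has_pcp <- rep_len(as.numeric(has_pcp), n)
  rates <- if (is.null(rates)) rep(1, n) else rep_len(rates, n)
  if (any(rates < 0) || sum(rates) <= 0) {
    abort_validation("rates must be non-negative with positive sum")
  }
  p <- loyalty_prob(config$loyalty_model, dist_miles, has_pcp)
  100 * sum(rates * p) / sum(rates)
}
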