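# Shared fixtures and independent oracles, built in code at test time.

seattleish_geo <- function() {
  hospitals <- tibble::tibble(
    id = c("H01", "H02", "H03"),
    name = c("Downtown", "Northside", "Lakeview"),
    lat = c(47.60, 47.66, 47.63),
    lon = c(-122.33, -122.32, -122.28))
  centroids <- tibble::tibble(
    zip = c("98101", "98115", "98500", "99201"),
    lat = c(47.61, 47.68, 47.04, 47.66),
    lon = c(-122.33, -122.30, -122.90, -117.43))
  list(hospitals = hospitals, centroids = centroids)
}

# a small random study for property tests: distances handed in directly so
# the constraint algebra is exercised without geography
random_constraint_fixture <- function(seed, n = 20) {
  set.seed(seed)
  design <- study_design("2017-04-01")
  ids <- sprintf("P%02d", seq_len(n))
  patients <- tibble::tibble(
    id = ids,
    zip = ifelse(runif(n) < 0.1, NA_character_,
                 sprintf("%05d", sample(10000:99999, n))),
    has_system_pcp = runif(n) < 0.5)
  m <- rpois(1, 6 * n)
  encounters <- tibble::tibble(
    patient_id = sample(ids, m, replace = TRUE),
    date = design$index_date + sample(-800:182, m, replace = TRUE),
    klass = sample(c("inpatient", "ed", "outpatient", "other"), m,
                   replace = TRUE, prob = c(0.1, 0.2, 0.45, 0.25)),
    in_system = runif(m) < 0.6,
    facility_id = NA_character_)
  distances <- tibble::tibble(
    id = ids,
    dist_miles = ifelse(is.na(patients$zip), NA_real_,
                        rexp(n, 1 / 8)))
  list(patients = patients, encounters = encounters,
       distances = distances, design = design)
}

# independent re-evaluation of the ten written constraint definitions:
# a literal per-patient translation, sharing no code with the package's
# vectorised path
brute_force_filter <- function(fix, family, r) {
  idx <- fix$design$index_date
  sapply(seq_len(nrow(fix$patients)), function(i) {
    p <- fix$patients[i, ]
    d <- fix$distances$dist_miles[fix$distances$id == p$id]
    if (is.na(d) || d > r) return(FALSE)
    e <- fix$encounters[fix$encounters$patient_id == p$id &
                          fix$encounters$in_system, , drop = FALSE]
    n_in <- function(days_back, classes) {
      sum(e$date >= idx - days_back & e$date < idx & e$klass %in% classes)
    }
    all_cl <- c("inpatient", "ed", "outpatient", "other")
    hosp_cl <- c("inpatient", "ed")
    switch(family,
      DISTANCE_ONLY = TRUE,
      PCP = p$has_system_pcp,
      ENC2_1Y = n_in(365, all_cl) >= 2,
      ENC2_2Y = n_in(730, all_cl) >= 2,
      HOSP1_1Y = n_in(365, hosp_cl) >= 1,
      HOSP2_1Y = n_in(365, hosp_cl) >= 2,
      HOSP2_2Y = n_in(730, hosp_cl) >= 2,
      OUTPT1_1Y = n_in(365, "outpatient") >= 1,
      OUTPT2_1Y = n_in(365, "outpatient") >= 2,
      OUTPT2_2Y = n_in(730, "outpatient") >= 2)
  })
}

# deterministic non-antipodal random coordinate pairs for geodesic checks
random_geo_pairs <- function(seed, n, max_sep_deg = NULL) {
  set.seed(seed)
  lat1 <- runif(n, -85, 85); lon1 <- runif(n, -180, 180)
  if (is.null(max_sep_deg)) {
    lat2 <- runif(n, -85, 85); lon2 <- runif(n, -180, 180)
    # keep pairs away from the antipode, where Vincenty legitimately fails
    anti <- abs(lat2 + lat1) < 2 & abs(abs(lon2 - lon1) - 180) < 2
    lat2[anti] <- lat2[anti] + 5
  } else {
    lat2 <- pmin(pmax(lat1 + runif(n, -max_sep_deg, max_sep_deg), -90), 90)
    lon2 <- lon1 + runif(n, -max_sep_deg, max_sep_deg)
    lon2 <- ((lon2 + 180) %% 360) - 180
  }
  data.frame(lat1, lon1, lat2, lon2)
}
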