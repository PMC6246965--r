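test_that("constraint_spec validates family and radius", {
  expect_equal(length(constraint_families()), 10)
  expect_error(constraint_spec("NOPE", 5), "unknown constraint family")
  expect_error(constraint_spec("PCP", 0), "positive")
  expect_error(constraint_spec("PCP", -3), "positive")
  expect_silent(constraint_spec("PCP", Inf))
})

empty_history <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 klass = character(), in_system = logical(),
                 facility_id = character())
}

test_that("satisfies_constraint implements the clause conjunction", {
  design <- study_design("2017-04-01")
  p_pcp <- tibble::tibble(id = "A", zip = "98101", has_system_pcp = TRUE)
  p_nopcp <- tibble::tibble(id = "B", zip = "98101", has_system_pcp = FALSE)

  # distance alone, r = Inf: vacuous distance clause for a located patient
  expect_true(satisfies_constraint(p_nopcp, empty_history(),
                                   constraint_spec("DISTANCE_ONLY", Inf),
                                   design, dist_miles = 500))
  # unlocatable patients fail every constraint, even at r = Inf
  expect_false(satisfies_constraint(p_pcp, empty_history(),
                                    constraint_spec("DISTANCE_ONLY", Inf),
                                    design, dist_miles = NA_real_))
  # conjunction fails without the PCP flag, however close the patient lives
  expect_false(satisfies_constraint(p_nopcp, empty_history(),
                                    constraint_spec("PCP", 5),
                                    design, dist_miles = 0.1))
  # "within r miles" is boundary-inclusive
  expect_true(satisfies_constraint(p_pcp, empty_history(),
                                   constraint_spec("PCP", 5),
                                   design, dist_miles = 5))
  expect_false(satisfies_constraint(p_pcp, empty_history(),
                                    constraint_spec("PCP", 5),
                                    design, dist_miles = 5.0001))

  # encounter-count threshold: 1 in-system encounter misses, 2 satisfy
  h1 <- tibble::tibble(patient_id = "A", date = as.Date("2016-06-01"),
                       klass = "outpatient", in_system = TRUE,
                       facility_id = NA_character_)
  h2 <- dplyr::bind_rows(h1, tibble::tibble(
    patient_id = "A", date = as.Date("2016-09-15"), klass = "other",
    in_system = TRUE, facility_id = NA_character_))
  spec <- constraint_spec("ENC2_1Y", 5)
  expect_false(satisfies_constraint(p_pcp, h1, spec, design, 1))
  expect_true(satisfies_constraint(p_pcp, h2, spec, design, 1))
})

test_that("a hand-enumerated 5-encounter history drives the hospital clause", {
  design <- study_design("2017-04-01")
  p <- tibble::tibble(id = "A", zip = "98101", has_system_pcp = FALSE)
  hist <- tibble::tibble(
    patient_id = "A",
    date = as.Date(c("2016-05-10", "2016-07-01", "2015-06-01",
                     "2016-08-20", "2017-01-05")),
    klass = c("ed", "outpatient", "inpatient", "inpatient", "other"),
    in_system = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    facility_id = c("H01", NA, "H02", NA, NA))
  # enumeration: in-system hospital encounters in the past year = {ed 2016-05-10}
  # (2015-06-01 inpatient is outside the short lookback, 2016-08-20 is out-of-system)
  expect_true(satisfies_constraint(p, hist, constraint_spec("HOSP1_1Y", 5),
                                   design, dist_miles = 2))
  expect_false(satisfies_constraint(p, hist, constraint_spec("HOSP2_1Y", 5),
                                    design, dist_miles = 2))
  # past 2 years adds the 2015 inpatient stay: two hospital encounters
  expect_true(satisfies_constraint(p, hist, constraint_spec("HOSP2_2Y", 5),
                                   design, dist_miles = 2))
  # one in-system outpatient visit in the past year
  expect_true(satisfies_constraint(p, hist, constraint_spec("OUTPT1_1Y", 5),
                                   design, dist_miles = 2))
  expect_false(satisfies_constraint(p, hist, constraint_spec("OUTPT2_2Y", 5),
                                    design, dist_miles = 2))
  # any-class in-system encounters in the past year = 3
  expect_true(satisfies_constraint(p, hist, constraint_spec("ENC2_1Y", 5),
                                   design, dist_miles = 2))
  # the clause holds but the distance clause fails beyond r
  expect_false(satisfies_constraint(p, hist, constraint_spec("HOSP1_1Y", 5),
                                    design, dist_miles = 7))
})

test_that("cohort_filter returns exactly the satisfying ids", {
  fix <- random_constraint_fixture(42, n = 10)
  # brute-force evaluation of the written definition, patient by patient
  expected <- fix$patients$id[brute_force_filter(fix, "PCP", 5)]
  got <- cohort_filter(fix$patients, fix$encounters,
                       constraint_spec("PCP", 5), fix$design, fix$distances)
  expect_identical(got, expected)

  # a vanishing radius with no patient at a hospital's own location
  tiny <- cohort_filter(fix$patients, fix$encounters,
                        constraint_spec("DISTANCE_ONLY", 1e-4),
                        fix$design, fix$distances)
  expect_length(tiny, 0)
})

test_that("filters are monotone in r and nested across families", {
  subset_pairs <- list(c("PCP", "DISTANCE_ONLY"),
                       c("ENC2_1Y", "ENC2_2Y"),
                       c("HOSP2_1Y", "HOSP1_1Y"),
                       c("HOSP2_1Y", "HOSP2_2Y"),
                       c("OUTPT2_1Y", "OUTPT1_1Y"),
                       c("OUTPT2_1Y", "OUTPT2_2Y"))
  for (seed in 1:20) {
    fix <- random_constraint_fixture(seed)
    radii <- c(1, 5, 20, Inf)
    for (family in constraint_families()) {
      sets <- lapply(radii, function(r) {
        cohort_filter(fix$patients, fix$encounters,
                      constraint_spec(family, r), fix$design, fix$distances)
      })
      for (k in 2:length(sets)) {
        expect_true(all(sets[[k - 1]] %in% sets[[k]]),
                    info = sprintf("seed %d family %s r %g < %g",
                                   seed, family, radii[k - 1], radii[k]))
      }
      # every family refines the pure distance constraint
      expect_true(all(sets[[2]] %in%
                        cohort_filter(fix$patients, fix$encounters,
                                      constraint_spec("DISTANCE_ONLY", 5),
                                      fix$design, fix$distances)))
    }
    for (pair in subset_pairs) {
      s1 <- cohort_filter(fix$patients, fix$encounters,
                          constraint_spec(pair[1], 5), fix$design,
                          fix$distances)
      s2 <- cohort_filter(fix$patients, fix$encounters,
                          constraint_spec(pair[2], 5), fix$design,
                          fix$distances)
      expect_true(all(s1 %in% s2),
                  info = sprintf("seed %d: %s should refine %s",
                                 seed, pair[1], pair[2]))
    }
  }
})

test_that("vectorised filtering agrees with the brute-force definitions", {
  for (seed in 21:40) {
    fix <- random_constraint_fixture(seed)
    for (family in constraint_families()) {
      for (r in c(3, 10, Inf)) {
        expect_identical(
          cohort_filter(fix$patients, fix$encounters,
                        constraint_spec(family, r), fix$design,
                        fix$distances),
          fix$patients$id[brute_force_filter(fix, family, r)],
          info = sprintf("seed %d family %s r %g", seed, family, r))
      }
    }
  }
})
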