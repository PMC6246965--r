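Package: carecapture
Title: Constraint-Based Identification of Patients Captured by a Health System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the subset of a health system's patients who receive
    most of their hospital care inside that system. Computes ellipsoid
    (Vincenty inverse) geodesic distances from patient home-zip centroids to
    system hospitals, evaluates ten candidate cohort constraints that combine
    a utilization or primary-care-attribution clause with a "lives within r
    miles of a system hospital" clause, sweeps two evaluation criteria
    (cohort share and pooled in-system hospital-encounter share) over a grid
    of radii, and selects the constraint that balances the two. Includes a
    synthetic fragmented-care data generator so the full pipeline can be
    exercised without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    geosphere,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
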