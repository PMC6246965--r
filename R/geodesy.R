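#' Reference ellipsoid
#'
#' Constructs an ellipsoid for geodesic computation. The default is WGS-84,
#' the ellipsoid underlying GPS coordinates and the usual default of geodesic
#' software.
#'
#' @param semi_major_axis Equatorial radius in meters (default 6378137).
#' @param flattening Dimensionless flattening (default 1/298.257223563).
#' @return An object of class `ellipsoid`.
#' @export
wgs84 <- function(semi_major_axis = 6378137,
                  flattening = 1 / 298.257223563) {
  if (!is.numeric(semi_major_axis) || length(semi_major_axis) != 1 ||
      !is.finite(semi_major_axis) || semi_major_axis <= 0) {
    abort_validation("semi_major_axis must be a single positive finite number")
  }
  if (!is.numeric(flattening) || length(flattening) != 1 ||
      !is.finite(flattening) || flattening <= 0 || flattening >= 1) {
    abort_validation("flattening must be a single number in (0, 1)")
  }
  structure(list(a = semi_major_axis, f = flattening), class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> a = %.3f m, f = 1/%.9f\n", x$a, 1 / x$f))
  invisible(x)
}

check_latlon <- function(lat, lon, what) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    abort_validation(sprintf("%s: coordinates must be finite", what))
  }
  if (any(lat < -90 | lat > 90)) {
    abort_validation(sprintf("%s: latitude outside [-90, 90]", what))
  }
  if (any(lon < -180 | lon > 180)) {
    abort_validation(sprintf("%s: longitude outside [-180, 180]", what))
  }
  invisible(TRUE)
}

#' Vincenty inverse geodesic distance
#'
#' Distance in meters between points on a reference ellipsoid, by Vincenty's
#' inverse formula. This is the straight-line ("ellipsoid great circle")
#' distance used as a rough proxy of travel distance between a patient's
#' home-zip centroid and a hospital.
#'
#' Vectorised over the coordinate arguments (recycled to a common length).
#' Iteration stops when the change in the auxiliary longitude is below `tol`
#' radians; nearly antipodal pairs for which the iteration has not converged
#' after `max_iter` steps raise an error rather than returning a silently
#' wrong number.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees
#'   (latitude in \[-90, 90\], longitude in \[-180, 180\]).
#' @param ellipsoid An [wgs84()] ellipsoid object.
#' @param tol Convergence tolerance in radians (default 1e-12, sub-millimeter).
#' @param max_iter Iteration cap (default 200).
#' @return Numeric vector of distances in meters.
#' @examples
#' vincenty_inverse(47.6, -122.3, 47.6, -122.3) # 0
#' vincenty_inverse(0, 0, 0, 1)                 # one degree along the equator
#' @export
vincenty_inverse <- function(lat1, lon1, lat2, lon2,
                             ellipsoid = wgs84(),
                             tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(ellipsoid, "ellipsoid"))
  check_latlon(lat1, lon1, "point a")
  check_latlon(lat2, lon2, "point b")
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)

  a <- ellipsoid$a
  f <- ellipsoid$f
  b <- a * (1 - f)

  deg2rad <- pi / 180
  U1 <- atan((1 - f) * tan(lat1 * deg2rad))
  U2 <- atan((1 - f) * tan(lat2 * deg2rad))
  L  <- (lon2 - lon1) * deg2rad
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)

  lambda <- L
  sinSigma <- numeric(n); cosSigma <- numeric(n); sigma <- numeric(n)
  cosSqAlpha <- numeric(n); cos2SigmaM <- numeric(n)
  coincident <- rep(FALSE, n)
  active <- rep(TRUE, n)

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    sinLambda <- sin(lambda[active]); cosLambda <- cos(lambda[active])
    sU1 <- sinU1[active]; cU1 <- cosU1[active]
    sU2 <- sinU2[active]; cU2 <- cosU2[active]

    sinSig <- sqrt((cU2 * sinLambda)^2 +
                   (cU1 * sU2 - sU1 * cU2 * cosLambda)^2)
    cosSig <- sU1 * sU2 + cU1 * cU2 * cosLambda
    coin <- sinSig == 0
    sig <- atan2(sinSig, cosSig)
    sinAlpha <- ifelse(coin, 0, cU1 * cU2 * sinLambda / sinSig)
    cosSqA <- 1 - sinAlpha^2
    # equatorial geodesics have cosSqAlpha = 0; cos(2*sigma_m) is then unused
    cos2SigM <- ifelse(cosSqA == 0, 0, cosSig - 2 * sU1 * sU2 / cosSqA)
    C <- f / 16 * cosSqA * (4 + f * (4 - 3 * cosSqA))
    lambdaNew <- L[active] + (1 - C) * f * sinAlpha *
      (sig + C * sinSig *
         (cos2SigM + C * cosSig * (-1 + 2 * cos2SigM^2)))

    converged <- coin | abs(lambdaNew - lambda[active]) < tol

    idx <- which(active)
    sinSigma[idx] <- sinSig; cosSigma[idx] <- cosSig; sigma[idx] <- sig
    cosSqAlpha[idx] <- cosSqA; cos2SigmaM[idx] <- cos2SigM
    coincident[idx] <- coincident[idx] | coin
    lambda[idx] <- lambdaNew
    active[idx] <- !converged
  }
  if (any(active)) {
    abort_validation(sprintf(
      "Vincenty iteration did not converge after %d iterations for %d pair(s) (indices: %s); the points are likely nearly antipodal",
      max_iter, sum(active),
      paste(utils::head(which(active), 5), collapse = ", ")))
  }

  uSq <- cosSqAlpha * (a^2 - b^2) / b^2
  A <- 1 + uSq / 16384 * (4096 + uSq * (-768 + uSq * (320 - 175 * uSq)))
  B <- uSq / 1024 * (256 + uSq * (-128 + uSq * (74 - 47 * uSq)))
  deltaSigma <- B * sinSigma *
    (cos2SigmaM + B / 4 *
       (cosSigma * (-1 + 2 * cos2SigmaM^2) -
          B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) *
          (-3 + 4 * cos2SigmaM^2)))
  s <- b * A * (sigma - deltaSigma)
  s[coincident] <- 0
  s
}

#' Read a zip-centroid table
#'
#' @param path CSV with header `zip,lat,lon` (WGS-84 decimal degrees).
#' @return Tibble with columns `zip` (5-digit string), `lat`, `lon`.
#' @export
read_zip_centroids <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    zip = readr::col_character(),
    lat = readr::col_double(),
    lon = readr::col_double()
  ))
  validate_zip_centroids(x)
}

#' Validate an in-memory centroid table
#' @param x Data frame with columns `zip`, `lat`, `lon`.
#' @return Validated tibble.
#' @export
validate_zip_centroids <- function(x) {
  need <- c("zip", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_validation(paste0("centroid table missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  bad <- which(!grepl("^[0-9]{5}$", x$zip))
  if (length(bad)) {
    abort_validation(sprintf("centroid row %d: malformed zip '%s'",
                             bad[1], x$zip[bad[1]]))
  }
  dup <- x$zip[duplicated(x$zip)]
  if (length(dup)) {
    abort_validation(paste0("duplicate zip in centroid table: ", dup[1]))
  }
  check_latlon(x$lat, x$lon, "centroid table")
  tibble::as_tibble(x[need])
}

#' Read a hospital table
#'
#' @param path CSV with header `id,name,lat,lon`.
#' @return Tibble with columns `id`, `name`, `lat`, `lon`.
#' @export
read_hospitals <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    name = readr::col_character(),
    lat = readr::col_double(),
    lon = readr::col_double()
  ))
  validate_hospitals(x)
}

#' Validate an in-memory hospital table
#' @param x Data frame with columns `id`, `name`, `lat`, `lon`.
#' @return Validated tibble.
#' @export
validate_hospitals <- function(x) {
  need <- c("id", "name", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_validation(paste0("hospital table missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) abort_validation("hospital table must have at least one row")
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) abort_validation(paste0("duplicate hospital id: ", dup[1]))
  check_latlon(x$lat, x$lon, "hospital table")
  tibble::as_tibble(x[need])
}

#' Minimum hospital distance per zip, in miles
#'
#' For each 5-digit zip, the minimum over hospitals of the Vincenty distance
#' from the zip centroid, converted to statute miles (1 mile = 1609.344 m).
#' Zips absent from the centroid table get `NA` (the patient is unlocatable).
#'
#' @param zips Character vector of 5-digit zips (`NA` allowed, stays `NA`).
#' @param centroids Centroid table (`zip`, `lat`, `lon`).
#' @param hospitals Hospital table (`id`, `name`, `lat`, `lon`).
#' @param ellipsoid Ellipsoid, default WGS-84.
#' @return Numeric vector of miles, aligned with `zips`; `NA` where the zip
#'   is missing or not in the centroid table.
#' @export
min_hospital_distance_miles <- function(zips, centroids, hospitals,
                                        ellipsoid = wgs84()) {
  centroids <- validate_zip_centroids(centroids)
  hospitals <- validate_hospitals(hospitals)
  known <- !is.na(zips)
  bad <- which(known & !grepl("^[0-9]{5}$", zips))
  if (length(bad)) {
    abort_validation(sprintf("malformed zip '%s'", zips[bad[1]]))
  }
  uz <- unique(zips[known])
  uz <- uz[uz %in% centroids$zip]
  out <- rep(NA_real_, length(zips))
  if (length(uz) == 0) return(out)

  ci <- match(uz, centroids$zip)
  nh <- nrow(hospitals)
  # distance matrix: unique zips x hospitals, fully vectorised
  d <- vincenty_inverse(
    lat1 = rep(centroids$lat[ci], times = nh),
    lon1 = rep(centroids$lon[ci], times = nh),
    lat2 = rep(hospitals$lat, each = length(uz)),
    lon2 = rep(hospitals$lon, each = length(uz)),
    ellipsoid = ellipsoid
  )
  dmin <- apply(matrix(d, nrow = length(uz), ncol = nh), 1, min)
  m <- match(zips, uz)
  out[!is.na(m)] <- meters_to_miles(dmin[m[!is.na(m)]])
  out
}

#' Per-patient distance table
#'
#' Joins each patient's home zip to the centroid table and computes the
#' minimum Vincenty distance (miles) to any system hospital. Patients with a
#' missing zip, or a zip absent from the centroid table, get `NA` and are
#' counted in the `n_unlocatable` attribute; such patients fail every
#' distance-gated constraint and are reported as exclusions.
#'
#' @param patients Patient table (needs `id`, `zip`).
#' @param centroids,hospitals As in [min_hospital_distance_miles()].
#' @param ellipsoid Ellipsoid, default WGS-84.
#' @return Tibble `id`, `dist_miles` with attribute `n_unlocatable`.
#' @export
patient_distances <- function(patients, centroids, hospitals,
                              ellipsoid = wgs84()) {
  d <- min_hospital_distance_miles(patients$zip, centroids, hospitals,
                                   ellipsoid = ellipsoid)
  out <- tibble::tibble(id = patients$id, dist_miles = d)
  attr(out, "n_unlocatable") <- sum(is.na(d))
  out
}
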