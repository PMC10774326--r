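#' @keywords internal
"_PACKAGE"

# Earth radius used throughout, km (documented constant).
EARTH_RADIUS_KM <- 6371.0

# km per degree of arc on the sphere of radius EARTH_RADIUS_KM
KM_PER_DEG <- 2 * pi * EARTH_RADIUS_KM / 360

#' Great-circle distance by the Haversine formula
#'
#' Distance between points on a sphere of radius 6371.0 km. Inputs are
#' recycled to a common length, so the function computes element-wise
#' distances between two sets of coordinates.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing between two points
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in degrees in \[0, 360).
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlon <- (lon2 - lon1) * rad
  y <- sin(dlon) * cos(lat2 * rad)
  x <- cos(lat1 * rad) * sin(lat2 * rad) -
    sin(lat1 * rad) * cos(lat2 * rad) * cos(dlon)
  (atan2(y, x) / rad) %% 360
}

# Unit-vector (3-D) mean of positions on the sphere, renormalized and
# converted back to lon/lat. Avoids longitude wrap-around artifacts.
unit_vector_mean <- function(lon, lat) {
  rad <- pi / 180
  x <- mean(cos(lat * rad) * cos(lon * rad))
  y <- mean(cos(lat * rad) * sin(lon * rad))
  z <- mean(sin(lat * rad))
  n <- sqrt(x^2 + y^2 + z^2)
  if (n == 0) stop("degenerate point set: antipodal cancellation in centroid")
  c(lon = atan2(y, x) / rad, lat = asin(z / n) / rad)
}

# Local equirectangular projection anchored at (lon0, lat0): degrees -> km.
# Adequate for the O(100 km) neighbourhoods the planar hex backend serves.
local_xy_km <- function(lon, lat, lon0, lat0) {
  cbind(
    x = (lon - lon0) * KM_PER_DEG * cos(lat0 * pi / 180),
    y = (lat - lat0) * KM_PER_DEG
  )
}

local_lonlat <- function(x, y, lon0, lat0) {
  cbind(
    lon = lon0 + x / (KM_PER_DEG * cos(lat0 * pi / 180)),
    lat = lat0 + y / KM_PER_DEG
  )
}

#' Median absolute deviation from the median, normalized by the median (MADm)
#'
#' A robust, scale-free variability measure: `median(|x - median(x)|) /
#' median(x)`. MADm = 1 means half the samples deviate from the median by
#' more than the median itself. Invariant to positive rescaling.
#'
#' @param values Numeric vector, typically positive (NAs dropped).
#' @return Dimensionless MADm; `NaN` (with a warning) if the median is zero.
#' @examples
#' compute_madm(c(1, 2, 3))  # 0.5
#' @export
compute_madm <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) return(NaN)
  m <- stats::median(values)
  if (m == 0) {
    warning("median of input is zero; MADm undefined")
    return(NaN)
  }
  stats::median(abs(values - m)) / m
}
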