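# Small shared helpers: angle wrapping, local planar frames, seeds.

EARTH_RADIUS_M <- 6371000

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' The wrap convention used throughout: values equal to -pi map to +pi, so
#' an exact reversal of direction is reported as +pi.
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- -((-a + pi) %% (2 * pi) - pi)
  w[w == -pi] <- pi
  w
}

# Mean direction and resultant length of a sample of angles.
circular_mean <- function(theta) {
  theta <- theta[!is.na(theta)]
  atan2(mean(sin(theta)), mean(cos(theta)))
}

circular_resultant <- function(theta) {
  theta <- theta[!is.na(theta)]
  sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
}

# Shortest angular distance between two directions.
angle_dist <- function(a, b) abs(wrap_angle(a - b))

#' Project WGS84 coordinates onto a local planar frame
#'
#' Local tangent-plane (azimuthal equidistant at small extents) projection
#' centred on `centre`; x east, y north, in metres. Adequate at herd scale
#' (tens of km) where distortion is far below GPS noise.
#'
#' @param lonlat matrix/data.frame with columns lon, lat (decimal degrees).
#' @param centre numeric c(lon, lat) of the projection centre.
#' @return two-column matrix (x, y) in metres.
#' @export
local_xy <- function(lonlat, centre) {
  lonlat <- as.matrix(lonlat)
  rad <- pi / 180
  x <- (lonlat[, 1] - centre[1]) * rad * EARTH_RADIUS_M * cos(centre[2] * rad)
  y <- (lonlat[, 2] - centre[2]) * rad * EARTH_RADIUS_M
  cbind(x = x, y = y)
}

#' Inverse of [local_xy()]
#'
#' @param xy two-column matrix (x, y) metres in the local frame.
#' @param centre numeric c(lon, lat) of the projection centre.
#' @return two-column matrix (lon, lat) in decimal degrees.
#' @export
local_lonlat <- function(xy, centre) {
  xy <- as.matrix(xy)
  deg <- 180 / pi
  lon <- centre[1] + xy[, 1] / (EARTH_RADIUS_M * cos(centre[2] * pi / 180)) * deg
  lat <- centre[2] + xy[, 2] / EARTH_RADIUS_M * deg
  cbind(lon = lon, lat = lat)
}

#' Convert a step length per fix interval to a speed
#'
#' @param step_m step length in metres covered during one fix interval.
#' @param interval_s fix interval in seconds (default 1800 s = 30 min).
#' @return speed in km/h.
#' @export
step_speed_kmh <- function(step_m, interval_s = 1800) {
  step_m / 1000 / (interval_s / 3600)
}

# Derive a child seed deterministically; kept below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(k) * 7919L
}

# run-length helper returning start/end indices of runs of TRUE
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
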