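# Solar position: sunrise/sunset in local apparent solar time, from the
# standard NOAA low-precision equations (fractional-year Fourier series for
# declination and the equation of time, zenith 90.833 degrees for
# refraction-corrected rise/set).

solar_decl_eot <- function(time_utc) {
  lt <- as.POSIXlt(time_utc, tz = "UTC")
  doy <- lt$yday
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(decl = decl, eqtime_min = eqtime)
}

#' Sunrise and sunset in local apparent solar time
#'
#' Hours of local apparent solar time (solar noon = 12.0) at which the sun
#' crosses the refraction-corrected horizon (zenith 90.833 deg).
#'
#' @param time_utc POSIXct timestamp(s), UTC (the date matters).
#' @param lat latitude in decimal degrees, |lat| <= 60 (tropical/temperate
#'   study areas; polar day/night cases are out of scope).
#' @return data.frame with columns `sunrise`, `sunset` (hours, apparent
#'   solar time).
#' @export
sun_times_apparent <- function(time_utc, lat) {
  if (any(abs(lat) > 60))
    stop("|lat| > 60 degrees: polar day/night handling is out of scope")
  se <- solar_decl_eot(time_utc)
  phi <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cosha <- (cos(zen) - sin(phi) * sin(se$decl)) / (cos(phi) * cos(se$decl))
  cosha <- pmin(pmax(cosha, -1), 1)
  ha <- acos(cosha) * 180 / pi # degrees
  data.frame(sunrise = 12 - ha / 15, sunset = 12 + ha / 15)
}

#' Local apparent solar time of a UTC timestamp
#'
#' UTC hours plus the longitude offset (4 min/deg) plus the equation of
#' time; diel labelling uses apparent solar time rather than a civil
#' timezone so that day/night is defined relative to the sun itself.
#'
#' @param time_utc POSIXct, UTC.
#' @param lon longitude in decimal degrees.
#' @return hours in \[0, 24).
#' @export
apparent_solar_time <- function(time_utc, lon) {
  lt <- as.POSIXlt(time_utc, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  se <- solar_decl_eot(time_utc)
  (hour + lon / 15 + se$eqtime_min / 60) %% 24
}
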