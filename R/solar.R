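#' Low-accuracy solar ephemeris
#'
#' Solar declination and equation of time from the NOAA low-accuracy
#' formulas (Fourier fits in the fractional year). Documented accuracy is
#' about 0.1 degrees in declination and 1 minute in the equation of time,
#' small against the positional error of threshold geolocation.
#'
#' @param time a `POSIXct` vector in UTC (years 1950-2100).
#' @return a data.frame with columns `declination` (degrees, in
#'   \[-23.5, 23.5\]) and `eq_of_time` (minutes, apparent minus mean solar
#'   time).
#' @examples
#' solar_ephemeris(as.POSIXct("2014-06-21 12:00:00", tz = "UTC"))
#' @export
solar_ephemeris <- function(time) {
  time <- .as_utc(time)
  yr <- as.integer(format(time, "%Y"))
  if (any(yr < 1950 | yr > 2100)) {
    stop("solar_ephemeris: time outside the 1950-2100 validity range")
  }
  doy <- as.integer(format(time, "%j"))
  hour <- as.numeric(time - trunc(time, "days"), units = "hours")
  days_in_year <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0),
                         366, 365)
  g <- 2 * pi / days_in_year * (doy - 1 + (hour - 12) / 24)

  eqtime <- 229.18 * (0.000075 +
    0.001868 * cos(g)     - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 -
    0.399912 * cos(g)     + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.001480 * sin(3 * g)

  data.frame(declination = decl * 180 / pi, eq_of_time = eqtime)
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon at a time and place, from the
#' standard hour-angle formula
#' `sin(h) = sin(phi) sin(delta) + cos(phi) cos(delta) cos(H)`,
#' with the hour angle derived from true solar time (UTC corrected by
#' longitude and the equation of time). No atmospheric refraction is
#' applied: the threshold method absorbs refraction into the calibrated
#' sun elevation angle.
#'
#' @param time `POSIXct` UTC (recycled against `lat`/`lon`).
#' @param lat,lon position in decimal degrees (north/east positive).
#' @return elevation in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  eph <- solar_ephemeris(time)
  time <- .as_utc(time)
  utc_min <- as.numeric(time - trunc(time, "days"), units = "mins")
  tst <- (utc_min + eph$eq_of_time + 4 * lon) %% 1440
  ha <- tst / 4 - 180                      # degrees from local solar noon
  phi <- lat * pi / 180
  dec <- eph$declination * pi / 180
  sinel <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha * pi / 180)
  asin(pmin(1, pmax(-1, sinel))) * 180 / pi
}

.as_utc <- function(time) {
  if (!inherits(time, "POSIXct")) {
    time <- as.POSIXct(time, tz = "UTC")
  }
  attr(time, "tzone") <- "UTC"
  time
}
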