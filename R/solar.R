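#' Sunrise and sunset times
#'
#' Solar ephemeris following the NOAA solar-calculator formulation
#' (Julian-century polynomial series for solar longitude, obliquity,
#' declination and the equation of time; zenith 90.833 degrees, i.e. the
#' apparent upper limb at standard refraction). Accuracy is well under a
#' minute at mid latitudes, which is ample for deciding whether a tracking
#' day is covered from sunrise to sunset.
#'
#' All times are UTC: the GPS devices log UTC and the whole pipeline avoids
#' local-time conversion.
#'
#' @param date A `Date` (or something coercible to one), or a vector of them.
#' @param lon,lat Site coordinates in decimal degrees.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct UTC)
#'   and `day_length` (seconds).
#' @examples
#' solar_times(as.Date("2013-06-21"), lon = -5.98, lat = 37.39)
#' @export
solar_times <- function(date, lon, lat) {
  date <- as.Date(date)
  check_coords(lon, lat)
  n <- max(length(date), length(lon))
  date <- rep_len(date, n)
  lon <- rep_len(lon, n)
  lat <- rep_len(lat, n)

  deg2rad <- pi / 180
  # Julian day at 00:00 UTC, then evaluated at local solar noon.
  jd <- as.numeric(date) + 2440587.5
  jc <- (jd + 0.5 - lon / 360 - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqc <- sin(gma * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * deg2rad) * 0.000289
  stl <- gml + eqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(oc * deg2rad) * sin(sal * deg2rad))
  var_y <- tan(oc / 2 * deg2rad)^2
  eq_time <- 4 / deg2rad * (var_y * sin(2 * gml * deg2rad) -
    2 * ecc * sin(gma * deg2rad) +
    4 * ecc * var_y * sin(gma * deg2rad) * cos(2 * gml * deg2rad) -
    0.5 * var_y^2 * sin(4 * gml * deg2rad) -
    1.25 * ecc^2 * sin(2 * gma * deg2rad))

  cos_ha <- cos(90.833 * deg2rad) / (cos(lat * deg2rad) * cos(decl)) -
    tan(lat * deg2rad) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    stop("polar day/night: sun does not rise and set at this date/latitude",
         call. = FALSE)
  }
  ha <- acos(cos_ha) / deg2rad

  solar_noon_min <- 720 - 4 * lon - eq_time
  sunrise_min <- solar_noon_min - 4 * ha
  sunset_min <- solar_noon_min + 4 * ha

  midnight <- as.POSIXct(as.numeric(date) * 86400,
                         origin = "1970-01-01", tz = "UTC")
  tibble::tibble(
    date = date,
    sunrise = midnight + sunrise_min * 60,
    sunset = midnight + sunset_min * 60,
    day_length = (sunset_min - sunrise_min) * 60
  )
}
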