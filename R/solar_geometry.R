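#' Construct a geographic location
#'
#' A named site with latitude, longitude and surface elevation; the spatial
#' key attached to every daily dose series.
#'
#' @param name Site name (character scalar).
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east, in \[-180, 180\].
#' @param elevation Surface elevation in metres (>= -430, the lowest land
#'   surface on Earth). Default 0.
#'
#' @return An object of class `geo_location`.
#' @examples
#' geo_location("Dublin", 53.35, -6.26, 20)
#' @export
geo_location <- function(name, latitude, longitude, elevation = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]", call. = FALSE)
  if (!is.finite(longitude) || longitude < -180 || longitude > 180)
    stop("longitude must be in [-180, 180]", call. = FALSE)
  if (!is.finite(elevation) || elevation < -430)
    stop("elevation must be finite and >= -430 m", call. = FALSE)
  structure(
    list(name = name, latitude = latitude, longitude = longitude,
         elevation = elevation),
    class = "geo_location"
  )
}

#' @export
print.geo_location <- function(x, ...) {
  cat(sprintf("<geo_location> %s (%.2f N, %.2f E, %.0f m)\n",
              x$name, x$latitude, x$longitude, x$elevation))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Fractional-year angle (radians) used by the Spencer (1971) Fourier fits.
year_angle <- function(day_of_year, hour = 12) {
  2 * pi * (day_of_year - 1 + (hour - 12) / 24) / 365
}

#' Solar declination
#'
#' Low-precision declination of the sun from the Spencer Fourier series,
#' accurate to about 0.3 degrees -- ample for dose climatology where the
#' solar zenith angle plays a structural role.
#'
#' @param day_of_year Integer day of year, 1..365 (leap-day callers should
#'   map Feb 29 to day 59 or 60; the climatology itself omits leap days).
#'
#' @return Declination in degrees, within \[-23.45, 23.45\].
#' @examples
#' solar_declination(172) # June solstice, close to +23.44
#' @export
solar_declination <- function(day_of_year) {
  if (any(!is.finite(day_of_year)) ||
      any(day_of_year < 1) || any(day_of_year > 365))
    stop("day_of_year must be in 1..365", call. = FALSE)
  g <- year_angle(day_of_year)
  delta <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  pmin(pmax(rad2deg(delta), -23.45), 23.45)
}

#' Equation of time
#'
#' Difference between apparent and mean solar time (Spencer fit).
#'
#' @param day_of_year Integer day of year, 1..365.
#' @return Minutes (apparent minus mean solar time), roughly in \[-15, 17\].
#' @export
equation_of_time <- function(day_of_year) {
  g <- year_angle(day_of_year)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
}

# day of year with Feb 29 folded onto Feb 28 so the 1..365 domain holds
day_of_year_365 <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  leap <- is_leap_year(as.integer(strftime(date, "%Y")))
  after_feb28 <- leap & doy >= 60
  doy[after_feb28] <- doy[after_feb28] - 1L
  doy
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Solar zenith angle at a UTC instant
#'
#' Computes the angle between the sun and the local vertical from
#' declination and the hour angle of longitude-corrected apparent solar
#' time: cos(SZA) = sin(lat) sin(dec) + cos(lat) cos(dec) cos(H).
#'
#' @param loc A [geo_location()].
#' @param instant A `POSIXct` instant (interpreted in UTC) or anything
#'   `as.POSIXct` accepts with `tz = "UTC"`.
#'
#' @return Zenith angle in degrees, in \[0, 180\].
#' @examples
#' dub <- geo_location("Dublin", 53.35, -6.26)
#' solar_zenith_angle(dub, as.POSIXct("2020-06-21 12:25:00", tz = "UTC"))
#' @export
solar_zenith_angle <- function(loc, instant) {
  stopifnot(inherits(loc, "geo_location"))
  instant <- as.POSIXct(instant, tz = "UTC")
  doy <- day_of_year_365(as.Date(instant, tz = "UTC"))
  utc_hours <- as.numeric(instant) %% 86400 / 3600
  # apparent solar time in hours: UTC + 4 min/deg of longitude + EoT
  solar_hours <- utc_hours + loc$longitude / 15 + equation_of_time(doy) / 60
  hour_angle <- deg2rad((solar_hours - 12) * 15)
  phi <- deg2rad(loc$latitude)
  delta <- deg2rad(solar_declination(doy))
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(hour_angle)
  rad2deg(acos(pmin(pmax(cosz, -1), 1)))
}

#' Noon solar zenith angle for a calendar date
#'
#' Zenith angle at local apparent solar noon, equal to |latitude -
#' declination|. Used by the high-latitude winter data-gap rule (cloud
#' retrieval unavailable when noon SZA exceeds 78 degrees).
#'
#' @param loc A [geo_location()].
#' @param date A `Date` (or coercible) vector.
#' @return Noon zenith angle(s) in degrees.
#' @export
noon_sza <- function(loc, date) {
  stopifnot(inherits(loc, "geo_location"))
  abs(loc$latitude - solar_declination(day_of_year_365(date)))
}

# UTC time of local apparent solar noon for a date, as POSIXct
solar_noon_utc <- function(loc, date) {
  date <- as.Date(date)
  doy <- day_of_year_365(date)
  noon_utc_hours <- 12 - loc$longitude / 15 - equation_of_time(doy) / 60
  as.POSIXct(date, tz = "UTC") + noon_utc_hours * 3600
}

#' Daylight window for a date
#'
#' Sunrise and sunset (zenith angle crossing 90 degrees, no refraction
#' correction), solved by bisection on SZA - 90 to one-minute resolution.
#'
#' @param loc A [geo_location()].
#' @param date A single `Date` (or coercible).
#'
#' @return A list with `status` ("ok", "no_daylight" for polar night,
#'   "no_night" for midnight sun) and, when `status == "ok"`, `sunrise` and
#'   `sunset` as UTC `POSIXct`.
#' @examples
#' daylight_window(geo_location("Quito", 0, -78.5), as.Date("2020-03-20"))
#' @export
daylight_window <- function(loc, date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L)
  noon <- solar_noon_utc(loc, date)
  if (solar_zenith_angle(loc, noon) >= 90)
    return(list(status = "no_daylight", sunrise = NULL, sunset = NULL))
  midnight_before <- noon - 12 * 3600
  midnight_after <- noon + 12 * 3600
  if (solar_zenith_angle(loc, midnight_before) < 90 &&
      solar_zenith_angle(loc, midnight_after) < 90)
    return(list(status = "no_night", sunrise = NULL, sunset = NULL))
  f <- function(t) solar_zenith_angle(loc, t) - 90
  sunrise <- bisect_time(f, midnight_before, noon, rising = FALSE)
  sunset <- bisect_time(f, noon, midnight_after, rising = TRUE)
  list(status = "ok", sunrise = sunrise, sunset = sunset)
}

# bisection for the sign change of f between two POSIXct instants, 60 s tol
bisect_time <- function(f, lo, hi, rising, tol = 60) {
  flo <- f(lo)
  fhi <- f(hi)
  if (sign(flo) == sign(fhi)) stop("no sign change in bracket", call. = FALSE)
  while (as.numeric(hi) - as.numeric(lo) > tol) {
    mid <- lo + (as.numeric(hi) - as.numeric(lo)) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  lo + (as.numeric(hi) - as.numeric(lo)) / 2
}
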