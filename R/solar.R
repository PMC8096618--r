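#' Solar position (low-precision ephemeris)
#'
#' Computes the sun's azimuth and elevation from a standard low-precision
#' astronomical algorithm (geometric mean longitude and anomaly, equation of
#' center, apparent ecliptic longitude, obliquity, equation of time, hour
#' angle), accurate to well under 0.3 degrees over 1950-2050. This is the
#' accuracy class of the desktop astronomy programs commonly used to read
#' off sun azimuth in orientation-cage work.
#'
#' @param position a [geo_position()].
#' @param instant a `POSIXct` instant (converted to UTC).
#' @return list of class `solar_position`: `azimuth` (degrees clockwise from
#'   geographic north, `[0, 360)`) and `elevation` (degrees above the
#'   geometric horizon; no refraction).
#' @examples
#' sun_position(geo_position(61.35, -165.1333),
#'              as.POSIXct("2005-09-01 05:00:00", tz = "UTC"))
#' @export
sun_position <- function(position, instant) {
  p <- as_geo_position(position)
  stopifnot(inherits(instant, "POSIXct"), length(instant) == 1)
  yr <- as.integer(format(instant, "%Y", tz = "UTC"))
  if (yr < 1950 || yr > 2050) stop("instant outside supported years 1950-2050")
  jd <- as.numeric(instant) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525

  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- deg2rad(357.52911 + 35999.05029 * T - 0.0001537 * T^2)
  e <- 0.016708634 - 0.000042037 * T - 0.0000001267 * T^2
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  lambda <- deg2rad(true_long - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + 21.448 / 60) / 60 -
    (46.815 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  delta <- asin(sin(eps) * sin(lambda))

  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0); Mr <- M
  eqtime <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  ) # minutes

  mins_utc <- (as.numeric(instant) %% 86400) / 60
  true_solar_min <- (mins_utc + eqtime + 4 * p$lon) %% 1440
  ha <- deg2rad(true_solar_min / 4 - 180)

  phi <- deg2rad(p$lat)
  elev <- asin(sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(ha))
  # azimuth measured clockwise from geographic north
  az <- atan2(sin(ha), cos(ha) * sin(phi) - tan(delta) * cos(phi))
  az <- norm360(rad2deg(az) + 180)
  structure(list(azimuth = az, elevation = rad2deg(elev)),
            class = "solar_position")
}

#' @export
print.solar_position <- function(x, ...) {
  cat(sprintf("<solar_position az %.2f deg, el %.2f deg>\n",
              x$azimuth, x$elevation))
  invisible(x)
}

#' Instant of local sunset
#'
#' Finds the UTC instant on the given local calendar date at which the sun's
#' elevation crosses the horizon going down, by scanning the local day and
#' bisecting the bracketed crossing to 1 s. "Local" is mean solar time at
#' the position's longitude. The default horizon is geometric (elevation 0);
#' set `horizon = -0.833` for the conventional refracted-disc definition.
#'
#' @param position a [geo_position()].
#' @param date a `Date` (or string `"YYYY-MM-DD"`), interpreted as the local
#'   calendar date.
#' @param horizon horizon elevation in degrees.
#' @return the sunset `POSIXct` instant (UTC).
#' @examples
#' sunset_instant(geo_position(61.35, -165.1333), as.Date("2005-09-01"))
#' @export
sunset_instant <- function(position, date, horizon = 0) {
  p <- as_geo_position(position)
  date <- as.Date(date)
  # UTC window covering the local mean-solar-time day
  offset_s <- p$lon / 15 * 3600
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") - offset_s
  ts <- t0 + seq(0, 86400, by = 600)
  el <- vapply(ts, function(t) sun_position(p, t)$elevation - horizon, 0)
  # downward zero crossings
  idx <- which(el[-length(el)] > 0 & el[-1] <= 0)
  if (length(idx) == 0) {
    stop("no sunset on ", format(date), " at this latitude (polar day or night)")
  }
  lo <- as.numeric(ts[idx[1]]); hi <- as.numeric(ts[idx[1] + 1])
  f <- function(t) sun_position(p, as.POSIXct(t, origin = "1970-01-01",
                                              tz = "UTC"))$elevation - horizon
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  as.POSIXct((lo + hi) / 2, origin = "1970-01-01", tz = "UTC")
}
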