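#' Angle utilities
#'
#' Small helpers shared across the package. All public interfaces use degrees;
#' trigonometry is done in radians internally.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize an angle to [0, 360)
#' @param x angle(s) in degrees.
#' @return angle(s) in `[0, 360)`.
#' @export
norm360 <- function(x) {
  y <- x %% 360
  # guard against -1e-15 %% 360 == 360 after rounding
  y[y >= 360] <- y[y >= 360] - 360
  y
}

#' Signed smallest angular difference a - b
#'
#' @param a,b angles in degrees.
#' @return signed difference in `(-180, 180]`.
#' @export
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Geographic position on a spherical Earth
#'
#' Validates and normalizes a latitude/longitude pair. Longitude is wrapped to
#' `(-180, 180]`.
#'
#' @param lat latitude, degrees North, in `[-90, 90]`.
#' @param lon longitude, degrees East; wrapped to `(-180, 180]`.
#' @return an object of class `geo_position`: a list with `lat` and `lon`.
#' @examples
#' geo_position(61.35, -165.1333)  # a stopover site in SW Alaska
#' @export
geo_position <- function(lat, lon) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(lat) == 1, length(lon) == 1,
            is.finite(lat), is.finite(lon))
  if (lat < -90 || lat > 90) stop("latitude must lie in [-90, 90]")
  lon <- ((lon + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  structure(list(lat = lat, lon = lon), class = "geo_position")
}

#' @export
print.geo_position <- function(x, ...) {
  cat(sprintf("<geo_position %.4f%s, %.4f%s>\n",
              abs(x$lat), if (x$lat >= 0) "N" else "S",
              abs(x$lon), if (x$lon >= 0) "E" else "W"))
  invisible(x)
}

as_geo_position <- function(x) {
  if (inherits(x, "geo_position")) return(x)
  if (is.numeric(x) && length(x) == 2) return(geo_position(x[1], x[2]))
  if (is.list(x) && all(c("lat", "lon") %in% names(x))) {
    return(geo_position(x$lat, x$lon))
  }
  stop("cannot interpret input as a geographic position")
}

# Mean Earth radius used throughout (km); IUGG mean radius.
EARTH_RADIUS_KM <- 6371.0088
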