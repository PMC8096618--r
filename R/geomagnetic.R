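#' Geomagnetic reference-field model
#'
#' The package ships a plain-text table of Schmidt quasi-normalized Gauss
#' coefficients for the definitive main-field model at epoch 2005.0
#' (truncated at degree 10), with linear secular-variation rates for
#' degrees 1-3, valid over 2005.0-2010.0. Field synthesis follows the
#' standard spherical-harmonic expansion of the internal potential on a
#' spherical Earth (geocentric colatitude = 90 - latitude, radius 6371.2 km
#' reference sphere, evaluation at sea level).
#'
#' An `axial_dipole` mode is provided for testing: a geocentric dipole
#' aligned with the rotation axis, for which declination is identically
#' zero and `tan(inclination) = 2 tan(latitude)`.
#'
#' @param model `"spherical_harmonic"` or `"axial_dipole"`.
#' @param epoch decimal year; must lie in the vendored table's validity
#'   window `[2005, 2010)` for the spherical-harmonic model.
#' @return an object of class `field_model` holding the evaluated
#'   coefficients for `epoch`.
#' @examples
#' fm <- field_model("spherical_harmonic", epoch = 2005.67)
#' field_at(geo_position(61.35, -165.1333), model = fm)
#' @export
field_model <- function(model = c("spherical_harmonic", "axial_dipole"),
                        epoch = 2005.67) {
  model <- match.arg(model)
  stopifnot(is.numeric(epoch), length(epoch) == 1, is.finite(epoch))
  if (model == "spherical_harmonic") {
    tab <- .vn_coef_table()
    if (epoch < 2005 || epoch >= 2010) {
      stop("epoch ", epoch, " outside the vendored coefficient validity window [2005, 2010)")
    }
    dt <- epoch - 2005
    g <- tab$g + dt * tab$gdot
    h <- tab$h + dt * tab$hdot
    obj <- list(model = model, epoch = epoch,
                n = tab$n, m = tab$m, g = g, h = h,
                nmax = max(tab$n))
  } else {
    # magnitude of the axial term taken from the vendored g(1,0) at 2005.0
    tab <- .vn_coef_table()
    b0 <- abs(tab$g[tab$n == 1 & tab$m == 0])
    obj <- list(model = model, epoch = epoch, b0 = b0)
  }
  class(obj) <- "field_model"
  obj
}

# cached read of the vendored coefficient file
.vn_coef_env <- new.env(parent = emptyenv())
.vn_coef_table <- function() {
  if (is.null(.vn_coef_env$tab)) {
    path <- system.file("extdata", "dgrf2005.csv", package = "vectornav")
    if (path == "") path <- file.path("inst", "extdata", "dgrf2005.csv")
    .vn_coef_env$tab <- utils::read.csv(path, comment.char = "#")
  }
  .vn_coef_env$tab
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf("<field_model %s, epoch %.2f>\n", x$model, x$epoch))
  invisible(x)
}

# Schmidt quasi-normalized associated Legendre functions and their
# theta-derivatives up to degree nmax, at colatitude theta (radians).
# Returns list(P, dP): (nmax+1) x (nmax+1) matrices indexed [n+1, m+1].
.vn_schmidt_legendre <- function(theta, nmax) {
  ct <- cos(theta); st <- sin(theta)
  P <- matrix(0, nmax + 1, nmax + 1)
  dP <- matrix(0, nmax + 1, nmax + 1)
  P[1, 1] <- 1; dP[1, 1] <- 0
  if (nmax >= 1) {
    P[2, 1] <- ct;  dP[2, 1] <- -st
    P[2, 2] <- st;  dP[2, 2] <- ct
  }
  for (n in 2:nmax) {
    # sectoral term
    k <- sqrt((2 * n - 1) / (2 * n))
    P[n + 1, n + 1] <- k * st * P[n, n]
    dP[n + 1, n + 1] <- k * (st * dP[n, n] + ct * P[n, n])
    for (m in 0:(n - 1)) {
      a <- (2 * n - 1) / sqrt(n^2 - m^2)
      b <- sqrt((n - 1)^2 - m^2) / sqrt(n^2 - m^2)
      Pn2 <- if (n - 2 >= m) P[n - 1, m + 1] else 0
      dPn2 <- if (n - 2 >= m) dP[n - 1, m + 1] else 0
      P[n + 1, m + 1] <- a * ct * P[n, m + 1] - b * Pn2
      dP[n + 1, m + 1] <- a * (ct * dP[n, m + 1] - st * P[n, m + 1]) - b * dPn2
    }
  }
  list(P = P, dP = dP)
}

#' Magnetic field elements at a position
#'
#' Synthesizes the geomagnetic field vector and returns the elements used by
#' the magnetic compass mechanisms: declination (degrees East of geographic
#' north), inclination (degrees below horizontal, positive downward),
#' horizontal and total intensity (nT).
#'
#' @param position a [geo_position()] (or `c(lat, lon)`).
#' @param model a [field_model()].
#' @return a list of class `field_vector` with elements `declination`,
#'   `inclination`, `horizontal_intensity`, `total_intensity`, and the
#'   local geocentric components `x` (north), `y` (east), `z` (down) in nT.
#' @export
field_at <- function(position, model = field_model()) {
  p <- as_geo_position(position)
  stopifnot(inherits(model, "field_model"))
  if (model$model == "axial_dipole") {
    lam <- deg2rad(p$lat)
    x <- model$b0 * cos(lam)          # northward
    z <- 2 * model$b0 * sin(lam)      # downward
    y <- 0
  } else {
    a <- 6371.2          # reference radius of the expansion, km
    r <- 6371.2          # sea level on the model sphere
    theta <- deg2rad(90 - p$lat)
    # avoid the exact pole where the east component is indeterminate
    if (theta < 1e-9) theta <- 1e-9
    if (pi - theta < 1e-9) theta <- pi - 1e-9
    phi <- deg2rad(p$lon)
    nmax <- model$nmax
    leg <- .vn_schmidt_legendre(theta, nmax)
    br <- 0; bt <- 0; bp <- 0
    for (i in seq_along(model$n)) {
      n <- model$n[i]; m <- model$m[i]
      gc <- model$g[i]; hc <- model$h[i]
      ar <- (a / r)^(n + 2)
      cmp <- cos(m * phi); smp <- sin(m * phi)
      Pnm <- leg$P[n + 1, m + 1]; dPnm <- leg$dP[n + 1, m + 1]
      br <- br + (n + 1) * ar * (gc * cmp + hc * smp) * Pnm
      bt <- bt - ar * (gc * cmp + hc * smp) * dPnm
      bp <- bp + ar * m * (gc * smp - hc * cmp) * Pnm / sin(theta)
    }
    x <- -bt   # north
    y <- bp    # east
    z <- -br   # down
  }
  h <- sqrt(x^2 + y^2)
  structure(list(
    declination = rad2deg(atan2(y, x)),
    inclination = rad2deg(atan2(z, h)),
    horizontal_intensity = h,
    total_intensity = sqrt(h^2 + z^2),
    x = x, y = y, z = z
  ), class = "field_vector")
}

#' @export
print.field_vector <- function(x, ...) {
  cat(sprintf("<field_vector D %.2f deg, I %.2f deg, H %.0f nT, F %.0f nT>\n",
              x$declination, x$inclination, x$horizontal_intensity,
              x$total_intensity))
  invisible(x)
}

#' Heading of the local constant-inclination contour (isocline)
#'
#' Returns the geographic heading tangent to the isocline through `position`:
#' the direction perpendicular to the horizontal gradient of inclination,
#' computed by central finite differences (step 0.1 degrees, km-scaled local
#' East/North axes). The two tangent branches differ by exactly 180 degrees;
#' `branch` picks the one in the requested half-plane (nearest to 315 for
#' `"NW"`, nearest to 135 for `"SE"`).
#'
#' @param position a [geo_position()].
#' @param branch `"NW"` or `"SE"`.
#' @param model a [field_model()].
#' @param step finite-difference step in degrees.
#' @return geographic heading in degrees `[0, 360)`.
#' @examples
#' isocline_heading(geo_position(61.35, -165.1333), "NW")
#' @export
isocline_heading <- function(position, branch = c("NW", "SE"),
                             model = field_model(), step = 0.1) {
  branch <- match.arg(branch)
  p <- as_geo_position(position)
  incl <- function(lat, lon) field_at(geo_position(lat, lon), model)$inclination
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  dN <- (incl(p$lat + step, p$lon) - incl(p$lat - step, p$lon)) /
    (2 * step * km_per_deg)
  dE <- (incl(p$lat, p$lon + step) - incl(p$lat, p$lon - step)) /
    (2 * step * km_per_deg * cos(deg2rad(p$lat)))
  if (sqrt(dN^2 + dE^2) < 1e-9) {
    stop("inclination gradient vanishes here (magnetic pole neighborhood); isocline heading undefined")
  }
  grad_az <- norm360(rad2deg(atan2(dE, dN)))
  cand <- norm360(grad_az + c(90, -90))
  ref <- if (branch == "NW") 315 else 135
  cand[which.min(abs(ang_diff(cand, ref)))]
}
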