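#' Great-circle step (direct geodesic problem on the sphere)
#'
#' Destination of a step of `distance` km from `position` along geographic
#' `heading`, on a sphere of radius 6371.0088 km. Thin wrapper over
#' [geosphere::destPoint()].
#'
#' @param position a [geo_position()].
#' @param heading geographic heading, degrees clockwise from north.
#' @param distance step length, km (>= 0).
#' @return a [geo_position()].
#' @export
advance <- function(position, heading, distance) {
  p <- as_geo_position(position)
  stopifnot(distance >= 0)
  if (distance == 0) return(p)
  d <- geosphere::destPoint(c(p$lon, p$lat), heading, distance * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  geo_position(d[1, "lat"], d[1, "lon"])
}

#' Great-circle distance between two positions (km)
#' @param a,b [geo_position()]s.
#' @return distance in km.
#' @export
gc_distance <- function(a, b) {
  a <- as_geo_position(a); b <- as_geo_position(b)
  geosphere::distHaversine(c(a$lon, a$lat), c(b$lon, b$lat),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Great-circle initial bearing from a to b (degrees)
#' @param a,b [geo_position()]s.
#' @return initial bearing, degrees in `[0, 360)`.
#' @export
gc_bearing <- function(a, b) {
  a <- as_geo_position(a); b <- as_geo_position(b)
  norm360(geosphere::bearing(c(a$lon, a$lat), c(b$lon, b$lat)))
}

#' Rhumb-line (loxodrome) course between two positions
#'
#' The constant geographic course that leads from `origin` to `destination`
#' along the loxodrome taking the shorter longitude difference; closed form
#' via Mercator-projected latitudes ([geosphere::bearingRhumb()]).
#'
#' @param origin,destination [geo_position()]s; must differ and not be poles.
#' @return course in degrees `[0, 360)`.
#' @examples
#' # SW Alaska stopover site to southern Japan
#' rhumb_course(geo_position(61.35, -165.1333), geo_position(31, 130.5))
#' @export
rhumb_course <- function(origin, destination) {
  o <- as_geo_position(origin); d <- as_geo_position(destination)
  if (abs(o$lat) == 90 || abs(d$lat) == 90) stop("rhumb course undefined at the poles")
  if (isTRUE(all.equal(c(o$lat, o$lon), c(d$lat, d$lon)))) {
    stop("origin and destination coincide")
  }
  # closed form on the Mercator projection, taking the shorter longitude
  # difference (a migratory course, not the long way around)
  dpsi <- log(tan(pi / 4 + deg2rad(d$lat) / 2)) -
    log(tan(pi / 4 + deg2rad(o$lat) / 2))
  dlon <- deg2rad(ang_diff(d$lon, o$lon))
  norm360(rad2deg(atan2(dlon, dpsi)))
}

#' Route specification for a compass mechanism
#'
#' Bundles everything [simulate_route()] needs: the mechanism, departure
#' point and date, the initial geographic direction, and route/step lengths.
#' For the magnetoclinic mechanism the initial direction may be omitted, in
#' which case the route starts by following the isocline through the
#' departure point on the chosen `branch` until `switch_lon` is crossed (a
#' stand-in for the coastline), then locks the apparent inclination implied
#' by `onward_course` at the switch point.
#'
#' @param mechanism one of `"geographic_loxodrome"`, `"magnetic_loxodrome"`,
#'   `"sun_compass"`, `"magnetoclinic"`.
#' @param departure a [geo_position()].
#' @param departure_date a `Date` or `"YYYY-MM-DD"` string.
#' @param initial_direction geographic degrees `[0, 360)`; for
#'   `magnetoclinic` it may be `NULL` (isocline-determined start).
#' @param total_length,step_length route and step lengths, km.
#' @param branch `"NW"` or `"SE"` (magnetoclinic isocline phase).
#' @param switch_lon longitude at which the magnetoclinic route leaves the
#'   isocline (first crossing), or `NULL` for a single-phase route.
#' @param onward_course geographic course used to set the fixed apparent
#'   inclination at the switch point.
#' @return an object of class `route_spec`.
#' @export
route_spec <- function(mechanism = c("geographic_loxodrome", "magnetic_loxodrome",
                                     "sun_compass", "magnetoclinic"),
                       departure, departure_date = as.Date("2005-09-01"),
                       initial_direction = NULL,
                       total_length = 5000, step_length = 10,
                       branch = c("NW", "SE"), switch_lon = NULL,
                       onward_course = NULL) {
  mechanism <- match.arg(mechanism)
  branch <- match.arg(branch)
  stopifnot(total_length > 0, step_length > 0, step_length <= 100)
  if (is.null(initial_direction)) {
    if (mechanism != "magnetoclinic") {
      stop("initial_direction is required for mechanism ", mechanism)
    }
  } else {
    stopifnot(is.numeric(initial_direction), length(initial_direction) == 1)
    initial_direction <- norm360(initial_direction)
  }
  structure(list(mechanism = mechanism, departure = as_geo_position(departure),
                 departure_date = as.Date(departure_date),
                 initial_direction = initial_direction,
                 total_length = total_length, step_length = step_length,
                 branch = branch, switch_lon = switch_lon,
                 onward_course = onward_course),
            class = "route_spec")
}

#' Magnetoclinic heading from a locked apparent inclination
#'
#' Given the locked apparent inclination `gamma_p` (degrees) and the local
#' field, solves `cos(beta) = tan(gamma) / tan(gamma_p)` for the magnetic
#' course `beta` relative to the magnetic meridian, keeping the persistent
#' `side` (which side of the meridian), and returns the geographic heading
#' `declination + side * beta`.
#'
#' The avian inclination compass reads the dip of the field axis, not its
#' polarity, so the apparent inclination is a dip that carries the sign of
#' the local inclination, and the course offset `beta` lies in `[0, 90]`:
#' the projection of the field axis into the bird's vertical flight plane
#' stays forward of vertical. A solution therefore requires
#' `0 <= tan(gamma)/tan(gamma_p) <= 1`; outside that range (the local dip
#' steeper than the locked apparent dip, or inclination of opposite sign)
#' the mechanism fails and `NA` is returned.
#'
#' @param gamma_p apparent inclination locked at route start, degrees.
#' @param side `+1` or `-1`: which side of the magnetic meridian.
#' @param field a `field_vector` from [field_at()].
#' @return geographic heading in degrees, or `NA_real_` if no solution.
#' @export
magnetoclinic_heading <- function(gamma_p, side, field) {
  stopifnot(side %in% c(-1, 1))
  ratio <- tan(deg2rad(field$inclination)) / tan(deg2rad(gamma_p))
  if (ratio < 0 || ratio > 1) return(NA_real_)
  beta <- rad2deg(acos(ratio))
  norm360(field$declination + side * beta)
}

# apparent inclination for a course beta (deg) off the magnetic meridian
.vn_apparent_inclination <- function(gamma, beta) {
  rad2deg(atan(tan(deg2rad(gamma)) / cos(deg2rad(beta))))
}

#' Simulate a vector-navigation route
#'
#' Integrates a route of `total_length` km in `step_length` km great-circle
#' steps from the departure point, choosing the heading at each step by the
#' mechanism's rule:
#' \describe{
#'   \item{geographic_loxodrome}{heading is the initial direction, always.}
#'   \item{magnetic_loxodrome}{a constant magnetic course (set so the first
#'     step equals the initial direction) plus the local declination.}
#'   \item{sun_compass}{initial direction plus the difference between the sun
#'     azimuth at the current position and at the departure point, both
#'     evaluated at one fixed internal-clock instant: the UTC time of sunset
#'     at the departure point on the departure date (the bird keeps its
#'     internal clock set at the departure location).}
#'   \item{magnetoclinic}{the bird holds a constant apparent inclination
#'     (inclination projected into the vertical plane of its track). With an
#'     explicit `initial_direction`, the apparent inclination is locked from
#'     it at the departure point. Without one, the route first follows the
#'     isocline through the departure point (`branch`) until crossing
#'     `switch_lon`, then locks the apparent inclination implied by
#'     `onward_course` there. The route terminates early, flagged, where no
#'     course keeps the apparent inclination.}
#' }
#'
#' @param spec a [route_spec()].
#' @param model a [field_model()].
#' @return an object of class `route`: a list with `positions` (data frame
#'   of `lat`, `lon`), `headings`, per-step `diagnostics` (declination,
#'   inclination, apparent inclination where applicable), `terminated_early`
#'   and `termination_reason`, plus the `spec`.
#' @examples
#' fm <- field_model()
#' sp <- route_spec("geographic_loxodrome", geo_position(61.35, -165.1333),
#'                  initial_direction = 113, total_length = 500)
#' r <- simulate_route(sp, fm)
#' tail(r$positions, 1)
#' @export
simulate_route <- function(spec, model = field_model()) {
  stopifnot(inherits(spec, "route_spec"))
  n_steps <- ceiling(spec$total_length / spec$step_length)
  pos <- spec$departure
  lat <- numeric(n_steps + 1); lon <- numeric(n_steps + 1)
  lat[1] <- pos$lat; lon[1] <- pos$lon
  headings <- rep(NA_real_, n_steps)
  decl <- rep(NA_real_, n_steps); incl <- rep(NA_real_, n_steps)
  gamma_app <- rep(NA_real_, n_steps)
  terminated <- FALSE; reason <- NA_character_

  mech <- spec$mechanism
  # mechanism state
  magnetic_course <- NULL
  clock_instant <- NULL; dep_sun_az <- NULL
  mc <- list(phase = if (is.null(spec$initial_direction)) "isocline" else "locked",
             gamma_p = NA_real_, side = NA_real_)

  if (mech == "sun_compass") {
    clock_instant <- sunset_instant(spec$departure, spec$departure_date)
    dep_sun_az <- sun_position(spec$departure, clock_instant)$azimuth
  }

  # lock the apparent dip implied by a geographic course: gamma_p carries the
  # sign of the local inclination (dip magnitude in the flight plane), and the
  # bird keeps flying on the same side of the magnetic meridian
  lock_gamma <- function(course, at) {
    fv <- field_at(at, model)
    beta <- ang_diff(course, fv$declination)
    if (abs(abs(beta) - 90) < 1e-9) stop("course perpendicular to the magnetic meridian: apparent inclination undefined")
    gp <- rad2deg(atan(tan(deg2rad(fv$inclination)) / abs(cos(deg2rad(beta)))))
    list(gamma_p = gp, side = if (beta >= 0) 1 else -1)
  }
  if (mech == "magnetoclinic" && mc$phase == "locked") {
    st <- lock_gamma(spec$initial_direction, spec$departure)
    mc$gamma_p <- st$gamma_p; mc$side <- st$side
  }

  for (k in seq_len(n_steps)) {
    fv <- NULL
    if (mech == "geographic_loxodrome") {
      hd <- spec$initial_direction
    } else if (mech == "magnetic_loxodrome") {
      fv <- field_at(pos, model)
      if (is.null(magnetic_course)) {
        magnetic_course <- spec$initial_direction - fv$declination
      }
      hd <- norm360(magnetic_course + fv$declination)
    } else if (mech == "sun_compass") {
      az_here <- sun_position(pos, clock_instant)$azimuth
      hd <- norm360(spec$initial_direction + ang_diff(az_here, dep_sun_az))
    } else { # magnetoclinic
      fv <- field_at(pos, model)
      if (mc$phase == "isocline") {
        hd <- isocline_heading(pos, spec$branch, model)
        if (!is.null(spec$switch_lon)) {
          crossed <- ang_diff(pos$lon, spec$switch_lon)
          prev_cross <- if (k == 1) crossed else
            ang_diff(lon[k - 1], spec$switch_lon)
          if (k > 1 && sign(crossed) != sign(prev_cross)) {
            if (is.null(spec$onward_course)) {
              stop("onward_course required at the isocline switch point")
            }
            st <- lock_gamma(spec$onward_course, pos)
            mc$gamma_p <- st$gamma_p; mc$side <- st$side
            mc$phase <- "locked"
            hd <- magnetoclinic_heading(mc$gamma_p, mc$side, fv)
          }
        }
      } else {
        hd <- magnetoclinic_heading(mc$gamma_p, mc$side, fv)
      }
      if (is.na(hd)) {
        terminated <- TRUE
        reason <- "no course keeps the locked apparent inclination (|tan(gamma)/tan(gamma_p)| > 1)"
        break
      }
      if (mc$phase == "locked") {
        gamma_app[k] <- .vn_apparent_inclination(
          fv$inclination, ang_diff(hd, fv$declination))
      }
    }
    headings[k] <- norm360(hd)
    if (!is.null(fv)) { decl[k] <- fv$declination; incl[k] <- fv$inclination }
    pos <- advance(pos, headings[k], spec$step_length)
    lat[k + 1] <- pos$lat; lon[k + 1] <- pos$lon
  }

  used <- if (terminated) seq_len(which(is.na(headings))[1] - 1) else seq_len(n_steps)
  npos <- length(used) + 1
  structure(list(
    positions = data.frame(lat = lat[seq_len(npos)], lon = lon[seq_len(npos)]),
    headings = headings[used],
    diagnostics = data.frame(declination = decl[used], inclination = incl[used],
                             apparent_inclination = gamma_app[used]),
    terminated_early = terminated,
    termination_reason = reason,
    spec = spec
  ), class = "route")
}

#' @export
print.route <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<route %s, %d steps%s, ends (%.2f, %.2f)>\n",
              x$spec$mechanism, n - 1,
              if (x$terminated_early) " [terminated early]" else "",
              x$positions$lat[n], x$positions$lon[n]))
  invisible(x)
}

#' Terminal position of a route
#' @param route a `route`.
#' @return a [geo_position()].
#' @export
route_terminus <- function(route) {
  n <- nrow(route$positions)
  geo_position(route$positions$lat[n], route$positions$lon[n])
}

# terminal distance (km) to goal of a route simulated with given initial dir
.vn_terminal_distance <- function(direction, mechanism, departure,
                                  departure_date, goal, model,
                                  total_length, step_length) {
  sp <- route_spec(mechanism, departure, departure_date,
                   initial_direction = direction,
                   total_length = total_length, step_length = step_length)
  gc_distance(route_terminus(simulate_route(sp, model)), goal)
}

# closest approach (km) of the whole route polyline to the goal
.vn_goal_miss <- function(direction, mechanism, departure, departure_date,
                          goal, model, total_length, step_length) {
  sp <- route_spec(mechanism, departure, departure_date,
                   initial_direction = direction,
                   total_length = total_length, step_length = step_length)
  r <- simulate_route(sp, model)
  g <- as_geo_position(goal)
  min(geosphere::distHaversine(cbind(r$positions$lon, r$positions$lat),
                               c(g$lon, g$lat),
                               r = EARTH_RADIUS_KM * 1000)) / 1000
}

#' Solve the initial direction that best reaches a goal
#'
#' Scans initial geographic directions at 1-degree resolution, then refines
#' the best candidate by golden-section search to 0.1 degrees, minimizing
#' the great-circle distance from the route's terminal point to `goal`.
#' Deterministic; ties in the scan go to the lowest direction.
#'
#' @param mechanism mechanism name as in [route_spec()] (magnetoclinic
#'   routes take their departure direction from the isocline instead; see
#'   [isocline_heading()]).
#' @param departure a [geo_position()].
#' @param departure_date a `Date`.
#' @param goal a [geo_position()].
#' @param model a [field_model()].
#' @param total_length,step_length km.
#' @return the initial geographic direction, degrees (0.1-degree resolution).
#' @export
solve_initial_direction <- function(mechanism, departure, departure_date,
                                    goal, model = field_model(),
                                    total_length = 5000, step_length = 10) {
  goal <- as_geo_position(goal)
  # routes must be able to pass the goal for the closest-approach criterion
  # to be meaningful; extend 25% past the great-circle distance if needed
  L <- max(total_length, 1.25 * gc_distance(departure, goal))
  obj <- function(d, step) .vn_goal_miss(d, mechanism, departure,
                                         departure_date, goal, model,
                                         L, step)
  dirs <- 0:359
  dist <- vapply(dirs, obj, 0, step = 50)  # coarse scan
  best <- dirs[which.min(dist)]
  lo <- best - 2; hi <- best + 2
  # golden-section refinement on [best-1, best+1]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- obj(norm360(c1), step_length); f2 <- obj(norm360(c2), step_length)
  while (b - a > 0.05) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- obj(norm360(c1), step_length)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- obj(norm360(c2), step_length)
    }
  }
  sol <- norm360(round(((a + b) / 2) * 10) / 10)
  if (obj(sol, step_length) > total_length / 2) {
    stop(sprintf(paste0("no initial direction brings the terminal point within ",
                        "%.0f km of the goal; best candidate %.1f deg at %.0f km"),
                 total_length / 2, sol, obj(sol)))
  }
  sol
}

#' Shared initial direction minimizing mean terminal distance
#'
#' Scans a 1-degree grid of shared initial geographic directions; for each,
#' simulates all four mechanisms with that direction (the magnetoclinic
#' route locks its apparent inclination from the shared direction and the
#' departure-point field) and returns the direction minimizing the mean
#' terminal great-circle distance to `goal`. Ties go to the lowest
#' direction.
#'
#' @inheritParams solve_initial_direction
#' @return direction in degrees (1-degree grid).
#' @export
shared_direction_min_mean_distance <- function(departure, departure_date, goal,
                                               model = field_model(),
                                               total_length = 5000,
                                               step_length = 10) {
  goal <- as_geo_position(goal)
  mechs <- c("geographic_loxodrome", "magnetic_loxodrome", "sun_compass",
             "magnetoclinic")
  mean_dist <- function(d) {
    mean(vapply(mechs, function(m)
      .vn_terminal_distance(d, m, departure, departure_date, goal, model,
                            total_length, step_length), 0))
  }
  dirs <- 0:359
  md <- vapply(dirs, mean_dist, 0)
  dirs[which.min(md)]
}
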