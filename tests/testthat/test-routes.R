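site <- geo_position(61.35, -165.1333)
japan <- geo_position(31, 130.5)
pnw <- geo_position(45, -124)

test_that("great-circle step matches the closed-form direct problem", {
  p <- geo_position(10, 0)
  expect_equal(advance(p, 123, 0), p)
  q <- advance(p, 180, 111.195)
  expect_lt(abs(q$lat - 9), 0.001)
  expect_lt(abs(q$lon - 0), 0.001)
  set.seed(303)
  for (i in 1:20) {
    lat <- runif(1, -80, 80); lon <- runif(1, -180, 180)
    brg <- runif(1, 0, 360); d <- runif(1, 1, 2000)
    got <- advance(geo_position(lat, lon), brg, d)
    want <- oracle_destination(lat, lon, brg, d)
    sep <- oracle_gc_dist(got$lat, got$lon, want["lat"], want["lon"])
    expect_lt(sep, 0.001) # 1 m
  }
})

test_that("rhumb course reproduces the two study departure courses and edge cases", {
  expect_equal(round(rhumb_course(site, japan)), 235)
  expect_equal(round(rhumb_course(site, pnw)), 124)
  expect_equal(rhumb_course(geo_position(50, 20), geo_position(40, 20)), 180)
  expect_error(rhumb_course(geo_position(90, 0), geo_position(0, 0)), "pole")
  expect_error(rhumb_course(site, site), "coincide")
})

test_that("a geographic loxodrome crosses every meridian at the same angle", {
  r <- simulate_route(route_spec("geographic_loxodrome", site, "2005-09-01",
                                 initial_direction = 113),
                      field_model("axial_dipole"))
  expect_true(all(r$headings == 113))
  segs <- nrow(r$positions) - 1
  brgs <- sapply(seq_len(segs), function(i) {
    gc_bearing(geo_position(r$positions$lat[i], r$positions$lon[i]),
               geo_position(r$positions$lat[i + 1], r$positions$lon[i + 1]))
  })
  expect_lt(max(abs(ang_diff(brgs, 113))), 0.2)
})

test_that("route length and step spacing honour the spec", {
  r <- simulate_route(route_spec("geographic_loxodrome", site, "2005-09-01",
                                 initial_direction = 200, total_length = 500,
                                 step_length = 25), field_model("axial_dipole"))
  steps <- nrow(r$positions) - 1
  d <- sapply(seq_len(steps), function(i) {
    gc_distance(geo_position(r$positions$lat[i], r$positions$lon[i]),
                geo_position(r$positions$lat[i + 1], r$positions$lon[i + 1]))
  })
  expect_true(all(abs(d - 25) / 25 < 0.001))
  expect_equal(sum(d), 500, tolerance = 25 / 500)
})

test_that("magnetic and geographic loxodromes coincide in an axial dipole field", {
  dm <- field_model("axial_dipole")
  r1 <- simulate_route(route_spec("geographic_loxodrome", site, "2005-09-01",
                                  initial_direction = 113), dm)
  r2 <- simulate_route(route_spec("magnetic_loxodrome", site, "2005-09-01",
                                  initial_direction = 113), dm)
  sep <- max(oracle_gc_dist(r1$positions$lat, r1$positions$lon,
                            r2$positions$lat, r2$positions$lon))
  expect_lt(sep, 1)
})

test_that("magnetoclinic heading solves the apparent-inclination equation", {
  fv <- field_at(geo_position(45, 10), field_model("axial_dipole"))
  # gamma' equal to local dip: flight along the magnetic meridian
  expect_equal(magnetoclinic_heading(fv$inclination, 1, fv), fv$declination)
  # locked apparent dip shallower than the local dip: no solution
  expect_true(is.na(magnetoclinic_heading(fv$inclination - 5, 1, fv)))
  # beta from the equation, on the requested side
  gp <- fv$inclination + 10
  hd <- magnetoclinic_heading(gp, -1, fv)
  beta <- acos(tan(fv$inclination * pi / 180) / tan(gp * pi / 180)) * 180 / pi
  expect_equal(hd, (fv$declination - beta) %% 360)
})

test_that("apparent inclination is conserved along magnetoclinic routes", {
  fm <- field_model(epoch = 2005.67)
  for (dir0 in c(100, 113, 150)) {
    r <- simulate_route(route_spec("magnetoclinic", site, "2005-09-01",
                                   initial_direction = dir0,
                                   total_length = 3000), fm)
    ga <- r$diagnostics$apparent_inclination
    ga <- ga[!is.na(ga)]
    expect_gt(length(ga), 10)
    expect_lt(max(abs(ga - ga[1])), 0.05)
    # and |gamma'| >= |gamma| wherever the route ran
    expect_true(all(abs(ga) >= abs(r$diagnostics$inclination[!is.na(
      r$diagnostics$apparent_inclination)]) - 1e-9))
  }
})

test_that("magnetoclinic failure terminates the route with a flag, not an error", {
  # dipole field, lock the local dip while flying along the meridian, then
  # head north into steeper dip: no course can keep the apparent inclination
  dm <- field_model("axial_dipole")
  p <- geo_position(45, 0)
  gp <- field_at(p, dm)$inclination + 0.2
  sp <- route_spec("magnetoclinic", p, "2005-09-01", initial_direction = 2,
                   total_length = 2000, step_length = 10)
  r <- simulate_route(sp, dm)
  expect_true(r$terminated_early)
  expect_match(r$termination_reason, "apparent inclination")
  expect_lt(nrow(r$positions), 201)
})

test_that("two-phase magnetoclinic route follows the isocline then locks the dip", {
  fm <- field_model(epoch = 2005.67)
  sp <- route_spec("magnetoclinic", site, "2005-09-01",
                   initial_direction = NULL, branch = "NW",
                   switch_lon = 175, onward_course = 235,
                   total_length = 4000, step_length = 20)
  r <- simulate_route(sp, fm)
  # departure heading equals the isocline tangent
  expect_equal(r$headings[1], isocline_heading(site, "NW", fm))
  # the route crosses the switch longitude (over the antimeridian)
  expect_true(any(r$positions$lon > 0))
  # after the switch the locked apparent dip is conserved
  ga <- r$diagnostics$apparent_inclination
  ga <- ga[!is.na(ga)]
  expect_gt(length(ga), 5)
  expect_lt(max(abs(ga - ga[1])), 0.05)
  # and the dip was locked at the switch point, steeper than the local dip
  expect_gt(abs(ga[1]),
            abs(r$diagnostics$inclination[match(TRUE, !is.na(
              r$diagnostics$apparent_inclination))]) - 1e-9)
})

test_that("halving the integration step moves the terminal point by < 5 km", {
  fm <- field_model(epoch = 2005.67)
  for (mech in c("magnetic_loxodrome", "sun_compass")) {
    t10 <- route_terminus(simulate_route(route_spec(
      mech, site, "2005-09-01", initial_direction = 113, step_length = 10), fm))
    t5 <- route_terminus(simulate_route(route_spec(
      mech, site, "2005-09-01", initial_direction = 113, step_length = 5), fm))
    expect_lt(gc_distance(t10, t5), 5)
  }
})

test_that("the solved sun-compass route approximates the orthodrome", {
  fm <- field_model(epoch = 2005.67)
  gcd <- gc_distance(site, japan)
  dir <- solve_initial_direction("sun_compass", site, as.Date("2005-09-01"),
                                 japan, fm)
  r <- simulate_route(route_spec("sun_compass", site, "2005-09-01",
                                 initial_direction = dir,
                                 total_length = 1.1 * gcd), fm)
  miss <- sapply(seq_len(nrow(r$positions)), function(i) {
    oracle_gc_dist(r$positions$lat[i], r$positions$lon[i], japan$lat, japan$lon)
  })
  k <- which.min(miss)
  expect_lt(miss[k], 100)                     # passes essentially through goal
  path_len <- (k - 1) * r$spec$step_length
  expect_lt(abs(path_len - gcd) / gcd, 0.03)  # within 3% of great-circle length
  # departing at the raw great-circle bearing still passes within 5%
  r2 <- simulate_route(route_spec("sun_compass", site, "2005-09-01",
                                  initial_direction = gc_bearing(site, japan),
                                  total_length = 1.1 * gcd), fm)
  miss2 <- min(sapply(seq_len(nrow(r2$positions)), function(i) {
    oracle_gc_dist(r2$positions$lat[i], r2$positions$lon[i], japan$lat, japan$lon)
  }))
  expect_lt(miss2 / gcd, 0.05)
})

test_that("direction solver reduces to the closed-form rhumb course for the geographic loxodrome", {
  fm <- field_model(epoch = 2005.67)
  solved <- solve_initial_direction("geographic_loxodrome", site,
                                    as.Date("2005-09-01"), japan, fm)
  expect_lt(abs(ang_diff(solved, rhumb_course(site, japan))), 0.5)
})

test_that("shared-direction scan is deterministic and recovers a rhumb goal", {
  fm <- field_model(epoch = 2005.67)
  # degenerate goal at the departure point: the scan is deterministic
  d0 <- shared_direction_min_mean_distance(site, as.Date("2005-09-01"), site,
                                           fm, total_length = 300,
                                           step_length = 50)
  d0b <- shared_direction_min_mean_distance(site, as.Date("2005-09-01"), site,
                                            fm, total_length = 300,
                                            step_length = 50)
  expect_identical(d0, d0b)
  # goal placed on the 235-degree rhumb at 1500 km
  g <- route_terminus(simulate_route(route_spec(
    "geographic_loxodrome", site, "2005-09-01", initial_direction = 235,
    total_length = 1500, step_length = 50), fm))
  d1 <- shared_direction_min_mean_distance(site, as.Date("2005-09-01"), g,
                                           fm, total_length = 1800,
                                           step_length = 50)
  expect_lt(abs(ang_diff(d1, 235)), 15)
})
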