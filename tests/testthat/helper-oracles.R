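# Independent oracle implementations used to cross-check the package.
# Each is written from a different published formulation (or brute force)
# than the code path it checks.

DEG <- pi / 180

# --- spherical direct geodesic problem (closed form) -------------------------
oracle_destination <- function(lat, lon, bearing, dist_km, R = 6371.0088) {
  d <- dist_km / R
  phi1 <- lat * DEG; th <- bearing * DEG
  phi2 <- asin(sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(th))
  dlon <- atan2(sin(th) * sin(d) * cos(phi1),
                cos(d) - sin(phi1) * sin(phi2))
  c(lat = phi2 / DEG, lon = ((lon + dlon / DEG + 180) %% 360) - 180)
}

oracle_gc_dist <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  a <- sin((lat2 - lat1) * DEG / 2)^2 +
    cos(lat1 * DEG) * cos(lat2 * DEG) * sin((lon2 - lon1) * DEG / 2)^2
  2 * R * asin(sqrt(pmin(a, 1)))
}

# --- PSA solar position algorithm (Blanco-Muriel et al.) ---------------------
oracle_sun <- function(lat, lon, time_utc) {
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  ejd <- jd - 2451545.0
  omega <- 2.1429 - 0.0010394594 * ejd
  mlon <- 4.8950630 + 0.017202791698 * ejd
  manom <- 6.2400600 + 0.0172019699 * ejd
  elon <- mlon + 0.03341607 * sin(manom) + 0.00034894 * sin(2 * manom) -
    0.0001134 - 0.0000203 * sin(omega)
  eobl <- 0.4090928 - 6.2140e-9 * ejd + 0.0000396 * cos(omega)
  ra <- atan2(cos(eobl) * sin(elon), cos(elon))
  if (ra < 0) ra <- ra + 2 * pi
  dec <- asin(sin(eobl) * sin(elon))
  hours <- (as.numeric(time_utc) %% 86400) / 3600
  gmst <- 6.6974243242 + 0.0657098283 * ejd + hours
  lmst <- (gmst * 15 + lon) * DEG
  ha <- lmst - ra
  latr <- lat * DEG
  zen <- acos(cos(latr) * cos(ha) * cos(dec) + sin(dec) * sin(latr))
  az <- atan2(-sin(ha), tan(dec) * cos(latr) - sin(latr) * cos(ha))
  if (az < 0) az <- az + 2 * pi
  # parallax correction (earth radius / AU)
  zen <- zen + 6371.01 / 149597890 * sin(zen)
  c(azimuth = az / DEG, elevation = 90 - zen / DEG)
}

# --- spherical-harmonic field synthesis via pracma Legendre ------------------
# Schmidt quasi-normalization applied to pracma::legendre (which carries the
# Condon-Shortley phase); theta-derivative by central differences.
oracle_field <- function(lat, lon, model) {
  nmax <- model$nmax
  theta <- (90 - lat) * DEG; phi <- lon * DEG
  schmidt_P <- function(th) {
    x <- cos(th)
    out <- matrix(0, nmax + 1, nmax + 1)
    out[1, 1] <- 1
    for (n in 1:nmax) {
      L <- pracma::legendre(n, x)
      for (m in 0:n) {
        norm <- sqrt((if (m == 0) 1 else 2) *
                       factorial(n - m) / factorial(n + m))
        out[n + 1, m + 1] <- (-1)^m * norm * L[m + 1, 1]
      }
    }
    out
  }
  h <- 1e-6
  P <- schmidt_P(theta)
  dP <- (schmidt_P(theta + h) - schmidt_P(theta - h)) / (2 * h)
  br <- bt <- bp <- 0
  for (i in seq_along(model$n)) {
    n <- model$n[i]; m <- model$m[i]
    cmp <- cos(m * phi); smp <- sin(m * phi)
    br <- br + (n + 1) * (model$g[i] * cmp + model$h[i] * smp) * P[n + 1, m + 1]
    bt <- bt - (model$g[i] * cmp + model$h[i] * smp) * dP[n + 1, m + 1]
    bp <- bp + m * (model$g[i] * smp - model$h[i] * cmp) * P[n + 1, m + 1] /
      sin(theta)
  }
  X <- -bt; Y <- bp; Z <- -br
  c(declination = atan2(Y, X) / DEG,
    inclination = atan2(Z, sqrt(X^2 + Y^2)) / DEG)
}

# --- von Mises A(kappa) by direct Bessel series ------------------------------
oracle_A <- function(kappa, terms = 60) {
  k2 <- (kappa / 2)
  i0 <- sum(sapply(0:terms, function(j) k2^(2 * j) / factorial(j)^2))
  i1 <- sum(sapply(0:terms, function(j) k2^(2 * j + 1) /
                     (factorial(j) * factorial(j + 1))))
  i1 / i0
}

# --- Pearson chi-square by hand ----------------------------------------------
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_)^2 / exp_)
}

# crafted cage-record rows for pipeline tests
make_records <- function(n, bearing, age = "juvenile",
                         capture_window = "early", sky = "clear",
                         bird_prefix = "B", fat_score = 3,
                         activity = 3, concentration = 3,
                         date = "2005-08-15", sun_azimuth = 295) {
  data.frame(
    bird_id = sprintf("%s%03d", bird_prefix, seq_len(n)),
    age = age, capture_window = capture_window, sky = sky,
    fat_score = fat_score, bearing = bearing,
    activity_score = activity, concentration_score = concentration,
    date = date, sun_azimuth = sun_azimuth, stringsAsFactors = FALSE
  )
}
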