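#' Group specification for synthetic cage records
#'
#' @param label group label (used in bird ids).
#' @param n number of active, includable records (the analysis-sample size).
#' @param mu mean direction, degrees.
#' @param r_target target mean vector length; bearings are drawn von Mises
#'   with `kappa = vonmises_kappa(r_target)`.
#' @param age `"adult"` or `"juvenile"`.
#' @param capture_window `"early"` (8-11 Aug) or `"late"` (4-9 Sep).
#' @param sky `"clear"` or `"overcast"` (split between natural and simulated
#'   overcast).
#' @param fat_scores pool of fat scores sampled uniformly per bird.
#' @param inactive_fraction fraction of all tests that are inactive
#'   (activity score 0); the generator adds an extra pool of inactive
#'   records on top of the `n` active ones.
#' @return object of class `group_spec`.
#' @export
group_spec <- function(label, n, mu, r_target, age, capture_window, sky,
                       fat_scores = 0:6, inactive_fraction = 0.2) {
  stopifnot(n >= 1, r_target >= 0, r_target < 1,
            inactive_fraction >= 0, inactive_fraction < 1,
            age %in% c("adult", "juvenile"),
            capture_window %in% c("early", "late"),
            sky %in% c("clear", "overcast"))
  structure(list(label = label, n = n, mu = norm360(mu), r_target = r_target,
                 age = age, capture_window = capture_window, sky = sky,
                 fat_scores = fat_scores,
                 inactive_fraction = inactive_fraction),
            class = "group_spec")
}

# (activity, concentration) score pairs that pass the inclusion rule
.vn_ok_scores <- {
  g <- expand.grid(a = 1:4, c = 1:4)
  g[g$a + g$c >= 3, ]
}

# session dates: tests start once birds reach the station, through the season
.vn_window_dates <- function(capture_window) {
  if (capture_window == "early") {
    seq(as.Date("2005-08-11"), as.Date("2005-08-25"), by = "day")
  } else {
    seq(as.Date("2005-09-04"), as.Date("2005-09-19"), by = "day")
  }
}

# cached sunset instants per date at the study site
.vn_sunset_env <- new.env(parent = emptyenv())
.vn_site_sunset <- function(date) {
  key <- as.character(date)
  if (is.null(.vn_sunset_env[[key]])) {
    .vn_sunset_env[[key]] <- sunset_instant(geo_position(61.35, -165.1333), date)
  }
  .vn_sunset_env[[key]]
}

#' Generate synthetic cage records for one group
#'
#' Draws `n` bearings from a von Mises distribution with the group's mean
#' direction and `kappa = vonmises_kappa(r_target)`, rounds them to the
#' nearest 5 degrees (the visual reading granularity of funnel papers),
#' attaches activity/concentration scores that pass the inclusion rule, and
#' adds an `inactive_fraction` pool of inactive tests (activity score 0).
#' Session dates fall in the group's capture window; each session starts
#' within 1.5 h before local sunset at the study site and the sun azimuth
#' at mid-session comes from the package ephemeris. Fully reproducible from
#' `seed`.
#'
#' @param spec a [group_spec()].
#' @param seed integer seed.
#' @return cage-record data frame (see [read_cage_records()]).
#' @export
generate_group <- function(spec, seed) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(seed)
  n_act <- spec$n
  n_inact <- round(n_act * spec$inactive_fraction / (1 - spec$inactive_fraction))
  n_tot <- n_act + n_inact
  kappa <- vonmises_kappa(spec$r_target)
  bearing <- norm360(round(rvonmises(n_tot, spec$mu, kappa) / 5) * 5)
  sc_idx <- sample.int(nrow(.vn_ok_scores), n_act, replace = TRUE)
  activity <- c(.vn_ok_scores$a[sc_idx], rep(0L, n_inact))
  conc <- c(.vn_ok_scores$c[sc_idx], sample(0:1, n_inact, replace = TRUE))
  dates <- sample(.vn_window_dates(spec$capture_window), n_tot, replace = TRUE)
  # sessions start 0.5-1.5 h before sunset so that mid-session sun elevations
  # stay inside the band the experiments were run at (about -2 to +8 deg)
  start_before_sunset <- stats::runif(n_tot, 0.5, 1.5) * 3600
  sun_az <- vapply(seq_len(n_tot), function(i) {
    mid <- .vn_site_sunset(dates[i]) - start_before_sunset[i] + 1800
    sun_position(geo_position(61.35, -165.1333), mid)$azimuth
  }, 0)
  sky <- if (spec$sky == "clear") rep("clear", n_tot) else
    sample(c("overcast_natural", "overcast_simulated"), n_tot,
           replace = TRUE, prob = c(0.3, 0.7))
  data.frame(
    bird_id = sprintf("%s_%02d", spec$label, seq_len(n_tot)),
    age = spec$age,
    capture_window = spec$capture_window,
    sky = sky,
    fat_score = sample(spec$fat_scores, n_tot, replace = TRUE),
    bearing = bearing,
    activity_score = activity,
    concentration_score = conc,
    date = as.character(dates),
    sun_azimuth = round(sun_az, 1),
    stringsAsFactors = FALSE
  )
}

#' Default study group specifications
#'
#' The five observed groups with their published sample sizes, mean
#' directions and mean vector lengths (the two pooled juvenile groups arise
#' from these in the analysis): adult clear (n=16, 114 deg, r=0.61), early
#' juvenile clear (n=22, 113, 0.47), late juvenile clear (n=21, 221, 0.37),
#' early juvenile overcast (n=23, 116, 0.40), late juvenile overcast
#' (n=22, 178, 0.42). Inactive fractions reflect the reported contrasts
#' (overcast tests far more often inactive than clear, early more than
#' late); fat-score pools are uniform over plausible ranges (late-season
#' birds carried little fat) and are synthetic placeholders, not published
#' distributions.
#'
#' @return named list of [group_spec()]s.
#' @export
study_group_specs <- function() {
  list(
    adult_clear = group_spec("AC", 16, 114, 0.61, "adult", "early", "clear",
                             fat_scores = 1:6, inactive_fraction = 0.45),
    early_juv_clear = group_spec("EJC", 22, 113, 0.47, "juvenile", "early",
                                 "clear", fat_scores = 1:6,
                                 inactive_fraction = 0.20),
    late_juv_clear = group_spec("LJC", 21, 221, 0.37, "juvenile", "late",
                                "clear", fat_scores = 0:2,
                                inactive_fraction = 0.14),
    early_juv_overcast = group_spec("EJO", 23, 116, 0.40, "juvenile", "early",
                                    "overcast", fat_scores = 1:6,
                                    inactive_fraction = 0.50),
    late_juv_overcast = group_spec("LJO", 22, 178, 0.42, "juvenile", "late",
                                   "overcast", fat_scores = 0:2,
                                   inactive_fraction = 0.38)
  )
}

#' Generate the full synthetic study dataset
#'
#' One dataset containing all study groups with their published parameters
#' (see [study_group_specs()]), ready for [run_analysis()].
#'
#' @param seed integer seed.
#' @param specs list of [group_spec()]s.
#' @return cage-record data frame.
#' @examples
#' d <- generate_study(1)
#' table(d$age, d$capture_window)
#' @export
generate_study <- function(seed, specs = study_group_specs()) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, length(specs))
  out <- do.call(rbind, lapply(seq_along(specs), function(i) {
    generate_group(specs[[i]], sub_seeds[i])
  }))
  rownames(out) <- NULL
  out
}
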