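#' Cage-record inclusion rule
#'
#' A funnel-cage experiment enters the analysis only if it produced a
#' readable scratch distribution: both the activity score (0: under 40
#' scratches ... 4: over 2000) and the concentration score (0: widest ...
#' 4: tightest) must be at least 1, and their sum at least 3.
#'
#' @param activity_score,concentration_score integer scores 0-4.
#' @return logical.
#' @examples
#' include_record(0, 4)  # inactive: excluded
#' include_record(1, 2)  # included
#' include_record(1, 1)  # sum below 3: excluded
#' @export
include_record <- function(activity_score, concentration_score) {
  stopifnot(all(activity_score %in% 0:4), all(concentration_score %in% 0:4))
  activity_score >= 1 & concentration_score >= 1 &
    (activity_score + concentration_score) >= 3
}

#' Fat class from a 9-grade visual fat score
#' @param fat_score integer 0-9.
#' @return `"fat"` (score >= 3) or `"lean"`.
#' @export
fat_class <- function(fat_score) {
  if (any(!fat_score %in% 0:9)) stop("fat score must be an integer in 0-9")
  ifelse(fat_score >= 3, "fat", "lean")
}

#' One record per bird per group
#'
#' Each individual is represented once in each diagram: within every group
#' cell, only the chronologically first included test of each bird is kept.
#'
#' @param records a cage-record data frame (see [read_cage_records()]);
#'   must contain `bird_id`, `group`, `date`.
#' @return the deduplicated data frame, original order of first occurrences.
#' @export
dedupe_per_group <- function(records) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$group, records$bird_id, as.Date(records$date))
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(r[, c("group", "bird_id")])
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical column set for cage-record CSVs
.vn_cage_cols <- c("bird_id", "age", "capture_window", "sky", "fat_score",
                   "bearing", "activity_score", "concentration_score",
                   "date", "sun_azimuth")

#' Read cage records from CSV
#'
#' Expects the documented header: `bird_id, age (adult|juvenile),
#' capture_window (early|late), sky (clear|overcast_natural|
#' overcast_simulated), fat_score (0-9), bearing (degrees, multiple of 5),
#' activity_score (0-4), concentration_score (0-4), date (YYYY-MM-DD),
#' sun_azimuth (degrees)`. Malformed rows raise an error naming the row.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_cage_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.vn_cage_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("cage CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  validate_cage_records(df)
}

#' Validate a cage-record data frame
#' @param df data frame with the columns of [read_cage_records()].
#' @return `df`, invisibly validated (errors name the offending row).
#' @export
validate_cage_records <- function(df) {
  chk <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) stop("row ", bad[1], ": ", what, call. = FALSE)
  }
  chk(df$age %in% c("adult", "juvenile"), "age must be adult|juvenile")
  chk(df$capture_window %in% c("early", "late"),
      "capture_window must be early|late")
  chk(df$sky %in% c("clear", "overcast_natural", "overcast_simulated"),
      "sky must be clear|overcast_natural|overcast_simulated")
  chk(!is.na(suppressWarnings(as.numeric(df$bearing))) &
        as.numeric(df$bearing) %% 5 == 0,
      "bearing must be a multiple of 5 degrees")
  chk(df$fat_score %in% 0:9, "fat_score must be in 0-9")
  chk(df$activity_score %in% 0:4, "activity_score must be in 0-4")
  chk(df$concentration_score %in% 0:4, "concentration_score must be in 0-4")
  chk(!is.na(as.Date(df$date, optional = TRUE)), "date must parse as YYYY-MM-DD")
  df$bearing <- norm360(as.numeric(df$bearing))
  df
}

# the seven analysis groups: label + predicate
.vn_group_defs <- list(
  adult_clear       = function(d) d$age == "adult" & d$sky == "clear",
  all_juv_clear     = function(d) d$age == "juvenile" & d$sky == "clear",
  all_juv_overcast  = function(d) d$age == "juvenile" & d$sky != "clear",
  early_juv_clear   = function(d) d$age == "juvenile" & d$sky == "clear" &
    d$capture_window == "early",
  late_juv_clear    = function(d) d$age == "juvenile" & d$sky == "clear" &
    d$capture_window == "late",
  early_juv_overcast = function(d) d$age == "juvenile" & d$sky != "clear" &
    d$capture_window == "early",
  late_juv_overcast = function(d) d$age == "juvenile" & d$sky != "clear" &
    d$capture_window == "late"
)

# comparisons reported in the study (group pairs)
.vn_comparison_pairs <- list(
  c("adult_clear", "early_juv_clear"),
  c("early_juv_clear", "early_juv_overcast"),
  c("late_juv_clear", "adult_clear"),
  c("late_juv_clear", "early_juv_clear"),
  c("late_juv_clear", "late_juv_overcast")
)

#' Run the orientation-cage analysis pipeline
#'
#' Applies the inclusion rule, assigns each included test to the analysis
#' groups (adult clear; all juveniles clear; all juveniles overcast; and
#' early/late juveniles under clear/overcast), keeps one record per bird
#' per group, and emits:
#' * per-group circular statistics (n, mean direction, mean vector length,
#'   Rayleigh p, 95% CI where significant, and whether the CI excludes the
#'   mean sun azimuth),
#' * pairwise comparisons between the study's group pairs, choosing
#'   Watson's U2 whenever either sample is not significantly directed
#'   (Rayleigh p >= 0.05) and Mardia's one-way classification F plus the
#'   concentration-homogeneity test otherwise,
#' * fat-versus-lean comparisons within each early-season category,
#' * activity chi-square tables (category x activity; sky x activity;
#'   period x activity; fat x activity), counting inactive tests
#'   (activity score 0) against active ones.
#'
#' The pipeline is deterministic: the same input yields byte-identical
#' outputs.
#'
#' @param records cage-record data frame ([read_cage_records()] format).
#'   Per-individual bearing tables from a published supplement can be fed
#'   through this same interface to replicate reported statistics exactly.
#' @param min_n smallest group analysed (smaller groups are flagged and
#'   skipped in comparisons).
#' @return list of class `cage_analysis` with `groups`, `comparisons`,
#'   `fat_comparisons`, `activity_tests`, `included`, `excluded_n`.
#' @export
run_analysis <- function(records, min_n = 5) {
  records <- validate_cage_records(records)
  inc <- include_record(records$activity_score, records$concentration_score)
  included <- records[inc, , drop = FALSE]

  # long format: one row per (group, record)
  assemble <- function(df) {
    do.call(rbind, lapply(names(.vn_group_defs), function(g) {
      sel <- df[.vn_group_defs[[g]](df), , drop = FALSE]
      if (nrow(sel) == 0) return(NULL)
      sel$group <- g
      sel
    }))
  }
  long <- assemble(included)
  if (is.null(long) || nrow(long) == 0) stop("no records pass the inclusion rule")
  long <- dedupe_per_group(long)

  sun_az <- stats::median(records$sun_azimuth, na.rm = TRUE)

  groups <- do.call(rbind, lapply(names(.vn_group_defs), function(g) {
    sel <- long[long$group == g, , drop = FALSE]
    n <- nrow(sel)
    if (n == 0) {
      return(data.frame(group = g, n = 0, alpha = NA, r = NA, rayleigh_p = NA,
                        ci_delta = NA, excludes_sun = NA, analysed = FALSE))
    }
    mv <- mean_vector(sel$bearing)
    ray <- if (n >= 4) rayleigh_test(n, mv$r)$p_value else NA
    ci <- if (n >= 4) suppressWarnings(mean_ci95(sel$bearing)) else
      list(defined = FALSE, delta = NA)
    excl <- if (isTRUE(ci$defined)) !ci_contains(ci, sun_az) else NA
    data.frame(group = g, n = n, alpha = mv$alpha, r = mv$r, rayleigh_p = ray,
               ci_delta = if (isTRUE(ci$defined)) ci$delta else NA,
               excludes_sun = excl, analysed = n >= min_n)
  }))

  grp_bearings <- function(g) long$bearing[long$group == g]

  comparisons <- do.call(rbind, lapply(.vn_comparison_pairs, function(pr) {
    b1 <- grp_bearings(pr[1]); b2 <- grp_bearings(pr[2])
    if (length(b1) < min_n || length(b2) < min_n) {
      return(data.frame(group_a = pr[1], group_b = pr[2], test = "skipped",
                        statistic = NA, p = NA, conc_t = NA, conc_p = NA))
    }
    p1 <- rayleigh_test(length(b1), mean_vector(b1)$r)$p_value
    p2 <- rayleigh_test(length(b2), mean_vector(b2)$r)$p_value
    if (p1 >= 0.05 || p2 >= 0.05) {
      tw <- suppressWarnings(watson_u2(b1, b2))
      data.frame(group_a = pr[1], group_b = pr[2], test = "watson_u2",
                 statistic = unname(tw$statistic), p = tw$p_value,
                 conc_t = NA, conc_p = NA)
    } else {
      tf <- suppressWarnings(mardia_classification_f(b1, b2))
      tc <- suppressWarnings(concentration_homogeneity(b1, b2))
      data.frame(group_a = pr[1], group_b = pr[2], test = "mardia_f",
                 statistic = unname(tf$statistic), p = tf$p_value,
                 conc_t = unname(tc$statistic), conc_p = tc$p_value)
    }
  }))

  # fat vs lean within early-season categories
  fat_cats <- list(
    adult_clear = .vn_group_defs$adult_clear,
    early_juv_clear = .vn_group_defs$early_juv_clear,
    early_juv_overcast = .vn_group_defs$early_juv_overcast
  )
  fat_comparisons <- do.call(rbind, lapply(names(fat_cats), function(g) {
    sel <- long[long$group == g, , drop = FALSE]
    fb <- sel$bearing[fat_class(sel$fat_score) == "fat"]
    lb <- sel$bearing[fat_class(sel$fat_score) == "lean"]
    if (length(fb) < min_n || length(lb) < min_n) {
      return(data.frame(category = g, test = "skipped", statistic = NA, p = NA))
    }
    pf_ <- rayleigh_test(length(fb), mean_vector(fb)$r)$p_value
    pl <- rayleigh_test(length(lb), mean_vector(lb)$r)$p_value
    if (pf_ >= 0.05 || pl >= 0.05) {
      tw <- suppressWarnings(watson_u2(fb, lb))
      data.frame(category = g, test = "watson_u2",
                 statistic = unname(tw$statistic), p = tw$p_value)
    } else {
      tf <- suppressWarnings(mardia_classification_f(fb, lb))
      data.frame(category = g, test = "mardia_f",
                 statistic = unname(tf$statistic), p = tf$p_value)
    }
  }))

  # activity contingency tables on ALL records (inactivity = activity 0)
  act <- records$activity_score >= 1
  cat6 <- interaction(records$age, records$capture_window, records$sky != "clear",
                      drop = TRUE)
  activity_tests <- list()
  ok_table <- function(tb) {
    all(dim(tb) >= 2) && all(rowSums(tb) > 0) && all(colSums(tb) > 0)
  }
  tb <- table(cat6, factor(act, c(FALSE, TRUE), c("inactive", "active")))
  if (ok_table(tb)) activity_tests$category <- chisq_independence(tb)
  juv <- records$age == "juvenile"
  tb2 <- table(factor(records$sky[juv] != "clear", c(FALSE, TRUE),
                      c("clear", "overcast")),
               factor(act[juv], c(FALSE, TRUE), c("inactive", "active")))
  if (ok_table(tb2)) activity_tests$sky <- chisq_independence(tb2)
  tb3 <- table(records$capture_window,
               factor(act, c(FALSE, TRUE), c("inactive", "active")))
  if (ok_table(tb3)) activity_tests$period <- chisq_independence(tb3)
  tb4 <- table(fat_class(records$fat_score),
               factor(act, c(FALSE, TRUE), c("inactive", "active")))
  if (ok_table(tb4)) activity_tests$fat <- chisq_independence(tb4)

  structure(list(groups = groups, comparisons = comparisons,
                 fat_comparisons = fat_comparisons,
                 activity_tests = activity_tests,
                 included = long, excluded_n = sum(!inc),
                 sun_azimuth = sun_az),
            class = "cage_analysis")
}

#' @export
print.cage_analysis <- function(x, ...) {
  cat("Orientation-cage analysis\n")
  cat(sprintf("  %d tests excluded by the activity/concentration rule\n",
              x$excluded_n))
  cat(sprintf("  mean sun azimuth used for CI comparisons: %.0f deg\n",
              x$sun_azimuth))
  print(transform(x$groups, alpha = round(alpha, 1), r = round(r, 2),
                  rayleigh_p = signif(rayleigh_p, 2),
                  ci_delta = round(ci_delta, 1)), row.names = FALSE)
  invisible(x)
}
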