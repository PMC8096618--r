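#' Circular sample of orientation bearings
#'
#' @param bearings numeric vector of bearings in degrees; normalized to
#'   `[0, 360)`.
#' @param label optional free-text label.
#' @return object of class `circular_sample`.
#' @export
circular_sample <- function(bearings, label = "") {
  stopifnot(is.numeric(bearings), length(bearings) >= 1, all(is.finite(bearings)))
  structure(list(bearings = norm360(bearings), label = label,
                 n = length(bearings)), class = "circular_sample")
}

#' @export
print.circular_sample <- function(x, ...) {
  mv <- mean_vector(x)
  cat(sprintf("<circular_sample '%s': n=%d, alpha=%.1f, r=%.3f>\n",
              x$label, x$n, mv$alpha, mv$r))
  invisible(x)
}

as_circular_sample <- function(x, label = "") {
  if (inherits(x, "circular_sample")) x else circular_sample(x, label)
}

# resultant length R (not normalized) of a bearing vector in degrees
.vn_resultant <- function(bearings) {
  th <- deg2rad(bearings)
  sqrt(sum(cos(th))^2 + sum(sin(th))^2)
}

#' Mean vector of a circular sample
#'
#' Mean direction `alpha` and mean vector length `r` by vector addition of
#' unit bearing vectors.
#'
#' @param sample a [circular_sample()] or numeric bearings (degrees).
#' @return list with `alpha` (degrees, `[0, 360)`; `NA` and `undefined =
#'   TRUE` when `r = 0`), `r` in `[0, 1]`, and `n`.
#' @examples
#' mean_vector(c(0, 90))  # alpha 45, r = cos(45 deg)
#' @export
mean_vector <- function(sample) {
  s <- as_circular_sample(sample)
  th <- deg2rad(s$bearings)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  if (r < 1e-12) {
    return(list(alpha = NA_real_, r = 0, n = s$n, undefined = TRUE))
  }
  list(alpha = norm360(rad2deg(atan2(S, C))), r = r, n = s$n,
       undefined = FALSE)
}

#' Construct a test-result record
#' @param test_name character.
#' @param statistic named statistic value.
#' @param df degrees of freedom (length 1 or 2), or `NA`.
#' @param p_value p-value in `[0, 1]`.
#' @param note optional annotation.
#' @return object of class `circ_test`.
#' @keywords internal
circ_test_result <- function(test_name, statistic, df, p_value, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, note = note), class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else paste0(" df=", paste(x$df, collapse = ","))
  cat(sprintf("<%s: %s=%.4g%s, p=%.4g>%s\n", x$test_name,
              names(x$statistic)[1], x$statistic[1], dfs, x$p_value,
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n r^2`; the p-value uses the standard second-order series
#' approximation
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clipped to `[0, 1]`.
#'
#' @param n sample size (>= 4; smaller samples need exact tables).
#' @param r mean vector length in `[0, 1]`.
#' @return a `circ_test` with statistic `Z`.
#' @examples
#' rayleigh_test(16, 0.61)  # adult group: p < 0.002
#' @export
rayleigh_test <- function(n, r) {
  stopifnot(r >= 0, r <= 1)
  if (n < 4) stop("Rayleigh series approximation unreliable for n < 4; use exact tables")
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  circ_test_result("Rayleigh test", c(Z = Z), NA, p)
}

#' Rayleigh test from raw bearings
#' @param sample a [circular_sample()] or bearings in degrees.
#' @return a `circ_test`.
#' @export
rayleigh_test_sample <- function(sample) {
  s <- as_circular_sample(sample)
  mv <- mean_vector(s)
  rayleigh_test(s$n, mv$r)
}

#' 95% confidence interval for a mean direction
#'
#' Symmetric arc `alpha +/- delta` using the chi-square-based approximation
#' for the circular mean (with the separate high-concentration variant for
#' `r > 0.9`). Requires a Rayleigh-significant sample; flagged undefined
#' otherwise (and a warning is raised for `n < 8`).
#'
#' @param sample a [circular_sample()] or bearings in degrees.
#' @param conf confidence level (only 0.95 supported).
#' @return list with `alpha`, `delta`, `lower`, `upper` (degrees) and
#'   `defined`; `contains(direction)` convenience is provided by
#'   [ci_contains()].
#' @export
mean_ci95 <- function(sample, conf = 0.95) {
  stopifnot(conf == 0.95)
  s <- as_circular_sample(sample)
  mv <- mean_vector(s)
  n <- s$n; r <- mv$r; R <- n * r
  if (n < 8) warning("mean-direction CI approximation is unreliable for n < 8")
  if (mv$undefined || rayleigh_test(max(n, 4), r)$p_value >= 0.05) {
    return(list(alpha = mv$alpha, delta = NA_real_, lower = NA_real_,
                upper = NA_real_, defined = FALSE))
  }
  chi <- stats::qchisq(conf, df = 1)
  if (r <= 0.9) {
    arg <- sqrt((2 * n * (2 * R^2 - n * chi)) / (R^2 * (4 * n - chi)))
  } else {
    arg <- sqrt(n^2 - (n^2 - R^2) * exp(chi / n)) / R
  }
  if (!is.finite(arg) || arg > 1) {
    return(list(alpha = mv$alpha, delta = NA_real_, lower = NA_real_,
                upper = NA_real_, defined = FALSE))
  }
  delta <- rad2deg(acos(arg))
  list(alpha = mv$alpha, delta = delta,
       lower = norm360(mv$alpha - delta), upper = norm360(mv$alpha + delta),
       defined = TRUE)
}

#' Does a mean-direction CI contain a fixed direction?
#' @param ci result of [mean_ci95()].
#' @param direction degrees.
#' @return `TRUE`/`FALSE`, or `NA` if the CI is undefined.
#' @export
ci_contains <- function(ci, direction) {
  if (!isTRUE(ci$defined)) return(NA)
  abs(ang_diff(direction, ci$alpha)) <= ci$delta
}

#' Watson's two-sample U-squared test
#'
#' Nonparametric test of a common circular distribution, from the pooled
#' ordered bearings: with empirical CDFs `F_a`, `F_b` evaluated at each of
#' the `N` pooled observations and `d_k = F_a - F_b`,
#' `U^2 = (n_a n_b / N^2) * sum_k (d_k - mean(d))^2`. Ties (the 5-degree
#' granularity of cage bearings) are handled by evaluating at each tied
#' observation (midrank-equivalent). The p-value uses the asymptotic series
#' `P(U^2 > u) = 2 * sum_{m>=1} (-1)^(m-1) exp(-2 m^2 pi^2 u)` after a
#' finite-sample moment match: the permutation null of `U^2` is
#' distribution-free with mean `(N+1)/(12N)` and variance close to
#' `(N-3)/(360N)` (the limiting law has mean 1/12, variance 1/360), so the
#' statistic is linearly mapped onto the limiting moments before the series
#' is evaluated. An optional permutation p-value is reported alongside when
#' `n_perm > 0`.
#'
#' @param a,b [circular_sample()]s or bearing vectors (degrees); each n >= 8.
#' @param n_perm number of random permutations for an exact-style p (0 = off).
#' @param seed optional seed for the permutation p.
#' @return a `circ_test` with statistic `U2` (and `p_perm` in `note` if
#'   requested).
#' @export
watson_u2 <- function(a, b, n_perm = 0, seed = NULL) {
  a <- as_circular_sample(a); b <- as_circular_sample(b)
  if (a$n < 8 || b$n < 8) {
    warning("Watson U2 asymptotic p is coarse for n < 8")
  }
  u2 <- .vn_watson_stat(a$bearings, b$bearings)
  N <- a$n + b$n
  u_adj <- 1 / 12 + (u2 - (N + 1) / (12 * N)) * sqrt(N / (N - 3))
  p <- .vn_watson_p(u_adj)
  res <- circ_test_result("Watson U2 test", c(U2 = u2), NA, p)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    pooled <- c(a$bearings, b$bearings)
    na <- a$n
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      if (.vn_watson_stat(pooled[idx], pooled[-idx]) >= u2 - 1e-12) {
        cnt <- cnt + 1L
      }
    }
    res$p_perm <- cnt / n_perm
    res$note <- sprintf("p_perm=%.4f (%d permutations)", res$p_perm, n_perm)
  }
  res
}

.vn_watson_stat <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- sort(c(x, y))
  Fx <- stats::ecdf(x)(pooled)
  Fy <- stats::ecdf(y)(pooled)
  d <- Fx - Fy
  (nx * ny / N^2) * sum((d - mean(d))^2)
}

.vn_watson_p <- function(u2, tol = 1e-10) {
  if (u2 < 0.0145) return(1)  # series unstable; statistic below any critical value
  s <- 0
  for (m in 1:100) {
    term <- (-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u2)
    s <- s + term
    if (abs(term) < tol) break
  }
  min(max(2 * s, 0), 1)
}

#' Mardia's one-way classification test for two mean directions
#'
#' `F = (N - 2) * (R_a + R_b - R) / (N - R_a - R_b)` on `(1, N - 2)` degrees
#' of freedom, where `R_a`, `R_b` are the two resultant lengths and `R` the
#' pooled resultant. Assumes both samples are concentrated (a warning is
#' raised when either is not Rayleigh-significant at 5%).
#'
#' @param a,b [circular_sample()]s or bearing vectors (degrees).
#' @return a `circ_test` with statistic `F`.
#' @export
mardia_classification_f <- function(a, b) {
  a <- as_circular_sample(a); b <- as_circular_sample(b)
  Ra <- .vn_resultant(a$bearings); Rb <- .vn_resultant(b$bearings)
  R <- .vn_resultant(c(a$bearings, b$bearings))
  N <- a$n + b$n
  if (rayleigh_test_sample(a)$p_value >= 0.05 ||
      rayleigh_test_sample(b)$p_value >= 0.05) {
    warning("one or both samples not significantly directed; prefer Watson's U2")
  }
  denom <- N - Ra - Rb
  if (denom < 1e-9) stop("degenerate concentration (all bearings identical within sample)")
  Fstat <- max((N - 2) * (Ra + Rb - R) / denom, 0)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  circ_test_result("Mardia one-way classification test", c(F = Fstat),
                   c(1, N - 2), p)
}

#' Mardia's test for homogeneity of concentration parameters
#'
#' Two-sample test that the von Mises concentrations are equal, using the
#' regime-dependent variance-stabilizing transformations, selected by the
#' pooled mean resultant length `r_bar = (R_a + R_b) / N`:
#' \describe{
#'   \item{`r_bar < 0.45`}{`g1(x) = asin(x * sqrt(3/8))` applied to `2 * r_i`
#'     (asymptotic variance 3/4 per observation), standard error
#'     `sqrt(3/4) * sqrt(1/(n_a - 4) + 1/(n_b - 4))`.}
#'   \item{`0.45 <= r_bar <= 0.70`}{`g2(x) = asinh((x - 1.089449) / 0.258)`,
#'     standard error `0.893 * sqrt(1/(n_a - 3) + 1/(n_b - 3))`.}
#'   \item{`r_bar > 0.70`}{variance-ratio statistic
#'     `F = [(n_a - R_a)/(n_a - 1)] / [(n_b - R_b)/(n_b - 1)]` on
#'     `(n_a - 1, n_b - 1)` df, reported with a two-sided p.}
#' }
#' The first two regimes give a standard-normal (t-type) statistic with a
#' two-sided p.
#'
#' @param a,b [circular_sample()]s or bearing vectors (degrees); n >= 10 each.
#' @return a `circ_test` (statistic `t` or `F` depending on regime).
#' @export
concentration_homogeneity <- function(a, b) {
  a <- as_circular_sample(a); b <- as_circular_sample(b)
  na <- a$n; nb <- b$n
  if (na < 10 || nb < 10) warning("concentration-homogeneity approximations assume n >= 10")
  Ra <- .vn_resultant(a$bearings); Rb <- .vn_resultant(b$bearings)
  r1 <- Ra / na; r2 <- Rb / nb
  rbar <- (Ra + Rb) / (na + nb)
  N <- na + nb
  if (rbar < 0.45) {
    g <- function(x) asin(pmin(pmax(x * sqrt(3 / 8), -1), 1))
    tstat <- (g(2 * r1) - g(2 * r2)) /
      sqrt((3 / 4) * (1 / (na - 4) + 1 / (nb - 4)))
    p <- 2 * stats::pnorm(-abs(tstat))
    circ_test_result("Mardia concentration homogeneity test", c(t = tstat),
                     N - 2, p, note = "low-concentration regime")
  } else if (rbar <= 0.70) {
    g <- function(x) asinh((x - 1.089449) / 0.258)
    tstat <- (g(r1) - g(r2)) /
      (0.893 * sqrt(1 / (na - 3) + 1 / (nb - 3)))
    p <- 2 * stats::pnorm(-abs(tstat))
    circ_test_result("Mardia concentration homogeneity test", c(t = tstat),
                     N - 2, p, note = "mid-concentration regime")
  } else {
    Fstat <- ((na - Ra) / (na - 1)) / ((nb - Rb) / (nb - 1))
    pup <- stats::pf(Fstat, na - 1, nb - 1, lower.tail = FALSE)
    p <- min(2 * min(pup, 1 - pup), 1)
    circ_test_result("Mardia concentration homogeneity test", c(F = Fstat),
                     c(na - 1, nb - 1), p, note = "high-concentration regime")
  }
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on a counts matrix, without continuity
#' correction, df `(rows - 1)(cols - 1)`.
#'
#' @param table a counts matrix (or table).
#' @return a `circ_test` with statistic `X2`.
#' @export
chisq_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row/column: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected count <= 0")
  circ_test_result("Chi-square test", c(X2 = unname(ct$statistic)),
                   unname(ct$parameter), unname(ct$p.value))
}

#' von Mises concentration from mean resultant length (and back)
#'
#' `vonmises_A(kappa) = I1(kappa)/I0(kappa)` is the expected mean resultant
#' length of a von Mises sample with concentration `kappa`;
#' `vonmises_kappa(r)` inverts it by the standard piecewise approximation
#' refined with Newton iterations to `|A(kappa) - r| < 1e-8`.
#'
#' @param kappa concentration parameter (>= 0).
#' @return `vonmises_A`: mean resultant length in `[0, 1)`.
#' @export
vonmises_A <- function(kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(0)
  if (kappa > 500) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' @rdname vonmises_A
#' @param r mean resultant length, `0 <= r < 1`.
#' @return `vonmises_kappa`: the concentration `kappa` with `A(kappa) = r`.
#' @examples
#' vonmises_kappa(0.61)
#' @export
vonmises_kappa <- function(r) {
  stopifnot(r >= 0)
  if (r >= 1) stop("r must be < 1")
  if (r == 0) return(0)
  # piecewise starting value (Fisher 1993 approximation)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:50) {
    fa <- vonmises_A(k)
    # d A / d kappa = 1 - A^2 - A/kappa
    dk <- (fa - r) / (1 - fa^2 - fa / k)
    k <- max(k - dk, 1e-12)
    if (abs(vonmises_A(k) - r) < 1e-8) break
  }
  k
}

#' Draw von Mises bearings (degrees)
#'
#' Best-Fisher wrapped-Cauchy rejection sampler; reproducible through R's
#' RNG (use `set.seed`).
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0); `kappa = 0` gives uniform bearings.
#' @return bearings in degrees `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(norm360(stats::runif(n, 0, 360)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      c0 <- kappa * (rr - f)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- mu + rad2deg(sign(u3 - 0.5) * acos(f))
  }
  norm360(out)
}
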