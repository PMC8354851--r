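# Height velocity and growth milestones.
#
# Velocity at a given age is the difference of two time-ordered
# length/height values 6-18 months apart, divided by the age difference
# and plotted at the midpoint age. Pairing is greedy and non-overlapping:
# each measurement is paired with the earliest subsequent measurement
# 6-18 months later, and the search resumes from that endpoint.

#' Per-subject pairwise height velocities
#'
#' For each subject's time-ordered length/height measurements, forms greedy
#' non-overlapping pairs: starting from the earliest point, the partner is
#' the first later point at least `min_gap` months away; if that partner is
#' within `max_gap` months the pair yields a velocity estimate and the scan
#' resumes from the partner, otherwise the start advances by one point.
#' Velocity is `(delta value / delta age) * 12` (cm/year) placed at the
#' midpoint age `(age1 + age2) / 2`.
#'
#' @param points An `achondro_registry` (length/height points are taken via
#'   [curve_points()]) or a data frame with `subject_id`, `age_months`,
#'   `value`.
#' @param sex Optional sex filter (registry input).
#' @param min_gap,max_gap Eligible pair gap in months (default 6--18).
#' @return Data frame: `subject_id`, `midpoint_age` (months), `velocity`
#'   (cm/year), `interval_length` (months). Subjects with fewer than two
#'   points contribute nothing.
#' @export
pairwise_velocities <- function(points, sex = NULL, min_gap = 6,
                                max_gap = 18) {
  if (inherits(points, "achondro_registry")) {
    points <- curve_points(points, sex = sex, measure = "length_height")
  }
  abort_if(!all(c("subject_id", "age_months", "value") %in% names(points)),
           "points need subject_id, age_months, value columns")
  out <- list()
  for (g in split(points, points$subject_id)) {
    g <- g[order(g$age_months), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    i <- 1L
    while (i < n) {
      gap <- g$age_months[(i + 1L):n] - g$age_months[i]
      j <- which(gap >= min_gap)
      if (!length(j)) break
      j <- i + j[1L]
      dt <- g$age_months[j] - g$age_months[i]
      if (dt <= max_gap) {
        out[[length(out) + 1L]] <- data.frame(
          subject_id = g$subject_id[1L],
          midpoint_age = (g$age_months[i] + g$age_months[j]) / 2,
          velocity = (g$value[j] - g$value[i]) / dt * 12,
          interval_length = dt, stringsAsFactors = FALSE)
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), midpoint_age = numeric(),
                      velocity = numeric(), interval_length = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default grid for mean velocity curves
#'
#' Extends the percentile grid past 18 years (monthly to 36 months,
#' quarterly to 120, semiannual to 252) because the velocity zero falls
#' beyond the stature-curve range.
#'
#' @return Ages in months.
#' @export
velocity_grid <- function() {
  c(0:36, seq(39, 120, by = 3), seq(126, 252, by = 6))
}

#' Mean height-velocity curve
#'
#' Bins velocity estimates by midpoint age using the same windowing scheme
#' as the percentile curves (the last band's half-width is reused beyond
#' 216 months) and takes the arithmetic mean per bin; bins with fewer than
#' `min_n` estimates are suppressed.
#'
#' @param estimates Output of [pairwise_velocities()].
#' @param scheme An [age_window_scheme()].
#' @param grid Bin centres in months.
#' @param min_n Minimum estimates per bin.
#' @return Data frame of class `velocity_curve`: `age_months`,
#'   `mean_velocity` (cm/year, NA where suppressed), `n`.
#' @export
mean_velocity_curve <- function(estimates, scheme = age_window_scheme(),
                                grid = velocity_grid(), min_n = 10) {
  abort_if(nrow(estimates) == 0, "no velocity estimates")
  out <- data.frame(age_months = grid, mean_velocity = NA_real_, n = 0L)
  hw <- window_half_width(grid, scheme, extend = TRUE)
  for (i in seq_along(grid)) {
    lo <- max(0, grid[i] - hw[i]); hi <- grid[i] + hw[i]
    v <- estimates$velocity[estimates$midpoint_age >= lo &
                              estimates$midpoint_age <= hi]
    out$n[i] <- length(v)
    if (length(v) >= max(min_n, 1)) out$mean_velocity[i] <- mean(v)
  }
  class(out) <- c("velocity_curve", "data.frame")
  out
}

# first downward crossing of `threshold` after the maximum of (x, y),
# linear interpolation between support points; NA if never crossed
.first_downward_crossing <- function(x, y, threshold) {
  imax <- which.max(y)
  if (imax >= length(x)) return(NA_real_)
  for (i in (imax + 1L):length(x)) {
    if (y[i] < threshold && y[i - 1L] >= threshold) {
      return(x[i - 1L] + (y[i - 1L] - threshold) / (y[i - 1L] - y[i]) *
               (x[i] - x[i - 1L]))
    }
  }
  NA_real_
}

#' Age at which the velocity curve falls to a threshold
#'
#' Reads off the first age beyond the curve's maximum at which the
#' (optionally spline-smoothed) mean velocity crosses the threshold from
#' above, with linear interpolation between evaluation points. Smoothing
#' (penalized spline with bin counts as weights, evaluated on a 0.1-month
#' grid) is recommended for binned empirical curves; disable it to read a
#' parametric curve exactly.
#'
#' For thresholds near zero, `method = "interpolate"` is biased late: a
#' measurement pair straddling the growth plateau maps its positive average
#' velocity onto a midpoint past the plateau, so binned means stay slightly
#' positive (and may never cross zero) for up to half the maximum pair gap
#' beyond it. Because the midpoint rule is exact for a linearly declining
#' velocity, `method = "tail_fit"` instead fits a weighted line to the
#' binned means over the terminal decline (smoothed curve between
#' `threshold + 0.5` and `threshold + 3` cm/year, past the maximum) and
#' extrapolates it to the threshold -- the recommended reader for the
#' velocity-zero milestone.
#'
#' @param vc A `velocity_curve`.
#' @param threshold Velocity in cm/year (e.g. 1 or 0).
#' @param smooth Smooth the binned means before reading (default `TRUE`).
#' @param step Evaluation step in months when smoothing.
#' @param method `"interpolate"` (first downward crossing) or `"tail_fit"`
#'   (linear extrapolation of the terminal decline).
#' @return Age in years, or `NA` if the curve never crosses the threshold
#'   within its grid (or, for `"tail_fit"`, if fewer than 4 bins span the
#'   decline window).
#' @export
velocity_threshold_age <- function(vc, threshold, smooth = TRUE,
                                   step = 0.1,
                                   method = c("interpolate", "tail_fit")) {
  abort_if(!is.finite(threshold), "threshold must be finite")
  method <- match.arg(method)
  est <- !is.na(vc$mean_velocity)
  abort_if(sum(est) < 2, "velocity curve has fewer than 2 estimable bins")
  x <- vc$age_months[est]
  y <- vc$mean_velocity[est]
  w <- vc$n[est]
  if (method == "tail_fit") {
    abort_if(sum(est) < 10, "tail_fit needs at least 10 estimable bins")
    fit <- smooth.spline(x, y, w = w, cv = FALSE)
    ys <- predict(fit, x)$y
    imax <- which.max(ys)
    sel <- seq_along(x) > imax & ys >= threshold + 0.5 & ys <= threshold + 3
    if (sum(sel) < 4) return(NA_real_)
    cf <- coef(stats::lm(y ~ x, weights = w, subset = sel))
    if (cf[[2]] >= 0) return(NA_real_)
    return(((threshold - cf[[1]]) / cf[[2]]) / 12)
  }
  if (smooth && sum(est) >= 10) {
    fit <- smooth.spline(x, y, w = w, cv = FALSE)
    xf <- seq(min(x), max(x), by = step)
    yf <- predict(fit, xf)$y
    x <- xf; y <- yf
  }
  cross <- .first_downward_crossing(x, y, threshold)
  if (is.na(cross)) NA_real_ else cross / 12
}

#' Age at which the cohort 95th percentile falls below the reference 5th
#'
#' Finds the smallest age at which the cohort's p95 curve is below the
#' reference p5 and stays below for all later grid ages, with linear
#' interpolation between the last non-crossed and first crossed grid ages.
#' A cohort already below the reference at the first shared grid age
#' yields 0.
#'
#' @param cohort_curve A `percentile_curve` with a `p95` series.
#' @param ref A `reference_curve`.
#' @param sex,measure Reference selection (defaults taken from the cohort
#'   curve).
#' @return Age in months, or `NA` if the curves never (permanently) cross.
#' @export
crossing_age <- function(cohort_curve, ref, sex = cohort_curve$sex[1],
                         measure = cohort_curve$measure[1]) {
  est <- !is.na(cohort_curve$p95)
  rr <- ref[ref$sex == sex & ref$measure == measure, , drop = FALSE]
  abort_if(nrow(rr) == 0, "no reference rows for sex=%s measure=%s", sex,
           measure)
  in_range <- cohort_curve$age_months >= min(rr$age_months) &
    cohort_curve$age_months <= max(rr$age_months)
  idx <- est & in_range
  abort_if(!any(idx), "cohort and reference age ranges do not overlap")
  x <- cohort_curve$age_months[idx]
  d <- cohort_curve$p95[idx] -
    evaluate_reference(ref, sex, measure, x, 0.05)
  below <- d < 0
  if (!below[length(below)]) return(NA_real_)
  last_above <- max(which(!below), 0L)
  if (last_above == 0L) return(0)
  if (last_above == length(below)) return(NA_real_)
  i <- last_above
  x[i] + d[i] / (d[i] - d[i + 1L]) * (x[i + 1L] - x[i])
}

#' Age at which a median curve attains a fraction of its plateau
#'
#' The plateau is the mean of the p50 series over the final
#' `plateau_window` months of the grid; the attainment age is the first
#' age at which p50 reaches `fraction` of that plateau value, linearly
#' interpolated between grid ages. A curve already at the target at the
#' first grid age yields that age (0 for a constant curve on the default
#' grid).
#'
#' @param curve A `percentile_curve` (typically smoothed OFC).
#' @param fraction Fraction of the plateau value (default 0.90).
#' @param plateau_window Months of trailing grid used for the plateau.
#' @return Age in months.
#' @export
attainment_age <- function(curve, fraction = 0.90, plateau_window = 12) {
  est <- !is.na(curve$p50)
  abort_if(!any(est), "no estimable p50 values")
  x <- curve$age_months[est]
  y <- curve$p50[est]
  tail_i <- x >= max(x) - plateau_window
  abort_if(!any(tail_i), "plateau not estimable")
  target <- fraction * mean(y[tail_i])
  if (y[1L] >= target) return(x[1L])
  i <- which(y >= target)
  abort_if(!length(i), "curve never attains the target fraction")
  i <- i[1L]
  x[i - 1L] + (target - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}
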