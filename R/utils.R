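# Shared constants and small helpers.

DAYS_PER_MONTH <- 30.4375 # 365.25 / 12; one canonical day->month conversion

SEX_LEVELS <- c("male", "female")
MEASURE_LEVELS <- c("length_height", "weight", "ofc")
DECADE_LEVELS <- c("pre1980", "d1980s", "d1990s", "d2000s", "post2010")
SITE_LEVELS <- c("hopkins", "dupont", "texas", "wisconsin")
VITAL_LEVELS <- c("living", "deceased")
GESTATION_LEVELS <- c("preterm", "term", "post_term", "unknown")
INHERITANCE_LEVELS <- c("de_novo", "inherited", "unknown")
TIMING_LEVELS <- c("prenatal", "at_birth", "within_first_month",
                   "after_first_month", "unknown")
DXMODE_LEVELS <- c("molecular_only", "clinical_with_or_without_molecular",
                   "unknown")
POSITION_LEVELS <- c("supine", "standing", "unknown")
SURGERY_LEVELS <- c("ent", "brain", "foramen_magnum", "spine", "extremity",
                    "non_achondroplasia_related")
ACH_SURGERY_LEVELS <- SURGERY_LEVELS[1:5]
PSG_LEVELS <- c("no_osa", "mild", "moderate", "severe", "inconclusive")
MODALITY_LEVELS <- c("xray", "ct", "mri", "echocardiogram", "ultrasound")
QC_FLAG_LEVELS <- c("unit_swap_suspect", "implausible", "within_subject_jump",
                    "duplicate", "ok")

#' Convert a calendar interval to decimal age in months
#'
#' Ages are carried internally in decimal months, computed from day
#' differences as `days / 30.4375`; years are `months / 12`.
#'
#' @param birth_date,event_date `Date` vectors (or strings coercible to
#'   dates).
#' @return Numeric vector of ages in months.
#' @export
#' @examples
#' age_months("2010-01-01", "2011-01-01")
age_months <- function(birth_date, event_date) {
  as.numeric(difftime(as.Date(event_date), as.Date(birth_date),
                      units = "days")) / DAYS_PER_MONTH
}

#' Round half away from zero
#'
#' Deterministic half-up rounding, the convention used for every percentage
#' in the summary tables (e.g. 594/1094 -> 54.3, 174/1374 -> 12.7). Base R's
#' `round()` rounds half to even and would disagree on exact halves.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals with ties going up.
#' @export
#' @examples
#' round_half_up(100 * 594 / 1094, 1)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  # small epsilon absorbs binary representation error in rationals like
  # count/denominator; percentages are <= 100 so 1e-8 is far below one ulp
  # of the rounding boundary yet far above double error at this scale
  floor(x * s + 0.5 + 1e-8) / s
}

# percentage of count/denom, half-up to `digits`; NA when denom == 0
pct_of <- function(count, denom, digits = 1) {
  ifelse(denom > 0, round_half_up(100 * count / denom, digits), NA_real_)
}

# Linear interpolation with linear end extrapolation from the two outermost
# support points on each side; single support point -> constant.
interp_extrap <- function(x, y, xout) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(xout)))
  if (n == 1L) return(rep(y, length(xout)))
  out <- approx(x, y, xout = xout, ties = mean)$y
  lo <- xout < x[1L]
  hi <- xout > x[n]
  if (any(lo)) {
    sl <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + sl * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    sl <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + sl * (xout[hi] - x[n])
  }
  out
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot-style check with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
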