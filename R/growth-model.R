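# Parametric growth process used by the synthetic cohort generator.
#
# The generator needs sex-specific median and spread curves for the three
# anthropometry measures, with closed-form milestones so parameter-recovery
# tests can compare estimates against known truth:
#
#   * stature: median is the integral of a velocity function
#       v(t) = a * exp(-t/tau) + b * (1 - t/T)   for t < T,  0 afterwards,
#     i.e. a fast infancy component plus a linearly decaying term that hits
#     exactly zero at the plateau age T. Total gain fixes b.
#   * OFC: saturating exponential  birth + gain * (1 - exp(-k * t));
#     k is anchored so that 90% of the asymptotic value is attained at the
#     configured attainment age (closed form ln(10*gain/(gain+birth))/k).
#   * weight: log-normal around a monotone log-scale median with an
#     age-increasing log-SD (right skew grows with age).
#
# Spread is split into a between-subject component (a per-subject centile
# offset, constant over life) and a small measurement component; the total
# at birth matches the published cohort birth SDs.

#' Default growth-model parameters for one sex
#'
#' Returns the parametric growth process used by [generate_cohort()]. Birth
#' means and SDs are anchored to published achondroplasia cohort birth
#' moments (length 47.90/47.28 cm, weight 3.41/3.32 kg, OFC 37.1/36.4 cm for
#' males/females); stature plateau ages are 19.37/18.44 years and the OFC
#' 90%-of-plateau attainment ages 11.1/11.2 months.
#'
#' @param sex `"male"` or `"female"`.
#' @return A list with components `stature`, `weight`, `ofc`; see source for
#'   the field meanings (ages in months, lengths cm, weights kg).
#' @export
default_growth_params <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    st <- list(birth = 47.90, adult = 131.0, sd_birth = 3.18, sd_adult = 5.9,
               infancy_rate = 18, infancy_tau = 9, plateau_age = 19.37 * 12,
               sd_meas = 0.5)
    wt <- list(birth = 3.41, adult = 55.0, sigma_birth = 0.145,
               sigma_adult = 0.28, w_infancy = 0.35, infancy_tau = 6,
               plateau_age = 19.37 * 12, sigma_meas = 0.015)
    oc <- list(birth = 37.1, gain = 21.0, attain_months = 11.1, sd = 3.2,
               sd_meas = 0.3)
  } else {
    st <- list(birth = 47.28, adult = 124.0, sd_birth = 2.85, sd_adult = 5.5,
               infancy_rate = 18, infancy_tau = 9, plateau_age = 18.44 * 12,
               sd_meas = 0.5)
    wt <- list(birth = 3.32, adult = 48.0, sigma_birth = 0.120,
               sigma_adult = 0.28, w_infancy = 0.35, infancy_tau = 6,
               plateau_age = 18.44 * 12, sigma_meas = 0.015)
    oc <- list(birth = 36.4, gain = 20.2, attain_months = 11.2, sd = 2.3,
               sd_meas = 0.3)
  }
  oc$k <- log(10 * oc$gain / (oc$gain + oc$birth)) / oc$attain_months
  list(stature = st, weight = wt, ofc = oc)
}

# linear-tail velocity coefficient b (cm/yr), from the total stature gain
.stature_b <- function(p) {
  tau_y <- p$infancy_tau / 12
  T_y <- p$plateau_age / 12
  2 * (p$adult - p$birth - p$infancy_rate * tau_y) / T_y
}

#' Median growth curve of the generator's model
#'
#' @param params Per-sex parameter list from [default_growth_params()].
#' @param measure One of `"length_height"`, `"weight"`, `"ofc"`.
#' @param age_months Ages in months (vectorized).
#' @return Median value (cm, or kg for weight) at each age. Non-decreasing
#'   in age for all three measures.
#' @export
growth_median <- function(params, measure, age_months) {
  if (measure == "length_height") {
    p <- params$stature
    tau <- p$infancy_tau / 12
    T_y <- p$plateau_age / 12
    b <- .stature_b(p)
    t <- pmin(pmax(age_months, 0) / 12, T_y)
    p$birth + p$infancy_rate * tau * (1 - exp(-t / tau)) +
      b * (t - t^2 / (2 * T_y))
  } else if (measure == "ofc") {
    p <- params$ofc
    p$birth + p$gain * (1 - exp(-p$k * pmax(age_months, 0)))
  } else if (measure == "weight") {
    p <- params$weight
    tn <- pmin(pmax(age_months, 0), p$plateau_age) / p$plateau_age
    s <- p$w_infancy * (1 - exp(-pmax(age_months, 0) / p$infancy_tau)) +
      (1 - p$w_infancy) * (2 * tn - tn^2)
    exp(log(p$birth) + (log(p$adult) - log(p$birth)) * s)
  } else stop("unknown measure: ", measure)
}

#' Total (between-subject + measurement) spread of the generator's model
#'
#' For stature the SD interpolates linearly from the birth SD to the adult
#' SD over the growth period; for OFC it is constant; for weight the value
#' is a log-scale SD interpolating between the birth and adult coefficients
#' of variation (skewness increasing with age).
#'
#' @inheritParams growth_median
#' @return SD at each age (cm / kg-log-scale).
#' @export
growth_sd <- function(params, measure, age_months) {
  a <- pmax(age_months, 0)
  if (measure == "length_height") {
    p <- params$stature
    f <- pmin(a, p$plateau_age) / p$plateau_age
    p$sd_birth + (p$sd_adult - p$sd_birth) * f
  } else if (measure == "ofc") {
    rep(params$ofc$sd, length(a))
  } else if (measure == "weight") {
    p <- params$weight
    f <- pmin(a, p$plateau_age) / p$plateau_age
    p$sigma_birth + (p$sigma_adult - p$sigma_birth) * f
  } else stop("unknown measure: ", measure)
}

#' True population quantile of the generator's model
#'
#' Gaussian for stature and OFC (`median + z * sd`), log-normal for weight
#' (`median * exp(z * sigma)`).
#'
#' @inheritParams growth_median
#' @param p Probability (e.g. 0.05, 0.5, 0.95).
#' @export
growth_quantile <- function(params, measure, age_months, p) {
  z <- qnorm(p)
  if (measure == "weight") {
    growth_median(params, measure, age_months) *
      exp(z * growth_sd(params, measure, age_months))
  } else {
    growth_median(params, measure, age_months) +
      z * growth_sd(params, measure, age_months)
  }
}

#' True stature velocity of the generator's model
#'
#' @inheritParams growth_median
#' @return Velocity in cm/year; exactly 0 at and beyond the plateau age.
#' @export
stature_velocity <- function(params, age_months) {
  p <- params$stature
  tau <- p$infancy_tau / 12
  T_y <- p$plateau_age / 12
  b <- .stature_b(p)
  t <- pmax(age_months, 0) / 12
  ifelse(t < T_y, p$infancy_rate * exp(-t / tau) + b * (1 - t / T_y), 0)
}
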