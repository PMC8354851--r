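# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately written from the definitions, not by calling package code.

# order-statistic quantile with linear interpolation at rank 1 + (n-1)p
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# window half-width by explicit case analysis of the banding rule
oracle_half_width <- function(age) {
  if (age <= 12) 0.5
  else if (age <= 36) 1
  else if (age <= 120) 3
  else 6
}

# windowed empirical percentiles at one grid age
oracle_window_percentiles <- function(age, value, grid_age, min_n = 20) {
  hw <- oracle_half_width(grid_age)
  v <- value[age >= max(0, grid_age - hw) & age <= grid_age + hw]
  if (length(v) < min_n) return(c(n = length(v), p5 = NA, p50 = NA, p95 = NA))
  c(n = length(v), p5 = oracle_quantile(v, 0.05),
    p50 = oracle_quantile(v, 0.5), p95 = oracle_quantile(v, 0.95))
}

# greedy non-overlapping velocity pairs, written as an index walk
oracle_velocity_pairs <- function(age, value, min_gap = 6, max_gap = 18) {
  ord <- order(age)
  age <- age[ord]; value <- value[ord]
  mids <- c(); vels <- c(); gaps <- c()
  i <- 1
  while (i < length(age)) {
    partner <- NA
    for (j in (i + 1):length(age)) {
      if (age[j] - age[i] >= min_gap) { partner <- j; break }
    }
    if (is.na(partner)) break
    if (age[partner] - age[i] <= max_gap) {
      mids <- c(mids, (age[i] + age[partner]) / 2)
      vels <- c(vels, (value[partner] - value[i]) /
                  (age[partner] - age[i]) * 12)
      gaps <- c(gaps, age[partner] - age[i])
      i <- partner
    } else {
      i <- i + 1
    }
  }
  data.frame(midpoint_age = mids, velocity = vels, interval_length = gaps)
}

# minimal valid subjects table; override any column via ...
make_subjects <- function(n, ...) {
  s <- data.frame(
    subject_id = sprintf("T%04d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    birth_date = as.Date("2005-06-15"),
    site = "hopkins",
    vital_status = "living",
    age_last_encounter = 10,
    gestation = "term",
    gestational_weeks = 39,
    inheritance = "de_novo",
    adopted = "false",
    diagnosis_timing = "at_birth",
    diagnosis_mode = "clinical_with_or_without_molecular",
    limb_lengthening = FALSE,
    gh_deficient = FALSE,
    gh_treated = FALSE,
    trial_participant = FALSE,
    surgical_history_known = TRUE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) s[[nm]] <- over[[nm]]
  s
}

make_anthro <- function(subject_id, measure, age_months, value,
                        position = "unknown", qc_flags = "ok") {
  data.frame(subject_id = subject_id, measure = measure,
             age_months = age_months, value = value, position = position,
             qc_flags = qc_flags, stringsAsFactors = FALSE)
}

# registry with one term subject following the model median, handy for
# cleaning tests
noiseless_cfg <- function(n = 20, seed = 5) {
  cohort_config(n_subjects = n, seed = seed, noise_scale = 0,
                preterm_rate = 0, unknown_gestation_rate = 0,
                post_term_rate = 0)
}
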