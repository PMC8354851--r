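# Synthetic cohort generator.
#
# Emulates the statistical structure of a multicenter achondroplasia
# natural-history registry so every downstream stage (cleaning, curve
# construction, milestones, summaries) is testable without patient data.
# Default rates are the published cohort proportions; growth trajectories
# come from the parametric model in growth-model.R. A single root seed is
# expanded into per-subject substreams, so subject k's data do not depend on
# the total cohort size.

.default_timing_by_decade <- function() {
  m <- rbind(
    pre1980  = c(0, 40, 16, 51, 127),
    d1980s   = c(13, 64, 42, 39, 73),
    d1990s   = c(53, 72, 51, 86, 52),
    d2000s   = c(73, 100, 74, 80, 29),
    post2010 = c(76, 67, 39, 45, 12))
  colnames(m) <- TIMING_LEVELS
  m / rowSums(m)
}

.default_mode_by_decade <- function() {
  m <- rbind(
    pre1980  = c(1, 85, 148),
    d1980s   = c(2, 138, 91),
    d1990s   = c(10, 239, 65),
    d2000s   = c(17, 315, 24),
    post2010 = c(19, 213, 7))
  colnames(m) <- DXMODE_LEVELS
  m / rowSums(m)
}

#' Configuration for the synthetic cohort generator
#'
#' All categorical default rates are the published cohort proportions
#' (sex 51.2% male; birth-decade weights 234/231/314/356/239; 12.7% preterm;
#' 76.0% de novo; per-category lifetime surgery probabilities 65.0/10.0/
#' 20.5/12.7/21.2%; polysomnography uptake rising from 15.0% to 81.2% across
#' decades; 20/1374 deceased), so a generated cohort run through the summary
#' engines reproduces the standard table structure up to sampling noise.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer root seed; expanded into per-subject substreams.
#' @param sex_ratio Probability of male.
#' @param decade_weights Five birth-decade weights (normalized internally).
#' @param preterm_rate,post_term_rate,unknown_gestation_rate Gestation
#'   category probabilities (`term` is the remainder).
#' @param de_novo_rate,unknown_inheritance_rate Inheritance probabilities
#'   (`inherited` is the remainder).
#' @param adopted_rate,adopted_unknown_rate Adoption probabilities.
#' @param site_weights Four clinical-site weights.
#' @param deceased_rate Probability of deceased vital status.
#' @param limb_lengthening_rate,gh_deficient_rate,gh_treated_rate,trial_rate
#'   Exclusion-relevant treatment probabilities.
#' @param surgical_unknown_rate Probability the surgical history is unknown.
#' @param growth_model Named list with `male`/`female` entries from
#'   [default_growth_params()].
#' @param noise_scale Multiplier on all growth-model spread components;
#'   0 gives the noiseless limit (values equal the median curves exactly).
#' @param birth_measurement_rate Probability a subject has an age-0 visit.
#' @param visit_gap_means Mean inter-visit gaps in months for the
#'   infant (<2 y), child (2--10 y), teen (10--18 y) and adult age bands;
#'   gaps are Gamma-distributed with shape `visit_gap_shape` (clinical
#'   follow-up is denser in infancy; the source registries do not document
#'   visit spacing, so these are stand-ins recorded in provenance).
#' @param visit_gap_shape Gamma shape of inter-visit gaps.
#' @param measure_probs Probability that length/height and weight are taken
#'   at a visit.
#' @param ofc_prob_young,ofc_prob_old,ofc_age_cut_months Head-circumference
#'   sampling: probability per visit before/after the age cut.
#' @param surgery_probs Per-category lifetime probabilities of at least one
#'   procedure (ent, brain, foramen_magnum, spine, extremity).
#' @param surgery_mean_procs Mean number of procedures per subject within a
#'   category, given at least one.
#' @param nonach_surgery_rate Probability of any non-achondroplasia-related
#'   surgery (counted, never percentaged).
#' @param psg_prob_by_decade Probability of >= 1 polysomnogram, by decade.
#' @param psg_extra_mean Mean number of additional studies beyond the first.
#' @param psg_outcome_probs Per-study outcome distribution.
#' @param psg_age_mean,psg_age_sd Mean/SD (years) of age at first study, by
#'   decade; draws are truncated to the subject's follow-up.
#' @param imaging_prob Probability of >= 1 imaging study.
#' @param imaging_extra_mean Mean number of additional studies.
#' @param imaging_modality_weights Modality weights
#'   (xray/ct/mri/echocardiogram/ultrasound).
#' @param images_available_rate Probability original images are available.
#' @param timing_by_decade,mode_by_decade Row-stochastic matrices of
#'   diagnosis timing and mode by birth decade.
#' @param error_rates Per-point corruption rates used by [inject_errors()]
#'   (`unit_swap`, `duplicate`, `implausible`); the generator itself always
#'   emits clean data.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1374,
                          seed = 1L,
                          sex_ratio = 0.512,
                          decade_weights = c(234, 231, 314, 356, 239),
                          preterm_rate = 0.127,
                          post_term_rate = 0.011,
                          unknown_gestation_rate = 0.128,
                          de_novo_rate = 0.760,
                          unknown_inheritance_rate = 0.101,
                          adopted_rate = 0.063,
                          adopted_unknown_rate = 0.03,
                          site_weights = c(0.217, 0.280, 0.159, 0.344),
                          deceased_rate = 20 / 1374,
                          limb_lengthening_rate = 0.012,
                          gh_deficient_rate = 4 / 1374,
                          gh_treated_rate = 2 / 1374,
                          trial_rate = 0.008,
                          surgical_unknown_rate = 113 / 1374,
                          growth_model = list(
                            male = default_growth_params("male"),
                            female = default_growth_params("female")),
                          noise_scale = 1,
                          birth_measurement_rate = 0.95,
                          visit_gap_means = c(infant = 3, child = 9,
                                              teen = 12, adult = 18),
                          visit_gap_shape = 4,
                          measure_probs = c(length_height = 0.92,
                                            weight = 0.95),
                          ofc_prob_young = 0.90,
                          ofc_prob_old = 0.15,
                          ofc_age_cut_months = 72,
                          surgery_probs = c(ent = 0.650, brain = 0.100,
                                            foramen_magnum = 0.205,
                                            spine = 0.127,
                                            extremity = 0.212),
                          surgery_mean_procs = c(ent = 3.14, brain = 2.38,
                                                 foramen_magnum = 1.12,
                                                 spine = 2.43,
                                                 extremity = 2.35),
                          nonach_surgery_rate = 302 / 1374,
                          psg_prob_by_decade = c(0.150, 0.342, 0.404,
                                                 0.680, 0.812),
                          psg_extra_mean = 1.41,
                          psg_outcome_probs = c(no_osa = 0.47, mild = 0.25,
                                                moderate = 0.11,
                                                severe = 0.07,
                                                inconclusive = 0.10),
                          psg_age_mean = c(31.1, 5.6, 3.0, 2.2, 0.8),
                          psg_age_sd = c(16.9, 7.9, 4.2, 3.1, 0.9),
                          imaging_prob = 0.91,
                          imaging_extra_mean = 7.58,
                          imaging_modality_weights = c(7201, 1069, 1826,
                                                       166, 465),
                          images_available_rate = 0.755,
                          timing_by_decade = .default_timing_by_decade(),
                          mode_by_decade = .default_mode_by_decade(),
                          error_rates = c(unit_swap = 0.02,
                                          duplicate = 0.01,
                                          implausible = 0.02)) {
  cfg <- as.list(environment())
  abort_if(!is.numeric(n_subjects) || n_subjects < 0 ||
             n_subjects != round(n_subjects),
           "n_subjects must be a non-negative integer")
  abort_if(any(decade_weights < 0) || sum(decade_weights) <= 0,
           "decade_weights must be non-negative with positive sum")
  cfg$decade_weights <- decade_weights / sum(decade_weights)
  abort_if(abs(sum(cfg$decade_weights) - 1) > 1e-9,
           "decade_weights must normalize to 1")
  probs <- c(sex_ratio, preterm_rate, post_term_rate, unknown_gestation_rate,
             de_novo_rate, unknown_inheritance_rate, adopted_rate,
             adopted_unknown_rate, deceased_rate, limb_lengthening_rate,
             gh_deficient_rate, gh_treated_rate, trial_rate,
             surgical_unknown_rate, birth_measurement_rate, surgery_probs,
             nonach_surgery_rate, psg_prob_by_decade, imaging_prob,
             images_available_rate, error_rates, ofc_prob_young,
             ofc_prob_old, measure_probs)
  abort_if(any(probs < 0 | probs > 1), "all probabilities must lie in [0, 1]")
  abort_if(noise_scale < 0, "noise_scale must be >= 0")
  cfg$site_weights <- site_weights / sum(site_weights)
  structure(cfg, class = "cohort_config")
}

# deterministic per-subject substream seed; injective in k for k < 33013
subject_seed <- function(root, k) {
  ((as.integer(root) %% 65011L) * 33013L + as.integer(k)) %% 2147483647L
}

#' Sample one measurement trajectory from the growth model
#'
#' Values are the model median plus a per-subject centile offset
#' (`subject_effect` standard normal units times the between-subject SD)
#' plus independent measurement noise; weight uses the same structure on the
#' log scale (multiplicative log-normal). With `noise_scale = 0` the values
#' equal the median curve exactly. Uses the current RNG state.
#'
#' @param params Per-sex parameter list from [default_growth_params()].
#' @param measure One of `"length_height"`, `"weight"`, `"ofc"`.
#' @param visit_ages Sorted non-negative ages in months.
#' @param subject_effect Standard-normal per-subject offset (constant over
#'   the trajectory; children track their centile).
#' @param noise_scale Multiplier on both spread components.
#' @return Numeric vector of measured values at `visit_ages`.
#' @export
sample_trajectory <- function(params, measure, visit_ages,
                              subject_effect = 0, noise_scale = 1) {
  abort_if(is.unsorted(visit_ages), "visit_ages must be sorted")
  abort_if(any(visit_ages < 0), "visit_ages must be >= 0")
  n <- length(visit_ages)
  med <- growth_median(params, measure, visit_ages)
  tot <- growth_sd(params, measure, visit_ages)
  sm <- if (measure == "weight") params$weight$sigma_meas
        else if (measure == "ofc") params$ofc$sd_meas
        else params$stature$sd_meas
  between <- sqrt(pmax(tot^2 - sm^2, 0))
  eps <- if (n > 0) rnorm(n, 0, sm * noise_scale) else numeric()
  if (measure == "weight") {
    med * exp(subject_effect * between * noise_scale + eps)
  } else {
    med + subject_effect * between * noise_scale + eps
  }
}

# visit ages (months) for one subject: optional birth visit, then gamma gaps
# whose mean depends on the current age band
.visit_ages <- function(cfg, age_last_months) {
  ages <- if (runif(1) < cfg$birth_measurement_rate) 0 else numeric()
  t <- runif(1, 0.5, 1.5)
  gm <- cfg$visit_gap_means
  sh <- cfg$visit_gap_shape
  while (t <= age_last_months && length(ages) < 400) {
    ages <- c(ages, t)
    mean_gap <- if (t < 24) gm[["infant"]] else if (t < 120) gm[["child"]]
                else if (t < 216) gm[["teen"]] else gm[["adult"]]
    t <- t + rgamma(1, shape = sh, scale = mean_gap / sh)
  }
  ages
}

.procedure_vocab <- list(
  ent = c("adenotonsillectomy", "pe_tubes", "revision_adenoidectomy"),
  brain = c("vp_shunt", "shunt_revision", "ventriculostomy"),
  foramen_magnum = c("cervicomedullary_decompression"),
  spine = c("laminectomy", "vertebral_fusion"),
  extremity = c("osteotomy", "guided_growth", "hardware_removal"),
  non_achondroplasia_related = c("appendectomy", "cesarean_section",
                                 "hernia_repair"))

# triangular (min, mode, max) in years
.surgery_age_tri <- list(
  ent = c(0.5, 4, 12), brain = c(0, 1.5, 10), foramen_magnum = c(0, 2, 10),
  spine = c(5, 30, 60), extremity = c(2, 8, 16),
  non_achondroplasia_related = c(1, 25, 60))

.rtriangular <- function(n, lo, mode, hi) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc, lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Generate a synthetic registry
#'
#' Draws a full registry (subjects, anthropometry, surgical events,
#' polysomnography, imaging) from a [cohort_config()]. Deterministic: the
#' same config (including its seed) always yields a structurally equal
#' registry, and each subject's data are drawn from a private substream so
#' they are invariant to `n_subjects`. The caller's RNG state is preserved.
#'
#' Subjects of unknown gestation may be latent preterm (at the configured
#' preterm rate); preterm subjects carry an infancy growth deficit
#' proportional to the weeks below 37, decaying with age, which is what the
#' preterm exclusion rule is designed to keep out of the curves.
#'
#' @param cfg A [cohort_config()].
#' @return A validated `achondro_registry`, canonically ordered.
#' @export
generate_cohort <- function(cfg) {
  abort_if(!inherits(cfg, "cohort_config"), "cfg must be a cohort_config")
  n <- as.integer(cfg$n_subjects)
  prov <- sprintf(
    "synthetic cohort: n=%d seed=%d (visit spacing and event-age distributions are simulator stand-ins)",
    n, as.integer(cfg$seed))
  if (n == 0L) return(registry(provenance = prov))

  decade_years <- list(pre1980 = 1945:1979, d1980s = 1980:1989,
                       d1990s = 1990:1999, d2000s = 2000:2009,
                       post2010 = 2010:2017)
  subj <- vector("list", n)
  anth <- vector("list", n)
  surg <- vector("list", n)
  psgl <- vector("list", n)
  imgl <- vector("list", n)

  gen_one <- function(k) {
    set.seed(subject_seed(cfg$seed, k))
    sid <- sprintf("S%05d", k)
    sex <- if (runif(1) < cfg$sex_ratio) "male" else "female"
    decade <- sample(DECADE_LEVELS, 1, prob = cfg$decade_weights)
    site <- sample(SITE_LEVELS, 1, prob = cfg$site_weights)
    birth_year <- sample(decade_years[[decade]], 1)
    birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
      sample(0:364, 1)
    max_age <- max(0.05, as.numeric(as.Date("2019-01-01") - birth_date) /
                     365.2425)
    age_last <- min(rbeta(1, 3, 1) * max_age, 79.7)
    vital <- if (runif(1) < cfg$deceased_rate) "deceased" else "living"
    inh <- sample(INHERITANCE_LEVELS, 1,
                  prob = c(cfg$de_novo_rate,
                           1 - cfg$de_novo_rate - cfg$unknown_inheritance_rate,
                           cfg$unknown_inheritance_rate))
    adopted <- sample(c("true", "false", "unknown"), 1,
                      prob = c(cfg$adopted_rate,
                               1 - cfg$adopted_rate - cfg$adopted_unknown_rate,
                               cfg$adopted_unknown_rate))
    term_rate <- 1 - cfg$preterm_rate - cfg$post_term_rate -
      cfg$unknown_gestation_rate
    gest <- sample(GESTATION_LEVELS, 1,
                   prob = c(cfg$preterm_rate, term_rate, cfg$post_term_rate,
                            cfg$unknown_gestation_rate))
    gw <- switch(gest,
                 preterm = round(runif(1, 26, 36.9), 1),
                 term = round(runif(1, 37, 41.9), 1),
                 post_term = round(runif(1, 42, 43.5), 1),
                 unknown = NA_real_)
    # latent prematurity among unknown-gestation subjects: same rate
    latent_preterm <- gest == "unknown" && runif(1) < cfg$preterm_rate
    deficit_weeks <- if (gest == "preterm") 37 - gw
                     else if (latent_preterm) 37 - runif(1, 28, 36.5)
                     else 0
    timing <- sample(TIMING_LEVELS, 1, prob = cfg$timing_by_decade[decade, ])
    mode <- sample(DXMODE_LEVELS, 1, prob = cfg$mode_by_decade[decade, ])
    limb <- runif(1) < cfg$limb_lengthening_rate
    ghd <- runif(1) < cfg$gh_deficient_rate
    ght <- runif(1) < cfg$gh_treated_rate
    trial <- runif(1) < cfg$trial_rate
    shk <- runif(1) >= cfg$surgical_unknown_rate

    subj[[k]] <<- data.frame(
      subject_id = sid, sex = sex, birth_date = birth_date, site = site,
      vital_status = vital, age_last_encounter = round(age_last, 3),
      gestation = gest, gestational_weeks = gw, inheritance = inh,
      adopted = adopted, diagnosis_timing = timing, diagnosis_mode = mode,
      limb_lengthening = limb, gh_deficient = ghd, gh_treated = ght,
      trial_participant = trial, surgical_history_known = shk,
      stringsAsFactors = FALSE)

    # ---- anthropometry ----
    gp <- cfg$growth_model[[sex]]
    age_last_mo <- age_last * 12
    ages <- round(.visit_ages(cfg, age_last_mo), 4)
    u <- rnorm(3)  # per-subject centile offsets: stature, weight, ofc
    rows <- list()
    if (length(ages)) {
      take_len <- runif(length(ages)) < cfg$measure_probs[["length_height"]]
      take_wt <- runif(length(ages)) < cfg$measure_probs[["weight"]]
      p_ofc <- ifelse(ages < cfg$ofc_age_cut_months, cfg$ofc_prob_young,
                      cfg$ofc_prob_old)
      take_ofc <- runif(length(ages)) < p_ofc
      mk <- function(measure, keep, u_i) {
        a <- ages[keep]
        if (!length(a)) return(NULL)
        v <- sample_trajectory(gp, measure, a, subject_effect = u_i,
                               noise_scale = cfg$noise_scale)
        if (deficit_weeks > 0) {
          dec <- exp(-a / 6)  # deficit fades over roughly the first year
          v <- switch(measure,
                      length_height = v - 0.85 * deficit_weeks * dec,
                      ofc = v - 0.45 * deficit_weeks * dec,
                      weight = v * exp(-0.05 * deficit_weeks * dec))
        }
        data.frame(subject_id = sid, measure = measure,
                   age_months = a, value = round(pmax(v, 0.05), 2),
                   position = ifelse(measure == "length_height",
                                     ifelse(a < 24, "supine", "standing"),
                                     "unknown"),
                   qc_flags = "ok", stringsAsFactors = FALSE)
      }
      rows <- list(mk("length_height", take_len, u[1]),
                   mk("weight", take_wt, u[2]),
                   mk("ofc", take_ofc, u[3]))
    }
    anth[[k]] <<- do.call(rbind, rows)

    # ---- surgeries ----
    if (shk) {
      ev <- list()
      for (cat in ACH_SURGERY_LEVELS) {
        if (runif(1) < cfg$surgery_probs[[cat]]) {
          m <- 1L + rpois(1, max(cfg$surgery_mean_procs[[cat]] - 1, 0))
          tri <- .surgery_age_tri[[cat]]
          age_yr <- pmin(pmax(.rtriangular(m, tri[1], tri[2], tri[3]), 0.05),
                         max(age_last, 0.1))
          ev[[cat]] <- data.frame(
            subject_id = sid, category = cat,
            procedure = sample(.procedure_vocab[[cat]], m, replace = TRUE),
            event_date = birth_date + round(age_yr * 365.2425),
            date_known = TRUE, stringsAsFactors = FALSE)
        }
      }
      if (runif(1) < cfg$nonach_surgery_rate) {
        m <- 1L + rpois(1, 0.5)
        tri <- .surgery_age_tri$non_achondroplasia_related
        age_yr <- pmin(pmax(.rtriangular(m, tri[1], tri[2], tri[3]), 0.05),
                       max(age_last, 0.1))
        ev$nonach <- data.frame(
          subject_id = sid, category = "non_achondroplasia_related",
          procedure = sample(.procedure_vocab$non_achondroplasia_related, m,
                             replace = TRUE),
          event_date = birth_date + round(age_yr * 365.2425),
          date_known = TRUE, stringsAsFactors = FALSE)
      }
      if (length(ev)) {
        evd <- do.call(rbind, ev)
        # some PE-tube placements have no recoverable date
        pe <- evd$procedure == "pe_tubes" & runif(nrow(evd)) < 0.08
        evd$date_known[pe] <- FALSE
        evd$event_date[pe] <- as.Date(NA)
        surg[[k]] <<- evd
      }
    }

    # ---- polysomnography ----
    di <- match(decade, DECADE_LEVELS)
    if (runif(1) < cfg$psg_prob_by_decade[di]) {
      m <- 1L + rpois(1, cfg$psg_extra_mean)
      first <- min(max(abs(rnorm(1, cfg$psg_age_mean[di],
                                 cfg$psg_age_sd[di])), 0.05),
                   max(age_last, 0.05))
      extra <- if (m > 1) first + cumsum(rgamma(m - 1, 2, rate = 1)) else
        numeric()
      ages_psg <- pmin(c(first, extra), max(age_last, 0.05))
      psgl[[k]] <<- data.frame(
        subject_id = sid, age_at_study = round(ages_psg, 2),
        outcome = sample(PSG_LEVELS, m, replace = TRUE,
                         prob = cfg$psg_outcome_probs[PSG_LEVELS]),
        is_first_study = seq_len(m) == 1L, stringsAsFactors = FALSE)
    }

    # ---- imaging ----
    if (runif(1) < cfg$imaging_prob) {
      m <- 1L + rpois(1, cfg$imaging_extra_mean)
      modality <- sample(MODALITY_LEVELS, m, replace = TRUE,
                         prob = cfg$imaging_modality_weights)
      region <- ifelse(modality == "xray",
                       sample(c("long_bones", "spine", "cranium"), m,
                              replace = TRUE),
                       sample(c("brain", "cervicomedullary_junction",
                                "chest"), m, replace = TRUE))
      imgl[[k]] <<- data.frame(
        subject_id = sid, modality = modality,
        study_date = birth_date +
          round(runif(m, 0.02, max(age_last, 0.05)) * 365.2425),
        body_region = region,
        images_available = runif(m) < cfg$images_available_rate,
        stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }

  with_seed(cfg$seed, for (k in seq_len(n)) gen_one(k))

  bind <- function(lst, empty) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (!length(lst)) return(empty)
    do.call(rbind, lst)
  }
  r <- registry(subjects = do.call(rbind, subj),
                anthropometry = bind(anth, empty_anthropometry()),
                surgeries = bind(surg, empty_surgeries()),
                psg = bind(psgl, empty_psg()),
                imaging = bind(imgl, empty_imaging()),
                provenance = prov)
  canonical_registry(r)
}

#' Inject known corruptions into a registry's anthropometry
#'
#' Adds the error types the QC layer is designed to catch -- cm-to-inch and
#' kg-to-pound unit swaps, exact duplicate rows, and gross outliers -- and
#' returns a ground-truth ledger of every corruption so sensitivity can be
#' measured. Each input row suffers at most one corruption; kinds are drawn
#' independently per row at the configured rates.
#'
#' @param r A clean `achondro_registry`.
#' @param error_rates Named rates for `unit_swap`, `duplicate`,
#'   `implausible`; their sum is the overall corruption rate.
#' @param seed Integer seed (caller RNG preserved).
#' @return List with elements `registry` (corrupted) and `ledger` (data
#'   frame: `subject_id`, `measure`, `age_months`, `kind`, `original_value`,
#'   `corrupted_value`; one row per corruption).
#' @export
inject_errors <- function(r, error_rates = c(unit_swap = 0.02,
                                             duplicate = 0.01,
                                             implausible = 0.02),
                          seed = 1L) {
  validate_registry(r)
  for (nm in c("unit_swap", "duplicate", "implausible"))
    abort_if(!nm %in% names(error_rates), "error_rates lacks '%s'", nm)
  abort_if(any(error_rates < 0) || sum(error_rates) > 1,
           "error_rates must be >= 0 and sum to <= 1")
  a <- r$anthropometry
  n <- nrow(a)
  empty_ledger <- data.frame(subject_id = character(), measure = character(),
                             age_months = numeric(),
                             kind = character(), original_value = numeric(),
                             corrupted_value = numeric(),
                             stringsAsFactors = FALSE)
  if (n == 0L || sum(error_rates) == 0) {
    return(list(registry = r, ledger = empty_ledger))
  }
  out <- with_seed(seed, {
    kind <- sample(c("none", "unit_swap", "duplicate", "implausible"), n,
                   replace = TRUE,
                   prob = c(1 - sum(error_rates),
                            error_rates[["unit_swap"]],
                            error_rates[["duplicate"]],
                            error_rates[["implausible"]]))
    sign_up <- runif(n) < 0.5
    list(kind = kind, sign_up = sign_up)
  })
  kind <- out$kind
  ledger <- list()
  dup_rows <- list()
  for (i in which(kind != "none")) {
    v0 <- a$value[i]
    m <- a$measure[i]
    v1 <- v0
    if (kind[i] == "unit_swap") {
      v1 <- if (m == "weight") v0 * 2.20462 else v0 / 2.54
    } else if (kind[i] == "implausible") {
      # gross outlier, roughly 8 population SDs
      v1 <- switch(m,
                   length_height = if (out$sign_up[i] || v0 <= 33) v0 + 32
                                   else v0 - 32,
                   ofc = if (out$sign_up[i] || v0 <= 21) v0 + 20 else v0 - 20,
                   weight = if (out$sign_up[i]) v0 * 4.2 else v0 / 4.2)
    }
    if (kind[i] == "duplicate") {
      dup_rows[[length(dup_rows) + 1L]] <- a[i, , drop = FALSE]
    } else {
      a$value[i] <- round(v1, 2)
      v1 <- a$value[i]
    }
    ledger[[length(ledger) + 1L]] <- data.frame(
      subject_id = a$subject_id[i], measure = m,
      age_months = a$age_months[i], kind = kind[i],
      original_value = v0, corrupted_value = v1, stringsAsFactors = FALSE)
  }
  if (length(dup_rows)) a <- rbind(a, do.call(rbind, dup_rows))
  rownames(a) <- NULL
  r$anthropometry <- a
  validate_registry(r)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else empty_ledger
  rownames(ledger) <- NULL
  list(registry = r, ledger = ledger)
}
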