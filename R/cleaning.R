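# Exclusion rules and anthropometry QC.
#
# The exclusion rules are the stated ones: preterm subjects are omitted
# from the growth-curve input before 2 years of age; subjects of unknown
# gestation whose birth parameters fall within +/-2 SD of the sex-specific
# achondroplasia birth reference are presumed term; anthropometry from
# limb-lengthened, growth-hormone-treated, or trial subjects is excluded
# entirely. The QC layer (duplicates, unit-swap suspects, implausible
# values, within-subject shrinkage) is a documented stand-in for
# unavailable source cleaning algorithms; all thresholds are config-exposed.

#' Published achondroplasia birth reference (means and SDs)
#'
#' Sex-specific birth means and SDs for length, weight and head
#' circumference in achondroplasia, used for the presumed-term rule
#' (birth parameters within +/-2 SD) and as generator anchors.
#'
#' @return Data frame with columns `sex`, `measure`, `mean`, `sd`.
#' @export
achondroplasia_birth_reference <- function() {
  data.frame(
    sex = rep(c("female", "male"), each = 3),
    measure = rep(c("length_height", "weight", "ofc"), 2),
    mean = c(47.28, 3.32, 36.4, 47.90, 3.41, 37.1),
    sd = c(2.85, 0.40, 2.3, 3.18, 0.50, 3.2),
    stringsAsFactors = FALSE)
}

#' Presume term gestation from birth anthropometry
#'
#' A subject of unknown gestation is presumed term if and only if every
#' available birth measurement (age < 0.5 months) lies within mean +/- 2 SD
#' of the sex-specific achondroplasia birth reference; otherwise the
#' gestation stays unknown (and the subject is excluded from curves before
#' 2 years of age). Measures absent from the reference are ignored; a
#' subject with no birth measurement stays unknown.
#'
#' @param subject One row of a subjects table.
#' @param birth_points Data frame with columns `measure`, `value` (the
#'   subject's measurements at age < 0.5 months).
#' @param ref Birth reference table ([achondroplasia_birth_reference()]).
#' @return `"term"` or `"unknown"`.
#' @export
presume_term <- function(subject, birth_points,
                         ref = achondroplasia_birth_reference()) {
  if (is.null(birth_points) || nrow(birth_points) == 0L) return("unknown")
  ref <- ref[ref$sex == subject$sex, , drop = FALSE]
  checked <- 0L
  for (i in seq_len(nrow(birth_points))) {
    m <- birth_points$measure[i]
    rr <- ref[ref$measure == m, , drop = FALSE]
    if (nrow(rr) == 0L) next
    checked <- checked + 1L
    if (abs(birth_points$value[i] - rr$mean[1]) > 2 * rr$sd[1])
      return("unknown")
  }
  if (checked == 0L) "unknown" else "term"
}

new_cleaning_report <- function(rules, subject_exclusions, input_n,
                                retained_n, dropped_n, presumed_term,
                                retained_by_measure) {
  structure(list(rules = rules, subject_exclusions = subject_exclusions,
                 input_n = input_n, retained_n = retained_n,
                 dropped_n = dropped_n, presumed_term = presumed_term,
                 retained_by_measure = retained_by_measure),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input points:    %d\n", x$input_n))
  cat(sprintf("  retained points: %d\n", x$retained_n))
  cat(sprintf("  dropped points:  %d\n", x$dropped_n))
  for (nm in names(x$rules))
    cat(sprintf("  %-28s %d\n", paste0(nm, ":"), x$rules[[nm]]))
  invisible(x)
}

#' Apply the growth-curve exclusion rules
#'
#' Removes from the anthropometry (a) all points, at every age, from
#' subjects who underwent limb lengthening, were treated with growth
#' hormone, or participated in a growth-modulating trial; and (b) points
#' before 24 months of age from preterm subjects and from unknown-gestation
#' subjects not presumed term. The 2-year boundary is read as [0, 24): a
#' point at exactly 24.0 months is retained. Growth-hormone deficiency
#' without treatment does not exclude. Idempotent.
#'
#' @param r An `achondro_registry`.
#' @param birth_ref Birth reference for the presumed-term rule.
#' @param presume Apply the presumed-term resolution to unknown-gestation
#'   subjects first (default `TRUE`).
#' @return List with elements `registry` (points removed; subjects table
#'   untouched) and `report` (a `cleaning_report`: per-rule counts, one
#'   exclusion reason per excluded subject, ids presumed term).
#' @export
apply_growth_exclusions <- function(r,
                                    birth_ref = achondroplasia_birth_reference(),
                                    presume = TRUE) {
  validate_registry(r)
  s <- r$subjects
  a <- r$anthropometry
  input_n <- nrow(a)

  reason <- ifelse(s$limb_lengthening %in% TRUE, "limb_lengthening",
            ifelse(s$gh_treated %in% TRUE, "gh_treated",
            ifelse(s$trial_participant %in% TRUE, "trial", NA_character_)))
  excl_ids <- s$subject_id[!is.na(reason)]

  eff_gest <- setNames(s$gestation, s$subject_id)
  presumed <- character()
  if (presume) {
    for (sid in s$subject_id[s$gestation == "unknown"]) {
      bp <- a[a$subject_id == sid & a$age_months < 0.5, , drop = FALSE]
      g <- presume_term(s[s$subject_id == sid, , drop = FALSE], bp, birth_ref)
      if (g == "term") {
        eff_gest[[sid]] <- "term"
        presumed <- c(presumed, sid)
      }
    }
  }

  subj_excluded <- a$subject_id %in% excl_ids
  infancy <- !subj_excluded &
    eff_gest[a$subject_id] %in% c("preterm", "unknown") & a$age_months < 24
  keep <- !subj_excluded & !infancy

  rules <- c(subject_excluded_points = sum(subj_excluded),
             preterm_infancy_points =
               sum(infancy & eff_gest[a$subject_id] == "preterm"),
             unknown_gestation_infancy_points =
               sum(infancy & eff_gest[a$subject_id] == "unknown"))
  excl_df <- data.frame(subject_id = s$subject_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  out <- r
  out$anthropometry <- a[keep, , drop = FALSE]
  rownames(out$anthropometry) <- NULL
  rep <- new_cleaning_report(
    rules = rules, subject_exclusions = excl_df, input_n = input_n,
    retained_n = sum(keep), dropped_n = sum(!keep),
    presumed_term = presumed,
    retained_by_measure = table(out$anthropometry$measure))
  list(registry = out, report = rep)
}

#' QC rule configuration
#'
#' Thresholds of the anthropometry QC layer. Hard physiologic bounds are
#' length/height 20--220 cm, weight 0.3--250 kg, OFC 20--70 cm. Trajectory
#' residual scales (`traj_sd`: cm for length/OFC, log-scale for weight) set
#' the outlier cut at `outlier_mult` scales from the subject's interpolated
#' trajectory and the unit-swap back-match tolerance at `unit_match_mult`
#' scales. Consecutive stature decreases beyond `shrink_cm` before
#' `shrink_age_limit` months are flagged as within-subject jumps.
#'
#' @param hard_bounds Named list of c(lo, hi) per measure.
#' @param traj_sd Named residual scales per measure.
#' @param outlier_mult,unit_match_mult Multipliers on `traj_sd`.
#' @param shrink_cm Stature shrinkage tolerance in cm.
#' @param shrink_age_limit Upper age (months) for the shrinkage rule.
#' @param drop_flagged Whether flagged points are excluded from curve input
#'   by [curve_points()] (they always remain in the registry).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(hard_bounds = list(length_height = c(20, 220),
                                         weight = c(0.3, 250),
                                         ofc = c(20, 70)),
                      traj_sd = c(length_height = 2, weight = 0.10,
                                  ofc = 1.5),
                      outlier_mult = 4,
                      unit_match_mult = 2,
                      shrink_cm = 2,
                      shrink_age_limit = 216,
                      drop_flagged = TRUE) {
  structure(list(hard_bounds = hard_bounds, traj_sd = traj_sd,
                 outlier_mult = outlier_mult,
                 unit_match_mult = unit_match_mult, shrink_cm = shrink_cm,
                 shrink_age_limit = shrink_age_limit,
                 drop_flagged = drop_flagged), class = "qc_config")
}

# population fallback: binned medians/MADs of y by age for one measure
.population_band <- function(age, y) {
  br <- seq(0, 1023, by = 3)
  bin <- findInterval(age, br)
  med <- tapply(y, bin, median)
  madv <- tapply(y, bin, mad)
  mids <- br[as.integer(names(med))] + 1.5
  list(pred = function(a) interp_extrap(mids, as.numeric(med), a),
       mad = function(a) {
         out <- interp_extrap(mids, as.numeric(madv), a)
         pmax(out, 0)
       })
}

# classify one residual: "ok", "unit_swap_suspect" or "implausible"
.classify_point <- function(y, pred, candidates, sdr, outlier_mult,
                            unit_match_mult) {
  if (abs(y - pred) <= outlier_mult * sdr) return("ok")
  if (any(abs(candidates - pred) <= unit_match_mult * sdr))
    return("unit_swap_suspect")
  "implausible"
}

#' Flag or drop suspect anthropometry points
#'
#' Applies four documented rules, flagging rather than silently deleting:
#' exact duplicates (same subject, measure, age, value) are collapsed to
#' one with the removed copies reported; values outside hard physiologic
#' bounds are flagged implausible; values far from the subject's
#' interpolated trajectory are flagged as unit-swap suspects when
#' multiplying by 2.54 (in->cm) or dividing by 2.20462 (lb->kg) lands back
#' on the trajectory, and implausible otherwise (a cohort-level binned
#' median curve is the fallback when a subject has fewer than three points
#' of a measure); consecutive stature decreases beyond the shrinkage
#' tolerance before age 18 years flag the later point. Trajectory
#' prediction runs twice so first-pass outliers do not contaminate their
#' neighbours' predictions. Weight is handled on the log scale.
#'
#' @param r An `achondro_registry`.
#' @param rules A [qc_config()].
#' @return List with `registry` (duplicates collapsed, `qc_flags` updated)
#'   and `report` (a `cleaning_report`; its `duplicates` element holds the
#'   removed copies). Every input point is exactly one of retained,
#'   flagged-retained, or dropped, and the counts reconcile.
#' @export
qc_anthropometry <- function(r, rules = qc_config()) {
  validate_registry(r)
  a <- r$anthropometry
  input_n <- nrow(a)
  counts <- c(duplicate = 0L, implausible = 0L, unit_swap_suspect = 0L,
              within_subject_jump = 0L)

  # 1. exact duplicates -> collapse, report removed copies
  key <- paste(a$subject_id, a$measure, a$age_months, a$value, sep = "\r")
  dup <- duplicated(key)
  dup_df <- a[dup, , drop = FALSE]
  counts[["duplicate"]] <- sum(dup)
  a <- a[!dup, , drop = FALSE]
  rownames(a) <- NULL
  n <- nrow(a)
  flags <- vector("list", n)

  # 2. hard physiologic bounds
  for (m in names(rules$hard_bounds)) {
    b <- rules$hard_bounds[[m]]
    bad <- a$measure == m & (a$value < b[1] | a$value > b[2])
    for (i in which(bad)) flags[[i]] <- c(flags[[i]], "implausible")
  }
  hard_bad <- vapply(flags, function(f) "implausible" %in% f, logical(1))

  # working scale: log for weight
  y <- ifelse(a$measure == "weight", log(a$value), a$value)
  cand1 <- ifelse(a$measure == "weight", log(a$value / 2.20462),
                  a$value * 2.54)
  cand2 <- ifelse(a$measure == "weight", log(a$value * 2.20462),
                  a$value / 2.54)

  bands <- list()
  for (m in MEASURE_LEVELS) {
    idx <- a$measure == m & !hard_bad
    if (sum(idx) >= 5)
      bands[[m]] <- .population_band(a$age_months[idx], y[idx])
  }

  groups <- split(seq_len(n), paste(a$subject_id, a$measure, sep = "\r"))
  for (g in groups) {
    m <- a$measure[g[1]]
    sdr <- rules$traj_sd[[m]]
    g <- g[order(a$age_months[g])]
    bad <- hard_bad[g]
    # two passes: predictions in the second exclude first-pass outliers
    for (pass in 1:2) {
      newbad <- bad
      for (j in seq_along(g)) {
        if (hard_bad[g[j]]) next
        others <- g[!bad & seq_along(g) != j]
        i <- g[j]
        if (length(others) >= 2) {
          pred <- interp_extrap(a$age_months[others], y[others],
                                a$age_months[i])
          # endpoints are extrapolated, where the linear-trajectory
          # assumption is weakest (infancy growth is strongly curved); a
          # flag there must be confirmed by the cohort-level band
          extrap <- a$age_months[i] < min(a$age_months[others]) ||
            a$age_months[i] > max(a$age_months[others])
          cls <- .classify_point(y[i], pred, c(cand1[i], cand2[i]), sdr,
                                 rules$outlier_mult, rules$unit_match_mult)
          if (cls != "ok" && extrap && !is.null(bands[[m]])) {
            pred_pop <- bands[[m]]$pred(a$age_months[i])
            sd_pop <- max(1.4826 * bands[[m]]$mad(a$age_months[i]), sdr)
            cls_pop <- .classify_point(y[i], pred_pop,
                                       c(cand1[i], cand2[i]), sd_pop,
                                       rules$outlier_mult,
                                       rules$unit_match_mult)
            if (cls_pop == "ok") cls <- "ok"
          }
          newbad[j] <- cls != "ok"
          if (pass == 2 && cls != "ok") flags[[i]] <- c(flags[[i]], cls)
          next
        } else if (!is.null(bands[[m]])) {
          pred <- bands[[m]]$pred(a$age_months[i])
          sd_pop <- max(1.4826 * bands[[m]]$mad(a$age_months[i]), sdr)
          cls <- .classify_point(y[i], pred, c(cand1[i], cand2[i]), sd_pop,
                                 rules$outlier_mult, rules$unit_match_mult)
          newbad[j] <- cls != "ok"
          if (pass == 2 && cls != "ok") flags[[i]] <- c(flags[[i]], cls)
          next
        } else next
      }
      bad <- newbad
    }
    # 4. within-subject stature shrinkage between consecutive clean visits
    if (m == "length_height") {
      ok_idx <- g[!bad & !hard_bad[g]]
      ok_idx <- ok_idx[a$age_months[ok_idx] < rules$shrink_age_limit]
      if (length(ok_idx) >= 2) {
        dv <- diff(a$value[ok_idx])
        for (j in which(dv < -rules$shrink_cm)) {
          i <- ok_idx[j + 1L]
          flags[[i]] <- c(flags[[i]], "within_subject_jump")
        }
      }
    }
  }

  flag_str <- vapply(flags, function(f) {
    if (is.null(f)) "ok" else paste(sort(unique(f)), collapse = ";")
  }, character(1))
  counts[["implausible"]] <- sum(grepl("implausible", flag_str, fixed = TRUE))
  counts[["unit_swap_suspect"]] <-
    sum(grepl("unit_swap_suspect", flag_str, fixed = TRUE))
  counts[["within_subject_jump"]] <-
    sum(grepl("within_subject_jump", flag_str, fixed = TRUE))
  a$qc_flags <- flag_str

  out <- r
  out$anthropometry <- a
  rep <- new_cleaning_report(
    rules = counts, subject_exclusions = data.frame(
      subject_id = character(), reason = character(),
      stringsAsFactors = FALSE),
    input_n = input_n, retained_n = nrow(a), dropped_n = sum(dup),
    presumed_term = character(),
    retained_by_measure = table(a$measure))
  rep$duplicates <- dup_df
  list(registry = out, report = rep)
}

#' Extract curve-ready measurement points
#'
#' Joins subject sex onto the anthropometry table and (by default) drops
#' points carrying any QC flag, returning the input expected by the curve
#' constructors.
#'
#' @param r An `achondro_registry` (typically after
#'   [apply_growth_exclusions()] and [qc_anthropometry()]).
#' @param sex,measure Optional filters.
#' @param drop_flagged Drop points whose `qc_flags` is not `"ok"`.
#' @return Data frame with columns `subject_id`, `sex`, `measure`,
#'   `age_months`, `value`.
#' @export
curve_points <- function(r, sex = NULL, measure = NULL, drop_flagged = TRUE) {
  a <- r$anthropometry
  a$sex <- r$subjects$sex[match(a$subject_id, r$subjects$subject_id)]
  if (drop_flagged) a <- a[a$qc_flags == "ok", , drop = FALSE]
  if (!is.null(sex)) a <- a[a$sex %in% sex, , drop = FALSE]
  if (!is.null(measure)) a <- a[a$measure %in% measure, , drop = FALSE]
  rownames(a) <- NULL
  a[, c("subject_id", "sex", "measure", "age_months", "value")]
}
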