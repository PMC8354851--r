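# Summary-table engines mirroring the standard natural-history report
# layout: demographics by vital status and activity, characteristics by
# birth decade, anthropometry point counts, surgical burden, sleep
# disordered breathing by decade, and the imaging catalogue.
#
# Every summary is a long table of labelled cells with explicit
# denominators; percentages are always round-half-up(100*count/denominator)
# to one decimal, and "unknown" is an explicit category so counts always
# sum to their denominator.

.cell <- function(stratum, section, label, count = NA, denominator = NA,
                  mean = NA, sd = NA, median = NA, q1 = NA, q3 = NA,
                  min = NA, max = NA) {
  data.frame(stratum = stratum, section = section, label = label,
             count = as.numeric(count), denominator = as.numeric(denominator),
             percent = pct_of(as.numeric(count), as.numeric(denominator)),
             mean = as.numeric(mean), sd = as.numeric(sd),
             median = as.numeric(median), q1 = as.numeric(q1),
             q3 = as.numeric(q3), min = as.numeric(min),
             max = as.numeric(max), stringsAsFactors = FALSE)
}

.count_cells <- function(x, levels, stratum, section, denom = length(x)) {
  do.call(rbind, lapply(levels, function(l)
    .cell(stratum, section, l, count = sum(x == l), denominator = denom)))
}

.stat_cells <- function(x, stratum, section) {
  x <- x[!is.na(x)]
  if (!length(x)) return(.cell(stratum, section, "stats"))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  .cell(stratum, section, "stats", mean = mean(x),
        sd = if (length(x) >= 2) sd(x) else NA, median = q[2], q1 = q[1],
        q3 = q[3], min = min(x), max = max(x))
}

new_cohort_summary <- function(table_id, cells) {
  rownames(cells) <- NULL
  structure(list(table_id = table_id, cells = cells),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %s> (%d cells)\n", x$table_id,
              nrow(x$cells)))
  cat(render_summary(x, "markdown"), sep = "\n")
  invisible(x)
}

# active = living and last encounter on/after the activity cutoff
.active_ids <- function(s, cutoff = as.Date("2017-01-01")) {
  enc <- s$birth_date + round(s$age_last_encounter * 365.2425)
  s$subject_id[s$vital_status == "living" & enc >= cutoff]
}

#' Demographic summary by vital status and activity
#'
#' Sex, age at last encounter, clinical site, inheritance, adoption,
#' gestation, limb lengthening, growth-hormone deficiency/treatment and
#' trial participation, for four strata: the full cohort, living, deceased,
#' and the clinically active subcohort (living subjects whose last
#' encounter is on or after `active_cutoff`).
#'
#' @param r An `achondro_registry`.
#' @param active_cutoff Date defining clinical activity.
#' @return A `cohort_summary` with `table_id = "demographics"`.
#' @export
summarize_demographics <- function(r, active_cutoff = as.Date("2017-01-01")) {
  s <- r$subjects
  strata <- list(total = s,
                 living = s[s$vital_status == "living", , drop = FALSE],
                 deceased = s[s$vital_status == "deceased", , drop = FALSE],
                 active = s[s$subject_id %in%
                              .active_ids(s, active_cutoff), , drop = FALSE])
  cells <- list()
  for (nm in names(strata)) {
    g <- strata[[nm]]
    n <- nrow(g)
    cells[[length(cells) + 1L]] <-
      .cell(nm, "participants", "n", count = n, denominator = n)
    cells[[length(cells) + 1L]] <- .count_cells(g$sex, SEX_LEVELS, nm, "sex",
                                                denom = n)
    cells[[length(cells) + 1L]] <-
      .stat_cells(g$age_last_encounter, nm, "age_last_encounter")
    cells[[length(cells) + 1L]] <- .count_cells(g$site, SITE_LEVELS, nm,
                                                "site", denom = n)
    cells[[length(cells) + 1L]] <-
      .count_cells(g$inheritance, INHERITANCE_LEVELS, nm, "inheritance",
                   denom = n)
    cells[[length(cells) + 1L]] <-
      .count_cells(g$adopted, c("true", "false", "unknown"), nm, "adopted",
                   denom = n)
    cells[[length(cells) + 1L]] <-
      .count_cells(g$gestation, GESTATION_LEVELS, nm, "gestation", denom = n)
    for (fl in c("limb_lengthening", "gh_deficient", "gh_treated",
                 "trial_participant")) {
      cells[[length(cells) + 1L]] <-
        .cell(nm, fl, "true", count = sum(g[[fl]] %in% TRUE),
              denominator = n)
    }
  }
  new_cohort_summary("demographics", do.call(rbind, cells))
}

#' Characteristics by 10-year birth cohort
#'
#' Per-decade (and total) population counts, active and deceased counts,
#' age at last encounter, and diagnosis timing and mode with per-decade
#' denominators.
#'
#' @inheritParams summarize_demographics
#' @return A `cohort_summary` with `table_id = "birth_decade"`.
#' @export
summarize_birth_decades <- function(r,
                                    active_cutoff = as.Date("2017-01-01")) {
  s <- r$subjects
  active <- .active_ids(s, active_cutoff)
  cells <- list()
  for (dec in c(DECADE_LEVELS, "total")) {
    g <- if (dec == "total") s else s[s$birth_decade == dec, , drop = FALSE]
    n <- nrow(g)
    cells[[length(cells) + 1L]] <-
      .cell(dec, "population", "pac", count = n, denominator = nrow(s))
    cells[[length(cells) + 1L]] <-
      .cell(dec, "population", "active",
            count = sum(g$subject_id %in% active), denominator = n)
    cells[[length(cells) + 1L]] <-
      .cell(dec, "population", "deceased",
            count = sum(g$vital_status == "deceased"), denominator = n)
    cells[[length(cells) + 1L]] <-
      .stat_cells(g$age_last_encounter, dec, "age_last_encounter")
    cells[[length(cells) + 1L]] <-
      .count_cells(g$diagnosis_timing, TIMING_LEVELS, dec,
                   "diagnosis_timing", denom = n)
    cells[[length(cells) + 1L]] <-
      .count_cells(g$diagnosis_mode, DXMODE_LEVELS, dec, "diagnosis_mode",
                   denom = n)
  }
  new_cohort_summary("birth_decade", do.call(rbind, cells))
}

.age_band <- function(age_years) {
  ifelse(age_years < 10, "lt10",
         ifelse(age_years < 18, "10to18", "ge18"))
}

#' Anthropometry point counts by measure and age band
#'
#' Cross-tabulates measurement points and contributing subjects by measure
#' and the subject's age at last contact (<10, 10 to <18, >=18 years), with
#' totals and the number of subjects contributing at least one value
#' overall.
#'
#' @param r An `achondro_registry`.
#' @return A `cohort_summary` with `table_id = "anthropometry_counts"`.
#' @export
summarize_anthropometry_counts <- function(r) {
  s <- r$subjects
  a <- r$anthropometry
  band <- setNames(.age_band(s$age_last_encounter), s$subject_id)
  a_band <- band[a$subject_id]
  bands <- c("lt10", "10to18", "ge18")
  cells <- list()
  for (m in c(MEASURE_LEVELS, "total")) {
    am <- if (m == "total") a else a[a$measure == m, , drop = FALSE]
    bm <- if (m == "total") a_band else a_band[a$measure == m]
    for (b in c(bands, "total")) {
      sel <- if (b == "total") rep(TRUE, nrow(am)) else bm == b
      cells[[length(cells) + 1L]] <-
        .cell(b, m, "points", count = sum(sel))
      cells[[length(cells) + 1L]] <-
        .cell(b, m, "subjects",
              count = length(unique(am$subject_id[sel])),
              denominator = nrow(s))
    }
  }
  cells[[length(cells) + 1L]] <-
    .cell("total", "contributors", "subjects_with_any_point",
          count = length(unique(a$subject_id)), denominator = nrow(s))
  new_cohort_summary("anthropometry_counts", do.call(rbind, cells))
}

# achondroplasia-related surgical events that count: the five categories,
# minus PE-tube placements with no recoverable date
.countable_ach_surgeries <- function(su) {
  su <- su[su$category %in% ACH_SURGERY_LEVELS, , drop = FALSE]
  su[!(su$procedure == "pe_tubes" & !su$date_known), , drop = FALSE]
}

#' Surgical burden summary
#'
#' Ever/never/unknown counts for at least one achondroplasia-related
#' surgery (never requires a known surgical history with no events;
#' unknown means unknown history and no events), per-category subject
#' counts and procedure totals, and the distribution of distinct surgical
#' categories per operated subject. The full cohort is the denominator
#' throughout. PE-tube placements without a recorded date are excluded
#' from counting; non-achondroplasia-related surgeries are tallied but
#' never percentaged.
#'
#' @param r An `achondro_registry`.
#' @return A `cohort_summary` with `table_id = "surgical_burden"`.
#' @export
summarize_surgical_burden <- function(r) {
  s <- r$subjects
  n <- nrow(s)
  su <- .countable_ach_surgeries(r$surgeries)
  ever_ids <- unique(su$subject_id)
  known <- setNames(s$surgical_history_known %in% TRUE, s$subject_id)
  ever <- s$subject_id %in% ever_ids
  never <- !ever & known[s$subject_id]
  unknown <- !ever & !known[s$subject_id]
  cells <- list(
    .cell("pac", "any_ach_surgery", "ever", count = sum(ever),
          denominator = n),
    .cell("pac", "any_ach_surgery", "never", count = sum(never),
          denominator = n),
    .cell("pac", "any_ach_surgery", "unknown", count = sum(unknown),
          denominator = n),
    .cell("pac", "any_ach_surgery", "procedures_total", count = nrow(su)))
  for (cat in ACH_SURGERY_LEVELS) {
    sc <- su[su$category == cat, , drop = FALSE]
    cells[[length(cells) + 1L]] <-
      .cell("pac", "category_subjects", cat,
            count = length(unique(sc$subject_id)), denominator = n)
    cells[[length(cells) + 1L]] <-
      .cell("pac", "category_procedures", cat, count = nrow(sc))
  }
  ncat <- if (nrow(su)) tapply(su$category, su$subject_id,
                               function(x) length(unique(x)))
          else integer(0)
  for (k in 1:5) {
    cells[[length(cells) + 1L]] <-
      .cell("pac", "distinct_categories", as.character(k),
            count = sum(ncat == k), denominator = length(ever_ids))
  }
  nonach <- r$surgeries[r$surgeries$category ==
                          "non_achondroplasia_related", , drop = FALSE]
  cells[[length(cells) + 1L]] <-
    .cell("pac", "non_ach_surgery", "procedures_total", count = nrow(nonach))
  cells[[length(cells) + 1L]] <-
    .cell("pac", "non_ach_surgery", "subjects",
          count = length(unique(nonach$subject_id)))
  new_cohort_summary("surgical_burden", do.call(rbind, cells))
}

# subject-level worst OSA grade: definitive outcomes dominate inconclusive
.worst_psg <- function(outcomes) {
  rank <- c(inconclusive = 0, no_osa = 1, mild = 2, moderate = 3,
            severe = 4)
  names(rank)[rank == max(rank[outcomes])][1]
}

#' Sleep disordered breathing by birth decade
#'
#' Per decade (and total): subjects with at least one polysomnogram and
#' the proportion of the decade population, mean and SD of age at first
#' study, and subjects whose worst study-level outcome is moderate or
#' severe OSA as a proportion of those with at least one study.
#'
#' @param r An `achondro_registry`.
#' @return A `cohort_summary` with `table_id = "psg_by_decade"`.
#' @export
summarize_psg <- function(r) {
  s <- r$subjects
  p <- r$psg
  decade <- setNames(s$birth_decade, s$subject_id)
  worst <- tapply(p$outcome, p$subject_id, .worst_psg)
  first_age <- tapply(p$age_at_study, p$subject_id, min)
  psg_ids <- names(first_age)
  cells <- list()
  for (dec in c(DECADE_LEVELS, "total")) {
    ids <- if (dec == "total") s$subject_id else
      s$subject_id[s$birth_decade == dec]
    with_psg <- intersect(ids, psg_ids)
    cells[[length(cells) + 1L]] <-
      .cell(dec, "psg", "subjects_with_psg", count = length(with_psg),
            denominator = length(ids))
    ages <- first_age[with_psg]
    cells[[length(cells) + 1L]] <-
      .cell(dec, "psg", "age_first_psg",
            mean = if (length(ages)) mean(ages) else NA,
            sd = if (length(ages) >= 2) sd(ages) else NA)
    modsev <- sum(worst[with_psg] %in% c("moderate", "severe"))
    cells[[length(cells) + 1L]] <-
      .cell(dec, "psg", "moderate_severe_osa", count = modsev,
            denominator = length(with_psg))
    cells[[length(cells) + 1L]] <-
      .cell(dec, "psg", "studies_total",
            count = sum(p$subject_id %in% ids))
  }
  new_cohort_summary("psg_by_decade", do.call(rbind, cells))
}

#' Imaging catalogue summary
#'
#' Per-modality study counts, the total, the number and proportion of
#' subjects with at least one study, and the proportion of studies with
#' original images available.
#'
#' @param r An `achondro_registry`.
#' @return A `cohort_summary` with `table_id = "imaging_catalogue"`.
#' @export
summarize_imaging <- function(r) {
  im <- r$imaging
  n <- nrow(r$subjects)
  cells <- list()
  for (m in MODALITY_LEVELS) {
    cells[[length(cells) + 1L]] <-
      .cell("pac", "modality", m, count = sum(im$modality == m))
  }
  cells[[length(cells) + 1L]] <-
    .cell("pac", "total", "studies", count = nrow(im))
  cells[[length(cells) + 1L]] <-
    .cell("pac", "total", "subjects_with_imaging",
          count = length(unique(im$subject_id)), denominator = n)
  cells[[length(cells) + 1L]] <-
    .cell("pac", "total", "images_available",
          count = sum(im$images_available %in% TRUE),
          denominator = nrow(im))
  new_cohort_summary("imaging_catalogue", do.call(rbind, cells))
}

#' Look up a summary cell
#'
#' Convenience accessor returning the single cell row matching the given
#' stratum/section/label.
#'
#' @param s A `cohort_summary`.
#' @param stratum,section,label Cell coordinates.
#' @return One-row data frame.
#' @export
summary_cell <- function(s, stratum, section, label) {
  out <- s$cells[s$cells$stratum == stratum & s$cells$section == section &
                   s$cells$label == label, , drop = FALSE]
  abort_if(nrow(out) != 1, "cell (%s, %s, %s) matches %d rows", stratum,
           section, label, nrow(out))
  out
}

#' Render a cohort summary
#'
#' Deterministic text rendering of the cell table: percentages and
#' means/SDs to one decimal in markdown; CSV and JSON carry the full
#' precision. JSON output round-trips through [parse_summary()].
#'
#' @param s A `cohort_summary`.
#' @param fmt `"csv"`, `"markdown"` or `"json"`.
#' @return Character scalar (CSV, JSON) or character vector of lines
#'   (markdown).
#' @export
render_summary <- function(s, fmt = c("markdown", "csv", "json")) {
  fmt <- match.arg(fmt)
  cells <- s$cells
  if (fmt == "json") {
    return(as.character(jsonlite::toJSON(
      list(table_id = jsonlite::unbox(s$table_id), cells = cells),
      dataframe = "rows", na = "null", digits = NA)))
  }
  if (fmt == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    write.csv(cells, con, row.names = FALSE, na = "")
    close(con)
    return(paste(out, collapse = "\n"))
  }
  fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  n_str <- ifelse(is.na(cells$count), "",
                  ifelse(is.na(cells$denominator),
                         sprintf("%d", as.integer(cells$count)),
                         sprintf("%d/%d (%s%%)", as.integer(cells$count),
                                 as.integer(cells$denominator),
                                 fmt1(cells$percent))))
  stat_str <- ifelse(is.na(cells$mean), "",
                     paste0(fmt1(cells$mean),
                            ifelse(is.na(cells$sd), "",
                                   paste0(" +/- ", fmt1(cells$sd)))))
  c(sprintf("## %s", s$table_id),
    "| stratum | section | label | n (%) | value |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |", cells$stratum, cells$section,
            cells$label, n_str, stat_str))
}

#' Parse a JSON-rendered cohort summary
#'
#' @param txt JSON text produced by `render_summary(s, "json")`.
#' @return A `cohort_summary` equal to the rendered one.
#' @export
parse_summary <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  cells <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  for (col in c("count", "denominator", "percent", "mean", "sd", "median",
                "q1", "q3", "min", "max")) {
    cells[[col]] <- if (col %in% names(cells)) as.numeric(cells[[col]])
                    else NA_real_
  }
  for (col in c("stratum", "section", "label"))
    cells[[col]] <- as.character(cells[[col]])
  cells <- cells[, c("stratum", "section", "label", "count", "denominator",
                     "percent", "mean", "sd", "median", "q1", "q3", "min",
                     "max")]
  new_cohort_summary(obj$table_id, cells)
}
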