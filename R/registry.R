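# Registry container: typed tables, invariants, CSV readers/writers.
#
# Five flat tables (subjects, anthropometry, surgeries, psg, imaging) share
# one CSV dialect: UTF-8, comma-separated, header row, RFC-4180 quoting.
# "unknown" is a first-class in-memory category serialized as the empty
# string; dates are ISO-8601; row and column order of serialized files is
# fixed (sorted by subject_id, then age/date) so round trips are bit-exact.

.registry_schemas <- list(
  subjects = c("subject_id", "sex", "birth_date", "site", "vital_status",
               "age_last_encounter", "gestation", "gestational_weeks",
               "inheritance", "adopted", "diagnosis_timing", "diagnosis_mode",
               "limb_lengthening", "gh_deficient", "gh_treated",
               "trial_participant", "surgical_history_known"),
  anthropometry = c("subject_id", "measure", "age_months", "value",
                    "position", "qc_flags"),
  surgeries = c("subject_id", "category", "procedure", "event_date",
                "date_known"),
  psg = c("subject_id", "age_at_study", "outcome", "is_first_study"),
  imaging = c("subject_id", "modality", "study_date", "body_region",
              "images_available")
)

.registry_files <- function(dir) {
  setNames(file.path(dir, paste0(names(.registry_schemas), ".csv")),
           names(.registry_schemas))
}

empty_subjects <- function() {
  data.frame(subject_id = character(), sex = character(),
             birth_date = as.Date(character()), site = character(),
             vital_status = character(), age_last_encounter = numeric(),
             gestation = character(), gestational_weeks = numeric(),
             inheritance = character(), adopted = character(),
             diagnosis_timing = character(), diagnosis_mode = character(),
             limb_lengthening = logical(), gh_deficient = logical(),
             gh_treated = logical(), trial_participant = logical(),
             surgical_history_known = logical(),
             stringsAsFactors = FALSE)
}

empty_anthropometry <- function() {
  data.frame(subject_id = character(), measure = character(),
             age_months = numeric(), value = numeric(),
             position = character(), qc_flags = character(),
             stringsAsFactors = FALSE)
}

empty_surgeries <- function() {
  data.frame(subject_id = character(), category = character(),
             procedure = character(), event_date = as.Date(character()),
             date_known = logical(), stringsAsFactors = FALSE)
}

empty_psg <- function() {
  data.frame(subject_id = character(), age_at_study = numeric(),
             outcome = character(), is_first_study = logical(),
             stringsAsFactors = FALSE)
}

empty_imaging <- function() {
  data.frame(subject_id = character(), modality = character(),
             study_date = as.Date(character()), body_region = character(),
             images_available = logical(), stringsAsFactors = FALSE)
}

#' Construct a validated registry
#'
#' A registry bundles the five tables of a natural-history database plus
#' free-text provenance. All type invariants are enforced at construction:
#' unique subject ids, referential integrity of every child table, valid
#' category levels, positive measurement values, ages within 0--1020 months,
#' and `gestational_weeks < 37` for subjects recorded preterm. The derived
#' `birth_decade` column (boundaries at 1 Jan 1980/1990/2000/2010) is
#' recomputed from `birth_date` and attached to the subjects table.
#'
#' @param subjects,anthropometry,surgeries,psg,imaging Data frames matching
#'   the documented schemas (missing tables default to empty).
#' @param provenance Free-text metadata (source, seed, version).
#' @param validate Set `FALSE` to skip validation (internal use).
#' @return An object of class `achondro_registry`.
#' @seealso [read_registry()], [write_registry()], [validate_registry()]
#' @export
registry <- function(subjects = empty_subjects(),
                     anthropometry = empty_anthropometry(),
                     surgeries = empty_surgeries(),
                     psg = empty_psg(),
                     imaging = empty_imaging(),
                     provenance = "",
                     validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (nrow(subjects)) {
    subjects$birth_decade <- derive_birth_decade(subjects$birth_date)
  } else {
    subjects$birth_decade <- character()
  }
  r <- structure(list(subjects = subjects,
                      anthropometry = as.data.frame(anthropometry),
                      surgeries = as.data.frame(surgeries),
                      psg = as.data.frame(psg),
                      imaging = as.data.frame(imaging),
                      provenance = provenance),
                 class = "achondro_registry")
  if (validate) validate_registry(r)
  r
}

#' Map a birth date to its birth-decade category
#'
#' Decade boundaries are closed on the decade-start date: before
#' 1 Jan 1980 is `pre1980`; 1 Jan 1980--31 Dec 1989 is `d1980s`; analogously
#' for the 1990s and 2000s; on or after 1 Jan 2010 is `post2010`. The
#' partition is exhaustive and mutually exclusive over all dates.
#'
#' @param birth_date `Date` vector (or strings coercible to dates).
#' @return Character vector with values in
#'   `c("pre1980", "d1980s", "d1990s", "d2000s", "post2010")`.
#' @export
#' @examples
#' derive_birth_decade(as.Date(c("1979-12-31", "1990-01-01", "2010-01-01")))
derive_birth_decade <- function(birth_date) {
  d <- as.Date(birth_date)
  y <- as.integer(format(d, "%Y"))
  out <- rep(NA_character_, length(y))
  out[!is.na(y) & y < 1980] <- "pre1980"
  out[!is.na(y) & y >= 1980 & y < 1990] <- "d1980s"
  out[!is.na(y) & y >= 1990 & y < 2000] <- "d1990s"
  out[!is.na(y) & y >= 2000 & y < 2010] <- "d2000s"
  out[!is.na(y) & y >= 2010] <- "post2010"
  out
}

#' List invariant violations of a registry
#'
#' Collects (rather than stops at the first) violation of the registry type
#' invariants; [validate_registry()] turns a non-empty result into an error.
#'
#' @param r An `achondro_registry` (or a bare list with the same shape).
#' @return Character vector of problem descriptions; empty when valid.
#' @export
registry_problems <- function(r) {
  p <- character()
  note <- function(fmt, ...) p[[length(p) + 1L]] <<- sprintf(fmt, ...)

  for (tab in names(.registry_schemas)) {
    missing <- setdiff(.registry_schemas[[tab]], names(r[[tab]]))
    if (length(missing))
      note("schema error: table '%s' lacks column(s): %s", tab,
           paste(missing, collapse = ", "))
  }
  if (length(p)) return(p)

  s <- r$subjects
  if (anyDuplicated(s$subject_id))
    note("duplicate subject_id(s): %s",
         paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "))
  if (any(is.na(s$subject_id) | s$subject_id == ""))
    note("empty subject_id in subjects table")
  chk_enum <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) note("invalid %s value(s): %s", what,
                       paste(unique(x[bad]), collapse = ", "))
  }
  chk_enum(s$sex, SEX_LEVELS, "sex")
  chk_enum(s$site, SITE_LEVELS, "site")
  chk_enum(s$vital_status, VITAL_LEVELS, "vital_status")
  chk_enum(s$gestation, GESTATION_LEVELS, "gestation")
  chk_enum(s$inheritance, INHERITANCE_LEVELS, "inheritance")
  chk_enum(s$adopted, c("true", "false", "unknown"), "adopted")
  chk_enum(s$diagnosis_timing, TIMING_LEVELS, "diagnosis_timing")
  chk_enum(s$diagnosis_mode, DXMODE_LEVELS, "diagnosis_mode")
  if (any(is.na(s$birth_date)))
    note("missing birth_date for subject(s): %s",
         paste(s$subject_id[is.na(s$birth_date)], collapse = ", "))
  if (any(!is.na(s$age_last_encounter) & s$age_last_encounter < 0))
    note("negative age_last_encounter")
  bad_pt <- !is.na(s$gestational_weeks) & s$gestation == "preterm" &
    s$gestational_weeks >= 37
  if (any(bad_pt))
    note("preterm subject(s) with gestational_weeks >= 37: %s",
         paste(s$subject_id[bad_pt], collapse = ", "))

  orphan <- function(tab) {
    ids <- setdiff(r[[tab]]$subject_id, s$subject_id)
    if (length(ids))
      note("referential-integrity error: %s row(s) reference unknown subject_id(s): %s",
           tab, paste(sort(unique(ids)), collapse = ", "))
  }
  for (tab in c("anthropometry", "surgeries", "psg", "imaging")) orphan(tab)

  a <- r$anthropometry
  chk_enum(a$measure, MEASURE_LEVELS, "measure")
  chk_enum(a$position, POSITION_LEVELS, "position")
  if (any(!is.na(a$value) & a$value <= 0)) note("non-positive anthropometry value")
  if (any(is.na(a$age_months) | a$age_months < 0 | a$age_months > 1020))
    note("anthropometry age_months outside [0, 1020]")
  flags <- setdiff(unlist(strsplit(a$qc_flags, ";", fixed = TRUE)),
                   QC_FLAG_LEVELS)
  if (length(flags))
    note("invalid qc flag(s): %s", paste(unique(flags), collapse = ", "))

  chk_enum(r$surgeries$category, SURGERY_LEVELS, "surgery category")
  chk_enum(r$psg$outcome, PSG_LEVELS, "psg outcome")
  if (any(!is.na(r$psg$age_at_study) & r$psg$age_at_study < 0))
    note("negative psg age_at_study")
  chk_enum(r$imaging$modality, MODALITY_LEVELS, "imaging modality")
  p
}

#' Validate a registry, stopping on any invariant violation
#'
#' @param r An `achondro_registry`.
#' @return `r`, invisibly, when valid; otherwise an error listing every
#'   violation (violations are collected, not reported one at a time).
#' @export
validate_registry <- function(r) {
  p <- registry_problems(r)
  abort_if(length(p) > 0, "invalid registry:\n  - %s",
           paste(p, collapse = "\n  - "))
  invisible(r)
}

#' @export
print.achondro_registry <- function(x, ...) {
  cat("<achondro_registry>\n")
  cat(sprintf("  subjects:      %d\n", nrow(x$subjects)))
  cat(sprintf("  anthropometry: %d points\n", nrow(x$anthropometry)))
  cat(sprintf("  surgeries:     %d events\n", nrow(x$surgeries)))
  cat(sprintf("  psg:           %d studies\n", nrow(x$psg)))
  cat(sprintf("  imaging:       %d studies\n", nrow(x$imaging)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  out
}

fmt_lgl <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

fmt_date <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))

fmt_unknown <- function(x) ifelse(is.na(x) | x == "unknown", "", x)

# canonical sort order per table
canonical_registry <- function(r) {
  s <- r$subjects[order(r$subjects$subject_id), , drop = FALSE]
  a <- r$anthropometry
  a <- a[order(a$subject_id, a$measure, a$age_months, a$value), , drop = FALSE]
  su <- r$surgeries
  su <- su[order(su$subject_id, su$category, su$event_date, su$procedure,
                 na.last = TRUE), , drop = FALSE]
  ps <- r$psg[order(r$psg$subject_id, r$psg$age_at_study), , drop = FALSE]
  im <- r$imaging
  im <- im[order(im$subject_id, im$study_date, im$modality, na.last = TRUE),
           , drop = FALSE]
  rownames(s) <- rownames(a) <- rownames(su) <- rownames(ps) <-
    rownames(im) <- NULL
  r$subjects <- s; r$anthropometry <- a; r$surgeries <- su
  r$psg <- ps; r$imaging <- im
  r
}

#' Write a registry to per-table CSV files
#'
#' Serializes the five tables with fixed column order and deterministic row
#' order (subjects by id; anthropometry by id, measure, age; events by id and
#' date), so that writing the same registry twice is byte-identical and
#' `read_registry(write_registry(r))` reproduces an equal registry. Unknown
#' categories and missing dates/values are written as empty strings.
#'
#' @param r A validated `achondro_registry`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_registry <- function(r, dir) {
  validate_registry(r)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r <- canonical_registry(r)
  paths <- .registry_files(dir)

  s <- r$subjects
  out <- data.frame(
    subject_id = s$subject_id,
    sex = s$sex,
    birth_date = fmt_date(s$birth_date),
    site = s$site,
    vital_status = s$vital_status,
    age_last_encounter = fmt_num(s$age_last_encounter),
    gestation = fmt_unknown(s$gestation),
    gestational_weeks = fmt_num(s$gestational_weeks),
    inheritance = fmt_unknown(s$inheritance),
    adopted = fmt_unknown(s$adopted),
    diagnosis_timing = fmt_unknown(s$diagnosis_timing),
    diagnosis_mode = fmt_unknown(s$diagnosis_mode),
    limb_lengthening = fmt_lgl(s$limb_lengthening),
    gh_deficient = fmt_lgl(s$gh_deficient),
    gh_treated = fmt_lgl(s$gh_treated),
    trial_participant = fmt_lgl(s$trial_participant),
    surgical_history_known = fmt_lgl(s$surgical_history_known),
    stringsAsFactors = FALSE)
  write.csv(out, paths[["subjects"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")

  a <- r$anthropometry
  out <- data.frame(subject_id = a$subject_id, measure = a$measure,
                    age_months = fmt_num(a$age_months),
                    value = fmt_num(a$value),
                    position = fmt_unknown(a$position),
                    qc_flags = a$qc_flags, stringsAsFactors = FALSE)
  write.csv(out, paths[["anthropometry"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")

  su <- r$surgeries
  out <- data.frame(subject_id = su$subject_id, category = su$category,
                    procedure = su$procedure,
                    event_date = fmt_date(su$event_date),
                    date_known = fmt_lgl(su$date_known),
                    stringsAsFactors = FALSE)
  write.csv(out, paths[["surgeries"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")

  ps <- r$psg
  out <- data.frame(subject_id = ps$subject_id,
                    age_at_study = fmt_num(ps$age_at_study),
                    outcome = ps$outcome,
                    is_first_study = fmt_lgl(ps$is_first_study),
                    stringsAsFactors = FALSE)
  write.csv(out, paths[["psg"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")

  im <- r$imaging
  out <- data.frame(subject_id = im$subject_id, modality = im$modality,
                    study_date = fmt_date(im$study_date),
                    body_region = im$body_region,
                    images_available = fmt_lgl(im$images_available),
                    stringsAsFactors = FALSE)
  write.csv(out, paths[["imaging"]], row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")

  invisible(paths)
}

as_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
as_lgl <- function(x) ifelse(x == "", NA, x == "true")
as_date <- function(x) {
  x[x == ""] <- NA_character_
  as.Date(x)
}
as_unknown <- function(x) {
  x[x == ""] <- "unknown"
  x
}

read_table_checked <- function(path, tab) {
  abort_if(!file.exists(path), "registry file does not exist: %s", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  missing <- setdiff(.registry_schemas[[tab]], names(df))
  abort_if(length(missing) > 0,
           "schema error in %s: missing required column(s): %s", path,
           paste(missing, collapse = ", "))
  df[, .registry_schemas[[tab]], drop = FALSE]
}

#' Read a registry from per-table CSV files
#'
#' @param path Either a directory containing `subjects.csv`,
#'   `anthropometry.csv`, `surgeries.csv`, `psg.csv` and `imaging.csv`, or a
#'   named character vector of the five file paths.
#' @param provenance Optional provenance string to attach.
#' @return A validated `achondro_registry`. Schema problems (missing
#'   columns) and invariant violations (including orphan child rows, named
#'   by subject id) are raised as errors listing every violation.
#' @export
read_registry <- function(path, provenance = "") {
  if (length(path) == 1L && dir.exists(path)) {
    paths <- .registry_files(path)
    if (provenance == "") provenance <- paste0("read from ", path)
  } else {
    abort_if(!all(names(.registry_schemas) %in% names(path)),
             "path must be a directory or a named vector with entries: %s",
             paste(names(.registry_schemas), collapse = ", "))
    paths <- path
  }

  s <- read_table_checked(paths[["subjects"]], "subjects")
  subjects <- data.frame(
    subject_id = s$subject_id, sex = s$sex,
    birth_date = as_date(s$birth_date), site = s$site,
    vital_status = s$vital_status,
    age_last_encounter = as_num(s$age_last_encounter),
    gestation = as_unknown(s$gestation),
    gestational_weeks = as_num(s$gestational_weeks),
    inheritance = as_unknown(s$inheritance),
    adopted = as_unknown(s$adopted),
    diagnosis_timing = as_unknown(s$diagnosis_timing),
    diagnosis_mode = as_unknown(s$diagnosis_mode),
    limb_lengthening = as_lgl(s$limb_lengthening),
    gh_deficient = as_lgl(s$gh_deficient),
    gh_treated = as_lgl(s$gh_treated),
    trial_participant = as_lgl(s$trial_participant),
    surgical_history_known = as_lgl(s$surgical_history_known),
    stringsAsFactors = FALSE)

  a <- read_table_checked(paths[["anthropometry"]], "anthropometry")
  anthropometry <- data.frame(
    subject_id = a$subject_id, measure = a$measure,
    age_months = as_num(a$age_months), value = as_num(a$value),
    position = as_unknown(a$position),
    qc_flags = {
      f <- a$qc_flags
      f[f == ""] <- "ok"
      f
    },
    stringsAsFactors = FALSE)

  su <- read_table_checked(paths[["surgeries"]], "surgeries")
  surgeries <- data.frame(
    subject_id = su$subject_id, category = su$category,
    procedure = su$procedure, event_date = as_date(su$event_date),
    date_known = as_lgl(su$date_known), stringsAsFactors = FALSE)

  ps <- read_table_checked(paths[["psg"]], "psg")
  psg <- data.frame(subject_id = ps$subject_id,
                    age_at_study = as_num(ps$age_at_study),
                    outcome = ps$outcome,
                    is_first_study = as_lgl(ps$is_first_study),
                    stringsAsFactors = FALSE)

  im <- read_table_checked(paths[["imaging"]], "imaging")
  imaging <- data.frame(subject_id = im$subject_id, modality = im$modality,
                        study_date = as_date(im$study_date),
                        body_region = im$body_region,
                        images_available = as_lgl(im$images_available),
                        stringsAsFactors = FALSE)

  registry(subjects, anthropometry, surgeries, psg, imaging,
           provenance = provenance)
}
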