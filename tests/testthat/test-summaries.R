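test_that("half-up rounding reproduces printed percentage arithmetic", {
  expect_equal(round_half_up(100 * 594 / 1094), 54.3)
  expect_equal(round_half_up(100 * 174 / 1374), 12.7)
  expect_equal(round_half_up(79.62), 79.6)
  expect_equal(round_half_up(0.15, 1), 0.2)   # ties go up
  expect_equal(round_half_up(20.25, 1), 20.3)
})

test_that("demographic summary equals an independent tally oracle", {
  set.seed(61)
  for (seed in c(1, 2)) {
    r <- generate_cohort(cohort_config(n_subjects = 60, seed = seed))
    s <- r$subjects
    dem <- summarize_demographics(r)
    # oracle: table() on the raw subjects frame
    tt <- table(factor(s$inheritance, levels = c("de_novo", "inherited",
                                                 "unknown")))
    for (lv in names(tt)) {
      cell <- summary_cell(dem, "total", "inheritance", lv)
      expect_equal(cell$count, unname(as.numeric(tt[lv])))
      expect_equal(cell$denominator, nrow(s))
      expect_equal(cell$percent,
                   floor(1000 * tt[[lv]] / nrow(s) + 0.5 + 1e-8) / 10)
    }
    liv <- summary_cell(dem, "living", "participants", "n")
    expect_equal(liv$count, sum(s$vital_status == "living"))
    ages <- summary_cell(dem, "total", "age_last_encounter", "stats")
    expect_equal(ages$mean, mean(s$age_last_encounter))
    expect_equal(ages$median, median(s$age_last_encounter))
  }
})

test_that("single-subject registry gives only 0 or 100 percentages", {
  r <- registry(make_subjects(1))
  dem <- summarize_demographics(r)
  pcts <- dem$cells$percent
  expect_true(all(is.na(pcts) | pcts %in% c(0, 100)))
})

test_that("decade summary handles empty decades without division errors", {
  s <- make_subjects(3, birth_date = as.Date(c("1975-05-01", "1975-06-01",
                                               "2012-01-15")))
  bd <- summarize_birth_decades(registry(s))
  empty <- summary_cell(bd, "d1990s", "population", "pac")
  expect_equal(empty$count, 0)
  pre <- summary_cell(bd, "pre1980", "population", "pac")
  expect_equal(pre$count, 2)
  tim <- summary_cell(bd, "d1990s", "diagnosis_timing", "prenatal")
  expect_true(is.na(tim$percent))  # 0/0, not an error
})

test_that("anthropometry counts cross-tabulate points and contributors", {
  s <- make_subjects(4, age_last_encounter = c(5, 12, 30, 40))
  a <- rbind(
    make_anthro(s$subject_id[1], "length_height", c(6, 12, 18), 60),
    make_anthro(s$subject_id[2], "weight", c(100, 120), 30),
    make_anthro(s$subject_id[3], "length_height", 300, 125))
  # subject 4 contributes nothing
  sm <- summarize_anthropometry_counts(registry(s, anthropometry = a))
  expect_equal(summary_cell(sm, "lt10", "length_height", "points")$count, 3)
  expect_equal(summary_cell(sm, "lt10", "length_height", "subjects")$count, 1)
  expect_equal(summary_cell(sm, "10to18", "weight", "points")$count, 2)
  expect_equal(summary_cell(sm, "ge18", "length_height", "points")$count, 1)
  expect_equal(summary_cell(sm, "total", "total", "points")$count, 6)
  expect_equal(
    summary_cell(sm, "total", "contributors", "subjects_with_any_point")$count,
    3)
})

test_that("surgical burden counts subjects once per category", {
  s <- make_subjects(3)
  mk_ev <- function(sid, cat, n) data.frame(
    subject_id = sid, category = cat, procedure = "osteotomy",
    event_date = as.Date("2010-01-01"), date_known = TRUE,
    stringsAsFactors = FALSE)[rep(1, n), ]
  su <- rbind(
    do.call(rbind, lapply(c("ent", "brain", "foramen_magnum", "spine",
                            "extremity"),
                          function(cat) mk_ev(s$subject_id[1], cat, 2))),
    mk_ev(s$subject_id[2], "ent", 3))
  s$surgical_history_known <- c(TRUE, TRUE, FALSE)
  sm <- summarize_surgical_burden(registry(s, surgeries = su))
  expect_equal(summary_cell(sm, "pac", "any_ach_surgery", "ever")$count, 2)
  expect_equal(summary_cell(sm, "pac", "any_ach_surgery", "unknown")$count, 1)
  expect_equal(summary_cell(sm, "pac", "category_subjects", "ent")$count, 2)
  expect_equal(summary_cell(sm, "pac", "category_procedures", "ent")$count, 5)
  # all-five-categories subject lands once in the "5 categories" bin
  expect_equal(summary_cell(sm, "pac", "distinct_categories", "5")$count, 1)
  expect_equal(summary_cell(sm, "pac", "distinct_categories", "1")$count, 1)
  expect_equal(
    summary_cell(sm, "pac", "any_ach_surgery", "procedures_total")$count, 13)
})

test_that("undated PE tubes are excluded from surgical counting", {
  s <- make_subjects(1)
  su <- data.frame(subject_id = s$subject_id,
                   category = "ent", procedure = "pe_tubes",
                   event_date = as.Date(NA), date_known = FALSE,
                   stringsAsFactors = FALSE)
  sm <- summarize_surgical_burden(registry(s, surgeries = su))
  expect_equal(summary_cell(sm, "pac", "any_ach_surgery", "ever")$count, 0)
  expect_equal(summary_cell(sm, "pac", "any_ach_surgery", "never")$count, 1)
})

test_that("PSG summary uses the worst-outcome rule per subject", {
  s <- make_subjects(3, birth_date = as.Date("1985-03-01"))
  p <- data.frame(
    subject_id = s$subject_id[c(1, 1, 2, 3)],
    age_at_study = c(4, 6, 3, 5),
    outcome = c("mild", "severe", "no_osa", "inconclusive"),
    is_first_study = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  sm <- summarize_psg(registry(s, psg = p))
  # subject 1: mild then severe -> severe (moderate/severe count = 1)
  expect_equal(
    summary_cell(sm, "d1980s", "psg", "moderate_severe_osa")$count, 1)
  expect_equal(
    summary_cell(sm, "d1980s", "psg", "subjects_with_psg")$count, 3)
  expect_equal(summary_cell(sm, "d1980s", "psg", "age_first_psg")$mean,
               mean(c(4, 3, 5)))
  expect_equal(summary_cell(sm, "total", "psg", "studies_total")$count, 4)
})

test_that("imaging catalogue tallies match a table() oracle", {
  r <- generate_cohort(cohort_config(n_subjects = 50, seed = 23))
  sm <- summarize_imaging(r)
  tt <- table(factor(r$imaging$modality,
                     levels = c("xray", "ct", "mri", "echocardiogram",
                                "ultrasound")))
  for (m in names(tt)) {
    expect_equal(summary_cell(sm, "pac", "modality", m)$count,
                 unname(as.numeric(tt[m])))
  }
  expect_equal(summary_cell(sm, "pac", "total", "studies")$count,
               nrow(r$imaging))
  expect_equal(
    summary_cell(sm, "pac", "total", "subjects_with_imaging")$count,
    length(unique(r$imaging$subject_id)))
})

test_that("summaries render deterministically and JSON round-trips", {
  r <- generate_cohort(cohort_config(n_subjects = 25, seed = 29))
  sm <- summarize_demographics(r)
  js <- render_summary(sm, "json")
  sm2 <- parse_summary(js)
  expect_equal(sm2$table_id, sm$table_id)
  expect_equal(sm2$cells, sm$cells, tolerance = 1e-12)
  md <- render_summary(sm, "markdown")
  expect_true(any(grepl("^\\| total \\| sex \\| male", md)))
  # rounding contract in the rendered text: 79.62% prints as 79.6
  cells <- sm$cells
  csv <- render_summary(sm, "csv")
  expect_match(csv, "stratum")
})
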