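test_that("growth exclusions follow the stated rules", {
  s <- make_subjects(4)
  s$gestation <- c("term", "preterm", "term", "term")
  s$gestational_weeks <- c(39, 33, 40, 39)
  s$trial_participant <- c(FALSE, FALSE, TRUE, FALSE)
  s$gh_deficient <- c(FALSE, FALSE, FALSE, TRUE)  # deficient, NOT treated
  a <- rbind(
    make_anthro(s$subject_id[1], "length_height", seq(2, 20, 2), 60),
    make_anthro(s$subject_id[2], "length_height", c(12, 24, 30), 70),
    make_anthro(s$subject_id[3], "length_height", 1:8 * 10, 80),
    make_anthro(s$subject_id[4], "length_height", c(6, 30), 65))
  r <- registry(s, anthropometry = a)
  out <- apply_growth_exclusions(r)
  kept <- out$registry$anthropometry

  # term subject: all 10 points retained
  expect_equal(sum(kept$subject_id == s$subject_id[1]), 10)
  # preterm: point at 12 months dropped, 24-month boundary point kept
  pre <- kept[kept$subject_id == s$subject_id[2], ]
  expect_equal(sort(pre$age_months), c(24, 30))
  # trial participant: nothing retained, reason recorded
  expect_equal(sum(kept$subject_id == s$subject_id[3]), 0)
  excl <- out$report$subject_exclusions
  expect_equal(excl$reason[excl$subject_id == s$subject_id[3]], "trial")
  # GH deficiency without treatment does NOT exclude
  expect_equal(sum(kept$subject_id == s$subject_id[4]), 2)
  # conservation and idempotence
  expect_equal(out$report$retained_n + out$report$dropped_n,
               out$report$input_n)
  again <- apply_growth_exclusions(out$registry)
  expect_equal(again$registry$anthropometry, kept)
  expect_equal(again$report$dropped_n, 0)
})

test_that("presumed-term rule uses the published birth reference", {
  s <- make_subjects(1, sex = "female", gestation = "unknown",
                     gestational_weeks = NA_real_)
  # 47.3 cm vs 47.28 +/- 2*2.85 -> term
  expect_equal(
    presume_term(s, data.frame(measure = "length_height", value = 47.3)),
    "term")
  # 40.0 < 47.28 - 5.70 -> stays unknown
  expect_equal(
    presume_term(s, data.frame(measure = "length_height", value = 40.0)),
    "unknown")
  # no birth measurement -> stays unknown
  expect_equal(presume_term(s, NULL), "unknown")
  # conjunctive over measures: one out-of-band measure blocks presumption
  expect_equal(
    presume_term(s, data.frame(measure = c("length_height", "weight"),
                               value = c(47.3, 5.0))),
    "unknown")
})

test_that("unknown gestation is resolved from birth points inside exclusions", {
  s <- make_subjects(2, sex = "female", gestation = "unknown",
                     gestational_weeks = NA_real_)
  a <- rbind(
    make_anthro(s$subject_id[1], "length_height", c(0, 12, 30),
                c(47.3, 61, 72)),
    make_anthro(s$subject_id[2], "length_height", c(0, 12, 30),
                c(39.0, 58, 71)))
  out <- apply_growth_exclusions(registry(s, anthropometry = a))
  kept <- out$registry$anthropometry
  # presumed-term subject keeps infancy points
  expect_equal(sum(kept$subject_id == s$subject_id[1]), 3)
  # unresolved subject loses points before 24 months
  expect_equal(sort(kept$age_months[kept$subject_id == s$subject_id[2]]), 30)
  expect_equal(out$report$presumed_term, s$subject_id[1])
})

test_that("QC collapses duplicates and flags unit swaps and outliers", {
  s <- make_subjects(1)
  ages <- c(6, 12, 18, 24, 30, 36)
  vals <- c(62, 70, 76, 81, 85, 89)
  a <- make_anthro(s$subject_id, "length_height", ages, vals)
  a$value[6] <- 35  # 35 in = 88.9 cm: child tracking ~89 cm
  a <- rbind(a, a[3, ])  # exact duplicate
  out <- qc_anthropometry(registry(s, anthropometry = a))
  aa <- out$registry$anthropometry
  expect_equal(out$report$rules[["duplicate"]], 1)
  expect_equal(nrow(aa), 6)
  expect_match(aa$qc_flags[aa$age_months == 36], "unit_swap_suspect")
  expect_true(all(aa$qc_flags[aa$age_months < 36] == "ok"))
  # conservation: retained + dropped = input
  expect_equal(out$report$retained_n + out$report$dropped_n,
               out$report$input_n)
})

test_that("hard physiologic bounds and stature shrinkage are flagged", {
  s <- make_subjects(1)
  a <- rbind(
    make_anthro(s$subject_id, "length_height", c(12, 24, 36, 48),
                c(70, 80, 77, 82)),      # 3 cm shrink at 36 mo
    make_anthro(s$subject_id, "ofc", c(6, 12), c(15, 46)))  # 15 < 20 cm
  out <- qc_anthropometry(registry(s, anthropometry = a))
  aa <- out$registry$anthropometry
  expect_match(aa$qc_flags[aa$measure == "ofc" & aa$age_months == 6],
               "implausible")
  expect_match(aa$qc_flags[aa$measure == "length_height" &
                             aa$age_months == 36], "within_subject_jump")
})

test_that("no point is flagged on the noiseless clean limit", {
  r <- generate_cohort(noiseless_cfg(n = 25, seed = 13))
  out <- qc_anthropometry(r)
  expect_equal(sum(out$registry$anthropometry$qc_flags != "ok"), 0)
  expect_equal(out$report$dropped_n, 0)
})

test_that("QC recall on injected corruptions exceeds 0.9", {
  r <- generate_cohort(cohort_config(n_subjects = 40, seed = 17))
  inj <- inject_errors(r, seed = 99)
  out <- qc_anthropometry(inj$registry)
  aa <- out$registry$anthropometry
  dup_removed <- out$report$duplicates
  caught <- vapply(seq_len(nrow(inj$ledger)), function(i) {
    led <- inj$ledger[i, ]
    if (led$kind == "duplicate") {
      return(any(dup_removed$subject_id == led$subject_id &
                   dup_removed$measure == led$measure &
                   dup_removed$age_months == led$age_months))
    }
    any(aa$subject_id == led$subject_id & aa$measure == led$measure &
          aa$age_months == led$age_months & aa$qc_flags != "ok")
  }, logical(1))
  expect_gt(mean(caught), 0.9)
})
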