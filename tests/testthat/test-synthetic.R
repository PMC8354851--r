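test_that("generator is deterministic and subject streams are n-invariant", {
  cfg <- cohort_config(n_subjects = 40, seed = 9)
  r1 <- generate_cohort(cfg)
  r2 <- generate_cohort(cfg)
  expect_identical(r1$subjects, r2$subjects)
  expect_identical(r1$anthropometry, r2$anthropometry)
  expect_identical(r1$surgeries, r2$surgeries)
  expect_identical(r1$psg, r2$psg)
  expect_identical(r1$imaging, r2$imaging)

  # subject k's data do not depend on cohort size
  r3 <- generate_cohort(cohort_config(n_subjects = 20, seed = 9))
  for (tab in c("subjects", "anthropometry", "psg")) {
    a <- r1[[tab]][r1[[tab]]$subject_id == "S00007", , drop = FALSE]
    b <- r3[[tab]][r3[[tab]]$subject_id == "S00007", , drop = FALSE]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, label = paste(tab, "of S00007"))
  }
})

test_that("n = 0 yields an empty registry; invalid configs are rejected", {
  r <- generate_cohort(cohort_config(n_subjects = 0, seed = 1))
  expect_equal(nrow(r$subjects), 0)
  expect_equal(nrow(r$anthropometry), 0)
  expect_error(cohort_config(n_subjects = -1), "non-negative")
  expect_error(cohort_config(de_novo_rate = 1.2), "probabilities")
  expect_error(cohort_config(decade_weights = c(-1, 1, 1, 1, 1)),
               "decade_weights")
})

test_that("categorical rates converge to the configured defaults", {
  r <- generate_cohort(cohort_config(n_subjects = 2000, seed = 3))
  s <- r$subjects
  n <- nrow(s)
  # binomial 3-SE bands around the configured rates
  band <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(s$inheritance == "de_novo") - 0.76), band(0.76))
  expect_lt(abs(mean(s$sex == "male") - 0.512), band(0.512))
  expect_lt(abs(mean(s$gestation == "preterm") - 0.127), band(0.127))
  expect_lt(abs(mean(s$surgical_history_known) - (1 - 113 / 1374)),
            band(113 / 1374))
})

test_that("noiseless trajectories equal the median curve exactly", {
  gp <- default_growth_params("female")
  ages <- c(0, 3, 12, 60, 120, 216)
  for (m in c("length_height", "weight", "ofc")) {
    v <- sample_trajectory(gp, m, ages, subject_effect = 1.7,
                           noise_scale = 0)
    expect_equal(v, growth_median(gp, m, ages), tolerance = 1e-12)
  }
  expect_error(sample_trajectory(gp, "weight", c(5, 3)), "sorted")
})

test_that("trajectory moments match the model at a fixed age (CLT check)", {
  gp <- default_growth_params("male")
  set.seed(77)
  n <- 10000
  v <- vapply(seq_len(n), function(i)
    sample_trajectory(gp, "length_height", 0, subject_effect = rnorm(1)),
    numeric(1))
  # mean within 3 SE, SD within 3 SE of the configured birth moments
  expect_lt(abs(mean(v) - 47.90), 3 * 3.18 / sqrt(n))
  expect_lt(abs(sd(v) - 3.18), 3 * 3.18 / sqrt(2 * (n - 1)))
  lw <- vapply(seq_len(n), function(i)
    log(sample_trajectory(gp, "weight", 0, subject_effect = rnorm(1))),
    numeric(1))
  expect_lt(abs(sd(lw) - 0.145), 3 * 0.145 / sqrt(2 * (n - 1)))
})

test_that("median curves are non-decreasing and anchored at birth", {
  ages <- seq(0, 252, by = 0.5)
  for (sx in c("male", "female")) {
    gp <- default_growth_params(sx)
    for (m in c("length_height", "weight", "ofc")) {
      med <- growth_median(gp, m, ages)
      expect_true(all(diff(med) >= -1e-9), label = paste(sx, m))
      expect_true(all(growth_sd(gp, m, ages) > 0))
    }
    expect_equal(growth_median(gp, "length_height", 0), gp$stature$birth)
    expect_equal(growth_median(gp, "ofc", 0), gp$ofc$birth)
    expect_equal(growth_median(gp, "weight", 0), gp$weight$birth)
    # stature velocity is zero at and beyond the plateau age
    expect_equal(stature_velocity(gp, gp$stature$plateau_age + c(0, 24)),
                 c(0, 0))
  }
})

test_that("90% of the OFC gain is attained at ln(10)/k on the median curve", {
  gp <- default_growth_params("male")
  k <- gp$ofc$k
  t90 <- log(10) / k
  gain_frac <- (growth_median(gp, "ofc", t90) - gp$ofc$birth) / gp$ofc$gain
  expect_equal(gain_frac, 0.9, tolerance = 1e-10)
  # and 90% of the plateau *value* is attained at the configured age
  plateau <- gp$ofc$birth + gp$ofc$gain
  t_attain <- gp$ofc$attain_months
  expect_equal(growth_median(gp, "ofc", t_attain), 0.9 * plateau,
               tolerance = 1e-10)
})

test_that("inject_errors keeps a faithful ledger", {
  r <- generate_cohort(cohort_config(n_subjects = 10, seed = 21))
  n0 <- nrow(r$anthropometry)

  none <- inject_errors(r, c(unit_swap = 0, duplicate = 0, implausible = 0))
  expect_equal(nrow(none$ledger), 0)
  expect_identical(none$registry$anthropometry, r$anthropometry)

  # duplicate rate 1 doubles the table and ledgers every row
  small <- r
  small$anthropometry <- r$anthropometry[1:10, ]
  small$psg <- small$psg[0, ]; small$surgeries <- small$surgeries[0, ]
  small$imaging <- small$imaging[0, ]
  dup <- inject_errors(small, c(unit_swap = 0, duplicate = 1,
                                implausible = 0), seed = 2)
  expect_equal(nrow(dup$ledger), 10)
  expect_equal(nrow(dup$registry$anthropometry), 20)
  expect_true(all(dup$ledger$kind == "duplicate"))

  # binomial ledger size at 5% corruption
  err <- inject_errors(r, seed = 8)
  p <- 0.05
  expect_lt(abs(nrow(err$ledger) - n0 * p), 3 * sqrt(n0 * p * (1 - p)) + 1)
  # corrupted values really differ for non-duplicates
  ch <- err$ledger[err$ledger$kind != "duplicate", ]
  expect_true(all(abs(ch$corrupted_value - ch$original_value) > 0.1))
})
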