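test_that("age windows match the banding rule", {
  expect_equal(window_for_age(6), c(5.5, 6.5))
  expect_equal(window_for_age(12), c(11.5, 12.5))   # 12 is in the 0-12 band
  expect_equal(window_for_age(12.5), c(11.5, 13.5)) # >12 band
  expect_equal(window_for_age(24), c(23, 25))
  expect_equal(window_for_age(36), c(35, 37))
  expect_equal(window_for_age(48), c(45, 51))
  expect_equal(window_for_age(150), c(144, 156))
  expect_equal(window_for_age(0), c(0, 0.5))        # truncated at 0
  expect_error(window_for_age(300), "outside")
  # every age in [0, 216] maps to exactly one band
  ages <- seq(0, 216, by = 0.25)
  hw <- vapply(ages, function(a) diff(window_for_age(a)) , numeric(1))
  expect_true(all(hw > 0))
})

test_that("empirical percentiles equal the brute-force oracle", {
  # constant window -> all percentiles equal the constant
  pts <- data.frame(age_months = runif(50, 5.6, 6.4), value = 50)
  c1 <- empirical_percentiles(pts, "male", "length_height", grid = 6,
                              min_n = 10)
  expect_equal(unlist(c1[, c("p5", "p50", "p95")], use.names = FALSE),
               c(50, 50, 50))

  # values 0..100 in one window -> p5 = 5, p50 = 50, p95 = 95
  pts <- data.frame(age_months = seq(5.51, 6.49, length.out = 101),
                    value = 0:100)
  c2 <- empirical_percentiles(pts, "male", "length_height", grid = 6,
                              min_n = 10)
  expect_equal(c(c2$p5, c2$p50, c2$p95), c(5, 50, 95))

  # random log-normal sample: exact equality with the oracle at every
  # tested grid age, including the min_n gap behaviour
  set.seed(101)
  pts <- data.frame(age_months = runif(600, 0, 216),
                    value = exp(rnorm(600, 4, 0.3)))
  grid <- c(0, 3, 6, 12, 24, 48, 96, 150, 210)
  cc <- empirical_percentiles(pts, "male", "length_height", grid = grid,
                              min_n = 5)
  for (i in seq_along(grid)) {
    o <- oracle_window_percentiles(pts$age_months, pts$value, grid[i],
                                   min_n = 5)
    expect_equal(cc$n[i], unname(o["n"]))
    expect_equal(cc$p50[i], unname(o["p50"]), tolerance = 1e-12)
    expect_equal(cc$p5[i], unname(o["p5"]), tolerance = 1e-12)
    expect_equal(cc$p95[i], unname(o["p95"]), tolerance = 1e-12)
  }
})

test_that("smoothing interpolates at zero penalty and never crosses", {
  gp <- default_growth_params("female")
  grid <- default_age_grid("length_height")
  smooth_df <- data.frame(
    age_months = grid, n = 50,
    p5 = growth_quantile(gp, "length_height", grid, 0.05),
    p50 = growth_quantile(gp, "length_height", grid, 0.50),
    p95 = growth_quantile(gp, "length_height", grid, 0.95))
  curve <- achondro:::new_percentile_curve(smooth_df, "female",
                                           "length_height", "empirical")
  sm <- smooth_isopleths(curve, lambda = 1e-15)
  expect_lt(max(abs(sm$p50 - curve$p50)), 1e-6)
  expect_lt(max(abs(sm$p5 - curve$p5)), 1e-6)

  # crossing inputs are repaired: p5 <= p50 <= p95 everywhere
  noisy <- curve
  set.seed(4)
  noisy$p5 <- noisy$p5 + rnorm(nrow(noisy), 0, 2)
  noisy$p50 <- noisy$p50 + rnorm(nrow(noisy), 0, 2)
  sm2 <- smooth_isopleths(noisy)
  expect_true(all(sm2$p5 <= sm2$p50 & sm2$p50 <= sm2$p95))
  expect_equal(sm2$method[1], "isopleth_smoothed")
})

test_that("weight splines are segmented, continuous and exact on constants", {
  set.seed(8)
  pts <- data.frame(age_months = runif(4000, 0, 216), value = 12)
  w <- spline_weight_percentiles(pts, "male", min_n = 5)
  est <- !is.na(w$p50)
  expect_true(all(abs(w$p50[est] - 12) < 1e-6))
  expect_lt(attr(w, "blend_gap"), 1e-6)
  expect_equal(unique(w$spline_segment[w$age_months <= 36]), "birth_to_3y")
  expect_equal(unique(w$spline_segment[w$age_months > 36]), "three_to_18y")

  # noiseless log-normal weight model: fitted p50 within 1% of the model
  gp <- default_growth_params("male")
  r <- generate_cohort(noiseless_cfg(n = 120, seed = 19))
  wc <- spline_weight_percentiles(r, "male", min_n = 10)
  est <- !is.na(wc$p50)
  rel <- abs(wc$p50[est] / growth_median(gp, "weight", wc$age_months[est]) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("birth statistics and the CI comparison rule", {
  pts <- data.frame(age_months = rep(0.1, 20), value = 47)
  b <- birth_stats(pts, "female", "length_height", ref_mean = 49.1)
  expect_equal(b$mean, 47)
  expect_equal(c(b$ci_low, b$ci_high), c(47, 47))
  expect_true(b$significantly_different)

  # CI [47.0, 47.5] vs 49.1 -> significant
  set.seed(12)
  v <- rnorm(500, 47.28, 2.85)
  pts <- data.frame(age_months = runif(500, 0, 0.5), value = v)
  b2 <- birth_stats(pts, "female", "length_height", ref_mean = 49.1)
  expect_equal(b2$ci_low, mean(v) - 1.96 * sd(v) / sqrt(500))
  expect_true(b2$significantly_different)

  # n < 2: no SD/CI
  b3 <- birth_stats(data.frame(age_months = 0, value = 47), "f", "weight",
                    3.2)
  expect_true(is.na(b3$sd) && is.na(b3$significantly_different))
})

test_that("birth mean lands within 3 SE of the configured moment (seeded replicates)", {
  hits <- 0L
  reps <- 25
  for (i in seq_len(reps)) {
    r <- generate_cohort(cohort_config(n_subjects = 120, seed = 400 + i,
                                       preterm_rate = 0,
                                       unknown_gestation_rate = 0,
                                       post_term_rate = 0))
    b <- birth_stats(curve_points(r, "female", "length_height"), "female",
                     "length_height", ref_mean = 49.1)
    if (abs(b$mean - 47.28) <= 3 * 2.85 / sqrt(b$n)) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("reference curves evaluate LMS and direct-percentile rows", {
  lms <- as_reference(data.frame(
    sex = "male", measure = "length_height", age_months = c(0, 24),
    kind = "lms", L = 1, M = 50, S = 0.02, p5 = NA, p50 = NA, p95 = NA))
  expect_equal(evaluate_reference(lms, "male", "length_height", 12, 0.5), 50)
  expect_equal(evaluate_reference(lms, "male", "length_height", 0, 0.95),
               50 * (1 + 0.02 * qnorm(0.95)), tolerance = 1e-12)
  expect_equal(round(evaluate_reference(lms, "male", "length_height", 0,
                                        0.95), 3), 51.645)

  # L = 0 branch: M * exp(S z)
  lms0 <- as_reference(data.frame(
    sex = "male", measure = "weight", age_months = c(0, 24), kind = "lms",
    L = 0, M = 10, S = 0.1, p5 = NA, p50 = NA, p95 = NA))
  expect_equal(evaluate_reference(lms0, "male", "weight", 6, 0.95),
               10 * exp(0.1 * qnorm(0.95)))

  pctr <- as_reference(data.frame(
    sex = "female", measure = "length_height", age_months = c(120, 144),
    kind = "pct", L = NA, M = NA, S = NA, p5 = c(60, 64),
    p50 = c(70, 74), p95 = c(80, 84)))
  expect_equal(evaluate_reference(pctr, "female", "length_height", 132, 0.5),
               72)
  expect_error(evaluate_reference(pctr, "female", "length_height", 300, 0.5),
               "outside")
  expect_error(as_reference(data.frame(
    sex = "m", measure = "x", age_months = 0, kind = "lms", L = 1, M = 50,
    S = 0.02, p5 = 1, p50 = 2, p95 = 3)), "exactly one")
})

test_that("synthetic reference round-trips through the CSV dialect", {
  ref <- synthetic_reference(grid = seq(0, 216, by = 6))
  d <- withr::local_tempfile(fileext = ".csv")
  write.csv(ref, d, row.names = FALSE, na = "")
  ref2 <- read_reference(d)
  expect_equal(as.data.frame(ref2), as.data.frame(ref), tolerance = 1e-12)
  # percentile ordering holds everywhere
  expect_true(all(ref$p5 < ref$p50 & ref$p50 < ref$p95))
})
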