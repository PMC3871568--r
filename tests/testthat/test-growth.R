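table1_slopes <- c(0.0057, 0.0182, 0.0096, 0.0297, 0.0134, 0.0195)
table1_vdt <- c(121.6, 38.08, 72.2, 23.34, 51.73, 35.55)
table1_gi <- c(18.95, 74, 33.94, 147.0, 50.36, 81.04)

test_that("exponential fit recovers noiseless parameters exactly", {
  t <- c(0, 30, 60, 90)
  d <- tibble::tibble(t_days = t, volume_mm3 = 0.05 * exp(0.02 * t))
  fit <- fit_exponential(d)
  expect_lt(abs(fit$r - 0.02), 1e-8)
  expect_lt(abs(fit$V0 - 0.05), 1e-8)
  expect_gt(fit$R2, 1 - 1e-10)
  ll <- loglinear_fit(d)
  expect_lt(abs(ll$slope - 0.02), 1e-10)
  expect_lt(abs(exp(ll$intercept) - 0.05), 1e-10)
  expect_equal(ll$R2, 1, tolerance = 1e-10)

  expect_error(fit_exponential(d[1:2, ]),
               class = "murinod_error_insufficient_data")
  bad <- d; bad$volume_mm3[2] <- -1
  expect_error(loglinear_fit(bad), class = "murinod_error_domain")
})

test_that("exponential fit has small bias over simulated noisy cohorts", {
  sims <- simulate_growth_series(n_series = 200, v0 = 0.05, r = 0.02,
                                 times = c(0, 30, 60, 90),
                                 sigma_log = 0.1, seed = 2024)
  fits <- fit_growth_cohort(sims)
  expect_true(all(fits$fitted))
  expect_lt(abs(mean(fits$r_per_day) - 0.02) / 0.02, 0.05)
})

test_that("log-linear slope equals the closed-form OLS solution", {
  set.seed(77)
  for (i in 1:5) {
    t <- sort(runif(6, 0, 120))
    v <- exp(rnorm(6, 0.01 * t - 3, 0.3))
    d <- tibble::tibble(t_days = t, volume_mm3 = v)
    ll <- loglinear_fit(d)
    y <- log(v)
    slope_oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_lt(abs(ll$slope - slope_oracle), 1e-10)
    intercept_oracle <- mean(y) - slope_oracle * mean(t)
    expect_lt(abs(ll$intercept - intercept_oracle), 1e-10)
  }
})

test_that("VDT and GI reproduce the published per-tumor kinetics", {
  expect_equal(vdt_from_rate(log(2)), 1.0, tolerance = 1e-12)
  expect_lt(max(abs(vdt_from_rate(table1_slopes) - table1_vdt)), 0.05)
  expect_equal(gi_from_rate(0), 0, tolerance = 1e-12)
  expect_lt(max(abs(gi_from_rate(table1_slopes) - table1_gi)), 0.1)
  expect_lt(abs(gi_from_rate(0.0182) - 74.0), 0.05)
  expect_equal(gi_from_vdt(30.44), 100, tolerance = 1e-12)
  expect_lt(abs(gi_from_vdt(121.6) - 18.95), 0.05)

  expect_error(vdt_from_rate(-0.01), class = "murinod_error_non_growing")
  expect_error(gi_from_vdt(0), class = "murinod_error_value")
})

test_that("rate, VDT and GI are mutually consistent and monotone", {
  rs <- exp(seq(log(1e-4), log(0.1), length.out = 40))
  expect_equal(gi_from_vdt(vdt_from_rate(rs)), gi_from_rate(rs),
               tolerance = 1e-10)
  expect_true(all(diff(gi_from_rate(rs)) > 0))
  expect_true(all(diff(vdt_from_rate(rs)) < 0))
})

test_that("slope comparison matches the interaction-model brute force", {
  set.seed(31)
  for (i in 1:5) {
    t1 <- sort(runif(5, 0, 100)); t2 <- sort(runif(6, 0, 100))
    d1 <- tibble::tibble(t_days = t1, volume_mm3 = exp(0.015 * t1 + rnorm(5, 0, 0.2)))
    d2 <- tibble::tibble(t_days = t2, volume_mm3 = exp(0.020 * t2 + rnorm(6, 0, 0.2)))
    cmp <- compare_slopes(loglinear_fit(d1), loglinear_fit(d2))
    expect_equal(cmp$df, 5 + 6 - 4)

    # oracle: dummy-coded combined regression with separate intercepts,
    # t test on the interaction term
    comb <- dplyr::bind_rows(dplyr::mutate(d1, g = 0), dplyr::mutate(d2, g = 1))
    lm_int <- lm(log(volume_mm3) ~ t_days + g + t_days:g, data = comb)
    t_oracle <- summary(lm_int)$coefficients["t_days:g", "t value"]
    expect_lt(abs(abs(cmp$statistic) - abs(t_oracle)), 1e-8)
  }

  # identical series vs itself: t = 0, p = 1
  d <- tibble::tibble(t_days = c(0, 20, 40, 60),
                      volume_mm3 = c(0.05, 0.09, 0.13, 0.30))
  self <- compare_slopes(loglinear_fit(d), loglinear_fit(d))
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)

  # symmetry up to the sign of t
  d2 <- tibble::tibble(t_days = c(0, 25, 50, 75),
                       volume_mm3 = c(0.04, 0.1, 0.2, 0.5))
  ab <- compare_slopes(loglinear_fit(d), loglinear_fit(d2))
  ba <- compare_slopes(loglinear_fit(d2), loglinear_fit(d))
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
})

test_that("cohort summary reproduces the published averages", {
  cs <- cohort_summary(tibble::tibble(vdt_days = table1_vdt, gi_pct = table1_gi))
  expect_lt(abs(cs$mean_vdt_days - 57.08), 0.01)
  expect_lt(abs(cs$mean_gi_pct - 67.55), 0.01)
  expect_lt(abs(cs$median_gi_pct - 62.18), 0.01)

  single <- cohort_summary(tibble::tibble(vdt_days = 50, gi_pct = 40))
  expect_equal(single$mean_vdt_days, 50)
  expect_equal(single$median_gi_pct, 40)
  expect_error(cohort_summary(tibble::tibble()),
               class = "murinod_error_empty_input")
})

test_that("cohort driver flags short series instead of dropping them", {
  d <- dplyr::bind_rows(
    simulate_growth_series(1, seed = 4),
    tibble::tibble(tumor_id = "short", t_days = c(0, 21), volume_mm3 = c(0.1, 0.2)))
  kin <- fit_growth_cohort(d)
  expect_equal(nrow(kin), 2)
  expect_false(kin$fitted[kin$tumor_id == "short"])
  expect_true(is.na(kin$vdt_days[kin$tumor_id == "short"]))
  expect_true(kin$fitted[kin$tumor_id != "short"])
})

test_that("tidiers return broom-shaped tibbles", {
  d <- simulate_growth_series(1, seed = 10)
  ef <- fit_exponential(d)
  td <- tidy(ef)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(ef)
  expect_true(all(c("r.squared", "vdt_days", "gi_pct") %in% names(gl)))
  ll <- loglinear_fit(d)
  expect_named(glance(ll), c("r.squared", "n", "slope", "slope_se"))
  expect_s3_class(autoplot(ef), "ggplot")
})
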