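test_that("water turnover is the rate constant times the pool size", {
  expect_equal(water_turnover(0.1, 2000), 200)
  expect_equal(water_turnover(0, 1000), 0)
  # bilinear in kd and tbw
  expect_equal(water_turnover(0.2, 2000), 2 * water_turnover(0.1, 2000))
  expect_equal(water_turnover(0.1, 4000), 2 * water_turnover(0.1, 2000))
  expect_equal(turnover_pct_tbw(200, 2000), 10)
  expect_equal(turnover_pct_tbw(365, 3698), 9.87, tolerance = 5e-3)
  expect_equal(turnover_pct_tbw(0, 3698), 0)
})

test_that("a noise-free synthetic male-sized subject is recovered end to end", {
  cfg <- noise_free_config(n_subjects = 1, n_periods = 1, seed = 2,
                           kd_range = c(0.0987, 0.0987),
                           male_mass_range = c(5553, 5553),
                           fat_fraction_range = c(0.1072, 0.1072))
  cohort <- generate_cohort(cfg)
  expect_equal(cohort$truths$true_tbw, 3698, tolerance = 1e-3)
  res <- run_pipeline(cohort$samples, cohort$doses)
  expect_equal(res$budget$water_turnover, 0.0987 * cohort$truths$true_tbw,
               tolerance = 1e-9)
  expect_equal(round(res$budget$water_turnover), 365)
})

test_that("weather aggregation averages and sums over the 10-day window", {
  days <- seq(as.Date("2015-03-02"), by = "day", length.out = 12)
  w <- tibble::tibble(date = days, tmean = 20, tmax = 20, tmin = 20,
                      dewpoint = 12, precip = 1)
  agg <- aggregate_weather(w, "2015-03-02")
  expect_equal(agg$mean_temp, 20)
  expect_equal(agg$cum_precip, 10) # 10 days, dose day inclusive
  expect_equal(agg$window_end, as.Date("2015-03-11"))

  w2 <- w
  w2$tmean <- c(6:15, 99, 99) # days beyond the window must not leak in
  expect_equal(aggregate_weather(w2, "2015-03-02")$mean_temp, 10.5)
  # order of rows is irrelevant
  w3 <- w2[sample(nrow(w2)), ]
  expect_equal(aggregate_weather(w3, "2015-03-02"),
               aggregate_weather(w2, "2015-03-02"))
})

test_that("missing weather days are reported explicitly", {
  days <- seq(as.Date("2015-03-02"), by = "day", length.out = 10)
  w <- tibble::tibble(date = days[-c(4, 7)], tmean = 20, tmax = 25,
                      tmin = 15, dewpoint = 12, precip = 0)
  expect_error(aggregate_weather(w, "2015-03-02"), "2015-03-05")
  expect_error(aggregate_weather(w, "2015-03-02"), "2015-03-08")
})

test_that("temperature model recovers a null temperature effect", {
  # biological + assay noise but no temperature forcing
  cfg <- simulation_config(n_subjects = 6, n_periods = 6,
                           temp_coefficient = 0, turnover_noise_cv = 0,
                           enrichment_noise_cv = 0, jitter_meanlog = -Inf,
                           seed = 31)
  cohort <- generate_cohort(cfg)
  res <- run_pipeline(cohort$samples, cohort$doses, cohort$weather)
  fit <- fit_temperature_model(res$budget)
  expect_lt(abs(fit$coef_temp), 1e-6)
})

test_that("standardized coefficients are invariant to temperature shifts", {
  cfg <- simulation_config(n_subjects = 6, n_periods = 6, seed = 17)
  cohort <- generate_cohort(cfg)
  res <- run_pipeline(cohort$samples, cohort$doses, cohort$weather)
  f1 <- fit_temperature_model(res$budget)
  shifted <- res$budget
  shifted$mean_temp <- shifted$mean_temp + 10
  f2 <- fit_temperature_model(shifted)
  expect_equal(f1$coef_temp, f2$coef_temp, tolerance = 1e-8)
  expect_equal(f1$coef_mass, f2$coef_mass, tolerance = 1e-8)
  expect_equal(f2$standardization$temp_mean,
               f1$standardization$temp_mean + 10)
})

test_that("temperature model flags singular designs", {
  d <- tibble::tibble(subject_id = "only_one", body_mass = 5000,
                      mean_temp = c(10, 20), water_turnover = c(300, 350))
  expect_error(fit_temperature_model(d), "2 subjects")
  d2 <- tibble::tibble(subject_id = rep(c("a", "b"), each = 3),
                       body_mass = 5000,
                       mean_temp = rep(c(5, 15, 25), 2),
                       water_turnover = runif(6, 200, 400))
  expect_error(fit_temperature_model(d2), "constant predictor")
})

test_that("turnover rises with temperature in a forced synthetic cohort", {
  cfg <- simulation_config(n_subjects = 6, n_periods = 6,
                           temp_coefficient = 0.02, seed = 41)
  cohort <- generate_cohort(cfg)
  res <- run_pipeline(cohort$samples, cohort$doses, cohort$weather)
  b <- res$budget
  warm <- b$water_turnover[b$mean_temp > median(b$mean_temp)]
  cool <- b$water_turnover[b$mean_temp < median(b$mean_temp)]
  # compare within subject-mean-normalized values to remove size effects
  bn <- normalize_to_subject_mean(b, "water_turnover")
  expect_gt(mean(bn$water_turnover[b$mean_temp > median(b$mean_temp)]),
            mean(bn$water_turnover[b$mean_temp < median(b$mean_temp)]))
  fit <- fit_temperature_model(b)
  expect_gt(fit$coef_temp, 0)
  expect_lt(fit$p_temp, 0.05)
})

test_that("subject intercept variance vanishes without heterogeneity", {
  cfg <- simulation_config(n_subjects = 8, n_periods = 6,
                           kd_range = c(0.1, 0.1),
                           male_mass_range = c(4000, 4001),
                           female_mass_range = c(3999, 4000),
                           fat_fraction_range = c(0.1, 0.1),
                           turnover_noise_cv = 0.05, seed = 53)
  cohort <- generate_cohort(cfg)
  res <- run_pipeline(cohort$samples, cohort$doses, cohort$weather)
  fit <- fit_temperature_model(res$budget)
  expect_lt(fit$subject_intercept_sd, 0.5 * fit$residual_sd)
})

test_that("drinking interval scales as critical reserve over net loss", {
  expect_equal(drinking_interval(5815, 427), 1.36, tolerance = 5e-3)
  expect_equal(drinking_interval(1000, 100), 1)
  expect_equal(drinking_interval(1000, 50), 2 * drinking_interval(1000, 100))
  expect_error(drinking_interval(1000, 0))
})
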