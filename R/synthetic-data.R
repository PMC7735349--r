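#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of [generate_cohort()] with defaults that emulate a
#' zoo-based repeated-measures deuterium study: a handful of adult elephants
#' dosed twice a year over three years, blood drawn near 24 h multiples over
#' the following 10 days, and weather recorded daily.
#'
#' Sampling-time jitter (deviation from exact 24 h multiples) is lognormal
#' on minutes with a random sign; the defaults `jitter_meanlog = log(40)`,
#' `jitter_sdlog = 0.95` give a median of 40 min and quartiles near
#' 22.5 / 81 min, a long right tail reaching a few hundred minutes. Set
#' `jitter_meanlog = -Inf` for exact 24 h sampling.
#'
#' Two noise sources are separated: `enrichment_noise_cv` is multiplicative
#' lognormal analytic noise on excess enrichment (isotope assay error),
#' while `turnover_noise_cv` is multiplicative lognormal variation on the
#' per-period depletion rate (day-to-day biological variation in water
#' flux). Set both to 0 for a noise-free cohort.
#'
#' The depletion rate responds to the period's mean air temperature as
#' `kd_effective = true_kd * exp(temp_coefficient * (T - reference_temp))`,
#' with `reference_temp` the midpoint of the seasonal cycle so `true_kd`
#' stays interpretable as the mid-season rate.
#'
#' @param n_subjects,n_periods Cohort dimensions (>= 1).
#' @param sampling_days Nominal post-dose sampling days (24 h multiples).
#' @param jitter_meanlog,jitter_sdlog Lognormal parameters of the jitter
#'   magnitude in minutes.
#' @param enrichment_noise_cv CV of assay noise on excess enrichment.
#' @param turnover_noise_cv CV of biological variation on the per-period
#'   depletion rate.
#' @param baseline_enrichment Background enrichment, ppm 2H of total
#'   hydrogen (155.76 is the ocean-water reference composition).
#' @param dose_rate Grams of labelled water per kg body mass (0.04).
#' @param dose_purity Fraction 2H2O in the dose (0.998).
#' @param temp_coefficient Effect of mean period temperature on the log
#'   depletion rate, per degree C.
#' @param reference_temp Centering temperature, degrees C.
#' @param hydration_ratio TBW : FFM ratio used to derive true TBW from
#'   generated fat-free mass.
#' @param male_mass_range,female_mass_range Body-mass draws (kg) by sex.
#' @param fat_fraction_range True fat fraction draws (0-1).
#' @param kd_range Baseline depletion-rate draws (per day).
#' @param gut_fraction_range,gut_hydration_range Gut-fill mass fraction and
#'   gut-content water fraction draws.
#' @param start_date Date of the first dosing.
#' @param period_spacing_days Days between consecutive dosings; the 182-day
#'   default alternates winter and summer periods.
#' @param seed Integer RNG seed; a fixed seed makes the output
#'   bit-reproducible.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 5, n_periods = 6,
                              sampling_days = c(1, 3, 5, 8, 10),
                              jitter_meanlog = log(40), jitter_sdlog = 0.95,
                              enrichment_noise_cv = 0.002,
                              turnover_noise_cv = 0.05,
                              baseline_enrichment = 155.76,
                              dose_rate = 0.04, dose_purity = 0.998,
                              temp_coefficient = 0.02, reference_temp = 15,
                              hydration_ratio = 0.746,
                              male_mass_range = c(5200, 5800),
                              female_mass_range = c(2600, 4400),
                              fat_fraction_range = c(0.05, 0.18),
                              kd_range = c(0.08, 0.12),
                              gut_fraction_range = c(0.07, 0.17),
                              gut_hydration_range = c(0.80, 0.90),
                              start_date = as.Date("2015-01-15"),
                              period_spacing_days = 182,
                              seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_periods = as.integer(n_periods),
    sampling_days = sampling_days,
    jitter_meanlog = jitter_meanlog, jitter_sdlog = jitter_sdlog,
    enrichment_noise_cv = enrichment_noise_cv,
    turnover_noise_cv = turnover_noise_cv,
    baseline_enrichment = baseline_enrichment,
    dose_rate = dose_rate, dose_purity = dose_purity,
    temp_coefficient = temp_coefficient, reference_temp = reference_temp,
    hydration_ratio = hydration_ratio,
    male_mass_range = male_mass_range, female_mass_range = female_mass_range,
    fat_fraction_range = fat_fraction_range, kd_range = kd_range,
    gut_fraction_range = gut_fraction_range,
    gut_hydration_range = gut_hydration_range,
    start_date = as.Date(start_date),
    period_spacing_days = period_spacing_days,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_subjects >= 1, cfg$n_periods >= 1,
            length(cfg$sampling_days) >= 1, all(cfg$sampling_days > 0),
            cfg$enrichment_noise_cv >= 0, cfg$turnover_noise_cv >= 0,
            cfg$baseline_enrichment > 0,
            cfg$dose_rate > 0, cfg$dose_purity > 0, cfg$dose_purity <= 1,
            cfg$hydration_ratio > 0, cfg$hydration_ratio <= 1,
            all(cfg$kd_range > 0),
            all(cfg$fat_fraction_range >= 0), all(cfg$fat_fraction_range < 1))
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw sampling-time jitter magnitudes
#'
#' Lognormal deviations (minutes) of actual blood-draw times from exact
#' 24 h multiples, as used by [generate_cohort()].
#'
#' @param n Number of draws.
#' @param config A [simulation_config()].
#' @return Positive jitter magnitudes in minutes (0 when
#'   `jitter_meanlog = -Inf`).
#' @export
sample_jitter_minutes <- function(n, config = simulation_config()) {
  if (!is.finite(config$jitter_meanlog)) return(rep(0, n))
  stats::rlnorm(n, config$jitter_meanlog, config$jitter_sdlog)
}

# Multiplicative lognormal noise factors with unit mean and the given CV.
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Smooth seasonal mean temperature (deg C) for a date, mid-latitude cycle
# centred on 15 C with +/-9 C amplitude, coldest mid-January.
.seasonal_tmean <- function(dates, reference_temp = 15) {
  doy <- as.integer(format(dates, "%j"))
  reference_temp - 9 * cos(2 * pi * (doy - 15) / 365.25)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates subjects, dosing records, enrichment time series and daily
#' weather for a repeated deuterium dilution study. For each
#' subject-period the initial excess enrichment is the *exact* tracer-mixing
#' value for the generated dose and true body water, the washout is a single
#' exponential at the temperature-adjusted depletion rate, and assay noise
#' is multiplicative on the excess. Running twice with the same config gives
#' identical tables.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with tibbles `truths`
#'   (per-subject ground truth), `samples` (one row per blood sample),
#'   `doses` (one row per subject-period dosing), `weather` (daily records
#'   covering all measurement windows), plus the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_subjects = 2, n_periods = 2))
#' head(cohort$samples)
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  n <- config$n_subjects
  sex <- rep(c("M", "F", "F"), length.out = n)
  body_mass <- ifelse(
    sex == "M",
    stats::runif(n, config$male_mass_range[1], config$male_mass_range[2]),
    stats::runif(n, config$female_mass_range[1], config$female_mass_range[2])
  )
  fat_fraction <- stats::runif(n, config$fat_fraction_range[1],
                               config$fat_fraction_range[2])
  ffm <- body_mass * (1 - fat_fraction)
  tbw <- config$hydration_ratio * ffm
  if (any(tbw <= 0) || any(tbw > body_mass)) {
    stop("generated TBW must be positive and no larger than body mass",
         call. = FALSE)
  }
  truths <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = sex,
    body_mass = body_mass,
    true_tbw = tbw,
    true_ffm = ffm,
    true_fat_fraction = fat_fraction,
    true_kd = stats::runif(n, config$kd_range[1], config$kd_range[2]),
    temp_coefficient = config$temp_coefficient,
    gut_fill_fraction = stats::runif(n, config$gut_fraction_range[1],
                                     config$gut_fraction_range[2]),
    gut_hydration = stats::runif(n, config$gut_hydration_range[1],
                                 config$gut_hydration_range[2])
  )

  dose_dates <- config$start_date +
    (seq_len(config$n_periods) - 1) * config$period_spacing_days
  period_ids <- sprintf("P%02d", seq_len(config$n_periods))

  # daily weather over the union of the 10-day windows
  weather_days <- sort(unique(do.call(
    c, lapply(dose_dates, function(d) seq(d, d + 9, by = "day"))
  )))
  tmean <- .seasonal_tmean(weather_days, config$reference_temp) +
    stats::rnorm(length(weather_days), 0, 1.5)
  weather <- tibble::tibble(
    date = weather_days,
    tmean = tmean,
    tmax = tmean + 6 + abs(stats::rnorm(length(weather_days), 0, 1)),
    tmin = tmean - 6 - abs(stats::rnorm(length(weather_days), 0, 1)),
    dewpoint = tmean - 4 + stats::rnorm(length(weather_days), 0, 1),
    precip = stats::rbinom(length(weather_days), 1, 0.35) *
      round(stats::rexp(length(weather_days), 1 / 6), 1)
  )
  period_tbar <- vapply(dose_dates, function(d) {
    mean(weather$tmean[weather$date >= d & weather$date <= d + 9])
  }, numeric(1))

  # one subject-period per row, vectorised over the sample dimension below
  n_days <- length(config$sampling_days)
  n_sp <- config$n_periods * n
  sp_subject <- integer(n_sp); sp_period <- integer(n_sp)
  sp_kd_eff <- numeric(n_sp); sp_e0 <- numeric(n_sp)
  sp_baseline_obs <- numeric(n_sp)
  t_days_all <- matrix(0, n_sp, n_days)
  excess_all <- matrix(0, n_sp, n_days)
  row <- 0L
  for (p in seq_len(config$n_periods)) {
    temp_scale <- exp(config$temp_coefficient *
                        (period_tbar[p] - config$reference_temp))
    for (i in seq_len(n)) {
      row <- row + 1L
      sp_subject[row] <- i; sp_period[row] <- p
      dose_mass <- dose_for_mass(truths$body_mass[i], config$dose_rate)
      sp_e0[row] <- mix_excess_enrichment(dose_mass, config$dose_purity,
                                          truths$true_tbw[i],
                                          config$baseline_enrichment)
      sp_kd_eff[row] <- truths$true_kd[i] * temp_scale *
        .mult_noise(1, config$turnover_noise_cv)
      jit_min <- sample_jitter_minutes(n_days, config) *
        sample(c(-1, 1), n_days, replace = TRUE)
      t_days_all[row, ] <- config$sampling_days + jit_min / 1440
      excess_all[row, ] <- sp_e0[row] * exp(-sp_kd_eff[row] * t_days_all[row, ]) *
        .mult_noise(n_days, config$enrichment_noise_cv)
      sp_baseline_obs[row] <- config$baseline_enrichment *
        .mult_noise(1, config$enrichment_noise_cv)
    }
  }
  dose_times <- as.POSIXct(paste(dose_dates[sp_period], "09:00:00"),
                           tz = "UTC")
  doses <- tibble::tibble(
    subject_id = truths$subject_id[sp_subject],
    period_id = period_ids[sp_period],
    dose_time = dose_times,
    dose_mass = dose_for_mass(truths$body_mass[sp_subject], config$dose_rate),
    purity = config$dose_purity,
    body_mass_at_dose = truths$body_mass[sp_subject],
    true_kd_effective = sp_kd_eff
  )
  # interleave the baseline draw (1 h pre-dose) with the post-dose series
  per_sp <- n_days + 1L
  idx <- rep(seq_len(n_sp), each = per_sp)
  within <- rep(seq_len(per_sp), times = n_sp) # 1 = baseline
  t_flat <- as.vector(t(cbind(NA_real_, t_days_all)))
  e_flat <- as.vector(t(cbind(sp_baseline_obs,
                              config$baseline_enrichment + excess_all)))
  samples <- tibble::tibble(
    subject_id = truths$subject_id[sp_subject][idx],
    period_id = period_ids[sp_period][idx],
    sample_time = dose_times[idx] +
      ifelse(within == 1L, -3600, t_flat * 86400),
    time_since_dose = t_flat,
    is_baseline = within == 1L,
    enrichment = e_flat
  )

  out <- list(
    truths = truths,
    samples = samples,
    doses = doses,
    weather = weather,
    config = config
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic deuterium-dilution cohort: %d subjects x %d periods, %d samples\n",
    nrow(x$truths), x$config$n_periods, nrow(x$samples)))
  invisible(x)
}
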