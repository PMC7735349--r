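#' Daily water turnover from washout kinetics
#'
#' The single-pool water flux: depletion rate constant times pool size,
#' `kd * tbw`, in litres per day.
#'
#' @param kd Depletion rate constant, per day (or a `washout_fit`).
#' @param tbw Total body water, litres.
#' @return Litres per day (vectorised).
#' @export
water_turnover <- function(kd, tbw) {
  if (inherits(kd, "washout_fit")) kd <- kd$kd
  stopifnot(all(tbw > 0), all(kd >= 0))
  kd * tbw
}

#' Water turnover as a percentage of the body water pool
#'
#' @param turnover Litres per day.
#' @param tbw Total body water, litres (> 0).
#' @return Percent of TBW turned over per day.
#' @export
turnover_pct_tbw <- function(turnover, tbw) {
  stopifnot(all(tbw > 0))
  100 * turnover / tbw
}

#' Aggregate daily weather over a measurement window
#'
#' Averages daily mean/max/min temperature and dewpoint and sums
#' precipitation over the measurement window: `window_days` calendar days
#' starting at (and including) the dose date.
#'
#' @param weather Tibble with columns `date`, `tmean`, `tmax`, `tmin`,
#'   `dewpoint`, `precip` (one row per day).
#' @param dose_date Date the window opens on.
#' @param window_days Window length in calendar days (default 10).
#' @return One-row tibble: `mean_temp`, `max_temp`, `min_temp`, `dewpoint`,
#'   `cum_precip`, `window_start`, `window_end`.
#' @export
aggregate_weather <- function(weather, dose_date, window_days = 10) {
  stopifnot(all(c("date", "tmean", "tmax", "tmin", "dewpoint", "precip")
                %in% names(weather)))
  dose_date <- as.Date(dose_date)
  days <- seq(dose_date, dose_date + window_days - 1, by = "day")
  missing <- days[!days %in% weather$date]
  if (length(missing) > 0) {
    stop("weather records missing for day(s): ",
         paste(format(missing), collapse = ", "), call. = FALSE)
  }
  w <- weather[weather$date %in% days, ]
  tibble::tibble(
    mean_temp = mean(w$tmean), max_temp = mean(w$tmax),
    min_temp = mean(w$tmin), dewpoint = mean(w$dewpoint),
    cum_precip = sum(w$precip),
    window_start = dose_date, window_end = dose_date + window_days - 1
  )
}

#' Mixed model of log water turnover on body mass and air temperature
#'
#' Fits `log(turnover) ~ z(mass) + z(temp) + (1 | subject)` by REML, with
#' numeric predictors z-transformed using the observation-level mean and SD
#' over all included subject-periods. The mass-by-temperature interaction is
#' fitted first and dropped when not significant at `interaction_alpha`
#' (Satterthwaite degrees of freedom).
#'
#' @param periods Tibble with one row per subject-period and columns
#'   `subject_id`, `body_mass`, `mean_temp`, `water_turnover`.
#' @param interaction_alpha Significance level for retaining the
#'   mass-by-temperature interaction (default 0.05).
#' @return A list of class `temperature_model_fit`: `coef_mass` and
#'   `coef_temp` (per SD of the predictor, on the natural-log turnover
#'   scale), their standard errors, `subject_intercept_sd`, `residual_sd`,
#'   `standardization` (stored means/SDs), `interaction_kept`,
#'   `interaction_p`, and the underlying `model`.
#' @export
fit_temperature_model <- function(periods, interaction_alpha = 0.05) {
  need <- c("subject_id", "body_mass", "mean_temp", "water_turnover")
  stopifnot(all(need %in% names(periods)))
  periods <- periods[stats::complete.cases(periods[need]), ]
  if (length(unique(periods$subject_id)) < 2) {
    stop("need at least 2 subjects to separate subject and fixed effects",
         call. = FALSE)
  }
  if (stats::sd(periods$body_mass) == 0 || stats::sd(periods$mean_temp) == 0) {
    stop("body mass and mean temperature must both vary across ",
         "subject-periods (constant predictor gives a singular design)",
         call. = FALSE)
  }
  std <- list(
    mass_mean = mean(periods$body_mass), mass_sd = stats::sd(periods$body_mass),
    temp_mean = mean(periods$mean_temp), temp_sd = stats::sd(periods$mean_temp)
  )
  d <- data.frame(
    log_turnover = log(periods$water_turnover),
    z_mass = (periods$body_mass - std$mass_mean) / std$mass_sd,
    z_temp = (periods$mean_temp - std$temp_mean) / std$temp_sd,
    subject = factor(periods$subject_id)
  )
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  full <- suppressMessages(suppressWarnings(lmerTest::lmer(
    log_turnover ~ z_mass * z_temp + (1 | subject), data = d,
    REML = TRUE, control = ctrl)))
  ip <- summary(full)$coefficients["z_mass:z_temp", "Pr(>|t|)"]
  interaction_kept <- is.finite(ip) && ip < interaction_alpha
  model <- if (interaction_kept) full else
    suppressMessages(suppressWarnings(lmerTest::lmer(
      log_turnover ~ z_mass + z_temp + (1 | subject), data = d,
      REML = TRUE, control = ctrl)))
  co <- summary(model)$coefficients
  vc <- as.data.frame(lme4::VarCorr(model))
  out <- list(
    coef_mass = co["z_mass", "Estimate"],
    coef_temp = co["z_temp", "Estimate"],
    se_mass = co["z_mass", "Std. Error"],
    se_temp = co["z_temp", "Std. Error"],
    p_mass = co["z_mass", "Pr(>|t|)"],
    p_temp = co["z_temp", "Pr(>|t|)"],
    subject_intercept_sd = vc$sdcor[vc$grp == "subject"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    standardization = std,
    interaction_kept = interaction_kept,
    interaction_p = ip,
    n_obs = nrow(d),
    model = model
  )
  class(out) <- "temperature_model_fit"
  out
}

#' @export
print.temperature_model_fit <- function(x, ...) {
  cat("Mixed model: log(turnover) ~ z(mass) + z(temp) + (1 | subject)\n")
  cat(sprintf("  mass: %+.4f (SE %.4f, p %.3g) per SD\n",
              x$coef_mass, x$se_mass, x$p_mass))
  cat(sprintf("  temp: %+.4f (SE %.4f, p %.3g) per SD\n",
              x$coef_temp, x$se_temp, x$p_temp))
  cat(sprintf("  subject intercept SD %.4f, residual SD %.4f, n = %d\n",
              x$subject_intercept_sd, x$residual_sd, x$n_obs))
  cat(sprintf("  mass x temp interaction %s (p = %.3g)\n",
              if (x$interaction_kept) "kept" else "dropped", x$interaction_p))
  invisible(x)
}

#' Days until a critical fraction of body mass is lost as water
#'
#' With water density 1 kg per litre, the time to lose `critical_fraction`
#' of body mass at a constant net water deficit is
#' `critical_fraction * body_mass / net_daily_loss`. The net loss is the
#' caller's responsibility: gross turnover minus preformed/metabolic water
#' intake, not gross turnover itself.
#'
#' @param body_mass kg.
#' @param net_daily_loss Net water deficit, litres per day (> 0).
#' @param critical_fraction Fraction of body mass considered critical
#'   (default 0.10).
#' @return Days between drinks.
#' @export
drinking_interval <- function(body_mass, net_daily_loss,
                              critical_fraction = 0.10) {
  stopifnot(all(body_mass > 0), all(net_daily_loss > 0),
            critical_fraction > 0)
  critical_fraction * body_mass / net_daily_loss
}
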