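#' Apply the comparative-dataset inclusion rules
#'
#' Retains terrestrial eutherian records not flagged as measured during
#' seasonal energy stress. Bats, aquatic mammals and marsupials are excluded
#' because their water economy or metabolic rate differs systematically from
#' terrestrial eutherians. The per-record decision is attached as the
#' `"retention_log"` attribute.
#'
#' @param species Tibble with columns `species`, `group` (one of
#'   `"terrestrial eutherian"`, `"marsupial"`, `"bat"`, `"aquatic"`),
#'   `seasonal_stress_flag` (logical), `body_mass`, `water_turnover`.
#' @return The retained rows; `attr(, "retention_log")` holds all rows with
#'   `retained` and `reason` columns.
#' @export
filter_species <- function(species) {
  need <- c("species", "group", "seasonal_stress_flag",
            "body_mass", "water_turnover")
  stopifnot(all(need %in% names(species)))
  reason <- dplyr::case_when(
    species$group %in% c("bat", "aquatic") ~ "non-terrestrial",
    species$group == "marsupial" ~ "marsupial",
    species$seasonal_stress_flag ~ "seasonal energy stress",
    TRUE ~ "retained"
  )
  log <- dplyr::mutate(species, retained = reason == "retained",
                       reason = reason)
  out <- species[reason == "retained", ]
  attr(out, "retention_log") <- log
  out
}

#' Fit the log-log allometry of water turnover on body mass
#'
#' Ordinary least squares of log10 water turnover (L/d) on log10 body mass
#' (kg), the standard form for physiological scaling laws.
#'
#' @param species Tibble with positive `body_mass` and `water_turnover`
#'   columns (typically the output of [filter_species()]).
#' @return A list of class `allometric_fit`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `adj_r_squared`, `n`, `model`.
#' @export
fit_allometry <- function(species) {
  stopifnot(all(c("body_mass", "water_turnover") %in% names(species)),
            all(species$body_mass > 0), all(species$water_turnover > 0))
  if (nrow(species) < 3) {
    stop("need at least 3 species records to fit the allometry, got ",
         nrow(species), call. = FALSE)
  }
  d <- data.frame(x = log10(species$body_mass),
                  y = log10(species$water_turnover))
  fit <- stats::lm(y ~ x, data = d)
  # suppressWarnings: summary.lm warns when points lie exactly on a line
  s <- suppressWarnings(summary(fit))
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = s$coefficients["x", "Std. Error"],
    intercept_se = s$coefficients["(Intercept)", "Std. Error"],
    adj_r_squared = s$adj.r.squared,
    n = nrow(d),
    model = fit
  )
  class(out) <- "allometric_fit"
  out
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "log10(turnover) = %.3f (+/-%.3f) log10(mass) %+.3f (+/-%.3f)\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  n = %d, adj R2 = %.3f\n", x$n, x$adj_r_squared))
  invisible(x)
}

#' Percentage deviation of an animal from the allometric line
#'
#' `100 * (turnover / predicted - 1)` where
#' `predicted = 10^(intercept + slope * log10(mass))`.
#'
#' @param mass Body mass in kg (> 0, vectorised).
#' @param turnover Water turnover in litres per day (vectorised).
#' @param fit An `allometric_fit`, or a list/vector with `slope` and
#'   `intercept`.
#' @return Percent above (+) or below (-) the regression line.
#' @export
deviation_percent <- function(mass, turnover, fit) {
  stopifnot(all(mass > 0))
  predicted <- 10^(fit$intercept + fit$slope * log10(mass))
  100 * (turnover / predicted - 1)
}

#' Synthetic comparative species table on a known power law
#'
#' Generates species records scattered around
#' `log10(turnover) = intercept + slope * log10(mass)` with Gaussian noise
#' on the log10 scale, plus optional excluded-group rows (bats, aquatic
#' mammals, marsupials, stress-flagged records) to exercise the inclusion
#' rules. Body masses are log-uniform between 10 g and 10 t, the span of
#' comparative mammal datasets.
#'
#' @param n Number of retained-group records.
#' @param slope,intercept True power-law parameters (defaults near the
#'   fitted terrestrial-mammal line).
#' @param sd_log10 Residual SD on the log10 turnover scale.
#' @param n_excluded Number of additional excluded-group records.
#' @param seed Integer seed.
#' @return A tibble in the [filter_species()] schema.
#' @export
simulate_species_table <- function(n = 40, slope = 0.92, intercept = -0.974,
                                   sd_log10 = 0.12, n_excluded = 6,
                                   seed = 1L) {
  set.seed(seed)
  logm <- stats::runif(n, log10(0.01), log10(10000))
  logt <- intercept + slope * logm + stats::rnorm(n, 0, sd_log10)
  core <- tibble::tibble(
    species = sprintf("eutherian_%02d", seq_len(n)),
    group = "terrestrial eutherian",
    seasonal_stress_flag = FALSE,
    body_mass = 10^logm,
    water_turnover = 10^logt
  )
  if (n_excluded > 0) {
    grp <- rep(c("bat", "aquatic", "marsupial", "terrestrial eutherian"),
               length.out = n_excluded)
    logm2 <- stats::runif(n_excluded, log10(0.01), log10(10000))
    logt2 <- intercept + slope * logm2 + stats::rnorm(n_excluded, 0, sd_log10)
    extra <- tibble::tibble(
      species = sprintf("excluded_%02d", seq_len(n_excluded)),
      group = grp,
      seasonal_stress_flag = grp == "terrestrial eutherian",
      body_mass = 10^logm2,
      water_turnover = 10^logt2
    )
    core <- dplyr::bind_rows(core, extra)
  }
  core
}
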