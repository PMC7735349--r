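# Molar masses (g/mol) used in the tracer mass balance.
MM_H2O <- 18.0153
MM_D2O <- 20.0276

#' Fit a deuterium washout line by the slope-intercept method
#'
#' Regresses the natural log of excess enrichment (enrichment minus the
#' pre-dose baseline) on time since dose by ordinary least squares. The
#' negated slope is the depletion rate constant `kd` (per day) and the
#' exponentiated intercept is the back-extrapolated excess enrichment at the
#' moment of dosing, `e0_excess`.
#'
#' @param time_days Numeric vector of post-dose sampling times in days.
#'   Must be strictly positive and distinct.
#' @param enrichment Numeric vector of measured enrichment (same unit as
#'   `baseline`, conventionally ppm 2H of total hydrogen).
#' @param baseline Pre-dose (background) enrichment, same unit.
#' @param qc_r2_min Minimum R-squared for the fit to pass quality control.
#'   Defaults to 0.99, the low end of R-squared values typically seen for
#'   well-behaved washout series.
#' @param min_time_days Samples earlier than this are excluded as an
#'   equilibration guard. Default 0 (include all post-dose samples).
#'
#' @return A list of class `washout_fit` with elements `e0_excess`, `kd`,
#'   `r_squared`, `n_points`, `qc_pass`, `baseline`.
#' @export
#' @examples
#' # exact two-point exponential: 100 * exp(-0.1 t) above a 150 baseline
#' fit_washout(c(1, 2), c(240.4837, 231.8731), baseline = 150)
fit_washout <- function(time_days, enrichment, baseline,
                        qc_r2_min = 0.99, min_time_days = 0) {
  stopifnot(is.numeric(time_days), is.numeric(enrichment),
            length(time_days) == length(enrichment),
            is.numeric(baseline), length(baseline) == 1)
  keep <- time_days >= min_time_days
  time_days <- time_days[keep]
  enrichment <- enrichment[keep]
  if (any(enrichment <= baseline)) {
    stop("post-dose enrichment at or below baseline for sample(s) ",
         paste(which(enrichment <= baseline), collapse = ", "),
         "; this signals an uningested or partial dose", call. = FALSE)
  }
  if (length(time_days) < 2) {
    stop("need at least 2 usable post-dose samples, got ", length(time_days),
         call. = FALSE)
  }
  if (any(time_days <= 0)) {
    stop("post-dose sampling times must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(time_days)) {
    stop("post-dose sampling times must be distinct", call. = FALSE)
  }
  ln_excess <- log(enrichment - baseline)
  # simple linear regression in closed form (identical to lm())
  tc <- time_days - mean(time_days)
  yc <- ln_excess - mean(ln_excess)
  sxx <- sum(tc^2)
  sxy <- sum(tc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  intercept <- mean(ln_excess) - slope * mean(time_days)
  kd <- -slope
  e0 <- exp(intercept)
  r2 <- if (syy == 0) 1 else min(sxy^2 / (sxx * syy), 1)
  out <- list(
    e0_excess = e0,
    kd = kd,
    r_squared = r2,
    n_points = length(time_days),
    qc_pass = is.finite(kd) && kd > 0 && e0 > 0 && r2 >= qc_r2_min,
    baseline = baseline
  )
  class(out) <- "washout_fit"
  out
}

#' @export
print.washout_fit <- function(x, ...) {
  cat("Washout fit (slope-intercept method)\n")
  cat(sprintf("  e0_excess: %.4f  kd: %.6f /d  R2: %.4f  n: %d  QC: %s\n",
              x$e0_excess, x$kd, x$r_squared, x$n_points,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

# Molar mass of water whose 2H atom fraction is f.
.water_molar_mass <- function(f) f * MM_D2O + (1 - f) * MM_H2O

#' Forward tracer mixing: excess enrichment from a dose into a water pool
#'
#' Exact mass balance for mixing `dose_mass` grams of labelled water
#' (2H atom fraction = `purity`) into `volume_l` litres of body water at the
#' baseline isotopic composition. Water density is taken as 1 kg per litre.
#'
#' @param dose_mass Grams of labelled water administered.
#' @param purity Fraction of the dose that is 2H2O (atom fraction of 2H).
#' @param volume_l Litres of body water before dosing.
#' @param baseline Baseline enrichment in the chosen unit.
#' @param unit_scale Enrichment units per unit atom fraction; 1e6 for ppm
#'   (the default), 1e3 for per mil.
#' @return Excess enrichment (above baseline) in the same unit as `baseline`.
#' @export
mix_excess_enrichment <- function(dose_mass, purity, volume_l, baseline,
                                  unit_scale = 1e6) {
  stopifnot(dose_mass > 0, purity > 0, purity <= 1, volume_l > 0)
  f_b <- baseline / unit_scale
  n_dose <- dose_mass / .water_molar_mass(purity)
  n_body <- 1000 * volume_l / .water_molar_mass(f_b)
  f_post <- (n_dose * purity + n_body * f_b) / (n_dose + n_body)
  (f_post - f_b) * unit_scale
}

#' Dilution space (total body water) from a washout fit and dose record
#'
#' Inverts the tracer mixing mass balance: returns the volume of body water
#' into which the administered 2H must have mixed to produce the
#' back-extrapolated excess enrichment `e0_excess`. This dilution space is
#' the total body water estimate (including gut-content water).
#'
#' @param fit A `washout_fit`, or a plain number taken as `e0_excess`.
#' @param dose_mass Grams of labelled water administered.
#' @param purity Fraction 2H2O in the dose (0.998 for typical stock).
#' @param baseline Baseline enrichment (same unit as the fit).
#' @param unit_scale Enrichment units per unit atom fraction (1e6 = ppm).
#' @param require_qc Refuse fits that failed quality control (default TRUE).
#' @return Body water volume in litres.
#' @export
dilution_space <- function(fit, dose_mass, purity = 0.998, baseline = NULL,
                           unit_scale = 1e6, require_qc = TRUE) {
  if (inherits(fit, "washout_fit")) {
    if (require_qc && !fit$qc_pass) {
      stop("washout fit failed QC; pass require_qc = FALSE to override",
           call. = FALSE)
    }
    e0 <- fit$e0_excess
    if (is.null(baseline)) baseline <- fit$baseline
  } else {
    e0 <- fit
    if (is.null(baseline)) stop("baseline required when fit is a bare number",
                                call. = FALSE)
  }
  if (!is.finite(e0) || e0 <= 0) stop("e0_excess must be positive", call. = FALSE)
  stopifnot(dose_mass > 0, purity > 0, purity <= 1)
  f_b <- baseline / unit_scale
  e <- e0 / unit_scale
  if (purity - f_b - e <= 0) {
    stop("excess enrichment exceeds what the dose can produce", call. = FALSE)
  }
  n_dose <- dose_mass / .water_molar_mass(purity)
  n_body <- n_dose * (purity - f_b - e) / e
  n_body * .water_molar_mass(f_b) / 1000
}

#' Dose mass for a given body mass
#'
#' Labelled-water dose scaled to body mass, default 0.04 g per kg.
#'
#' @param body_mass Body mass in kg (> 0).
#' @param dose_rate Grams of labelled water per kg body mass.
#' @return Dose in grams.
#' @export
#' @examples
#' dose_for_mass(5815) # ~233 g, the scale of an adult male elephant dose
dose_for_mass <- function(body_mass, dose_rate = 0.04) {
  stopifnot(all(body_mass > 0), dose_rate > 0)
  body_mass * dose_rate
}
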