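# CSV plumbing + end-to-end pipeline. Interchange format is plain CSV with
# documented headers, ISO-8601 timestamps (UTC), decimal point, UTF-8.

.samples_cols <- readr::cols(
  subject_id = readr::col_character(),
  period_id = readr::col_character(),
  sample_time = readr::col_datetime(),
  time_since_dose = readr::col_double(),
  is_baseline = readr::col_logical(),
  enrichment = readr::col_double()
)
.doses_cols <- readr::cols(
  subject_id = readr::col_character(),
  period_id = readr::col_character(),
  dose_time = readr::col_datetime(),
  dose_mass = readr::col_double(),
  purity = readr::col_double(),
  body_mass_at_dose = readr::col_double()
)
.weather_cols <- readr::cols(
  date = readr::col_date(),
  tmean = readr::col_double(), tmax = readr::col_double(),
  tmin = readr::col_double(), dewpoint = readr::col_double(),
  precip = readr::col_double()
)

.read_checked <- function(path, spec, what) {
  stopifnot(file.exists(path))
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing <- setdiff(names(spec$cols), names(out))
  if (length(missing) > 0) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read pipeline input tables
#'
#' Readers for the four CSV schemas used throughout the package. Columns are
#' type-checked on load; timestamps are parsed as UTC.
#'
#' @param path CSV file path.
#' @return A tibble in the corresponding schema.
#' @name readers
NULL

#' @rdname readers
#' @export
read_samples <- function(path) .read_checked(path, .samples_cols, "samples")

#' @rdname readers
#' @export
read_doses <- function(path) .read_checked(path, .doses_cols, "doses")

#' @rdname readers
#' @export
read_weather <- function(path) .read_checked(path, .weather_cols, "weather")

#' Write a synthetic cohort to CSV files
#'
#' Writes `samples.csv`, `doses.csv`, `weather.csv` and `truths.csv` into
#' `dir`; the first three are the pipeline's input schema and `truths.csv`
#' carries the generator's ground truth for validation.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    doses = file.path(dir, "doses.csv"),
    weather = file.path(dir, "weather.csv"),
    truths = file.path(dir, "truths.csv")
  )
  readr::write_csv(cohort$samples, paths["samples"], progress = FALSE)
  readr::write_csv(
    cohort$doses[c("subject_id", "period_id", "dose_time", "dose_mass",
                   "purity", "body_mass_at_dose")],
    paths["doses"], progress = FALSE)
  readr::write_csv(cohort$weather, paths["weather"], progress = FALSE)
  readr::write_csv(cohort$truths, paths["truths"], progress = FALSE)
  invisible(paths)
}

#' Load and validate a pipeline configuration
#'
#' Flat key-value YAML; unknown keys are rejected with a warning and
#' dropped. Recognised keys: `samples`, `doses`, `weather` (input paths),
#' `output_dir`, `hydration_ratio`, `dose_rate`, `qc_r2_min`,
#' `min_time_days`, `window_days`, `seed`.
#'
#' @param path YAML file path.
#' @return Named list of settings merged over the defaults.
#' @export
pipeline_config <- function(path) {
  defaults <- list(
    samples = NULL, doses = NULL, weather = NULL, output_dir = NULL,
    hydration_ratio = 0.746, dose_rate = 0.04, qc_r2_min = 0.99,
    min_time_days = 0, window_days = 10, seed = 1L
  )
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    cfg <- cfg[setdiff(names(cfg), unknown)]
  }
  utils::modifyList(defaults, cfg)
}

#' Run the full dilution-to-budget pipeline
#'
#' For every subject-period with a dosing record: fits the washout line,
#' inverts the tracer mass balance to total body water, derives body
#' composition from the scale mass at dosing, computes daily water turnover
#' and aggregates weather over the measurement window. Subject-periods that
#' fail quality control (low R-squared, samples at or below baseline,
#' too few points) are reported in `qc_failures` and the run continues on
#' the rest; samples whose subject-period has no dosing record abort the
#' run with their row numbers.
#'
#' @param samples Samples tibble or CSV path (see [read_samples()]). Each
#'   subject-period needs exactly one row with `is_baseline = TRUE`.
#' @param doses Doses tibble or CSV path.
#' @param weather Optional weather tibble or CSV path; when given, each
#'   period's window is aggregated and merged into the budget table.
#' @param hydration_ratio TBW : FFM conversion ratio.
#' @param qc_r2_min Minimum washout R-squared to pass QC.
#' @param min_time_days Equilibration guard passed to [fit_washout()].
#' @param window_days Weather window length (calendar days from dose date).
#' @param output_dir If non-NULL, writes `compositions.csv`, `budget.csv`,
#'   `fits.csv`, `summary.txt` and `run_log.txt` there.
#' @return A list of class `pipeline_result`: `fits`, `compositions`,
#'   `budget`, `summary` (group means/SDs of turnover by sex when a `sex`
#'   column is present), `qc_failures`, `log`.
#' @export
run_pipeline <- function(samples, doses, weather = NULL,
                         hydration_ratio = 0.746, qc_r2_min = 0.99,
                         min_time_days = 0, window_days = 10,
                         output_dir = NULL) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(doses)) doses <- read_doses(doses)
  if (is.character(weather)) weather <- read_weather(weather)

  key <- function(d) paste(d$subject_id, d$period_id, sep = "/")
  orphan <- which(!key(samples) %in% key(doses))
  if (length(orphan) > 0) {
    stop("sample row(s) without a matching dosing record: ",
         paste(utils::head(orphan, 10), collapse = ", "),
         if (length(orphan) > 10) " ..." else "", call. = FALSE)
  }

  log_lines <- c(
    sprintf("isodilute %s | run at %s",
            as.character(utils::packageVersion("isodilute")),
            format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    sprintf("hydration_ratio=%g qc_r2_min=%g min_time_days=%g window_days=%d",
            hydration_ratio, qc_r2_min, min_time_days, window_days),
    sprintf("%d samples, %d dosing records", nrow(samples), nrow(doses))
  )

  nd <- nrow(doses)
  sample_key <- key(samples)
  dose_key <- key(doses)
  sp_split <- split(seq_len(nrow(samples)), sample_key)
  s_isbase <- samples$is_baseline
  s_enr <- samples$enrichment
  s_tsd <- if ("time_since_dose" %in% names(samples)) {
    samples$time_since_dose
  } else {
    rep(NA_real_, nrow(samples))
  }
  s_time <- samples$sample_time
  e0_v <- numeric(nd); kd_v <- numeric(nd); r2_v <- numeric(nd)
  np_v <- integer(nd); tbw_v <- numeric(nd); ok <- logical(nd)
  fail_reason <- character(nd)
  for (j in seq_len(nd)) {
    rows <- sp_split[[dose_key[j]]]
    res <- tryCatch({
      base_rows <- rows[s_isbase[rows]]
      if (length(base_rows) != 1) {
        stop("expected exactly 1 baseline sample, found ", length(base_rows))
      }
      post <- rows[!s_isbase[rows]]
      t_days <- if (all(is.finite(s_tsd[post]))) {
        s_tsd[post]
      } else {
        as.numeric(difftime(s_time[post], doses$dose_time[j],
                            units = "days"))
      }
      fit <- fit_washout(t_days, s_enr[post],
                         baseline = s_enr[base_rows],
                         qc_r2_min = qc_r2_min,
                         min_time_days = min_time_days)
      if (!fit$qc_pass) stop(sprintf("washout fit failed QC (R2 = %.4f)",
                                     fit$r_squared))
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_reason[j] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("QC FAIL %s/%s: %s",
                                        doses$subject_id[j],
                                        doses$period_id[j],
                                        conditionMessage(res)))
      next
    }
    ok[j] <- TRUE
    e0_v[j] <- res$e0_excess; kd_v[j] <- res$kd
    r2_v[j] <- res$r_squared; np_v[j] <- res$n_points
    tbw_v[j] <- dilution_space(res, dose_mass = doses$dose_mass[j],
                               purity = doses$purity[j])
  }

  fits <- tibble::tibble(
    subject_id = doses$subject_id[ok], period_id = doses$period_id[ok],
    e0_excess = e0_v[ok], kd = kd_v[ok], r_squared = r2_v[ok],
    n_points = np_v[ok], qc_pass = TRUE)
  compositions <- if (any(ok)) {
    suppressWarnings(body_composition(
      doses$body_mass_at_dose[ok], tbw_v[ok], hydration_ratio,
      subject_id = doses$subject_id[ok], period_id = doses$period_id[ok]))
  } else {
    tibble::tibble()
  }
  turnover <- water_turnover(kd_v[ok], pmax(tbw_v[ok], .Machine$double.eps))
  budget <- tibble::tibble(
    subject_id = doses$subject_id[ok], period_id = doses$period_id[ok],
    body_mass = doses$body_mass_at_dose[ok], tbw = tbw_v[ok], kd = kd_v[ok],
    water_turnover = turnover,
    turnover_pct_tbw = turnover_pct_tbw(turnover, tbw_v[ok]))
  if (!is.null(weather) && nrow(budget) > 0) {
    # aggregate each distinct window once, then join back
    win <- tibble::tibble(dose_date = as.Date(doses$dose_time[ok]))
    uniq <- unique(win$dose_date)
    agg <- dplyr::bind_rows(lapply(uniq, function(d) {
      aggregate_weather(weather, d, window_days)
    }))
    budget <- dplyr::bind_cols(budget,
                               agg[match(win$dose_date, uniq), ])
  }
  qc_failures <- tibble::tibble(
    subject_id = doses$subject_id[!ok], period_id = doses$period_id[!ok],
    reason = fail_reason[!ok])
  log_lines <- c(log_lines,
                 sprintf("%d subject-periods fitted, %d failed QC",
                         nrow(fits), nrow(qc_failures)))

  summary_tbl <- NULL
  if (nrow(budget) > 0 && "sex" %in% names(samples)) {
    sex_lookup <- dplyr::distinct(samples, .data$subject_id, .data$sex)
    summary_tbl <- group_summary(
      dplyr::left_join(budget, sex_lookup, by = "subject_id"),
      "water_turnover")
  }

  out <- list(fits = fits, compositions = compositions, budget = budget,
              summary = summary_tbl, qc_failures = qc_failures,
              log = log_lines)
  class(out) <- "pipeline_result"

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(fits, file.path(output_dir, "fits.csv"), progress = FALSE)
    readr::write_csv(compositions, file.path(output_dir, "compositions.csv"),
                     progress = FALSE)
    readr::write_csv(budget, file.path(output_dir, "budget.csv"),
                     progress = FALSE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
    writeLines(utils::capture.output(print(out)),
               file.path(output_dir, "summary.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subject-periods fitted, %d QC failures\n",
              nrow(x$fits), nrow(x$qc_failures)))
  if (nrow(x$budget) > 0) {
    cat(sprintf("  TBW %.0f-%.0f L, turnover %.0f-%.0f L/d\n",
                min(x$budget$tbw), max(x$budget$tbw),
                min(x$budget$water_turnover), max(x$budget$water_turnover)))
  }
  if (nrow(x$qc_failures) > 0) {
    cat("  QC failures:\n")
    for (i in seq_len(nrow(x$qc_failures))) {
      cat(sprintf("    %s/%s: %s\n", x$qc_failures$subject_id[i],
                  x$qc_failures$period_id[i], x$qc_failures$reason[i]))
    }
  }
  invisible(x)
}
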