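#' Per-subject means across measurement periods
#'
#' @param periods Tibble with one row per subject-period, a `subject_id`
#'   column, and the numeric columns in `vars`.
#' @param vars Character vector of columns to average (default: all numeric
#'   columns).
#' @return One row per subject with the arithmetic mean of each variable.
#' @export
subject_means <- function(periods, vars = NULL) {
  stopifnot("subject_id" %in% names(periods))
  if (is.null(vars)) {
    vars <- names(periods)[vapply(periods, is.numeric, logical(1))]
  }
  keep <- intersect(c("sex"), names(periods))
  dplyr::summarise(
    dplyr::group_by(periods, dplyr::across(dplyr::all_of(c("subject_id", keep)))),
    dplyr::across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Group-level mean and SD of subject means
#'
#' Cohort summaries are computed over subject means (one value per animal),
#' so repeatedly measured subjects are not over-weighted. SD uses the n-1
#' denominator.
#'
#' @param periods Subject-period tibble (see [subject_means()]).
#' @param variable Column to summarise (string).
#' @param group_by Grouping column, default `"sex"`.
#' @return Tibble with `group`, `mean`, `sd`, `n` (subjects).
#' @export
group_summary <- function(periods, variable, group_by = "sex") {
  stopifnot(variable %in% names(periods), group_by %in% names(periods))
  sm <- subject_means(periods, vars = variable)
  if (!group_by %in% names(sm)) {
    lookup <- dplyr::distinct(periods, .data$subject_id,
                              .data[[group_by]])
    sm <- dplyr::left_join(sm, lookup, by = "subject_id")
  }
  dplyr::summarise(
    dplyr::group_by(sm, group = .data[[group_by]]),
    mean = mean(.data[[variable]]),
    sd = stats::sd(.data[[variable]]),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Normalize each subject's series to its own mean
#'
#' Divides every value by that subject's mean of the same variable, so each
#' subject's normalized series averages to 1; used for visualising pooled
#' longitudinal trends across animals of very different size.
#'
#' @param periods Subject-period tibble.
#' @param vars Character vector of columns to normalize.
#' @return The tibble with `vars` replaced by normalized values.
#' @export
normalize_to_subject_mean <- function(periods, vars) {
  stopifnot("subject_id" %in% names(periods), all(vars %in% names(periods)))
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(periods, .data$subject_id),
    dplyr::across(dplyr::all_of(vars), ~ .x / mean(.x, na.rm = TRUE))
  ))
}

#' Paired t-test of each subject's first versus last measurement
#'
#' Takes each subject's chronologically first and last usable period (rows
#' are ordered by `order_by` within subject) and runs a classical paired
#' t-test on last minus first.
#'
#' @param periods Subject-period tibble.
#' @param variable Column to test (string).
#' @param order_by Column defining chronological order within subject
#'   (default `"period_id"`).
#' @return Tibble with `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_first_last <- function(periods, variable, order_by = "period_id") {
  stopifnot(variable %in% names(periods), order_by %in% names(periods))
  ordered <- dplyr::arrange(periods, .data$subject_id, .data[[order_by]])
  fl <- dplyr::summarise(
    dplyr::group_by(ordered, .data$subject_id),
    first = dplyr::first(.data[[variable]]),
    last = dplyr::last(.data[[variable]]),
    .groups = "drop"
  )
  fl <- fl[stats::complete.cases(fl), ]
  if (nrow(fl) < 2) {
    stop("need at least 2 subjects with both first and last values",
         call. = FALSE)
  }
  diffs <- fl$last - fl$first
  if (stats::sd(diffs) == 0 && any(diffs != 0)) {
    stop("all paired differences are identical and non-zero: the t ",
         "statistic is undefined (zero variance)", call. = FALSE)
  }
  if (all(diffs == 0)) {
    return(tibble::tibble(t = 0, df = nrow(fl) - 1, p = 1, n = nrow(fl),
                          mean_diff = 0))
  }
  tt <- stats::t.test(fl$last, fl$first, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = nrow(fl), mean_diff = mean(diffs))
}

#' Pearson correlations, pooled or within subject
#'
#' @param periods Subject-period tibble.
#' @param x,y Column names (strings).
#' @param scope `"pooled"` for one correlation over all subject-periods, or
#'   `"within"` for one per subject (subjects with fewer than 3 periods are
#'   skipped).
#' @return Tibble with `subject_id` (`"pooled"` for the pooled scope), `r`,
#'   `t`, `df`, `p`, `n`.
#' @export
cohort_correlations <- function(periods, x, y,
                                scope = c("pooled", "within")) {
  scope <- match.arg(scope)
  stopifnot(all(c(x, y) %in% names(periods)))
  one <- function(d, label) {
    d <- d[stats::complete.cases(d[c(x, y)]), ]
    if (nrow(d) < 3) return(NULL)
    ct <- stats::cor.test(d[[x]], d[[y]], method = "pearson")
    tibble::tibble(subject_id = label, r = unname(ct$estimate),
                   t = unname(ct$statistic), df = unname(ct$parameter),
                   p = ct$p.value, n = nrow(d))
  }
  if (scope == "pooled") return(one(periods, "pooled"))
  dplyr::bind_rows(lapply(
    split(periods, periods$subject_id),
    function(d) one(d, d$subject_id[1])
  ))
}

#' Slope of subject-mean water turnover on subject-mean body mass
#'
#' OLS slope scaled to litres per day per 100 kg of body mass.
#'
#' @param periods Subject-period tibble with `body_mass` and
#'   `water_turnover` columns (or a subject-mean tibble; means are taken
#'   either way).
#' @return Litres per day per 100 kg.
#' @export
turnover_mass_slope <- function(periods) {
  sm <- subject_means(periods, vars = c("body_mass", "water_turnover"))
  stopifnot(nrow(sm) >= 2)
  fit <- stats::lm(water_turnover ~ body_mass, data = sm)
  unname(stats::coef(fit)[2]) * 100
}

#' Two-way fixed-effects ANOVA quality-control check
#'
#' Tests whether a measurement depends on a nuisance factor (e.g. time of
#' day of dosing), on subject identity, and on their interaction, using
#' classical sequential sums of squares. Used as a QC screen: large p-values
#' support pooling over the nuisance factor.
#'
#' @param values Numeric response vector.
#' @param factor_a First factor (e.g. time of day), coerced to factor.
#' @param factor_b Second factor (e.g. subject id), coerced to factor.
#' @return Tibble with one row per term: `term`, `df`, `sum_sq`, `mean_sq`,
#'   `f`, `p` (the residual row has `NA` for `f` and `p`).
#' @export
covariate_check_anova <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  d <- data.frame(y = values, a = factor(factor_a), b = factor(factor_b))
  fit <- stats::aov(y ~ a * b, data = d)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    f = tab$`F value`, p = tab$`Pr(>F)`
  )
}
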