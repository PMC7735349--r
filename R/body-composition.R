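#' Body composition from total body water
#'
#' Converts a total body water estimate to fat-free mass (FFM), fat mass and
#' body fat percentage using a hydration ratio (TBW : FFM). The default
#' ratio, 0.746, is the mean across 15 mammal species; 0.730 is a commonly
#' used alternative. In animals measured with full guts both TBW and FFM
#' include gut content. Litres of body water convert to kg at density 1.
#'
#' Fat mass may come out negative when measurement error pushes the TBW
#' estimate high relative to scale mass; such rows are flagged
#' (`negative_fat`), not clamped, because a small negative value is
#' informative about the error budget. A fat percentage below -5% is treated
#' as a dosing or assay failure and raises an error.
#'
#' @param body_mass Scale body mass in kg (vectorised).
#' @param tbw Total body water in litres (vectorised).
#' @param hydration_ratio TBW : FFM ratio, in (0, 1].
#' @param subject_id,period_id Optional labels carried through.
#' @return A tibble with columns `subject_id`, `period_id`, `body_mass`,
#'   `tbw`, `hydration_ratio`, `ffm`, `fat_mass`, `fat_percent`,
#'   `negative_fat`.
#' @export
#' @examples
#' body_composition(4401, 2817) # FFM ~3776 kg, ~14% fat
body_composition <- function(body_mass, tbw, hydration_ratio = 0.746,
                             subject_id = NA_character_,
                             period_id = NA_character_) {
  stopifnot(all(body_mass > 0), all(tbw > 0),
            hydration_ratio > 0, hydration_ratio <= 1)
  ffm <- tbw / hydration_ratio
  fat_mass <- body_mass - ffm
  fat_percent <- 100 * fat_mass / body_mass
  if (any(fat_percent < -5)) {
    stop("fat percentage below -5% for ",
         sum(fat_percent < -5), " record(s): TBW grossly exceeds what body ",
         "mass allows; check dose ingestion and assay", call. = FALSE)
  }
  if (any(fat_mass < 0)) {
    warning(sum(fat_mass < 0),
            " record(s) with negative fat mass (flagged, not clamped)",
            call. = FALSE)
  }
  tibble::tibble(
    subject_id = subject_id, period_id = period_id,
    body_mass = body_mass, tbw = tbw, hydration_ratio = hydration_ratio,
    ffm = ffm, fat_mass = fat_mass, fat_percent = fat_percent,
    negative_fat = fat_mass < 0
  )
}

#' Sensitivity of body fat percentage to the hydration ratio
#'
#' Change in estimated body fat percentage (percentage points) when moving
#' from `ratio_a` to `ratio_b`; positive values mean the fat estimate is
#' *reduced* by the switch. Closed form:
#' `100 * (tbw / body_mass) * (1 / ratio_b - 1 / ratio_a)`.
#'
#' @inheritParams body_composition
#' @param ratio_a Reference hydration ratio (default 0.746).
#' @param ratio_b Alternative hydration ratio (default 0.730).
#' @return Percentage-point change in fat percent (vectorised).
#' @export
hydration_sensitivity <- function(body_mass, tbw,
                                  ratio_a = 0.746, ratio_b = 0.730) {
  stopifnot(all(body_mass > 0), all(tbw > 0),
            ratio_a > 0, ratio_a <= 1, ratio_b > 0, ratio_b <= 1)
  100 * (tbw / body_mass) * (1 / ratio_b - 1 / ratio_a)
}

#' FFM overestimation due to gut fill hydrated above the assumed ratio
#'
#' Gut contents are much wetter (80-90% water) than the hydration assumed in
#' the TBW-to-FFM conversion, so the gut-water pool inflates the FFM estimate
#' and deflates fat mass by the same amount. The bias in kg is
#' `body_mass * gut_fraction * (gut_hydration - hydration_ratio) / hydration_ratio`.
#'
#' @param body_mass Body mass in kg.
#' @param gut_fraction Gut contents as a fraction of body mass (0.07-0.17 in
#'   elephants).
#' @param gut_hydration Water fraction of gut contents (0.80-0.90).
#' @param hydration_ratio Assumed TBW : FFM ratio.
#' @return kg of FFM overestimation (equals kg of fat-mass underestimation).
#' @export
gut_fill_bias <- function(body_mass, gut_fraction, gut_hydration,
                          hydration_ratio = 0.746) {
  stopifnot(all(body_mass > 0),
            all(gut_fraction >= 0), all(gut_fraction < 1),
            all(gut_hydration > 0), all(gut_hydration <= 1),
            hydration_ratio > 0, hydration_ratio <= 1)
  body_mass * gut_fraction * (gut_hydration - hydration_ratio) / hydration_ratio
}

#' Round a composition table for reporting
#'
#' Masses to the nearest kg and fat percent to the nearest integer, the
#' presentation convention for cohort summary tables; full precision is kept
#' in the unrounded input.
#'
#' @param composition Output of [body_composition()].
#' @return The tibble with `tbw`, `ffm`, `fat_mass` rounded to kg/L and
#'   `fat_percent` to integer.
#' @export
round_composition <- function(composition) {
  dplyr::mutate(
    composition,
    tbw = round(.data$tbw), ffm = round(.data$ffm),
    fat_mass = round(.data$fat_mass), fat_percent = round(.data$fat_percent)
  )
}
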