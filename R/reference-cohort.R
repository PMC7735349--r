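#' Published summary measurements for five zoo-living African elephants
#'
#' Per-subject means (and SDs over measurement periods) of body mass, total
#' body water, fat-free mass (including gut content), body fat percentage
#' and daily water turnover for two male and three female adult African
#' elephants measured repeatedly by deuterium dilution at a North American
#' zoo. These printed summary values serve as a worked-example fixture for
#' the composition and cohort-statistics functions: FFM was derived from
#' TBW with hydration ratio 0.746, and group turnover statistics computed
#' over the subject means reproduce the published cohort figures.
#'
#' @return Tibble with columns `subject_id`, `sex`, `age_range`,
#'   `body_mass`, `body_mass_sd`, `tbw`, `tbw_sd`, `ffm`, `ffm_sd`,
#'   `fat_percent`, `fat_percent_sd`, `water_turnover`,
#'   `water_turnover_sd`. Masses in kg, water volumes in litres, turnover
#'   in litres per day.
#' @export
#' @examples
#' elephant_summary()
elephant_summary <- function() {
  tibble::tibble(
    subject_id = c("1770", "327", "1772", "1611", "1771"),
    sex = c("M", "M", "F", "F", "F"),
    age_range = c("32-34", "41-43", "13-15", "33-35", "37-39"),
    body_mass = c(5815, 5553, 2654, 4401, 3905),
    body_mass_sd = c(190, 107, 96, 140, 150),
    tbw = c(4020, 3698, 1731, 2817, 2587),
    tbw_sd = c(349, 177, 79, 131, 142),
    ffm = c(5389, 4957, 2320, 3776, 3467),
    ffm_sd = c(467, 238, 106, 175, 190),
    fat_percent = c(7, 11, 13, 14, 11),
    fat_percent_sd = c(6, 4, 2, 2, 2),
    water_turnover = c(353, 365, 227, 223, 273),
    water_turnover_sd = c(4, 9, 40, 42, 47)
  )
}
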