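#' Weekly drinking quantity
#'
#' Sum of the seven daily drink counts of one diary week; `NA` for a
#' missing week.
#'
#' @param drinks 7 daily drink counts (`NA` for missing days).
#' @return standard drinks per week, or `NA`.
#' @export
weekly_quantity <- function(drinks) {
  if (all(is.na(drinks))) return(NA_real_)
  sum(drinks, na.rm = TRUE)
}

#' Weekly drinking frequency
#'
#' Number of drinking occasions in one diary week; a day with at least one
#' drink counts as one occasion.
#'
#' @inheritParams weekly_quantity
#' @return occasions per week (0-7), or `NA` for a missing week.
#' @export
weekly_frequency <- function(drinks) {
  if (all(is.na(drinks))) return(NA_real_)
  sum(drinks >= 1, na.rm = TRUE)
}

#' Binge drinking occasions per week
#'
#' Days at or above the heavy-episodic-drinking threshold: 4 or more
#' standard drinks for women, 5 or more for men (the conventional gendered
#' binge definition; configurable).
#'
#' @inheritParams weekly_quantity
#' @param gender `"M"` or `"W"`.
#' @param thresholds named (`W`, `M`) minimum drinks per binge occasion.
#' @return binge occasions per week, or `NA` for a missing week.
#' @export
binge_occasions <- function(drinks, gender, thresholds = c(W = 4, M = 5)) {
  if (all(is.na(drinks))) return(NA_real_)
  sum(drinks >= thresholds[[gender]], na.rm = TRUE)
}

#' Hazardous drinking by AUDIT score
#'
#' `TRUE` when the AUDIT score is at least 6 for women or 8 for men (the
#' trial's inclusion criterion).
#'
#' @param audit AUDIT score, 0-40.
#' @param gender `"M"` or `"W"` (vectorized).
#' @param cutoffs named (`W`, `M`) minimum hazardous scores.
#' @return logical vector.
#' @export
is_hazardous <- function(audit, gender, cutoffs = c(W = 6, M = 8)) {
  stopifnot(all(audit >= 0 & audit <= 40, na.rm = TRUE))
  audit >= cutoffs[gender]
}

#' Excessive weekly drinking
#'
#' `TRUE` when weekly quantity exceeds the Swedish recommended limit: more
#' than 9 drinks/week for women, more than 14 for men.
#'
#' @param quantity standard drinks per week (>= 0).
#' @param gender `"M"` or `"W"` (vectorized).
#' @param limits named (`W`, `M`) recommended weekly maxima.
#' @return logical vector.
#' @export
is_excessive <- function(quantity, gender, limits = c(W = 9, M = 14)) {
  stopifnot(all(quantity >= 0, na.rm = TRUE))
  quantity > limits[gender]
}

#' Derive the drinking outcomes per student and wave
#'
#' Computes the five primary drinking parameters (weekly quantity,
#' frequency, binge occasions, weekly mean eBAC, peak eBAC) and the
#' excessive-drinking status from the diaries, one row per student x wave.
#' Missing waves yield missing outcomes (no imputation).
#'
#' @param diaries diaries tibble (`student_id`, `wave`, `weekday`,
#'   `drinks`, `hours`).
#' @param students students tibble (`student_id`, `gender`, `weight`,
#'   `audit`).
#' @param constants a [widmark_constants] object.
#' @param binge_thresholds named (`W`, `M`) binge thresholds.
#' @param limits named (`W`, `M`) recommended weekly maxima.
#' @return a tibble with columns `student_id`, `wave`, `quantity`,
#'   `frequency`, `binge_occasions`, `weekly_mean_ebac`,
#'   `peak_ebac_month`, `excessive`, `hazardous`.
#' @export
derive_outcomes <- function(diaries, students,
                            constants = widmark_constants(),
                            binge_thresholds = c(W = 4, M = 5),
                            limits = c(W = 9, M = 14)) {
  info <- students[c("student_id", "gender", "weight", "audit")]
  diaries |>
    dplyr::inner_join(info, by = "student_id") |>
    dplyr::group_by(.data$student_id, .data$wave) |>
    dplyr::summarise(
      quantity = weekly_quantity(.data$drinks),
      frequency = weekly_frequency(.data$drinks),
      binge_occasions = binge_occasions(.data$drinks, .data$gender[1],
                                        binge_thresholds),
      weekly_mean_ebac = weekly_mean_ebac(.data$drinks, .data$hours,
                                          .data$gender[1], .data$weight[1],
                                          constants),
      peak_ebac_month = peak_ebac_month(.data$drinks, .data$hours,
                                        .data$gender[1], .data$weight[1],
                                        constants),
      gender = .data$gender[1],
      hazardous = is_hazardous(.data$audit[1], .data$gender[1]),
      .groups = "drop") |>
    dplyr::mutate(excessive = is_excessive(.data$quantity, .data$gender,
                                           limits)) |>
    dplyr::select(-"gender")
}
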