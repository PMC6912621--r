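#' Widmark constants
#'
#' Constants of the Widmark estimated blood alcohol concentration (eBAC)
#' computation: the body-water distribution ratio r by gender, the
#' elimination rate beta, the grams of ethanol in one standard drink
#' (Swedish convention, 12 g), and the output scale.
#'
#' @param r_by_gender named (`M`, `W`) distribution ratios in (0, 1\].
#' @param beta elimination rate in percent per hour.
#' @param grams_per_standard_drink grams of ethanol per standard drink.
#' @param output_scale `"percent"` (g/dL x 100, the US-style percent
#'   BAC) or `"permille"` (g/L, ten times the percent value).
#' @return a `widmark_constants` list.
#' @examples
#' widmark_constants()
#' widmark_constants(output_scale = "permille")
#' @export
widmark_constants <- function(r_by_gender = c(M = 0.68, W = 0.55),
                              beta = 0.017,
                              grams_per_standard_drink = 12,
                              output_scale = c("percent", "permille")) {
  output_scale <- match.arg(output_scale)
  stopifnot(all(r_by_gender > 0 & r_by_gender <= 1),
            all(c("M", "W") %in% names(r_by_gender)),
            beta > 0, grams_per_standard_drink > 0)
  structure(list(r_by_gender = r_by_gender, beta = beta,
                 grams_per_standard_drink = grams_per_standard_drink,
                 output_scale = output_scale),
            class = "widmark_constants")
}

#' Single-occasion estimated blood alcohol concentration
#'
#' Widmark formula: eBAC = 100 x (drinks x grams per drink) / (body weight
#' in grams x r) - beta x hours, floored at zero, on the percent scale
#' (multiplied by 10 for per-mille output). A day with zero drinks always
#' gives 0. Vectorized over all arguments.
#'
#' @param drinks standard drinks consumed on the occasion (>= 0).
#' @param hours occasion duration in hours (> 0; ignored when
#'   `drinks = 0`).
#' @param gender `"M"` or `"W"`.
#' @param weight body weight in kg (> 0).
#' @param constants a [widmark_constants] object.
#' @return eBAC on the configured output scale, >= 0.
#' @examples
#' ebac_occasion(5, 2, "M", 80)  # 0.0763 percent
#' @export
ebac_occasion <- function(drinks, hours, gender, weight,
                          constants = widmark_constants()) {
  stopifnot(inherits(constants, "widmark_constants"))
  if (any(weight <= 0, na.rm = TRUE)) stop("weight must be positive")
  if (any(drinks < 0, na.rm = TRUE)) stop("drinks must be nonnegative")
  if (any(drinks > 0 & !is.na(drinks) & (is.na(hours) | hours <= 0)))
    stop("hours must be positive on drinking occasions")
  grams <- drinks * constants$grams_per_standard_drink
  r <- constants$r_by_gender[gender]
  raw <- 100 * grams / (weight * 1000 * r) -
    constants$beta * ifelse(drinks > 0, hours, 0)
  out <- pmax(0, raw)
  out[!is.na(drinks) & drinks == 0] <- 0
  if (constants$output_scale == "permille") out <- 10 * out
  unname(out)
}

#' Weekly mean eBAC
#'
#' Mean single-occasion eBAC over the days of one diary week, counting
#' non-drinking days as zero. A fully missing week gives `NA`, never 0.
#'
#' @param drinks 7 daily drink counts (`NA` for missing days).
#' @param hours 7 occasion durations (`NA` on non-drinking days).
#' @inheritParams ebac_occasion
#' @return mean eBAC on the configured scale, or `NA` for a missing week.
#' @export
weekly_mean_ebac <- function(drinks, hours, gender, weight,
                             constants = widmark_constants()) {
  obs <- !is.na(drinks)
  if (!any(obs)) return(NA_real_)
  vals <- ebac_occasion(drinks[obs], hours[obs], gender, weight, constants)
  mean(vals)
}

#' Peak eBAC over a recall window
#'
#' Maximum single-occasion eBAC across all observed days of the window
#' (here, the wave's diary week stands in for the past-month recall).
#'
#' @inheritParams weekly_mean_ebac
#' @return maximum eBAC, or `NA` when no day is observed.
#' @export
peak_ebac_month <- function(drinks, hours, gender, weight,
                            constants = widmark_constants()) {
  obs <- !is.na(drinks)
  if (!any(obs)) return(NA_real_)
  max(ebac_occasion(drinks[obs], hours[obs], gender, weight, constants))
}
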