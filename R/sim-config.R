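#' Latent drinking-class specification
#'
#' One latent behavioural class of the synthetic cohort: a weekday profile
#' of drinking probabilities (Monday-first), the mean and dispersion of the
#' drink count on drinking days, and the day-to-day persistence of the
#' class's pattern. With `state_persistence < 1` a member can drift out of
#' the class pattern (and drink like the average of the other classes)
#' before possibly returning; this is what produces itinerant members of
#' the frequent-heavy state.
#'
#' @param label class name.
#' @param prevalence fraction of the cohort in this class.
#' @param drink_prob_by_weekday 7 probabilities of any drinking,
#'   Monday-first.
#' @param quantity_mean_given_drinking mean standard drinks on drinking
#'   days (> 1; a positive count has mean above 1).
#' @param quantity_dispersion dispersion of the zero-truncated count
#'   distribution; `Inf` (default) gives the zero-truncated Poisson.
#' @param state_persistence daily probability of staying in the class's
#'   own pattern.
#' @param frequent_heavy flag marking the frequent-heavy class (at most
#'   one class may carry it).
#' @return a `latent_class` list.
#' @export
latent_class <- function(label, prevalence, drink_prob_by_weekday,
                         quantity_mean_given_drinking,
                         quantity_dispersion = Inf,
                         state_persistence = 1,
                         frequent_heavy = FALSE) {
  stopifnot(length(drink_prob_by_weekday) == 7,
            all(drink_prob_by_weekday >= 0 & drink_prob_by_weekday <= 1),
            prevalence >= 0, prevalence <= 1,
            quantity_mean_given_drinking > 0,
            quantity_dispersion > 0,
            state_persistence >= 0, state_persistence <= 1)
  structure(list(label = label, prevalence = prevalence,
                 drink_prob_by_weekday = as.numeric(drink_prob_by_weekday),
                 quantity_mean_given_drinking = quantity_mean_given_drinking,
                 quantity_dispersion = quantity_dispersion,
                 state_persistence = state_persistence,
                 frequent_heavy = isTRUE(frequent_heavy)),
            class = "latent_class")
}

#' Default latent-class specification
#'
#' Seven weekday-anchored moderate classes plus one frequent-heavy class.
#' Moderate drinking follows a shared weekend-peaked base profile
#' (drinking is rare on Monday-Wednesday and common on Friday/Saturday,
#' as in student diary data) with a personal bump to 0.85 on the class's
#' own weekday; class prevalences concentrate on the weekend. The
#' frequent-heavy class (7% of the cohort) drinks on about 65% of days -
#' 4.55 days/week - at quantities that put its members far above the
#' weekly recommended limits, and keeps that pattern with daily
#' persistence 0.992, so roughly a fifth of its members leave it at some
#' point over the four diary weeks.
#'
#' @param fh_prevalence prevalence of the frequent-heavy class; the seven
#'   weekday classes share the remainder in fixed proportions.
#' @return list of [latent_class] objects.
#' @export
default_class_spec <- function(fh_prevalence = 0.07) {
  stopifnot(fh_prevalence >= 0, fh_prevalence < 1)
  base <- c(.06, .08, .11, .17, .46, .42, .17)
  wd_prev <- c(.02, .03, .05, .08, .32, .28, .15)
  wd_prev <- wd_prev / sum(wd_prev) * (1 - fh_prevalence)
  qmean <- c(3.6, 3.6, 3.8, 4.0, 4.6, 4.6, 4.0)
  days <- c("monday", "tuesday", "wednesday", "thursday", "friday",
            "saturday", "sunday")
  cls <- lapply(1:7, function(w) {
    prof <- base
    prof[w] <- 0.85
    latent_class(days[w], wd_prev[w], prof, qmean[w])
  })
  if (fh_prevalence > 0)
    cls <- c(cls, list(latent_class("frequent_heavy", fh_prevalence,
                                    rep(0.65, 7), 3.6,
                                    state_persistence = 0.992,
                                    frequent_heavy = TRUE)))
  cls
}

#' Simulation configuration for a synthetic trial cohort
#'
#' Describes a three-arm randomized trial in university students with
#' hazardous alcohol use: cohort size and randomization ratio, covariate
#' distributions (gender mix, age, body weight by gender, AUDIT score,
#' motivation), the latent drinking classes, arm-dependent change in the
#' daily drinking log-odds per follow-up wave, and per-wave response
#' rates. Defaults emulate a 2166-student cohort (67.5% women, age 25.8,
#' AUDIT 11) followed over four diary weeks at baseline and 7, 14 and 20
#' weeks, with response rates in the 55-83% band.
#'
#' @param n_students cohort size.
#' @param arm_ratio three nonnegative randomization weights for
#'   (control, promillekoll, partyplanner).
#' @param prop_women fraction of women.
#' @param age_mean,age_sd age distribution (years).
#' @param weight_mean_by_gender,weight_sd_by_gender named (`W`, `M`) body
#'   weight moments (kg), truncated below at 45 kg.
#' @param audit_mean,audit_sd AUDIT score moments; scores are rounded and
#'   clamped to the hazardous-drinking inclusion range (>= 6 women / 8
#'   men, <= 40).
#' @param motivation_mean,motivation_sd motivation ruler moments; rounded
#'   and clamped to 0-10.
#' @param class_spec list of [latent_class] objects; prevalences must sum
#'   to 1 and at most one class may be flagged frequent-heavy.
#' @param arm_slope_logodds named per-arm additive change in the daily
#'   drinking log-odds per wave.
#' @param response_rate_by_wave response probabilities for waves 1-3
#'   (baseline is always observed).
#' @param mar_audit_logodds response log-odds shift per AUDIT point above
#'   the cohort mean (missingness at random through an observed baseline
#'   covariate; 0 gives pure per-wave rates).
#' @param fh_covariate_shift list with `age` and `audit` additive shifts
#'   and `prop_women` replacement for the frequent-heavy class, mirroring
#'   that heavy-pattern drinkers tend to be older, more often male and
#'   higher-scoring.
#' @param pattern_return_prob daily probability of returning to the own
#'   class pattern after drifting out of it.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_students = 2166L,
                       arm_ratio = c(1, 1, 1),
                       prop_women = 0.675,
                       age_mean = 25.8, age_sd = 6.6,
                       weight_mean_by_gender = c(W = 70, M = 82),
                       weight_sd_by_gender = c(W = 10, M = 12),
                       audit_mean = 11, audit_sd = 4.3,
                       motivation_mean = 4.1, motivation_sd = 2.6,
                       class_spec = default_class_spec(),
                       arm_slope_logodds = c(control = -0.02,
                                             promillekoll = -0.05,
                                             partyplanner = -0.04),
                       response_rate_by_wave = c(0.78, 0.60, 0.65),
                       mar_audit_logodds = 0.08,
                       fh_covariate_shift = list(age = 3.9, audit = 3,
                                                 prop_women = 0.48),
                       pattern_return_prob = 0.02,
                       seed = 1L) {
  if (n_students < 1) stop("n_students must be at least 1")
  if (length(arm_ratio) != 3 || any(arm_ratio < 0) || sum(arm_ratio) <= 0)
    stop("arm_ratio needs 3 nonnegative weights, not all zero")
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (!frac_ok(prop_women)) stop("prop_women must be in [0, 1]")
  if (length(response_rate_by_wave) != 3 || !frac_ok(response_rate_by_wave))
    stop("response_rate_by_wave needs 3 fractions in [0, 1]")
  stopifnot(all(vapply(class_spec, inherits, TRUE, "latent_class")))
  prev <- vapply(class_spec, `[[`, 0, "prevalence")
  if (abs(sum(prev) - 1) > 1e-9)
    stop("class prevalences must sum to 1 (got ", sum(prev), ")")
  if (sum(vapply(class_spec, `[[`, TRUE, "frequent_heavy")) > 1)
    stop("at most one class may be flagged frequent_heavy")
  if (!all(c("control", "promillekoll", "partyplanner") %in%
           names(arm_slope_logodds)))
    stop("arm_slope_logodds must name control, promillekoll, partyplanner")
  structure(list(n_students = as.integer(n_students),
                 arm_ratio = arm_ratio, prop_women = prop_women,
                 age_mean = age_mean, age_sd = age_sd,
                 weight_mean_by_gender = weight_mean_by_gender,
                 weight_sd_by_gender = weight_sd_by_gender,
                 audit_mean = audit_mean, audit_sd = audit_sd,
                 motivation_mean = motivation_mean,
                 motivation_sd = motivation_sd,
                 class_spec = class_spec,
                 arm_slope_logodds = arm_slope_logodds,
                 response_rate_by_wave = response_rate_by_wave,
                 mar_audit_logodds = mar_audit_logodds,
                 fh_covariate_shift = fh_covariate_shift,
                 pattern_return_prob = pattern_return_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}
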