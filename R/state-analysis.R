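#' Identify the frequent-heavy hidden state
#'
#' The frequent-heavy state is the state with the largest expected number
#' of drinking days per week (`7 * p_drink`) among states that drink
#' several days a week (at least `min_days`) and are stable
#' (self-transition at least `min_self`); ties go to the larger
#' self-transition. Returns `NA` when no state qualifies.
#'
#' @param params an [hmm_parameters] object or a `drink_hmm` fit.
#' @param min_days minimum expected drinking days/week to qualify.
#' @param min_self minimum self-transition probability to qualify.
#' @return 1-based state index, or `NA_integer_`.
#' @export
identify_frequent_heavy <- function(params, min_days = 3.5,
                                    min_self = 0.5) {
  if (inherits(params, "drink_hmm")) params <- params$params
  stopifnot(inherits(params, "hmm_parameters"))
  days <- 7 * params$p_drink
  self <- diag(params$transition)
  ok <- which(days >= min_days & self >= min_self)
  if (!length(ok)) return(NA_integer_)
  ok[order(-days[ok], -self[ok])][1]
}

#' Label the hidden states
#'
#' Assigns the frequent-heavy label first (see
#' [identify_frequent_heavy]); each remaining state is labelled with the
#' calendar weekday (Monday-first) holding the largest share of its
#' decoded occupancy, or left unlabelled when that share is below
#' `min_share`. Occupancy is counted over observed days of the Viterbi
#' paths.
#'
#' @param params an [hmm_parameters] object or a `drink_hmm` fit.
#' @param decoding a decoding tibble from [decode_cohort].
#' @param min_share minimum weekday occupancy share for a weekday label.
#' @param min_days,min_self frequent-heavy thresholds, passed on.
#' @return a tibble with one row per state: `state`, `label`,
#'   `top_weekday_share`, `drinking_days_per_week`, `self_transition`,
#'   and the seven occupancy shares `share_mon..share_sun`.
#' @export
label_states <- function(params, decoding, min_share = 0.5,
                         min_days = 3.5, min_self = 0.5) {
  if (inherits(params, "drink_hmm")) params <- params$params
  stopifnot(inherits(params, "hmm_parameters"))
  if (is.null(decoding) || nrow(decoding) == 0)
    stop("no decodings supplied")
  K <- params$K
  wd_names <- c("monday", "tuesday", "wednesday", "thursday", "friday",
                "saturday", "sunday")
  occ <- matrix(0, K, 7, dimnames = list(NULL, wd_names))
  obs <- decoding[decoding$observed, ]
  tab <- table(factor(obs$state, levels = seq_len(K)),
               factor(obs$weekday, levels = 1:7))
  occ[] <- as.numeric(tab)
  share <- occ / pmax(rowSums(occ), 1)

  fh <- identify_frequent_heavy(params, min_days, min_self)
  label <- rep("unlabeled", K)
  top <- apply(share, 1, max)
  top_wd <- apply(share, 1, which.max)
  for (k in seq_len(K)) {
    if (!is.na(fh) && k == fh) label[k] <- "frequent_heavy"
    else if (rowSums(occ)[k] > 0 && top[k] >= min_share)
      label[k] <- wd_names[top_wd[k]]
  }
  out <- tibble::tibble(state = seq_len(K), label = label,
                        top_weekday_share = top,
                        drinking_days_per_week = 7 * params$p_drink,
                        self_transition = diag(params$transition))
  colnames(share) <- paste0("share_", substr(wd_names, 1, 3))
  dplyr::bind_cols(out, tibble::as_tibble(share))
}

#' Classify continual and itinerant frequent-heavy members
#'
#' A student is a continual member when every observed decoded day lies in
#' the frequent-heavy state, an itinerant member when some but not all
#' observed days do, and a non-member otherwise. Students without any
#' observed day are excluded with a warning.
#'
#' @param decoding a decoding tibble from [decode_cohort].
#' @param fh_state 1-based index of the frequent-heavy state.
#' @return a tibble with `student_id`, `membership` (factor `continual` /
#'   `itinerant` / `non_member`), `days_in_state`, `days_observed`.
#' @export
classify_membership <- function(decoding, fh_state) {
  stopifnot(is.numeric(fh_state), length(fh_state) == 1)
  per <- decoding |>
    dplyr::group_by(.data$student_id) |>
    dplyr::summarise(
      days_observed = sum(.data$observed),
      days_in_state = sum(.data$observed & .data$state == fh_state),
      .groups = "drop")
  none <- per$days_observed == 0
  if (any(none)) {
    warning(sum(none), " student(s) with zero observed days excluded")
    per <- per[!none, ]
  }
  per$membership <- factor(
    ifelse(per$days_in_state == 0, "non_member",
           ifelse(per$days_in_state == per$days_observed, "continual",
                  "itinerant")),
    levels = c("continual", "itinerant", "non_member"))
  per[c("student_id", "membership", "days_in_state", "days_observed")]
}

#' Pooled two-proportion Z test
#'
#' The Z-score proportions test used for binary baseline comparisons:
#' `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion; the sign follows the group order.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @return a one-row tibble with `estimate1`, `estimate2`, `statistic`
#'   (Z) and `p_value` (two-sided).
#' @examples
#' prop_z_test(76, 146, 628, 2020)
#' @export
prop_z_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(estimate1 = p1, estimate2 = p2, statistic = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Baseline comparison of frequent-heavy members against the rest
#'
#' Compares total frequent-heavy members (continual plus itinerant)
#' against all other students on baseline variables: Welch two-sample
#' t-tests (with Welch-Satterthwaite degrees of freedom) for continuous
#' variables, and the pooled two-proportion Z test for binary variables
#' (gender, excessive status). Two-sided p-values throughout.
#'
#' @param students students tibble.
#' @param outcomes outcomes tibble from [derive_outcomes]; the wave given
#'   by `wave` is used (default baseline).
#' @param membership membership tibble from [classify_membership].
#' @param wave wave of the outcomes used in the comparison.
#' @return a tibble with one row per variable: `variable`, `type`,
#'   `estimate_fh`, `estimate_other`, `statistic`, `df`, `p_value`,
#'   `flagged` (`TRUE` when a group was too small for the test).
#' @export
compare_groups <- function(students, outcomes, membership, wave = 0) {
  out_w <- outcomes[outcomes$wave == wave, ]
  d <- students |>
    dplyr::inner_join(membership[c("student_id", "membership")],
                      by = "student_id") |>
    dplyr::left_join(out_w, by = "student_id") |>
    dplyr::mutate(fh = .data$membership %in% c("continual", "itinerant"))

  cont_vars <- c("age", "audit", "motivation", "quantity", "frequency",
                 "binge_occasions", "weekly_mean_ebac", "peak_ebac_month")
  cont_vars <- intersect(cont_vars, names(d))
  rows <- lapply(cont_vars, function(v) {
    x <- d[[v]][d$fh]
    y <- d[[v]][!d$fh]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    tt <- if (length(x) < 2 || length(y) < 2) NULL
          else tryCatch(t.test(x, y),  # Welch by default
                        error = function(e) NULL)
    if (is.null(tt))  # group too small or essentially constant data
      return(tibble::tibble(variable = v, type = "continuous",
                            estimate_fh = mean(x), estimate_other = mean(y),
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, flagged = TRUE))
    tibble::tibble(variable = v, type = "continuous",
                   estimate_fh = mean(x), estimate_other = mean(y),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value, flagged = FALSE)
  })

  bin_defs <- list(gender_m = d$gender == "M",
                   excessive = d$excessive)
  brows <- lapply(names(bin_defs), function(v) {
    val <- bin_defs[[v]]
    ok <- !is.na(val)
    n1 <- sum(ok & d$fh)
    n2 <- sum(ok & !d$fh)
    if (n1 == 0 || n2 == 0)  # empty comparison group
      return(tibble::tibble(variable = v, type = "binary",
                            estimate_fh = NA_real_,
                            estimate_other = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, flagged = TRUE))
    zt <- prop_z_test(sum(val[ok & d$fh]), n1, sum(val[ok & !d$fh]), n2)
    tibble::tibble(variable = v, type = "binary",
                   estimate_fh = zt$estimate1,
                   estimate_other = zt$estimate2,
                   statistic = zt$statistic, df = NA_real_,
                   p_value = zt$p_value, flagged = FALSE)
  })
  dplyr::bind_rows(c(rows, brows))
}

#' Arm-wise trend in the daily drinking probability
#'
#' Fits, by maximum likelihood, a day-level logistic regression of the
#' drinking indicator on the wave index, an arm indicator and their
#' interaction, within a membership stratum, with cluster-robust (by
#' student) standard errors. The exponentiated interaction coefficient is
#' the odds ratio comparing the two arms' per-wave trends in the daily
#' drinking probability (OR > 1: the first arm reduces its drinking
#' probability less steeply than the second). Also returns the per-wave
#' drinking proportions underlying the trend plots.
#'
#' @param diaries diaries tibble.
#' @param students students tibble with `arm` (or `addon_arm`).
#' @param arms character of length 2: the compared arm (first) and the
#'   reference arm (second).
#' @param membership optional membership tibble from
#'   [classify_membership]; when given, only continual and itinerant
#'   frequent-heavy members enter the model.
#' @param waves waves entering the model (e.g. `1:3` for add-on
#'   contrasts, available from the first follow-up onwards).
#' @param arm_var column of `students` holding the compared assignment
#'   (`"arm"` or `"addon_arm"`).
#' @return an object of class `drinking_trend`: list with `or` (one-row
#'   tibble: `odds_ratio`, `se_log_or`, `conf_low`, `conf_high`,
#'   `p_value`, `flagged`, `note`), `proportions` (per wave x arm), and
#'   the `contrast`.
#' @export
drinking_trend <- function(diaries, students, arms, membership = NULL,
                           waves = 0:3, arm_var = "arm") {
  stopifnot(length(arms) == 2)
  info <- students[c("student_id", arm_var)]
  names(info)[2] <- "group"
  d <- diaries |>
    dplyr::filter(.data$wave %in% waves, !is.na(.data$drinks)) |>
    dplyr::inner_join(info, by = "student_id") |>
    dplyr::filter(.data$group %in% arms)
  if (!is.null(membership)) {
    keep <- membership$student_id[membership$membership %in%
                                    c("continual", "itinerant")]
    d <- d[d$student_id %in% keep, ]
  }
  d$drink <- as.integer(d$drinks > 0)
  d$arm1 <- as.integer(d$group == arms[1])

  props <- d |>
    dplyr::group_by(.data$group, .data$wave, .data$student_id) |>
    dplyr::summarise(any_drinking = any(.data$drink > 0),
                     prop_days = mean(.data$drink), .groups = "drop") |>
    dplyr::group_by(.data$group, .data$wave) |>
    dplyr::summarise(prop_drinking = mean(.data$any_drinking),
                     prop_drinking_days = mean(.data$prop_days),
                     n_students = dplyr::n(), .groups = "drop")

  flagged <- FALSE
  note <- ""
  or_row <- tibble::tibble(odds_ratio = NA_real_, se_log_or = NA_real_,
                           conf_low = NA_real_, conf_high = NA_real_,
                           p_value = NA_real_, flagged = TRUE, note = "")
  n_arm <- length(unique(d$arm1))
  w_obs <- length(unique(d$wave))
  if (nrow(d) == 0 || n_arm < 2 || w_obs < 2 ||
      length(unique(d$drink)) < 2) {
    or_row$note <- "degenerate stratum: no contrast estimable"
  } else {
    fit <- tryCatch(
      glm(drink ~ wave * arm1, family = binomial(), data = d),
      warning = function(w) w, error = function(e) e)
    if (inherits(fit, "glm") && fit$converged) {
      vc <- sandwich::vcovCL(fit, cluster = d$student_id)
      ct <- lmtest::coeftest(fit, vcov. = vc)
      b <- ct["wave:arm1", "Estimate"]
      se <- ct["wave:arm1", "Std. Error"]
      or_row <- tibble::tibble(
        odds_ratio = exp(b), se_log_or = se,
        conf_low = exp(b - qnorm(0.975) * se),
        conf_high = exp(b + qnorm(0.975) * se),
        p_value = ct["wave:arm1", "Pr(>|z|)"],
        flagged = FALSE, note = "")
    } else {
      or_row$note <- "model did not converge (possible separation)"
    }
  }
  structure(list(or = or_row, proportions = props,
                 contrast = paste(arms[1], "vs", arms[2]),
                 n_students = length(unique(d$student_id)),
                 n_days = nrow(d)),
            class = "drinking_trend")
}

#' @export
print.drinking_trend <- function(x, ...) {
  cat("<drinking_trend>", x$contrast, "(", x$n_students, "students,",
      x$n_days, "student-days )\n")
  print(x$or)
  invisible(x)
}

#' @describeIn drinking_trend the odds-ratio row as a tibble.
#' @param x a `drinking_trend`.
#' @param ... unused.
#' @export
tidy.drinking_trend <- function(x, ...) {
  dplyr::mutate(x$or, contrast = x$contrast, .before = 1)
}

#' @describeIn drinking_trend proportion of students drinking per
#'   measurement week, by arm, with a linear trend line.
#' @param object a `drinking_trend`.
#' @export
autoplot.drinking_trend <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$wave, y = .data$prop_drinking)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linetype = "dashed", colour = "grey30") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "measurement wave", y = "proportion drinking",
                  title = object$contrast) +
    ggplot2::theme_minimal()
}
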