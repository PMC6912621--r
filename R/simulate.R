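#' Simulate a synthetic trial cohort with drinking diaries
#'
#' Generates students, randomizes them to the three arms, draws four
#' weekly drinking diaries per student (one at each wave) from the latent
#' drinking classes, assigns the nested add-on arms, and applies
#' wave-level missingness. Every step is driven by the single seed in the
#' configuration, so identical configurations yield identical cohorts.
#'
#' Each student's daily drinking indicator follows their class's weekday
#' profile shifted on the log-odds scale by the arm slope times the wave
#' index; the count on drinking days is a zero-truncated Poisson (or
#' negative binomial, if the class specifies finite dispersion) with the
#' class's conditional mean; classes with `state_persistence < 1` can
#' drift out of their own pattern into the prevalence-weighted average
#' pattern of the other classes.
#'
#' @param config a [sim_config].
#' @param complete if `TRUE` (default) also assign the add-on arms and
#'   apply wave-level missingness; if `FALSE`, stop after arm assignment
#'   with fully observed diaries.
#' @return an object of class `cohort_sim`: a list with tibbles
#'   `students` (one row per participant), `diaries` (long, one row per
#'   student x wave x weekday), and `truth` (the simulated in-pattern
#'   indicator per student-day, for evaluating classification against the
#'   generative truth), plus the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_students = 30, seed = 7))
#' dplyr::count(cohort$students, arm)
#' @export
simulate_cohort <- function(config, complete = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_students
  spec <- config$class_spec
  n_cls <- length(spec)
  prev <- vapply(spec, `[[`, 0, "prevalence")
  labels <- vapply(spec, `[[`, "", "label")
  fh_flag <- vapply(spec, `[[`, TRUE, "frequent_heavy")

  cls <- sample.int(n_cls, n, replace = TRUE, prob = prev)
  is_fh <- fh_flag[cls]
  shift <- config$fh_covariate_shift

  p_w <- ifelse(is_fh, shift$prop_women, config$prop_women)
  gender <- ifelse(runif(n) < p_w, "W", "M")
  age <- pmax(18, rnorm(n, config$age_mean + is_fh * shift$age,
                        config$age_sd))
  weight <- rtrunc_norm(n, config$weight_mean_by_gender[gender],
                        config$weight_sd_by_gender[gender], lower = 45)
  audit_lo <- ifelse(gender == "W", 6L, 8L)  # hazardous-use inclusion
  audit <- pmin(40L, pmax(audit_lo,
                          round(rnorm(n, config$audit_mean +
                                        is_fh * shift$audit,
                                      config$audit_sd))))
  motivation <- pmin(10L, pmax(0L, round(rnorm(n, config$motivation_mean,
                                               config$motivation_sd))))

  students <- tibble::tibble(
    student_id = sprintf("S%05d", seq_len(n)),
    gender = gender, age = age, weight = weight,
    audit = as.integer(audit), motivation = as.integer(motivation),
    true_class = labels[cls])
  students <- assign_arms(students, config$arm_ratio,
                          seed = config$seed + 1L)
  students$addon_arm <- "none"

  # prevalence-weighted mean profile of the other classes: the behaviour
  # of a member who has drifted out of their own pattern
  profiles <- vapply(spec, `[[`, numeric(7), "drink_prob_by_weekday")
  drift_prof <- vapply(seq_len(n_cls), function(k) {
    w <- prev
    w[k] <- 0
    if (sum(w) == 0) return(profiles[, k])
    as.numeric(profiles %*% (w / sum(w)))
  }, numeric(7))  # 7 x n_cls

  slope <- config$arm_slope_logodds[as.character(students$arm)]
  wd <- rep(1:7, 4)
  wave_of_day <- rep(0:3, each = 7)

  in_pattern <- matrix(TRUE, n, 28)
  for (k in which(vapply(spec, `[[`, 0, "state_persistence") < 1)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    stay <- spec[[k]]$state_persistence
    back <- config$pattern_return_prob
    state <- rep(TRUE, length(idx))
    for (t in 1:28) {
      in_pattern[idx, t] <- state
      u <- runif(length(idx))
      state <- ifelse(state, u < stay, u < back)
    }
  }

  p_own <- t(profiles[wd, cls])       # n x 28 own-pattern probabilities
  p_drift <- t(drift_prof[wd, cls])
  p_day <- ifelse(in_pattern, p_own, p_drift)
  eta <- qlogis(p_day) + slope %o% wave_of_day
  p_day <- plogis(eta)
  p_day[is.nan(p_day)] <- 0  # qlogis(0) - Inf*0 edge: a never-drinking day stays 0

  drink <- matrix(runif(n * 28), n) < p_day
  counts <- matrix(0L, n, 28)
  for (k in seq_len(n_cls)) {
    sel <- drink & (cls == k)
    nk <- sum(sel)
    if (!nk) next
    m <- spec[[k]]$quantity_mean_given_drinking
    disp <- spec[[k]]$quantity_dispersion
    counts[sel] <- if (is.finite(disp)) rztnbinom(nk, m, disp)
                   else rztpois(nk, ztp_rate_from_mean(m))
  }

  diaries <- tibble::tibble(
    student_id = rep(students$student_id, each = 28),
    wave = rep(wave_of_day, n),
    weekday = rep(wd, n),
    drinks = as.integer(t(counts)))
  diaries$hours <- ifelse(diaries$drinks > 0,
                          pmax(1, diaries$drinks / 2), NA_real_)
  truth <- tibble::tibble(
    student_id = diaries$student_id, wave = diaries$wave,
    weekday = diaries$weekday,
    in_fh_pattern = as.logical(t(in_pattern)) & rep(is_fh, each = 28))

  if (complete) {
    diaries <- apply_missingness(diaries, students,
                                 config$response_rate_by_wave,
                                 seed = config$seed + 2L,
                                 mar_audit_logodds = config$mar_audit_logodds)
    students <- assign_addon(students, diaries, seed = config$seed + 3L)
  }

  structure(list(students = students, diaries = diaries, truth = truth,
                 config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", nrow(x$students), "students,",
      nrow(x$diaries), "diary days (",
      sum(is.na(x$diaries$drinks)), "missing )\n")
  print(dplyr::count(x$students, .data$arm, .data$addon_arm))
  invisible(x)
}

# normal draws truncated below, by rejection
rtrunc_norm <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Block-randomize students to the trial arms
#'
#' Assigns arms (control, promillekoll, partyplanner) in the exact target
#' counts implied by the ratio (largest-remainder apportionment, so counts
#' differ by at most one under a 1:1:1 ratio) and a seeded random
#' permutation.
#'
#' @param students students tibble.
#' @param ratio three nonnegative weights for (control, promillekoll,
#'   partyplanner).
#' @param seed integer seed.
#' @return the students tibble with an `arm` factor column.
#' @export
assign_arms <- function(students, ratio = c(1, 1, 1), seed = 1L) {
  if (length(ratio) != 3 || any(ratio < 0) || sum(ratio) <= 0)
    stop("ratio needs 3 nonnegative entries, not all zero")
  arms <- c("control", "promillekoll", "partyplanner")
  n <- nrow(students)
  if (n == 0) {
    students$arm <- factor(character(), levels = arms)
    return(students)
  }
  w <- ratio / sum(ratio)
  counts <- floor(n * w)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * w - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  set.seed(seed)
  students$arm <- factor(sample(rep(arms, counts)), levels = arms)
  students
}

#' Assign the nested add-on arms
#'
#' App-arm students who report excessive weekly consumption (over 9
#' drinks/week for women, 14 for men) at the first follow-up are split 1:1
#' into the skills-based add-on (`telecoach`) and a waitlist; control-arm
#' students excessive at baseline form the assessment-only comparison
#' group. Students with a missing eligibility wave are not considered.
#'
#' @param students students tibble with `arm` and `gender`.
#' @param diaries diaries tibble.
#' @param seed integer seed.
#' @param app_wave wave used for app-arm eligibility (default 1, the 7
#'   week follow-up).
#' @param control_wave wave used for control-arm eligibility (default 0,
#'   baseline).
#' @return the students tibble with an `addon_arm` column.
#' @export
assign_addon <- function(students, diaries, seed = 1L, app_wave = 1L,
                         control_wave = 0L) {
  qty <- diaries |>
    dplyr::group_by(.data$student_id, .data$wave) |>
    dplyr::summarise(quantity = if (all(is.na(.data$drinks))) NA_real_
                     else sum(.data$drinks), .groups = "drop")
  get_qty <- function(w) {
    q <- qty$quantity[qty$wave == w]
    names(q) <- qty$student_id[qty$wave == w]
    unname(q[students$student_id])
  }
  q_app <- get_qty(app_wave)
  q_ctl <- get_qty(control_wave)
  exc_app <- !is.na(q_app) & is_excessive(q_app, students$gender)
  exc_ctl <- !is.na(q_ctl) & is_excessive(q_ctl, students$gender)

  addon <- rep("none", nrow(students))
  eligible <- which(students$arm %in% c("promillekoll", "partyplanner") &
                    exc_app)
  set.seed(seed)
  if (length(eligible)) {
    perm <- sample(eligible)
    half <- ceiling(length(perm) / 2)
    addon[perm[seq_len(half)]] <- "telecoach"
    if (length(perm) > half)
      addon[perm[(half + 1):length(perm)]] <- "waitlist"
  }
  addon[students$arm == "control" & exc_ctl] <- "assessment_control"
  students$addon_arm <- factor(addon, levels = c("none", "telecoach",
                                                 "waitlist",
                                                 "assessment_control"))
  students
}

#' Apply wave-level missingness to the diaries
#'
#' Drops whole follow-up waves (all 7 days jointly) with probability one
#' minus the configured response rate; the baseline wave is never dropped.
#' Missingness may depend on the observed baseline AUDIT score (a
#' missing-at-random mechanism) through `mar_audit_logodds`.
#'
#' @param diaries diaries tibble.
#' @param students students tibble (for the AUDIT covariate).
#' @param response_rate_by_wave response probabilities for waves 1-3.
#' @param seed integer seed.
#' @param mar_audit_logodds response log-odds shift per AUDIT point above
#'   the cohort mean; 0 gives pure per-wave rates.
#' @return the diaries tibble with dropped waves set to `NA`.
#' @export
apply_missingness <- function(diaries, students, response_rate_by_wave,
                              seed = 1L, mar_audit_logodds = 0) {
  if (length(response_rate_by_wave) != 3 ||
      any(response_rate_by_wave < 0 | response_rate_by_wave > 1))
    stop("response rates must be 3 fractions in [0, 1]")
  set.seed(seed)
  audit <- setNames(students$audit, students$student_id)
  ids <- unique(diaries$student_id)
  centred <- audit[ids] - mean(audit)
  dropped <- matrix(FALSE, length(ids), 3, dimnames = list(ids, NULL))
  for (w in 1:3) {
    p_obs <- plogis(qlogis(response_rate_by_wave[w]) +
                    mar_audit_logodds * centred)
    p_obs[is.na(p_obs) | is.nan(p_obs)] <-
      response_rate_by_wave[w]  # rate 0/1: logit is infinite, keep exact
    if (response_rate_by_wave[w] %in% c(0, 1))
      p_obs <- rep(response_rate_by_wave[w], length(ids))
    dropped[, w] <- runif(length(ids)) >= p_obs
  }
  hit <- rep(FALSE, nrow(diaries))
  fu <- which(diaries$wave >= 1)
  hit[fu] <- dropped[cbind(match(diaries$student_id[fu], ids),
                           diaries$wave[fu])]
  diaries$drinks[hit] <- NA_integer_
  diaries$hours[hit] <- NA_real_
  diaries
}
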