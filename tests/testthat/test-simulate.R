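no_slopes <- c(control = 0, promillekoll = 0, partyplanner = 0)

test_that("identical configurations give bit-identical cohorts", {
  cfg <- sim_config(n_students = 80, seed = 19)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$students, b$students)
  expect_identical(a$diaries, b$diaries)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate classes produce degenerate diaries", {
  never <- list(latent_class("dry", 1, rep(0, 7), 2))
  cfg <- sim_config(n_students = 10, class_spec = never,
                    response_rate_by_wave = c(1, 1, 1),
                    mar_audit_logodds = 0, seed = 42)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$diaries), 10 * 28)
  expect_true(all(co$diaries$drinks == 0))

  always <- list(latent_class("daily", 1, rep(1, 7), 3))
  cfg2 <- sim_config(n_students = 10, class_spec = always,
                     arm_slope_logodds = no_slopes,
                     response_rate_by_wave = c(1, 1, 1),
                     mar_audit_logodds = 0, seed = 42)
  co2 <- simulate_cohort(cfg2)
  expect_true(all(co2$diaries$drinks >= 1))
  expect_true(all(co2$diaries$hours > 0))
})

test_that("block randomization hits exact arm counts", {
  st <- tibble::tibble(student_id = as.character(1:6))
  expect_equal(unname(table(assign_arms(st, c(1, 1, 1), 1)$arm)),
               rep(2L, 3), ignore_attr = TRUE)
  st2 <- tibble::tibble(student_id = as.character(1:2166))
  expect_equal(unname(c(table(assign_arms(st2, c(1, 1, 1), 5)$arm))),
               rep(722L, 3))
  st3 <- assign_arms(st2, c(1, 0, 0), 2)
  expect_true(all(st3$arm == "control"))
  # permutation is deterministic given the seed
  expect_identical(assign_arms(st2, c(1, 1, 1), 7)$arm,
                   assign_arms(st2, c(1, 1, 1), 7)$arm)
  expect_equal(nrow(assign_arms(st[0, ], c(1, 1, 1), 1)), 0)
})

test_that("add-on assignment follows the excessive-drinking eligibility rules", {
  mk_diary <- function(id, wave, total) {
    tibble::tibble(student_id = id, wave = wave, weekday = 1:7,
                   drinks = c(total, rep(0L, 6)),
                   hours = c(ifelse(total > 0, total / 2, NA), rep(NA, 6)))
  }
  st <- tibble::tibble(
    student_id = c("a", "b", "c", "d", "e", "f"),
    gender = c("W", "M", "W", "W", "M", "M"),
    arm = factor(c("promillekoll", "partyplanner", "promillekoll",
                   "partyplanner", "promillekoll", "control"),
                 levels = c("control", "promillekoll", "partyplanner")))
  di <- dplyr::bind_rows(
    mk_diary("a", 1, 10L),   # W, 10 > 9: eligible
    mk_diary("b", 1, 14L),   # M, 14 <= 14: not eligible
    mk_diary("c", 1, 12L),   # eligible
    mk_diary("d", 1, 11L),   # eligible
    mk_diary("e", 1, 20L),   # eligible
    mk_diary("f", 0, 30L))   # control arm, excessive at baseline
  out <- assign_addon(st, di, seed = 4)
  expect_equal(as.character(out$addon_arm[out$student_id == "b"]), "none")
  four <- out$addon_arm[out$student_id %in% c("a", "c", "d", "e")]
  expect_equal(sum(four == "telecoach"), 2)
  expect_equal(sum(four == "waitlist"), 2)
  expect_equal(as.character(out$addon_arm[out$student_id == "f"]),
               "assessment_control")
})

test_that("wave-level missingness respects the configured rates", {
  co <- simulate_cohort(sim_config(n_students = 40, seed = 2),
                        complete = FALSE)
  d1 <- apply_missingness(co$diaries, co$students, c(1, 1, 1), seed = 1)
  expect_false(anyNA(d1$drinks))
  d0 <- apply_missingness(co$diaries, co$students, c(0, 0, 0), seed = 1)
  expect_true(all(is.na(d0$drinks[d0$wave > 0])))
  expect_false(anyNA(d0$drinks[d0$wave == 0]))
  # observed fraction concentrates around the rate
  co2 <- simulate_cohort(sim_config(n_students = 5000, seed = 8),
                         complete = FALSE)
  d2 <- apply_missingness(co2$diaries, co2$students, c(0.7, 0.6, 0.8),
                          seed = 3)
  obs1 <- with(d2[d2$wave == 1, ], mean(!is.na(drinks)))
  expect_lt(abs(obs1 - 0.7), 0.02)
  expect_error(apply_missingness(co$diaries, co$students, c(1.2, 1, 1), 1),
               "rates")
})

test_that("cohort marginals match the configuration within 3 standard errors", {
  cfg <- sim_config(seed = 31)  # default 2166 students
  co <- simulate_cohort(cfg)
  n <- nrow(co$students)
  # gender (frequent-heavy class shifts it slightly; bound still holds)
  p_w <- mean(co$students$gender == "W")
  p_cfg <- 0.93 * 0.675 + 0.07 * 0.48
  expect_lt(abs(p_w - p_cfg), 3 * sqrt(p_cfg * (1 - p_cfg) / n))
  # class prevalences
  prev <- vapply(cfg$class_spec, `[[`, 0, "prevalence")
  names(prev) <- vapply(cfg$class_spec, `[[`, "", "label")
  emp <- table(co$students$true_class) / n
  for (cl in names(prev))
    expect_lt(abs(emp[[cl]] - prev[[cl]]),
              3 * sqrt(prev[[cl]] * (1 - prev[[cl]]) / n))
  # per-wave response fractions
  for (w in 1:3) {
    rate <- cfg$response_rate_by_wave[w]
    obs <- with(co$diaries[co$diaries$wave == w, ], mean(!is.na(drinks)))
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / n) + 0.005)
  }
  # inclusion-style covariate ranges
  expect_true(all(co$students$audit >= 6 & co$students$audit <= 40))
  expect_true(all(co$students$motivation >= 0 &
                    co$students$motivation <= 10))
  expect_true(all(co$students$weight >= 45))
})

test_that("frequent-heavy drinking days match an independent Monte-Carlo oracle", {
  cfg <- sim_config(n_students = 2000, seed = 1)
  co <- simulate_cohort(cfg)
  fh_ids <- co$students$student_id[co$students$true_class ==
                                     "frequent_heavy"]
  d <- co$diaries[co$diaries$student_id %in% fh_ids &
                    !is.na(co$diaries$drinks), ]
  emp <- 7 * mean(d$drinks > 0)
  oracle <- mc_fh_days_per_week(
    fh_p = 0.65, drift_profile = drift_profile_of(cfg$class_spec),
    persistence = 0.992, return_prob = cfg$pattern_return_prob,
    slopes = unname(cfg$arm_slope_logodds), n = 100000, seed = 99)
  expect_lt(abs(emp - oracle), 0.3)
  # without arm slopes, a 0.65 daily drinking probability implies close
  # to 7 x 0.65 = 4.55 drinking days/week
  oracle_flat <- mc_fh_days_per_week(
    fh_p = 0.65, drift_profile = drift_profile_of(cfg$class_spec),
    persistence = 0.992, return_prob = cfg$pattern_return_prob,
    slopes = c(0, 0, 0), n = 100000, seed = 99)
  expect_lt(abs(oracle_flat - 4.55), 0.3)
})

test_that("zero arm slopes leave the pooled drinking trend flat", {
  cfg <- sim_config(n_students = 3000, arm_slope_logodds = no_slopes,
                    response_rate_by_wave = c(1, 1, 1),
                    mar_audit_logodds = 0, seed = 13)
  co <- simulate_cohort(cfg)
  pw <- tapply(co$diaries$drinks > 0, co$diaries$wave, mean)
  # per-wave proportions of drinking days stay within sampling noise
  se <- sqrt(mean(pw) * (1 - mean(pw)) / (3000 * 7))
  expect_lt(max(pw) - min(pw), 4 * se + 0.005)
})
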