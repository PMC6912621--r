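# minimal decoding tibble builder: one student per path
mk_decoding <- function(paths, observed = NULL) {
  n <- length(paths)
  T_len <- length(paths[[1]])
  if (is.null(observed)) observed <- lapply(paths, function(p) rep(TRUE, T_len))
  tibble::tibble(
    student_id = rep(sprintf("s%02d", seq_len(n)), each = T_len),
    day = rep(seq_len(T_len), n),
    wave = (rep(seq_len(T_len), n) - 1L) %/% 7L,
    weekday = (rep(seq_len(T_len), n) - 1L) %% 7L + 1L,
    drinks = 0L,
    observed = unlist(observed),
    state = unlist(paths))
}

test_that("frequent-heavy identification applies the days and stability rules", {
  mk <- function(p, self) {
    K <- length(p)
    A <- matrix((1 - self) / (K - 1), K, K)
    diag(A) <- self
    hmm_parameters(rep(1 / K, K), A, p, rep(3, K))
  }
  # 7 x 0.65 = 4.55 days/week, self-transition 0.9: qualifies
  expect_equal(identify_frequent_heavy(mk(c(0.1, 0.1, 0.65),
                                          c(0.3, 0.3, 0.9))), 3L)
  # nothing drinks often enough
  expect_true(is.na(identify_frequent_heavy(mk(c(0.1, 0.2, 0.3),
                                               c(0.9, 0.9, 0.9)))))
  # stability gate: frequent but unstable state is not eligible
  expect_true(is.na(identify_frequent_heavy(mk(c(0.7, 0.1), c(0.4, 0.9)))))
  # two qualifying states: more drinking days wins
  expect_equal(identify_frequent_heavy(mk(c(0.6, 0.8), c(0.9, 0.9))), 2L)
  # exact tie on days: larger self-transition wins
  expect_equal(identify_frequent_heavy(mk(c(0.7, 0.7), c(0.8, 0.95))), 2L)
})

test_that("states lock to calendar weekdays through decoded occupancy", {
  A <- matrix(c(0.9, 0.4, 0.1, 0.6), 2)
  # neither state drinks often enough to be frequent-heavy (7 x 0.4 < 3.5)
  par <- hmm_parameters(c(0.5, 0.5), A, c(0.1, 0.4), c(2, 4))
  # state 2 occupied only at 0-based positions 4, 11, 18, 25 -> Friday
  path <- rep(1L, 28)
  path[c(5, 12, 19, 26)] <- 2L
  lab <- label_states(par, mk_decoding(list(path)))
  expect_equal(lab$label[2], "friday")
  expect_equal(lab$share_fri[2], 1)
  # occupancy spread evenly over all weekdays (share 1/7) stays unlabeled
  lab2 <- label_states(par, mk_decoding(list(rep(1L, 28))))
  expect_equal(lab2$label[1], "unlabeled")
  expect_equal(max(lab2[1, paste0("share_", c("mon", "tue", "wed", "thu",
                                              "fri", "sat", "sun"))]),
               1 / 7, tolerance = 1e-12)
  expect_error(label_states(par, NULL), "decod")
})

test_that("membership classification follows the decoded path semantics", {
  paths <- list(rep(2L, 28),                      # continual
                c(rep(2L, 20), rep(1L, 8)),       # itinerant
                rep(1L, 28))                      # never in the state
  dec <- mk_decoding(paths)
  m <- classify_membership(dec, fh_state = 2)
  expect_equal(as.character(m$membership), c("continual", "itinerant",
                                             "non_member"))
  # only observed days count; a student with zero observed days is dropped
  obs <- list(rep(TRUE, 28), rep(TRUE, 28), rep(FALSE, 28))
  expect_warning(m2 <- classify_membership(mk_decoding(paths, obs), 2),
                 "zero observed")
  expect_equal(nrow(m2), 2)
  # continual + itinerant + non-member partition the decoded cohort
  expect_equal(sum(table(m$membership)), 3)
})

test_that("pooled-Z statistics reproduce the printed baseline comparisons", {
  z1 <- prop_z_test(76, 146, 628, 2020)
  expect_lt(abs(abs(z1$statistic) - 5.2231), 0.01)
  z2 <- prop_z_test(94, 146, 575, 2020)
  expect_lt(abs(z2$statistic - 9.0714), 0.01)
  # agreement with the uncorrected chi-square proportions test
  pt <- prop.test(c(76, 628), c(146, 2020), correct = FALSE)
  expect_equal(z1$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(z1$p_value, pt$p.value, tolerance = 1e-10)
  # identical groups: Z = 0
  expect_equal(prop_z_test(5, 10, 50, 100)$statistic, 0)
})

test_that("group comparison runs Welch t and pooled Z with correct directions", {
  set.seed(4)
  co <- simulate_cohort(sim_config(n_students = 1200, seed = 4))
  out <- derive_outcomes(co$diaries, co$students)
  # membership from the generative class: isolates the comparison itself
  memb <- tibble::tibble(
    student_id = co$students$student_id,
    membership = factor(ifelse(co$students$true_class == "frequent_heavy",
                               "continual", "non_member"),
                        levels = c("continual", "itinerant", "non_member")))
  gs <- compare_groups(co$students, out, memb)
  get <- function(v) gs[gs$variable == v, ]
  # configured directions: frequent-heavy members are older, more often
  # male, higher AUDIT, and drink more, more often
  for (v in c("age", "audit", "quantity", "frequency", "gender_m",
              "excessive")) {
    expect_gt(get(v)$statistic, 0)
    expect_lt(get(v)$p_value, 0.05)
  }
  expect_true(all(is.finite(gs$df[gs$type == "continuous"])))
  # identical groups give a zero t statistic
  st <- tibble::tibble(student_id = as.character(1:8),
                       gender = rep(c("M", "W"), 4),
                       age = rep(c(20, 30), 4), weight = 70,
                       audit = rep(c(8, 12), 4),
                       motivation = rep(c(4, 6), 4))
  memb0 <- tibble::tibble(student_id = as.character(1:8),
                          membership = factor(rep(c("continual",
                                                    "non_member"),
                                                  each = 4),
                                              levels = levels(memb$membership)))
  st$age <- rep(c(20, 30), 4)  # same mean in both halves
  out0 <- tibble::tibble(student_id = as.character(1:8), wave = 0,
                         quantity = rep(c(5, 9), 4),
                         frequency = rep(c(1, 2), 4),
                         binge_occasions = 0, weekly_mean_ebac = 0.01,
                         peak_ebac_month = 0.05,
                         excessive = rep(c(FALSE, TRUE), 4),
                         hazardous = TRUE)
  gs0 <- compare_groups(st, out0, memb0)
  expect_equal(gs0$statistic[gs0$variable == "age"], 0, tolerance = 1e-12)
  expect_equal(gs0$statistic[gs0$variable == "gender_m"], 0)
})

test_that("trend estimator is unbiased under the null and flags degeneracy", {
  flat <- list(latent_class("fh", 1, rep(0.65, 7), 3.6))
  cfg <- sim_config(n_students = 250, arm_ratio = c(1, 1, 0),
                    class_spec = flat,
                    arm_slope_logodds = c(control = -0.04,
                                          promillekoll = -0.04,
                                          partyplanner = 0),
                    response_rate_by_wave = c(1, 1, 1),
                    mar_audit_logodds = 0, seed = 55)
  co <- simulate_cohort(cfg)
  tr <- drinking_trend(co$diaries, co$students,
                       arms = c("control", "promillekoll"))
  expect_false(tr$or$flagged)
  expect_true(tr$or$conf_low < 1 & 1 < tr$or$conf_high)
  expect_equal(nrow(tr$proportions), 8)  # 2 arms x 4 waves
  # all-zero stratum cannot support an estimate
  co0 <- co
  co0$diaries$drinks <- 0L
  tr0 <- drinking_trend(co0$diaries, co0$students,
                        arms = c("control", "promillekoll"))
  expect_true(tr0$or$flagged)
  expect_true(is.na(tr0$or$odds_ratio))
})
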