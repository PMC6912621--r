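# Independent oracles used across the suite. These stay deliberately naive
# (exhaustive enumeration, direct Monte Carlo) and never call the code paths
# they check.

# log-likelihood by exhaustive sum over all K^T state paths
bf_loglik <- function(seq, par) {
  K <- par$K
  T_len <- length(seq)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(st) {
    l <- log(par$initial[st[1]]) +
      emission_logprob(seq[1], par$p_drink[st[1]], par$lambda[st[1]])
    for (t in seq_len(T_len)[-1])
      l <- l + log(par$transition[st[t - 1], st[t]]) +
        emission_logprob(seq[t], par$p_drink[st[t]], par$lambda[st[t]])
    l
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most probable path by exhaustive argmax; expand.grid varies the first
# day fastest, so enumeration order is lexicographic in the path and
# which.max resolves ties toward lower state indices on earlier days
bf_viterbi <- function(seq, par) {
  K <- par$K
  T_len <- length(seq)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(st) {
    l <- log(par$initial[st[1]]) +
      emission_logprob(seq[1], par$p_drink[st[1]], par$lambda[st[1]])
    for (t in seq_len(T_len)[-1])
      l <- l + log(par$transition[st[t - 1], st[t]]) +
        emission_logprob(seq[t], par$p_drink[st[t]], par$lambda[st[t]])
    l
  })
  unname(paths[which.max(lp), ])
}

# random valid parameter set for property tests
rand_params <- function(K) {
  pi0 <- rgamma(K, 1) + 0.05
  A <- matrix(rgamma(K * K, 1) + 0.05, K)
  hmm_parameters(pi0 / sum(pi0), A / rowSums(A),
                 runif(K, 0.05, 0.95), runif(K, 0.5, 6))
}

# random observation sequence with occasional missing days
rand_seq <- function(T_len, p_missing = 0.2) {
  y <- rpois(T_len, 1.5)
  y[runif(T_len) < p_missing] <- NA
  y
}

# align estimated states to truth: the permutation minimizing total
# emission-parameter error (exhaustive over permutations, fine for K <= 4)
match_states <- function(est, truth) {
  K <- truth$K
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  err <- apply(perms, 1, function(p)
    sum(abs(est$p_drink[p] - truth$p_drink)) +
      sum(abs(est$lambda[p] - truth$lambda)) / 10)
  p <- perms[which.min(err), ]
  hmm_parameters(est$initial[p], est$transition[p, p, drop = FALSE],
                 est$p_drink[p], est$lambda[p])
}

# Monte-Carlo oracle for the frequent-heavy class's expected drinking
# days/week: direct simulation of the in/out-of-pattern switching plus
# the weekday drinking profiles, independent of the package generator
mc_fh_days_per_week <- function(fh_p = 0.65, drift_profile,
                                persistence = 0.992, return_prob = 0.02,
                                slopes = c(-0.02, -0.05, -0.04),
                                n = 100000, seed = 1) {
  set.seed(seed)
  wd <- rep(1:7, 4)
  wave <- rep(0:3, each = 7)
  slope <- sample(slopes, n, replace = TRUE)  # arms equally likely
  state <- rep(TRUE, n)
  days <- numeric(n)
  for (t in 1:28) {
    p <- ifelse(state, fh_p, drift_profile[wd[t]])
    p <- plogis(qlogis(p) + slope * wave[t])
    days <- days + (runif(n) < p)
    u <- runif(n)
    state <- ifelse(state, u < persistence, u < return_prob)
  }
  mean(days) / 4
}

# drift profile implied by a class spec: prevalence-weighted mean weekday
# profile of the non-frequent-heavy classes
drift_profile_of <- function(class_spec) {
  fh <- vapply(class_spec, `[[`, TRUE, "frequent_heavy")
  prev <- vapply(class_spec, `[[`, 0, "prevalence")[!fh]
  profs <- vapply(class_spec[!fh], `[[`, numeric(7),
                  "drink_prob_by_weekday")
  as.numeric(profs %*% (prev / sum(prev)))
}

# generative membership truth over observed days of a simulated cohort
true_membership <- function(cohort) {
  obs <- !is.na(cohort$diaries$drinks)
  d <- cohort$truth[obs, ]
  agg <- stats::aggregate(in_fh_pattern ~ student_id, data = d,
                          FUN = function(x) c(n_in = sum(x), n = length(x)))
  n_in <- agg$in_fh_pattern[, "n_in"]
  n_obs <- agg$in_fh_pattern[, "n"]
  data.frame(student_id = agg$student_id,
             truth = ifelse(n_in == 0, "non_member",
                            ifelse(n_in == n_obs, "continual",
                                   "itinerant")))
}

balanced_accuracy <- function(truth, pred) {
  lv <- c("continual", "itinerant", "non_member")
  tab <- table(factor(truth, lv), factor(pred, lv))
  mean(vapply(lv, function(l) {
    n <- sum(tab[l, ])
    if (n == 0) NA_real_ else tab[l, l] / n
  }, numeric(1)), na.rm = TRUE)
}
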