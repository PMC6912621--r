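toy2 <- hmm_parameters(c(0.6, 0.4),
                       matrix(c(0.8, 0.3, 0.2, 0.7), 2),
                       p_drink = c(0.1, 0.8), lambda = c(1, 4))

test_that("hurdle emission log-probabilities match closed forms", {
  expect_equal(emission_logprob(0, 0.5, 2), log(0.5), tolerance = 1e-12)
  expect_identical(emission_logprob(NA, 0.5, 2), 0)  # marginalized out
  # obs 2, p .5, lambda 2: log(0.5 x ZTP(2; 2))
  expect_equal(emission_logprob(2, 0.5, 2),
               log(0.5 * dpois(2, 2) / (1 - exp(-2))), tolerance = 1e-12)
  expect_equal(round(emission_logprob(2, 0.5, 2), 4), -1.8546)
  expect_error(emission_logprob(-1, 0.5, 2), "negative")
})

test_that("single-state model reduces to independent emissions", {
  par1 <- hmm_parameters(1, matrix(1), 0.4, 2.5)
  s <- c(0, 3, NA, 1, 0)
  fb <- forward_backward(s, par1)
  expect_equal(fb$loglik, sum(emission_logprob(s, 0.4, 2.5)),
               tolerance = 1e-10)
  expect_true(all(fb$posterior == 1))
  expect_equal(viterbi_path(s, par1), rep(1L, 5))
})

test_that("an all-missing sequence carries no evidence", {
  s <- rep(NA_integer_, 6)
  fb <- forward_backward(s, toy2)
  expect_equal(fb$loglik, 0, tolerance = 1e-12)
  # posteriors follow the chain marginals from pi and A
  marg <- toy2$initial
  for (t in 1:6) {
    expect_equal(unname(fb$posterior[t, ]), unname(marg),
                 tolerance = 1e-10)
    marg <- as.numeric(marg %*% toy2$transition)
  }
})

test_that("forward-backward and Viterbi agree with exhaustive enumeration", {
  set.seed(5)
  for (i in 1:8) {
    s <- rand_seq(6, p_missing = ifelse(i %% 2, 0, 0.3))
    fb <- forward_backward(s, toy2)
    expect_equal(fb$loglik, bf_loglik(s, toy2), tolerance = 1e-10)
    expect_equal(viterbi_path(s, toy2), bf_viterbi(s, toy2))
    expect_equal(rowSums(fb$posterior), rep(1, 6), tolerance = 1e-9)
  }
  expect_error(forward_backward(integer(0), toy2), "length")
})

test_that("a deterministic chain decodes to the emission-matching state", {
  par <- hmm_parameters(c(0.5, 0.5), diag(2),
                        p_drink = c(0.01, 0.99), lambda = c(1, 5))
  expect_equal(viterbi_path(c(3, 4, 5, 2, 6), par), rep(2L, 5))
  expect_equal(viterbi_path(rep(0L, 5), par), rep(1L, 5))
})

test_that("missing days never alter the observed days' emission contributions", {
  set.seed(11)
  for (i in 1:5) {
    s <- rpois(6, 2)
    s_gap <- c(s[1:3], NA, s[4:6])
    # brute-force oracle treats the inserted day as emission probability 1
    expect_equal(forward_backward(s_gap, toy2)$loglik,
                 bf_loglik(s_gap, toy2), tolerance = 1e-10)
  }
})

test_that("EM recovers a single-state hurdle model and keeps its invariants", {
  truth <- hmm_parameters(1, matrix(1), 0.35, 2.2)
  sim <- simulate_hmm(500, 28, truth, seed = 21)
  fit <- hmm_fit(sim$counts, K = 1, n_restarts = 2, seed = 3)
  expect_lt(abs(fit$params$p_drink - 0.35), 0.02)
  expect_lt(abs(fit$params$lambda - 2.2), 0.1)
  expect_true(fit$converged)
  # monotone likelihood trace
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # BIC bookkeeping
  expect_equal(fit$n_free_params, (1 - 1) + 1 * 0 + 2 * 1)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_free_params * log(fit$n_obs))
})

test_that("all-zero sequences give exactly zero drinking probability", {
  Y <- matrix(0L, 20, 28)
  expect_warning(fit <- hmm_fit(Y, K = 2, n_restarts = 2, seed = 1),
                 "distinct")
  fit1 <- suppressWarnings(hmm_fit(Y, K = 1, n_restarts = 2, seed = 1))
  expect_identical(fit1$params$p_drink, 0)
  expect_equal(fit1$loglik, 0)
})

test_that("EM keeps simplex constraints and a monotone likelihood at K = 2", {
  truth <- hmm_parameters(c(0.5, 0.5),
                          matrix(c(0.9, 0.2, 0.1, 0.8), 2),
                          p_drink = c(0.1, 0.7), lambda = c(1.5, 4))
  sim <- simulate_hmm(150, 28, truth, seed = 5)
  fit <- hmm_fit(sim$counts, K = 2, n_restarts = 3, seed = 7)
  p <- fit$params
  expect_equal(sum(p$initial), 1, tolerance = 1e-9)
  expect_equal(rowSums(p$transition), c(1, 1), tolerance = 1e-9)
  expect_true(all(p$p_drink >= 0 & p$p_drink <= 1))
  expect_true(all(p$lambda > 0))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # tolerance must be positive
  expect_error(hmm_fit(sim$counts, K = 2, tol = 0), "tol")
})

test_that("BIC selection prefers the parsimonious fit on degenerate data", {
  Y <- matrix(0L, 15, 28)
  sc <- suppressWarnings(hmm_select(Y, K_range = 1:2, n_restarts = 2,
                                    seed = 2))
  expect_equal(sc$best_K, 1L)  # equal likelihood, fewer parameters
  expect_equal(nrow(tidy(sc)), 2)
})
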