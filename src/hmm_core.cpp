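// Scaled forward-backward, posterior smoothing and Viterbi decoding for a
// population HMM over equal-length daily drink-count sequences.
//
// Emission probabilities are passed as a lookup table E ((ymax + 2) x K):
// row y holds P(obs = y | state k) for y = 0..ymax, and the final row holds
// 1 for a missing observation (marginalized out of the likelihood).
// Yidx (n x T) holds the row index of each observation (0-based), with
// missing days pointing at the final row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TINY = 1e-300;

// E-step for Baum-Welch: total log-likelihood, initial-state and transition
// expected counts, and the emission sufficient statistics
// (sum of gamma over observed days / drinking days / drinks on drinking days).
// [[Rcpp::export]]
List cpp_hmm_estep(const arma::mat& E, const arma::umat& Yidx,
                   const arma::vec& pi, const arma::mat& A) {
  const arma::uword n = Yidx.n_rows, T = Yidx.n_cols, K = pi.n_elem;
  const arma::uword miss = E.n_rows - 1;  // row index meaning "missing"

  arma::cube alpha(n, K, T);
  arma::mat cs(n, T);

  // forward pass with per-sequence scaling
  arma::mat a(n, K);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword k = 0; k < K; ++k)
      a(i, k) = pi(k) * E(Yidx(i, 0), k);
  arma::vec ct = arma::sum(a, 1);
  ct.transform([](double v) { return v > TINY ? v : TINY; });
  a.each_col() /= ct;
  cs.col(0) = ct;
  alpha.slice(0) = a;

  for (arma::uword t = 1; t < T; ++t) {
    a = a * A;
    for (arma::uword i = 0; i < n; ++i) {
      const arma::uword y = Yidx(i, t);
      for (arma::uword k = 0; k < K; ++k) a(i, k) *= E(y, k);
    }
    ct = arma::sum(a, 1);
    ct.transform([](double v) { return v > TINY ? v : TINY; });
    a.each_col() /= ct;
    cs.col(t) = ct;
    alpha.slice(t) = a;
  }
  const double ll = arma::accu(arma::log(cs));

  // backward pass, accumulating transition counts and emission statistics
  arma::mat b(n, K, arma::fill::ones);
  arma::mat xi(K, K, arma::fill::zeros);
  arma::vec s_obs(K, arma::fill::zeros), s_pos(K, arma::fill::zeros),
      s_y(K, arma::fill::zeros);
  arma::mat gamma1(n, K);

  for (arma::uword tt = T; tt-- > 0;) {
    arma::mat g = alpha.slice(tt) % b;  // rows ~ posterior state probs
    arma::vec rs = arma::sum(g, 1);
    rs.transform([](double v) { return v > TINY ? v : TINY; });
    g.each_col() /= rs;

    for (arma::uword i = 0; i < n; ++i) {
      const arma::uword y = Yidx(i, tt);
      if (y == miss) continue;
      for (arma::uword k = 0; k < K; ++k) {
        s_obs(k) += g(i, k);
        if (y > 0) {
          s_pos(k) += g(i, k);
          s_y(k) += g(i, k) * static_cast<double>(y);
        }
      }
    }
    if (tt == 0) { gamma1 = g; break; }

    // xi accumulation: w(i,l) = E(y_t, l) * beta_t(i,l) / c_t, t = tt
    arma::mat w(n, K);
    for (arma::uword i = 0; i < n; ++i) {
      const double c = cs(i, tt);
      const arma::uword y = Yidx(i, tt);
      for (arma::uword l = 0; l < K; ++l)
        w(i, l) = E(y, l) * b(i, l) / c;
    }
    xi += A % (alpha.slice(tt - 1).t() * w);
    b = w * A.t();
  }

  return List::create(_["loglik"] = ll,
                      _["gamma1"] = arma::sum(gamma1, 0).t(),
                      _["xi"] = xi,
                      _["s_obs"] = s_obs,
                      _["s_pos"] = s_pos,
                      _["s_y"] = s_y);
}

// Per-sequence log-likelihoods and smoothed posteriors (n x K x T cube).
// [[Rcpp::export]]
List cpp_hmm_posterior(const arma::mat& E, const arma::umat& Yidx,
                       const arma::vec& pi, const arma::mat& A) {
  const arma::uword n = Yidx.n_rows, T = Yidx.n_cols, K = pi.n_elem;

  arma::cube alpha(n, K, T);
  arma::mat cs(n, T);
  arma::mat a(n, K);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword k = 0; k < K; ++k)
      a(i, k) = pi(k) * E(Yidx(i, 0), k);
  arma::vec ct = arma::sum(a, 1);
  ct.transform([](double v) { return v > TINY ? v : TINY; });
  a.each_col() /= ct;
  cs.col(0) = ct;
  alpha.slice(0) = a;
  for (arma::uword t = 1; t < T; ++t) {
    a = a * A;
    for (arma::uword i = 0; i < n; ++i) {
      const arma::uword y = Yidx(i, t);
      for (arma::uword k = 0; k < K; ++k) a(i, k) *= E(y, k);
    }
    ct = arma::sum(a, 1);
    ct.transform([](double v) { return v > TINY ? v : TINY; });
    a.each_col() /= ct;
    cs.col(t) = ct;
    alpha.slice(t) = a;
  }

  arma::cube gamma(n, K, T);
  arma::mat b(n, K, arma::fill::ones);
  for (arma::uword tt = T; tt-- > 0;) {
    arma::mat g = alpha.slice(tt) % b;
    arma::vec rs = arma::sum(g, 1);
    rs.transform([](double v) { return v > TINY ? v : TINY; });
    g.each_col() /= rs;
    gamma.slice(tt) = g;
    if (tt == 0) break;
    arma::mat w(n, K);
    for (arma::uword i = 0; i < n; ++i) {
      const double c = cs(i, tt);
      const arma::uword y = Yidx(i, tt);
      for (arma::uword l = 0; l < K; ++l)
        w(i, l) = E(y, l) * b(i, l) / c;
    }
    b = w * A.t();
  }

  return List::create(_["loglik"] = arma::sum(arma::log(cs), 1),
                      _["gamma"] = gamma);
}

// Viterbi decoding in log space; ties broken toward the lower state index
// (strict improvement required to move to a higher-indexed state).
// Returns 0-based state paths (n x T).
// [[Rcpp::export]]
arma::umat cpp_hmm_viterbi(const arma::mat& logE, const arma::umat& Yidx,
                           const arma::vec& log_pi, const arma::mat& log_A) {
  const arma::uword n = Yidx.n_rows, T = Yidx.n_cols, K = log_pi.n_elem;
  arma::umat path(n, T);
  arma::mat delta(T, K);
  arma::umat psi(T, K);

  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword k = 0; k < K; ++k)
      delta(0, k) = log_pi(k) + logE(Yidx(i, 0), k);
    for (arma::uword t = 1; t < T; ++t) {
      const arma::uword y = Yidx(i, t);
      for (arma::uword k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + log_A(0, k);
        arma::uword arg = 0;
        for (arma::uword j = 1; j < K; ++j) {
          const double v = delta(t - 1, j) + log_A(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logE(y, k);
        psi(t, k) = arg;
      }
    }
    arma::uword s = 0;
    double best = delta(T - 1, 0);
    for (arma::uword k = 1; k < K; ++k)
      if (delta(T - 1, k) > best) { best = delta(T - 1, k); s = k; }
    path(i, T - 1) = s;
    for (arma::uword t = T - 1; t-- > 0;) {
      s = psi(t + 1, s);
      path(i, t) = s;
    }
  }
  return path;
}
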