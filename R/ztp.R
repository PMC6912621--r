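#' Zero-truncated Poisson density
#'
#' Density of the zero-truncated Poisson distribution with rate `lambda`,
#' i.e. a Poisson conditioned on being at least 1. This is the quantity
#' component of the hurdle emission model: a daily drink count, given that
#' any drinking happened.
#'
#' @param x vector of counts (>= 1; the density is 0 elsewhere).
#' @param lambda rate of the underlying (untruncated) Poisson, > 0.
#' @param log if `TRUE`, return log-density.
#' @return numeric vector of (log-)densities.
#' @examples
#' dztpois(1:5, lambda = 2)
#' @export
dztpois <- function(x, lambda, log = FALSE) {
  stopifnot(all(lambda > 0))
  ld <- dpois(x, lambda, log = TRUE) - log1p(-exp(-lambda))
  ld[x < 1 | x != floor(x)] <- -Inf
  if (log) ld else exp(ld)
}

#' Zero-truncated Poisson sampler
#'
#' @param n number of draws.
#' @param lambda rate of the underlying Poisson.
#' @return integer vector of draws, all >= 1.
#' @export
rztpois <- function(n, lambda) {
  # inverse-CDF through the untruncated quantile function: u is uniform on
  # (P(X=0), 1), so qpois maps it to a positive count
  u <- runif(n, dpois(0, lambda), 1)
  qpois(u, lambda)
}

#' Zero-truncated negative binomial sampler
#'
#' Used by the cohort simulator when a class specifies finite quantity
#' dispersion; `size = Inf` collapses to the zero-truncated Poisson.
#'
#' @param n number of draws.
#' @param mu mean of the underlying (untruncated) negative binomial.
#' @param size dispersion parameter (`Inf` for Poisson).
#' @return integer vector of draws, all >= 1.
#' @export
rztnbinom <- function(n, mu, size = Inf) {
  if (!is.finite(size)) return(rztpois(n, mu))
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Convert a zero-truncated Poisson mean to its rate
#'
#' Solves `m = lambda / (1 - exp(-lambda))` for `lambda`. The simulator's
#' class specifications give the mean number of drinks on drinking days;
#' the emission model is parameterized by the underlying Poisson rate.
#'
#' @param m target conditional mean, > 1 (a zero-truncated count has mean
#'   above 1; values at or below 1 map to a rate of ~0).
#' @return numeric vector of rates.
#' @examples
#' ztp_rate_from_mean(3.5)
#' ztp_mean_from_rate(ztp_rate_from_mean(3.5))
#' @export
ztp_rate_from_mean <- function(m) {
  vapply(m, function(mi) {
    if (!is.finite(mi) || mi <= 1 + 1e-10) return(1e-4)
    uniroot(function(l) l / (1 - exp(-l)) - mi,
            lower = 1e-10, upper = mi + 20, tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname ztp_rate_from_mean
#' @param lambda rate of the underlying Poisson.
#' @export
ztp_mean_from_rate <- function(lambda) {
  lambda / (1 - exp(-lambda))
}
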