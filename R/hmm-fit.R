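#' Hidden Markov model parameters for daily drink counts
#'
#' Bundles the three ingredients of the population HMM used throughout the
#' package: an initial state distribution, a row-stochastic transition
#' matrix over days, and per-state hurdle emissions. Each state k emits a
#' daily drink count as a hurdle pair: any drinking happens with
#' probability `p_drink[k]`, and the count given drinking follows a
#' zero-truncated Poisson with rate `lambda[k]`.
#'
#' @param initial K-vector of initial state probabilities (summing to 1).
#' @param transition K x K row-stochastic transition matrix.
#' @param p_drink K-vector of daily drinking probabilities in \[0, 1\].
#' @param lambda K-vector of positive zero-truncated Poisson rates.
#' @return an object of class `hmm_parameters`.
#' @examples
#' hmm_parameters(c(.5, .5), matrix(c(.9, .2, .1, .8), 2),
#'                p_drink = c(.1, .8), lambda = c(1, 4))
#' @export
hmm_parameters <- function(initial, transition, p_drink, lambda) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  K <- length(initial)
  if (K < 1) stop("need at least one state")
  if (!all(dim(transition) == c(K, K)))
    stop("transition must be ", K, " x ", K)
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < -1e-12))
    stop("initial distribution must be a probability vector summing to 1")
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < -1e-12))
    stop("every transition row must sum to 1")
  if (length(p_drink) != K || any(p_drink < 0) || any(p_drink > 1))
    stop("p_drink must be K probabilities")
  if (length(lambda) != K || any(lambda <= 0))
    stop("lambda must be K positive rates")
  structure(list(K = K, initial = initial, transition = transition,
                 p_drink = as.numeric(p_drink), lambda = as.numeric(lambda)),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat("<hmm_parameters> K =", x$K, "states\n")
  cat("  p_drink:", paste(signif(x$p_drink, 3), collapse = " "), "\n")
  cat("  lambda: ", paste(signif(x$lambda, 3), collapse = " "), "\n")
  cat("  self-transitions:",
      paste(signif(diag(x$transition), 3), collapse = " "), "\n")
  invisible(x)
}

#' Hurdle emission log-probability
#'
#' Log-probability of one daily observation under one state of the hurdle
#' emission model: `log(1 - p)` for a dry day, `log(p) + log ZTP(obs;
#' lambda)` for a drinking day, and exactly 0 (probability 1) for a missing
#' day, which marginalizes the observation out of the likelihood.
#'
#' @param obs drink counts (non-negative integers, `NA` for missing).
#' @param p_drink daily drinking probability of the state.
#' @param lambda zero-truncated Poisson rate of the state.
#' @return numeric vector of log-probabilities.
#' @examples
#' emission_logprob(0, .5, 2)   # log(0.5)
#' emission_logprob(NA, .5, 2)  # 0: marginalized
#' @export
emission_logprob <- function(obs, p_drink, lambda) {
  if (any(obs < 0, na.rm = TRUE)) stop("negative drink counts are invalid")
  out <- numeric(length(obs))
  zero <- !is.na(obs) & obs == 0
  pos <- !is.na(obs) & obs > 0
  out[zero] <- log1p(-p_drink)
  out[pos] <- log(p_drink) + dztpois(obs[pos], lambda, log = TRUE)
  out  # NA days stay 0
}

# emission lookup tables over the integer support 0..ymax, with a final
# row for missing observations (probability 1 / log-probability 0)
emission_tables <- function(params, ymax) {
  K <- params$K
  ymax <- max(ymax, 1L)
  logE <- matrix(0, ymax + 2L, K)
  for (k in seq_len(K)) {
    logE[seq_len(ymax + 1L), k] <-
      emission_logprob(0:ymax, params$p_drink[k], params$lambda[k])
  }
  list(E = exp(logE), logE = logE)
}

# coerce a diaries tibble or a numeric matrix into the n x T count matrix
# (rows ordered by student, columns day 1..T = wave * 7 + weekday)
as_diary_matrix <- function(data) {
  if (is.matrix(data)) {
    Y <- data
    storage.mode(Y) <- "integer"
    if (is.null(rownames(Y)))
      rownames(Y) <- as.character(seq_len(nrow(Y)))
    return(Y)
  }
  stopifnot(is.data.frame(data))
  need <- c("student_id", "wave", "weekday", "drinks")
  if (!all(need %in% names(data)))
    stop("diaries need columns: ", paste(need, collapse = ", "))
  ids <- unique(data$student_id)
  waves <- sort(unique(data$wave))
  T_len <- length(waves) * 7L
  Y <- matrix(NA_integer_, length(ids), T_len,
              dimnames = list(as.character(ids), NULL))
  day <- match(data$wave, waves) * 7L - 7L + data$weekday
  Y[cbind(match(data$student_id, ids), day)] <- as.integer(data$drinks)
  Y
}

# 1-based row indices into the emission lookup: obs y -> row y + 1,
# missing -> final row
yidx_matrix <- function(Y, ymax) {
  idx <- Y + 1L
  idx[is.na(idx)] <- ymax + 2L
  storage.mode(idx) <- "integer"
  idx
}

#' Forward-backward smoothing for one diary sequence
#'
#' Computes the exact sequence log-likelihood (the log of the sum over all
#' state paths) and the smoothed per-day posterior state probabilities,
#' using a scaled forward-backward pass that is stable over the 28-day
#' horizon. Missing days contribute emission probability 1.
#'
#' @param seq vector of daily drink counts (`NA` for missing days).
#' @param params an [hmm_parameters] object.
#' @return a list with `loglik` (scalar) and `posterior` (T x K matrix
#'   whose rows sum to 1).
#' @export
forward_backward <- function(seq, params) {
  stopifnot(inherits(params, "hmm_parameters"))
  if (length(seq) == 0) stop("sequence must have positive length")
  if (any(seq < 0, na.rm = TRUE)) stop("negative drink counts are invalid")
  ymax <- max(seq, 1L, na.rm = TRUE)
  tab <- emission_tables(params, ymax)
  Y <- matrix(as.integer(seq), nrow = 1)
  res <- cpp_hmm_posterior(tab$E, yidx_matrix(Y, ymax) - 1L,
                           params$initial, params$transition)
  list(loglik = as.numeric(res$loglik),
       posterior = t(matrix(res$gamma, params$K, length(seq))))
}

#' Viterbi decoding for one diary sequence
#'
#' Most probable joint state path given the observations; ties are broken
#' toward the lower state index.
#'
#' @inheritParams forward_backward
#' @return integer vector of 1-based state indices.
#' @export
viterbi_path <- function(seq, params) {
  stopifnot(inherits(params, "hmm_parameters"))
  if (length(seq) == 0) stop("sequence must have positive length")
  if (any(seq < 0, na.rm = TRUE)) stop("negative drink counts are invalid")
  ymax <- max(seq, 1L, na.rm = TRUE)
  tab <- emission_tables(params, ymax)
  Y <- matrix(as.integer(seq), nrow = 1)
  path <- cpp_hmm_viterbi(tab$logE, yidx_matrix(Y, ymax) - 1L,
                          log(params$initial), log(params$transition))
  as.integer(path[1, ]) + 1L
}

#' Simulate diary sequences from HMM parameters
#'
#' Draws state paths from the chain and daily counts from the hurdle
#' emissions. Used for parameter-recovery studies and tests.
#'
#' @param n_seq number of sequences (students).
#' @param n_days sequence length (28 for the four-wave diary design).
#' @param params an [hmm_parameters] object.
#' @param seed integer seed.
#' @return a list with `counts` (n x T integer matrix) and `states`
#'   (n x T matrix of 1-based true states).
#' @export
simulate_hmm <- function(n_seq, n_days, params, seed = 1L) {
  stopifnot(inherits(params, "hmm_parameters"))
  set.seed(seed)
  K <- params$K
  states <- matrix(0L, n_seq, n_days)
  states[, 1] <- sample.int(K, n_seq, TRUE, prob = params$initial)
  if (n_days > 1 && K > 1) {
    cumA <- t(apply(params$transition, 1, cumsum))
    for (t in 2:n_days) {
      u <- runif(n_seq)
      cum <- cumA[states[, t - 1], , drop = FALSE]
      states[, t] <- max.col(u <= cum, ties.method = "first")
    }
  } else if (n_days > 1) {
    states[] <- 1L
  }
  drink <- matrix(runif(n_seq * n_days), n_seq) <
    matrix(params$p_drink[states], n_seq)
  counts <- matrix(0L, n_seq, n_days)
  if (any(drink))
    counts[drink] <- rztpois(sum(drink), params$lambda[states[drink]])
  list(counts = counts, states = states)
}

# one random restart initialization
random_init <- function(K) {
  pi0 <- rgamma(K, 1)
  A0 <- matrix(rgamma(K * K, 1), K)
  list(initial = pi0 / sum(pi0), transition = A0 / rowSums(A0),
       p_drink = runif(K, 0.05, 0.95), lambda = runif(K, 0.5, 8))
}

# one EM run from a given initialization; returns params + trace
em_run <- function(Yidx, ymax, n_obs_mat, init, K, max_iter, tol) {
  pi0 <- init$initial; A <- init$transition
  p <- init$p_drink; lam <- init$lambda
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    par <- hmm_parameters(pi0, A, p, lam)
    tab <- emission_tables(par, ymax)
    es <- cpp_hmm_estep(tab$E, Yidx - 1L, pi0, A)
    ll <- es$loglik
    trace <- c(trace, ll)
    # M-step
    g1 <- as.numeric(es$gamma1)
    pi0 <- g1 / sum(g1)
    xi <- es$xi
    rs <- rowSums(xi)
    for (k in seq_len(K)) {
      if (rs[k] > 0) A[k, ] <- xi[k, ] / rs[k]
    }
    s_obs <- as.numeric(es$s_obs); s_pos <- as.numeric(es$s_pos)
    s_y <- as.numeric(es$s_y)
    for (k in seq_len(K)) {
      if (s_obs[k] > 0) {
        pk <- s_pos[k] / s_obs[k]
        # keep an exact zero when the drinking mass is exactly zero;
        # otherwise stay off the simplex boundary
        p[k] <- if (pk > 0) min(max(pk, 1e-6), 1 - 1e-6) else 0
      }
      if (s_pos[k] > 0) lam[k] <- ztp_rate_from_mean(s_y[k] / s_pos[k])
    }
    if (it > 1) {
      prev <- trace[it - 1]
      if (abs(ll - prev) / (abs(ll) + 1e-10) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(params = hmm_parameters(pi0, A, p, lam),
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' Fit a population HMM by multi-restart Baum-Welch EM
#'
#' Estimates one shared parameter set from all students' sequences, which
#' are treated as independent realizations of the same chain. Missing days
#' are marginalized out of the likelihood (missing-at-random handling by
#' maximum likelihood, no imputation). Each restart draws a random
#' initialization (Dirichlet(1) for the initial distribution and the
#' transition rows, uniform emission parameters) and the best restart by
#' log-likelihood is returned.
#'
#' @param data a diaries tibble (columns `student_id`, `wave`, `weekday`,
#'   `drinks`) or an n x T integer matrix with `NA` for missing days.
#' @param K number of hidden states.
#' @param n_restarts number of random restarts.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param tol relative log-likelihood convergence tolerance (> 0).
#' @param max_iter maximum EM iterations per restart.
#' @param restart_iter if given, each restart is first run for only this
#'   many iterations and only the best short run is continued to
#'   convergence (a standard economy for large state spaces).
#' @return an object of class `drink_hmm` with elements `params`
#'   ([hmm_parameters]), `loglik`, `loglik_trace`, `n_free_params`, `bic`,
#'   `n_obs`, `n_restarts_used`, `converged`, `degenerate_states`, `seed`.
#' @export
hmm_fit <- function(data, K, n_restarts = 20L, seed = 1L, tol = 1e-6,
                    max_iter = 500L, restart_iter = NULL) {
  if (tol <= 0) stop("tol must be positive")
  if (K < 1) stop("K must be at least 1")
  Y <- as_diary_matrix(data)
  if (nrow(Y) < 1) stop("need at least one sequence")
  n_patterns <- nrow(unique(Y))
  if (K > n_patterns)
    warning("K = ", K, " exceeds the ", n_patterns,
            " distinct observed sequences; expect degenerate states")
  ymax <- max(Y, 1L, na.rm = TRUE)
  Yidx <- yidx_matrix(Y, ymax)
  n_obs <- sum(!is.na(Y))

  set.seed(seed)
  inits <- lapply(seq_len(n_restarts), function(r) random_init(K))

  if (is.null(restart_iter)) {
    runs <- lapply(inits, em_run, Yidx = Yidx, ymax = ymax,
                   n_obs_mat = NULL, K = K, max_iter = max_iter, tol = tol)
    best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
  } else {
    shorts <- lapply(inits, em_run, Yidx = Yidx, ymax = ymax,
                     n_obs_mat = NULL, K = K,
                     max_iter = as.integer(restart_iter), tol = tol)
    top <- which.max(vapply(shorts, `[[`, 0, "loglik"))
    bp <- shorts[[top]]$params
    best <- em_run(Yidx, ymax, NULL,
                   list(initial = bp$initial, transition = bp$transition,
                        p_drink = bp$p_drink, lambda = bp$lambda),
                   K, max_iter, tol)
  }

  n_free <- (K - 1) + K * (K - 1) + 2 * K
  bic <- -2 * best$loglik + n_free * log(n_obs)
  # states carrying essentially no posterior mass
  occ <- state_occupancy(best$params, Yidx, ymax)
  degenerate <- which(occ < 1e-6)

  structure(list(params = best$params, loglik = best$loglik,
                 loglik_trace = best$trace, n_free_params = n_free,
                 bic = bic, n_obs = n_obs, K = K,
                 n_sequences = nrow(Y), n_days = ncol(Y),
                 n_restarts_used = n_restarts, converged = best$converged,
                 degenerate_states = degenerate, seed = seed),
            class = "drink_hmm")
}

state_occupancy <- function(params, Yidx, ymax) {
  tab <- emission_tables(params, ymax)
  res <- cpp_hmm_posterior(tab$E, Yidx - 1L, params$initial,
                           params$transition)
  apply(res$gamma, 2, mean)
}

#' @export
print.drink_hmm <- function(x, ...) {
  cat("<drink_hmm> ", x$K, " states, ", x$n_sequences, " sequences x ",
      x$n_days, " days (", x$n_obs, " observed)\n", sep = "")
  cat("  log-likelihood ", format(x$loglik), ", BIC ", format(x$bic),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @describeIn hmm_fit per-state emission and persistence summary, one row
#'   per state.
#' @param x,object a `drink_hmm` fit.
#' @param ... unused.
#' @export
tidy.drink_hmm <- function(x, ...) {
  p <- x$params
  tibble::tibble(state = seq_len(p$K),
                 initial = p$initial,
                 p_drink = p$p_drink,
                 lambda = p$lambda,
                 mean_drinks_given_drinking = ztp_mean_from_rate(p$lambda),
                 drinking_days_per_week = 7 * p$p_drink,
                 self_transition = diag(p$transition))
}

#' @describeIn hmm_fit one-row model-level summary.
#' @export
glance.drink_hmm <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_free_params = x$n_free_params,
                 n_obs = x$n_obs, bic = x$bic, converged = x$converged,
                 n_restarts = x$n_restarts_used)
}

#' Select the number of hidden states by BIC
#'
#' Fits the HMM for each candidate K and returns the fit minimizing the
#' Bayesian information criterion `-2 loglik + n_free log(n_obs)`, where
#' `n_obs` counts observed (non-missing) daily observations. Ties go to the
#' smaller K. A failure at a single K is recorded, not fatal.
#'
#' @inheritParams hmm_fit
#' @param K_range candidate numbers of states.
#' @return an object of class `drink_hmm_scan` with elements `best` (the
#'   selected `drink_hmm`), `best_K`, `fits` (list indexed by K), and
#'   `errors`.
#' @export
hmm_select <- function(data, K_range = 2:12, n_restarts = 20L, seed = 1L,
                       tol = 1e-6, max_iter = 500L, restart_iter = NULL) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0) stop("K_range must be nonempty")
  Y <- as_diary_matrix(data)
  fits <- list(); errors <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    res <- tryCatch(
      hmm_fit(Y, K, n_restarts = n_restarts, seed = seed + i - 1L,
              tol = tol, max_iter = max_iter, restart_iter = restart_iter),
      error = function(e) e)
    if (inherits(res, "error")) errors[[as.character(K)]] <- conditionMessage(res)
    else fits[[as.character(K)]] <- res
  }
  if (length(fits) == 0)
    stop("every candidate K failed: ",
         paste(unlist(errors), collapse = "; "))
  bics <- vapply(fits, `[[`, 0, "bic")
  Ks <- as.integer(names(fits))
  # minimize BIC; ties (within numerical noise) to the smaller K
  best_idx <- order(round(bics, 9), Ks)[1]
  structure(list(best = fits[[best_idx]], best_K = Ks[best_idx],
                 fits = fits, errors = errors, K_range = K_range),
            class = "drink_hmm_scan")
}

#' @export
print.drink_hmm_scan <- function(x, ...) {
  cat("<drink_hmm_scan> K in {", paste(x$K_range, collapse = ", "),
      "}; best K = ", x$best_K, " by BIC\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn hmm_select per-K fit summary (one row per candidate).
#' @param x a `drink_hmm_scan`.
#' @param ... unused.
#' @export
tidy.drink_hmm_scan <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, glance)) |>
    dplyr::mutate(selected = .data$K == x$best_K)
}

#' @describeIn hmm_select BIC curve over the candidate numbers of states.
#' @param object a `drink_hmm_scan`.
#' @export
autoplot.drink_hmm_scan <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "number of hidden states K", y = "BIC",
                  title = "BIC state selection") +
    ggplot2::theme_minimal()
}

#' Decode every student's state path
#'
#' Runs Viterbi decoding (and optionally posterior smoothing) for each
#' student under a fitted model, returning one row per student-day.
#'
#' @param object a `drink_hmm` fit or an [hmm_parameters] object.
#' @param data diaries tibble or count matrix (as in [hmm_fit]).
#' @param posterior if `TRUE`, append smoothed posterior state
#'   probabilities as columns `posterior_1..K`.
#' @return a tibble with columns `student_id`, `day` (1..T), `wave`,
#'   `weekday` (1 = Monday), `drinks`, `observed`, `state`; per-student
#'   log-likelihoods are attached as attribute `loglik`.
#' @export
decode_cohort <- function(object, data, posterior = FALSE) {
  params <- if (inherits(object, "drink_hmm")) object$params else object
  stopifnot(inherits(params, "hmm_parameters"))
  Y <- as_diary_matrix(data)
  ymax <- max(Y, 1L, na.rm = TRUE)
  Yidx <- yidx_matrix(Y, ymax)
  tab <- emission_tables(params, ymax)
  paths <- cpp_hmm_viterbi(tab$logE, Yidx - 1L, log(params$initial),
                           log(params$transition)) + 1L
  n <- nrow(Y); T_len <- ncol(Y)
  out <- tibble::tibble(
    student_id = rep(rownames(Y), each = T_len),
    day = rep(seq_len(T_len), n),
    wave = (rep(seq_len(T_len), n) - 1L) %/% 7L,
    weekday = (rep(seq_len(T_len), n) - 1L) %% 7L + 1L,
    drinks = as.integer(t(Y)),
    observed = !is.na(as.integer(t(Y))),
    state = as.integer(t(paths)))
  res <- cpp_hmm_posterior(tab$E, Yidx - 1L, params$initial,
                           params$transition)
  if (posterior) {
    gam <- res$gamma  # n x K x T
    for (k in seq_len(params$K))
      out[[paste0("posterior_", k)]] <- as.numeric(t(gam[, k, ]))
  }
  attr(out, "loglik") <- tibble::tibble(student_id = rownames(Y),
                                        loglik = as.numeric(res$loglik))
  attr(out, "K") <- params$K
  out
}
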