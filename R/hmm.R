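#' Bernoulli-emission HMM parameters
#'
#' @param A N x N row-stochastic transition matrix.
#' @param alpha0 initial state distribution.
#' @param p_s per-state Bernoulli success probabilities.
#' @return an `hmm_params` object.
#' @export
hmm_params <- function(A, alpha0, p_s) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), length(alpha0) == nrow(A),
            length(p_s) == nrow(A),
            all(abs(rowSums(A) - 1) < 1e-8), abs(sum(alpha0) - 1) < 1e-8,
            all(p_s > 0), all(p_s < 1))
  structure(list(A = A, alpha0 = alpha0, p_s = p_s, N = nrow(A)),
            class = "hmm_params")
}

#' Sticky initialization of the engagement HMM
#'
#' Transition matrix `(I + eps * J) / (1 + N * eps)` (J all-ones), which is
#' row-stochastic with self-transition weight controlled by `eps` (smaller
#' eps = stickier states; eps -> Inf gives the uniform matrix). The initial
#' distribution is uniform and the emission probabilities are N uniformly
#' spaced values from 0.1 to 0.9.
#'
#' @param N number of states (>= 1; the analysis default is 3).
#' @param epsilon stickiness parameter (> 0), default 0.5.
#' @return an `hmm_params`.
#' @export
init_params <- function(N = 3, epsilon = 0.5) {
  stopifnot(N >= 1, epsilon > 0)
  A <- (diag(N) + epsilon * matrix(1, N, N)) / (1 + N * epsilon)
  p_s <- if (N == 1) 0.5 else seq(0.1, 0.9, length.out = N)
  hmm_params(A = A, alpha0 = rep(1 / N, N), p_s = p_s)
}

emission_probs <- function(obs, p_s) {
  # obs: logical vector; returns T x N matrix of emission likelihoods
  outer(obs, p_s, function(c, p) ifelse(c, p, 1 - p))
}

# scaled forward pass; returns list(alpha, scale, loglik)
forward_pass <- function(obs, params) {
  Tn <- length(obs); N <- params$N
  B <- emission_probs(obs, params$p_s)
  alpha <- matrix(0, Tn, N); cs <- numeric(Tn)
  a <- params$alpha0 * B[1, ]
  cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- as.numeric(crossprod(params$A, alpha[t - 1, ])) * B[t, ]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  list(alpha = alpha, scale = cs, loglik = sum(log(cs)))
}

backward_pass <- function(obs, params, scale) {
  Tn <- length(obs); N <- params$N
  B <- emission_probs(obs, params$p_s)
  beta <- matrix(0, Tn, N)
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- as.numeric(params$A %*% (B[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
  beta
}

#' Per-trial state marginals by the forward-backward algorithm
#'
#' Sessions are treated as independent sequences, each restarting from the
#' initial distribution.
#'
#' @param choices logical vector of correct/incorrect outcomes.
#' @param sessions session id per trial.
#' @param params an `hmm_params`.
#' @return list: `marginals` (trials x states, rows sum to 1), `loglik`.
#' @export
forward_backward <- function(choices, sessions, params) {
  marg <- matrix(NA_real_, length(choices), params$N)
  ll <- 0
  for (s in unique(sessions)) {
    idx <- which(sessions == s)
    fw <- forward_pass(choices[idx], params)
    bw <- backward_pass(choices[idx], params, fw$scale)
    g <- fw$alpha * bw
    marg[idx, ] <- g / rowSums(g)
    ll <- ll + fw$loglik
  }
  list(marginals = marg, loglik = ll)
}

#' Most likely state path by the Viterbi algorithm
#'
#' Computed per session; ties are broken toward the lowest state index.
#'
#' @inheritParams forward_backward
#' @return integer vector of states, one per trial.
#' @export
viterbi <- function(choices, sessions, params) {
  path <- integer(length(choices))
  for (s in unique(sessions)) {
    idx <- which(sessions == s)
    path[idx] <- viterbi_one(choices[idx], params)
  }
  path
}

viterbi_one <- function(obs, params) {
  Tn <- length(obs); N <- params$N
  lB <- log(emission_probs(obs, params$p_s))
  lA <- log(params$A)
  delta <- log(params$alpha0) + lB[1, ]
  psi <- matrix(0L, Tn, N)
  if (Tn > 1) for (t in 2:Tn) {
    m <- delta + lA                       # m[i, j]: from i to j
    best <- apply(m, 2, which.max)        # which.max takes the lowest on ties
    psi[t, ] <- best
    delta <- m[cbind(best, seq_len(N))] + lB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Fit the HMM by Baum-Welch expectation-maximization
#'
#' EM over multiple independent sequences (each session restarts from the
#' initial distribution). The log-likelihood is asserted non-decreasing at
#' every iteration; fitting stops when its relative change falls below
#' `tol` or after `max_iter` iterations.
#'
#' @param choices logical correct/incorrect per trial.
#' @param sessions session id per trial.
#' @param init initial `hmm_params` (default [init_params] with N = 3).
#' @param max_iter,tol EM controls.
#' @return list: `params` (fitted `hmm_params`), `loglik`, `trace`
#'   (log-likelihood per iteration), `n_iter`.
#' @export
baum_welch <- function(choices, sessions = rep(1L, length(choices)),
                       init = init_params(3), max_iter = 500, tol = 1e-6) {
  stopifnot(length(choices) >= 1)
  params <- init
  N <- params$N
  ses_ids <- unique(sessions)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, N, N); a0_num <- numeric(N)
    e_num <- numeric(N); e_den <- numeric(N)
    ll <- 0
    for (s in ses_ids) {
      idx <- which(sessions == s)
      if (!length(idx)) { warning("empty session skipped: ", s); next }
      obs <- choices[idx]
      Tn <- length(obs)
      B <- emission_probs(obs, params$p_s)
      fw <- forward_pass(obs, params)
      bw <- backward_pass(obs, params, fw$scale)
      g <- fw$alpha * bw
      g <- g / rowSums(g)
      ll <- ll + fw$loglik
      a0_num <- a0_num + g[1, ]
      if (Tn > 1) {
        # sum_t alpha[t, i] A[i, j] B[t+1, j] beta[t+1, j] / scale[t+1]
        rhs <- (B * bw / fw$scale)[-1, , drop = FALSE]
        A_num <- A_num + params$A *
          crossprod(fw$alpha[-Tn, , drop = FALSE], rhs)
      }
      e_num <- e_num + colSums(g * obs)
      e_den <- e_den + colSums(g)
    }
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased: numerical failure")
    params <- hmm_params(
      A = A_num / pmax(rowSums(A_num), .Machine$double.eps),
      alpha0 = a0_num / sum(a0_num),
      p_s = pmin(pmax(e_num / pmax(e_den, .Machine$double.eps), 1e-6), 1 - 1e-6))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  final_ll <- forward_backward(choices, sessions, params)$loglik
  list(params = params, loglik = final_ll, trace = ll_trace, n_iter = iter)
}

#' Hierarchical bootstrap of per-state means
#'
#' Trials are stratified by decoded state. For each replicate, trials are
#' resampled with replacement by first picking an animal with probability
#' proportional to its trial count within the state, then one of its trials,
#' until the stratum size is reached; the replicate mean is recorded.
#'
#' @param values per-trial values (e.g., delay-zone exit times, s).
#' @param states decoded state per trial.
#' @param animals animal id per trial.
#' @param n_rep bootstrap replicates.
#' @param conf confidence level for the percentile interval.
#' @param seed integer seed.
#' @return data.frame per state: `state`, `n`, `mean`, `lower`, `upper`.
#' @export
hierarchical_bootstrap <- function(values, states, animals, n_rep = 1000,
                                   conf = 0.95, seed = 1L) {
  stopifnot(length(values) == length(states), length(animals) == length(values))
  set.seed(seed)
  out <- list()
  for (s in sort(unique(states))) {
    idx <- which(states == s)
    if (!length(idx)) { warning("state with no trials omitted: ", s); next }
    an <- animals[idx]
    an_ids <- unique(an)
    by_an <- lapply(an_ids, function(a) idx[an == a])
    wts <- vapply(by_an, length, numeric(1))
    reps <- vapply(seq_len(n_rep), function(r) {
      picks <- sample.int(length(an_ids), length(idx), replace = TRUE,
                          prob = wts)
      mean(values[vapply(picks, function(p) {
        pool <- by_an[[p]]
        pool[sample.int(length(pool), 1)]
      }, numeric(1))])
    }, numeric(1))
    a <- (1 - conf) / 2
    out[[length(out) + 1L]] <- data.frame(
      state = s, n = length(idx), mean = mean(reps),
      lower = quantile(reps, a, names = FALSE),
      upper = quantile(reps, 1 - a, names = FALSE))
  }
  do.call(rbind, out)
}
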