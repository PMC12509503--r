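# shared fixtures: small synthetic recordings with well-separated events

spaced_events <- function(n, t_max, gap = 2, seed = 1) {
  set.seed(seed)
  sort(sample(seq(gap, t_max - gap, by = gap), n)) + runif(n, -0.3, 0.3)
}

small_lfp_cfg <- function(seed = 3, duration_s = 60, ...) {
  synth_config(seed = seed, duration_s = duration_s, ...)
}

# brute-force Skaggs information: naive double loop over the grid
si_bruteforce <- function(P, lambda) {
  L <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    L <- L + lambda[i, j] * P[i, j]
  I <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0 && lambda[i, j] > 0)
      I <- I + lambda[i, j] * P[i, j] * log2(lambda[i, j] / L)
  }
  list(I = I, I_spike = I / L)
}

random_map <- function(n = 15) {
  P <- matrix(rexp(n * n), n, n)
  # leave some bins unoccupied
  P[sample(n * n, n)] <- 0
  P <- P / sum(P)
  lambda <- matrix(rexp(n * n, rate = 2), n, n)
  lambda[sample(n * n, n)] <- 0
  list(P = P, lambda = lambda)
}

# brute-force HMM posterior/Viterbi by enumerating all state paths
hmm_bruteforce <- function(obs, params) {
  N <- params$N; Tn <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  lp <- apply(paths, 1, function(s) {
    v <- log(params$alpha0[s[1]])
    if (Tn > 1) for (t in 2:Tn) v <- v + log(params$A[s[t - 1], s[t]])
    for (t in seq_len(Tn))
      v <- v + log(if (obs[t]) params$p_s[s[t]] else 1 - params$p_s[s[t]])
    v
  })
  post <- sapply(seq_len(Tn), function(t)
    sapply(seq_len(N), function(k) sum(exp(lp)[paths[, t] == k])) / sum(exp(lp)))
  list(viterbi = paths[which.max(lp), ], marginals = t(post),
       loglik = log(sum(exp(lp))))
}

random_hmm <- function(N = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rexp(N * N), N, N); A <- A / rowSums(A)
  a0 <- rexp(N); a0 <- a0 / sum(a0)
  hmm_params(A, a0, runif(N, 0.05, 0.95))
}

# log probability of one state path under an HMM
hmm_path_logprob <- function(obs, params, path) {
  v <- log(params$alpha0[path[1]])
  Tn <- length(obs)
  if (Tn > 1) for (t in 2:Tn) v <- v + log(params$A[path[t - 1], path[t]])
  for (t in seq_len(Tn))
    v <- v + log(if (obs[t]) params$p_s[path[t]] else 1 - params$p_s[path[t]])
  v
}
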