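# Exact (O(n^2)) t-SNE for small waveform sets: binary-search perplexity
# calibration, early exaggeration, momentum gradient descent. Deterministic
# given the seed (Gaussian initialization is the only random element).

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

tsne_embed <- function(X, perplexity = 30, n_iter = 500, seed = 1L,
                       eta = 200, exaggeration = 12) {
  n <- nrow(X)
  if (n < 10) stop("need at least 10 rows to embed")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2)
    stop("too few rows for the perplexity constraint; supply more waveforms")
  P <- tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    W <- (Pe - Q) * num
    G <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
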