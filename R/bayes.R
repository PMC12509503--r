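#' Zone-gain Poisson model
#'
#' Hierarchical non-homogeneous Poisson model of IS counts:
#' `S[a,z] ~ Poisson(T[a,z] * rho_a * eta_z)` with animal baselines
#' `rho_a ~ LogNormal(-1, 0.3)` (Hz) and shared zone gains
#' `eta_z ~ LogNormal(0, 1)`; a gain of 1 is a neutral zone effect.
#' Sampling is done in unconstrained log space where both priors are
#' Gaussian.
#'
#' @param S,T animal-by-zone matrices of spike counts and occupancy seconds
#'   (equal dimensions; `T > 0` wherever `S > 0`).
#' @return a `bayes_model` object usable with [sample_posterior].
#' @export
zone_model <- function(S, T) {
  S <- as.matrix(S); T <- as.matrix(T)
  stopifnot(all(dim(S) == dim(T)), all(S >= 0), all(T[S > 0] > 0))
  A <- nrow(S); Z <- ncol(S)
  par_names <- c(paste0("rho[", seq_len(A), "]"),
                 paste0("eta[", if (!is.null(colnames(S))) colnames(S) else seq_len(Z), "]"))
  log_post <- function(theta) {
    lr <- theta[seq_len(A)]; le <- theta[A + seq_len(Z)]
    mu <- T * exp(outer(lr, le, "+"))
    sum(dpois(S, mu, log = TRUE)) +
      sum(dnorm(lr, -1, 0.3, log = TRUE)) +
      sum(dnorm(le, 0, 1, log = TRUE))
  }
  structure(list(log_post = log_post, par_names = par_names,
                 n_par = A + Z, init_mean = c(rep(-1, A), rep(0, Z)),
                 init_sd = c(rep(0.3, A), rep(1, Z)),
                 gauge = c(rep(1, A), rep(-1, Z)),
                 kind = "zone", S = S, T = T, A = A, Z = Z),
            class = "bayes_model")
}

#' Log posterior density of the zone-gain model at natural-scale parameters
#'
#' @param rho positive per-animal baseline rates (Hz).
#' @param eta positive per-zone gains.
#' @param S,T as in [zone_model].
#' @return unnormalized log posterior; `-Inf` for non-positive parameters.
#' @export
log_posterior_zone <- function(rho, eta, S, T) {
  if (any(rho <= 0) || any(eta <= 0)) return(-Inf)
  mu <- as.matrix(T) * outer(rho, eta)
  sum(dpois(as.matrix(S), mu, log = TRUE)) +
    sum(dlnorm(rho, -1, 0.3, log = TRUE)) +
    sum(dlnorm(eta, 0, 1, log = TRUE))
}

#' Behavioral-state-gain Poisson model for delay-zone IS
#'
#' Per-trial likelihood `S_i ~ Poisson(T_i * rho_{a(i)} * sum_s eta_s p_i(s))`
#' where `p_i(s)` are fixed per-trial state marginals from the engagement
#' HMM. Priors: `rho_a ~ Normal(0.5, 0.5)` truncated to `(0, Inf)` (the
#' printed prior's point mass at zero is replaced by the zero-truncated
#' normal, which leaves the inference target unchanged and keeps the density
#' smooth), `eta_s ~ LogNormal(0, 1)`.
#'
#' @param S_i per-trial delay-zone spike counts.
#' @param T_i per-trial delay-zone occupancy seconds (positive).
#' @param marginals trials x states matrix of state probabilities (rows sum
#'   to 1).
#' @param animal integer/factor animal id per trial.
#' @return a `bayes_model`.
#' @export
state_model <- function(S_i, T_i, marginals, animal = rep(1L, length(S_i))) {
  marginals <- as.matrix(marginals)
  stopifnot(length(S_i) == length(T_i), nrow(marginals) == length(S_i),
            all(T_i > 0), all(abs(rowSums(marginals) - 1) < 1e-6))
  animal <- as.integer(factor(animal))
  A <- max(animal); N <- ncol(marginals)
  par_names <- c(paste0("rho[", seq_len(A), "]"),
                 paste0("eta[", seq_len(N), "]"))
  ltrunc <- pnorm(0, 0.5, 0.5, lower.tail = FALSE, log.p = TRUE)
  log_post <- function(theta) {
    lr <- theta[seq_len(A)]; le <- theta[A + seq_len(N)]
    rho <- exp(lr); eta <- exp(le)
    gain <- as.numeric(marginals %*% eta)
    mu <- T_i * rho[animal] * gain
    # zero-truncated normal prior on rho, with log-space Jacobian
    sum(dpois(S_i, mu, log = TRUE)) +
      sum(dnorm(rho, 0.5, 0.5, log = TRUE) - ltrunc + lr) +
      sum(dnorm(le, 0, 1, log = TRUE))
  }
  structure(list(log_post = log_post, par_names = par_names,
                 n_par = A + N, init_mean = c(rep(log(0.5), A), rep(0, N)),
                 init_sd = c(rep(0.3, A), rep(1, N)),
                 gauge = c(rep(1, A), rep(-1, N)),
                 kind = "state", S = S_i, T = T_i, marginals = marginals,
                 animal = animal, A = A, Z = N),
            class = "bayes_model")
}

#' Draw posterior samples by adaptive random-walk Metropolis
#'
#' Chains run in unconstrained log space. Each iteration sweeps a
#' component-wise random-walk Metropolis update over all parameters plus one
#' joint move along the rate/gain rescaling direction (`rho * c`,
#' `eta / c`), which the Poisson likelihood leaves unconstrained and which
#' would otherwise mix slowly; every step size is adapted toward the
#' acceptance target during warmup (Robbins-Monro) and frozen afterwards.
#' Draws are reported on the natural scale. Split R-hat and effective sample
#' sizes are attached; poor diagnostics produce warnings, never silent
#' failure.
#'
#' @param model a `bayes_model` from [zone_model] or [state_model].
#' @param n_chains,n_iter,n_warmup chain layout (post-warmup draws per chain).
#' @param target_accept Metropolis acceptance target during adaptation.
#' @param seed integer seed.
#' @return a `posterior_samples` object: `draws` (iterations x chains x
#'   parameters, natural scale), `par_names`, `diagnostics` (R-hat, ESS,
#'   acceptance rate).
#' @export
sample_posterior <- function(model, n_chains = 4, n_iter = 2000,
                             n_warmup = 1000, target_accept = 0.65,
                             seed = 1L) {
  stopifnot(inherits(model, "bayes_model"), n_chains >= 2)
  d <- model$n_par
  draws <- array(NA_real_, c(n_iter, n_chains, d),
                 dimnames = list(NULL, NULL, model$par_names))
  accept <- numeric(n_chains)
  set.seed(seed)
  for (ch in seq_len(n_chains)) {
    theta <- rnorm(d, model$init_mean, model$init_sd)
    lp <- model$log_post(theta)
    step <- rep(0.5, d)          # per-coordinate proposal SDs
    step_g <- 0.2                # rescaling-direction proposal SD
    n_acc <- 0; n_try <- 0
    for (it in seq_len(n_warmup + n_iter)) {
      for (k in seq_len(d)) {
        prop <- theta
        prop[k] <- theta[k] + step[k] * rnorm(1)
        lp_prop <- model$log_post(prop)
        acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
        if (acc) { theta <- prop; lp <- lp_prop }
        if (it <= n_warmup) {
          # Robbins-Monro adaptation of each coordinate's step size
          step[k] <- step[k] * exp((as.numeric(acc) - target_accept) /
                                     sqrt(it))
        } else {
          n_try <- n_try + 1
          n_acc <- n_acc + as.numeric(acc)
        }
      }
      # joint move along the likelihood-flat rescaling direction
      prop <- theta + model$gauge * (step_g * rnorm(1))
      lp_prop <- model$log_post(prop)
      acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
      if (acc) { theta <- prop; lp <- lp_prop }
      if (it <= n_warmup)
        step_g <- step_g * exp((as.numeric(acc) - target_accept) / sqrt(it))
      if (it > n_warmup) draws[it - n_warmup, ch, ] <- exp(theta)
    }
    accept[ch] <- n_acc / n_try
  }
  rhat <- apply(draws, 3, split_rhat)
  ess <- apply(draws, 3, ess_basic)
  if (any(rhat > 1.01, na.rm = TRUE))
    warning("split R-hat > 1.01 for: ",
            paste(model$par_names[rhat > 1.01], collapse = ", "))
  if (any(ess < 400, na.rm = TRUE))
    warning("effective sample size < 400 for: ",
            paste(model$par_names[ess < 400], collapse = ", "))
  structure(list(draws = draws, par_names = model$par_names,
                 diagnostics = data.frame(parameter = model$par_names,
                                          rhat = rhat, ess = ess),
                 accept_rate = accept, model = model),
            class = "posterior_samples")
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half; R-hat is the usual between/within variance
#' ratio over the split halves.
#'
#' @param x iterations x chains matrix of draws of one parameter.
#' @return the potential scale reduction factor.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); h <- floor(n / 2)
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves); s2 <- apply(halves, 2, var)
  W <- mean(s2); B <- h * var(mu)
  if (W == 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Effective sample size via initial positive autocorrelation sums
#'
#' @param x iterations x chains matrix of draws.
#' @return estimated effective sample size pooled over chains.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    a <- acf(x[, ch], lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    as.numeric(a)
  }, numeric(min(n - 2, 200))))
  # Geyer-style: accumulate consecutive pairs while their sum stays positive
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    rho_sum <- rho_sum + pair
    k <- k + 2
  }
  n * m / (1 + 2 * rho_sum)
}

#' Extract natural-scale draws of one parameter
#'
#' @param samples a `posterior_samples`.
#' @param par parameter name (see `samples$par_names`).
#' @return numeric vector pooling all chains.
#' @export
extract_par <- function(samples, par) {
  stopifnot(par %in% samples$par_names)
  as.numeric(samples$draws[, , par])
}

#' Highest posterior density interval with null-breach level
#'
#' Shortest sorted-sample window containing the requested mass. If the null
#' value lies outside the interval, `breach_alpha` is the significance level
#' at which the widening HPD interval first contains the null, found by
#' bisection on the coverage (tolerance 1e-3).
#'
#' @param x draws (>= 100), or a `posterior_samples` with `par`.
#' @param coverage interval mass.
#' @param null null value to compare against (default 1, a neutral gain).
#' @param par parameter name when `x` is a `posterior_samples`.
#' @return list: `lower`, `upper`, `coverage`, `contains_null`,
#'   `breach_alpha` (NA when the null is inside the interval).
#' @export
hpd <- function(x, coverage = 0.95, null = 1, par = NULL) {
  if (inherits(x, "posterior_samples")) x <- extract_par(x, par)
  stopifnot(length(x) >= 100, coverage > 0, coverage < 1)
  xs <- sort(x)
  iv <- hpd_window(xs, coverage)
  contains <- null >= iv[1] && null <= iv[2]
  breach <- NA_real_
  if (!contains) {
    # widen coverage until the null enters; bisect on the entry point
    lo <- coverage; hi <- 1 - 1 / length(xs)
    iv_hi <- hpd_window(xs, hi)
    if (null >= iv_hi[1] && null <= iv_hi[2]) {
      while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        ivm <- hpd_window(xs, mid)
        if (null >= ivm[1] && null <= ivm[2]) hi <- mid else lo <- mid
      }
      breach <- 1 - hi
    }
  }
  list(lower = iv[1], upper = iv[2], coverage = coverage,
       contains_null = contains, breach_alpha = breach)
}

hpd_window <- function(xs, coverage) {
  n <- length(xs)
  k <- max(1L, ceiling(coverage * n))
  if (k >= n) return(c(xs[1], xs[n]))
  widths <- xs[(k + 1):n] - xs[seq_len(n - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

#' Posterior predictive replicates and model comparison
#'
#' Draws replicated counts from the fitted model, summarizes per-datum
#' replicate distributions, computes the replicate-vs-observed mean squared
#' error, and reports plug-in AIC for the full model and the clamped variant
#' (all gains fixed at 1).
#'
#' @param samples a fitted `posterior_samples` for a zone model.
#' @param n_rep replicate draws (subsampled from the posterior).
#' @return list: `rep_mean` (per-datum replicate means), `coverage95`
#'   (fraction of observations inside their central 95% replicate interval),
#'   `mse`, `aic_full`, `aic_clamped`.
#' @export
posterior_predictive <- function(samples, n_rep = 500) {
  model <- samples$model
  stopifnot(model$kind == "zone")
  S <- model$S; T <- model$T; A <- model$A; Z <- model$Z
  dr <- samples$draws
  flat <- matrix(dr, ncol = dim(dr)[3])
  colnames(flat) <- samples$par_names
  take <- sample.int(nrow(flat), min(n_rep, nrow(flat)))
  reps <- array(NA_real_, c(length(take), A, Z))
  for (r in seq_along(take)) {
    rho <- flat[take[r], seq_len(A)]
    eta <- flat[take[r], A + seq_len(Z)]
    reps[r, , ] <- matrix(rpois(A * Z, T * outer(rho, eta)), A, Z)
  }
  rep_mean <- apply(reps, c(2, 3), mean)
  qlo <- apply(reps, c(2, 3), quantile, 0.025)
  qhi <- apply(reps, c(2, 3), quantile, 0.975)
  coverage95 <- mean(S >= qlo & S <= qhi)
  mse <- mean((rep_mean - S)^2)
  # plug-in AIC at posterior means; clamped model refits rho only
  rho_hat <- colMeans(flat)[seq_len(A)]
  eta_hat <- colMeans(flat)[A + seq_len(Z)]
  ll_full <- sum(dpois(S, T * outer(rho_hat, eta_hat), log = TRUE))
  rho_clamped <- rowSums(S) / rowSums(T)
  ll_clamped <- sum(dpois(S, T * outer(rho_clamped, rep(1, Z)), log = TRUE))
  list(rep_mean = rep_mean, coverage95 = coverage95, mse = mse,
       aic_full = -2 * ll_full + 2 * (A + Z),
       aic_clamped = -2 * ll_clamped + 2 * A)
}

#' Fit the zone-gain model to a zone count table
#'
#' @param zone_tables list of per-animal data.frames from [count_by_zone]
#'   (or a single animal's table).
#' @param ... passed to [sample_posterior].
#' @return a `posterior_samples`.
#' @export
fit_zone_model <- function(zone_tables, ...) {
  if (is.data.frame(zone_tables)) zone_tables <- list(zone_tables)
  S <- do.call(rbind, lapply(zone_tables, function(d) setNames(d$S, d$zone)))
  T <- do.call(rbind, lapply(zone_tables, function(d) setNames(d$T, d$zone)))
  sample_posterior(zone_model(S, T), ...)
}

#' Fit the behavioral-state gain model
#'
#' @param trials data.frame with per-trial `S` (delay-zone spike count),
#'   `T` (delay occupancy s) and `animal`.
#' @param marginals trials x states matrix of HMM state marginals.
#' @param ... passed to [sample_posterior].
#' @return a `posterior_samples`.
#' @export
fit_state_rate_model <- function(trials, marginals, ...) {
  sample_posterior(state_model(trials$S, trials$T, marginals, trials$animal),
                   ...)
}
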