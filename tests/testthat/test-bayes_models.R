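test_that("zone-model log posterior matches closed forms and symmetry", {
  # single cell: Poisson term log pmf(3; 10 * 0.3 * 1) = 3 log 3 - 3 - log 3!
  S <- matrix(3, 1, 1); Tocc <- matrix(10, 1, 1)
  lp <- log_posterior_zone(0.3, 1, S, Tocc)
  pois <- 3 * log(3) - 3 - log(factorial(3))
  prior <- dlnorm(0.3, -1, 0.3, log = TRUE) + dlnorm(1, 0, 1, log = TRUE)
  expect_equal(lp, pois + prior, tolerance = 1e-12)

  # doubling eta and halving rho leaves the likelihood term unchanged
  set.seed(12)
  S4 <- matrix(rpois(12, 5), 3, 4); T4 <- matrix(10, 3, 4)
  rho <- runif(3, 0.2, 0.8); eta <- runif(4, 0.5, 2)
  lik <- function(r, e) sum(dpois(S4, T4 * outer(r, e), log = TRUE))
  expect_equal(lik(rho / 2, eta * 2), lik(rho, eta), tolerance = 1e-10)

  expect_equal(log_posterior_zone(-0.1, eta, S4, T4), -Inf)
})

test_that("log-posterior gradients agree with finite differences", {
  set.seed(13)
  S <- matrix(rpois(8, 6), 2, 4); Tocc <- matrix(runif(8, 5, 20), 2, 4)
  m <- zone_model(S, Tocc)
  theta <- rnorm(m$n_par, m$init_mean, 0.2)
  # analytic gradient in log space: d/dlog rho_a = sum_z (S - mu) + prior term
  mu <- Tocc * exp(outer(theta[1:2], theta[3:6], "+"))
  g_rho <- rowSums(S - mu) - (theta[1:2] + 1) / 0.3^2
  g_eta <- colSums(S - mu) - theta[3:6] / 1^2
  g_num <- vapply(seq_len(m$n_par), function(k) {
    h <- 1e-6; tp <- theta; tm <- theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (m$log_post(tp) - m$log_post(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(g_num, c(g_rho, g_eta), tolerance = 1e-4)
})

test_that("prior-only sampling recovers the priors", {
  # negligible exposure: the Poisson factor is flat and the posterior is the prior
  S <- matrix(0, 2, 2); Tocc <- matrix(1e-9, 2, 2)
  ps <- suppressWarnings(sample_posterior(zone_model(S, Tocc), n_iter = 1500,
                                          n_warmup = 500, seed = 3))
  eta_draws <- extract_par(ps, "eta[1]")
  rho_draws <- extract_par(ps, "rho[1]")
  expect_lt(abs(median(log(eta_draws))), 0.15)        # prior median 1
  expect_lt(abs(median(log(rho_draws)) + 1), 0.1)     # prior median e^-1
})

test_that("posterior concentrates on identified rate products", {
  set.seed(14)
  Tocc <- matrix(600, 4, 4, dimnames = list(NULL, zone_names()))
  rho <- c(0.4, 0.5, 0.6, 0.5); eta <- c(1, 1, 1.3, 1.9)
  S <- matrix(rpois(16, Tocc * outer(rho, eta)), 4, 4,
              dimnames = list(NULL, zone_names()))
  ps <- suppressWarnings(sample_posterior(zone_model(S, Tocc), seed = 5))
  expect_true(all(ps$diagnostics$rhat < 1.02))
  # the products rho_a * eta_z are likelihood-identified and must be recovered
  rho_hat <- vapply(1:4, function(a) mean(extract_par(ps, paste0("rho[", a, "]"))),
                    numeric(1))
  eta_hat <- vapply(zone_names(), function(z)
    mean(extract_par(ps, paste0("eta[", z, "]"))), numeric(1))
  prod_hat <- outer(rho_hat, eta_hat)
  expect_equal(as.numeric(prod_hat), as.numeric(outer(rho, eta)),
               tolerance = 0.1)
  # reward vs delay gain ratio is identified and recovered
  rw <- extract_par(ps, "eta[reward]") / extract_par(ps, "eta[delay]")
  expect_equal(mean(rw), 1.9, tolerance = 0.15)
})

test_that("HPD intervals are shortest windows with correct breach levels", {
  expect_equal(unlist(hpd(rep(2.5, 150))[c("lower", "upper")]),
               c(lower = 2.5, upper = 2.5))

  set.seed(15)
  x <- rnorm(1e5)
  h <- hpd(x, 0.95, null = 0)
  expect_equal(h$lower, -1.96, tolerance = 0.05)
  expect_equal(h$upper, 1.96, tolerance = 0.05)
  expect_true(h$contains_null)
  expect_true(is.na(h$breach_alpha))

  # null just outside: breach level consistent with the normal tail
  h2 <- hpd(x + 3, 0.95, null = 0)
  expect_false(h2$contains_null)
  expect_false(is.na(h2$breach_alpha))
  expect_lt(h2$breach_alpha, 0.05)

  # all samples above the null: no coverage < 1 ever contains it
  h3 <- hpd(runif(500, 2, 3), null = 1)
  expect_false(h3$contains_null)
  expect_true(is.na(h3$breach_alpha))
})

test_that("posterior predictive replicates calibrate and rank models", {
  set.seed(16)
  Tocc <- matrix(600, 4, 4, dimnames = list(NULL, zone_names()))
  # data generated with all gains neutral
  S <- matrix(rpois(16, Tocc * 0.5), 4, 4, dimnames = list(NULL, zone_names()))
  ps <- suppressWarnings(sample_posterior(zone_model(S, Tocc), seed = 6))
  pp <- posterior_predictive(ps)
  expect_gte(pp$coverage95, 0.8)
  expect_true(is.finite(pp$mse))
  # no strong spurious preference for the full model on null data
  expect_gte(pp$aic_full, pp$aic_clamped - 4)
})

test_that("the state-gain model recovers planted state effects", {
  set.seed(17)
  n <- 400
  st <- sample(1:3, n, replace = TRUE)
  marg <- matrix(0, n, 3); marg[cbind(seq_len(n), st)] <- 1
  eta <- c(0.4, 1, 1); Tocc <- rep(10, n)
  S <- rpois(n, Tocc * 0.5 * eta[st])
  ps <- suppressWarnings(
    fit_state_rate_model(data.frame(S = S, T = Tocc, animal = 1), marg,
                         seed = 7))
  expect_true(all(ps$diagnostics$rhat < 1.02))
  h <- hpd(ps, par = "eta[1]")
  expect_false(h$contains_null)       # guess-state suppression detected
  expect_lt(h$upper, 1)
  g <- mean(extract_par(ps, "eta[1]"))
  expect_equal(g, 0.4, tolerance = 0.35)
  # neutral states stay consistent with unity
  expect_true(hpd(ps, par = "eta[2]")$contains_null)
})

test_that("zone relabeling permutes the posterior coherently", {
  set.seed(18)
  Tocc <- matrix(300, 2, 4, dimnames = list(NULL, zone_names()))
  S <- matrix(rpois(8, Tocc * 0.5 * rep(c(1, 1, 1, 2), each = 2)), 2, 4,
              dimnames = list(NULL, zone_names()))
  perm <- c(4, 1, 2, 3)
  ps1 <- suppressWarnings(sample_posterior(zone_model(S, Tocc), n_iter = 1000,
                                           n_warmup = 500, seed = 9))
  ps2 <- suppressWarnings(sample_posterior(zone_model(S[, perm], Tocc[, perm]),
                                           n_iter = 1000, n_warmup = 500,
                                           seed = 9))
  m1 <- vapply(zone_names(), function(z)
    mean(extract_par(ps1, paste0("eta[", z, "]"))), numeric(1))
  m2 <- vapply(zone_names()[perm], function(z)
    mean(extract_par(ps2, paste0("eta[", z, "]"))), numeric(1))
  expect_equal(unname(m2), unname(m1[perm]), tolerance = 0.1)
})
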