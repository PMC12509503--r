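test_that("waveform extraction is aligned, fixed-length and z-scored", {
  cfg <- small_lfp_cfg(seed = 51, duration_s = 30, noise_sd_uV = 30,
                       theta_amp_uV = 0)
  ev <- spaced_events(8, 30)
  tr <- make_lfp(cfg, ev)
  wf <- extract_waveforms(tr, ev)
  expect_equal(ncol(wf$waveforms), 401)      # +/-100 ms at 2 kHz, inclusive
  expect_lt(max(abs(rowMeans(wf$waveforms))), 1e-9)
  expect_lt(max(abs(apply(wf$waveforms, 1, sd) - 1)), 1e-9)

  # a lone impulse extracted at its own time lands on the center sample
  imp <- numeric(10000); imp[5001] <- 100
  wi <- extract_waveforms(lfp_trace(imp, 1000), 5.0)
  expect_equal(which.max(wi$waveforms[1, ]), 201)

  # events at the trace edge are dropped with a warning
  expect_warning(w2 <- extract_waveforms(tr, c(0.05, ev)), "dropped")
  expect_equal(nrow(w2$waveforms), 8)
})

test_that("the 2-D embedding separates distinct waveform families", {
  set.seed(52)
  n <- 120
  t <- seq(-0.1, 0.1, length.out = 401)
  base1 <- exp(-t^2 / (2 * 0.01^2))
  base2 <- exp(-t^2 / (2 * 0.03^2)) * sin(2 * pi * 40 * t + 1)
  W <- rbind(t(replicate(n / 2, base1 + rnorm(401, 0, 0.08))),
             t(replicate(n / 2, base2 + rnorm(401, 0, 0.08))))
  W <- t(apply(W, 1, function(r) (r - mean(r)) / sd(r)))
  lab <- rep(1:2, each = n / 2)
  emb <- embed_2d(W, seed = 4)
  expect_equal(dim(emb), c(n, 2))
  expect_identical(embed_2d(W, seed = 4), emb)

  # silhouette of the two classes in the embedding
  d <- as.matrix(dist(emb))
  sil <- vapply(seq_len(n), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  expect_error(embed_2d(W[1:5, ]), "at least 10")
})

test_that("reward classification scores separable and null data correctly", {
  set.seed(53)
  emb <- rbind(matrix(rnorm(200, mean = 3), 100, 2),
               matrix(rnorm(200, mean = -3), 100, 2))
  lab <- rep(c(TRUE, FALSE), each = 100)
  cl <- classify_reward(emb, lab, seed = 2)
  expect_equal(cl$auc, 1)

  # permuted labels: AUC hovers at chance
  emb2 <- matrix(rnorm(4000), 2000, 2)
  lab2 <- sample(rep(c(TRUE, FALSE), 1000))
  cl2 <- classify_reward(emb2, lab2, seed = 3)
  expect_gt(cl2$auc, 0.45)
  expect_lt(cl2$auc, 0.55)

  expect_error(classify_reward(emb, rep(TRUE, 200)), "classes")
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(54)
  y <- factor(rep(c(TRUE, FALSE), each = 50))
  sc <- c(rnorm(50, 1), rnorm(50, 0))
  a1 <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                       levels = levels(y), direction = "<")))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, exp(3 * sc), quiet = TRUE,
                                       levels = levels(y), direction = "<")))
  expect_equal(a1, a2)
})

test_that("performance-on-AUC regression returns the standard summary", {
  auc <- seq(0.5, 0.9, length.out = 7)
  perf <- 20 + 100 * auc
  fit <- auc_vs_performance(auc, perf)
  expect_equal(fit$coefficients$estimate, c(20, 100), tolerance = 1e-9)
  expect_equal(fit$r_squared_adj, 1, tolerance = 1e-9)

  set.seed(55)
  fit2 <- auc_vs_performance(runif(7, 0.4, 0.9), runif(7, 40, 90))
  expect_true(is.finite(fit2$f_statistic))
  expect_true(fit2$p_value >= 0 && fit2$p_value <= 1)
  expect_error(auc_vs_performance(rep(0.5, 5), runif(5)), "constant")
})

test_that("amplitude comparison normalizes per animal and detects shifts", {
  set.seed(56)
  n <- 2000
  animal <- rep(1:5, each = n / 5)
  grp <- rep(c("reward", "other"), n / 2)
  scale_a <- c(50, 100, 200, 25, 75)[animal]   # animal-specific amplitude scale
  rms <- scale_a * abs(rnorm(n, 10, 1))
  rms[grp == "reward"] <- rms[grp == "reward"] +
    0.5 * scale_a[grp == "reward"]               # planted +0.5 SD shift
  res <- rms_compare(rms, grp, animal)
  for (a in 1:5)
    expect_equal(sd(res$normalized[animal == a]), 1, tolerance = 1e-12)
  expect_lt(res$test$p.value, 0.001)

  # identical distributions: no significant difference expected
  res0 <- rms_compare(rlnorm(400, 5, 0.3), rep(c("a", "b"), 200),
                      rep(1:4, each = 100))
  expect_gt(res0$test$p.value, 0.001)
  expect_error(rms_compare(rms, rep("one", length(rms)), animal), "two groups")
})

test_that("raw-waveform classification tracks the embedded classification", {
  set.seed(57)
  n <- 80
  t <- seq(-0.1, 0.1, length.out = 401)
  W <- rbind(t(replicate(n / 2, exp(-t^2 / 2e-4) + rnorm(401, 0, 0.1))),
             t(replicate(n / 2, exp(-(t - 0.03)^2 / 2e-4) + rnorm(401, 0, 0.1))))
  W <- t(apply(W, 1, function(r) (r - mean(r)) / sd(r)))
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  emb <- embed_2d(W, seed = 6)
  auc_emb <- classify_reward(emb, lab, seed = 6)$auc
  auc_raw <- classify_reward(W, lab, seed = 6)$auc
  expect_lt(abs(auc_emb - auc_raw), 0.1)
})
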