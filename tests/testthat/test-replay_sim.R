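test_that("clamped exploration rates follow the place/theta tuning", {
  # stationary animal at the field center: mean rate lambda_max / 2
  pfm <- place_field_map(1)
  pfm$centers <- 0
  x <- rep(0, 200 * 1000)   # 200 s at 1 ms
  set.seed(61)
  sp <- spikelapse:::place_spikes_cpp(x, 0.001, pfm$centers, 20, 7, 7)
  rate <- length(sp$t_s) / 200
  expect_lt(abs(rate - 10), 3 * sqrt(10 * 200) / 200)

  # one field-width away the Gaussian envelope scales the rate by e^{-1/2}
  x2 <- rep(7, 200 * 1000)
  sp2 <- spikelapse:::place_spikes_cpp(x2, 0.001, pfm$centers, 20, 7, 7)
  rate2 <- length(sp2$t_s) / 200
  expect_lt(abs(rate2 - 10 * exp(-0.5)), 3 * sqrt(6.07 * 200) / 200)
})

test_that("exploration is reproducible and interictal modes gate delivery", {
  pfm3 <- place_field_map(60); pfm1 <- place_field_map(60)
  e1 <- simulate_exploration(pfm3, pfm1, is_stim_config("off"),
                             duration_s = 20, seed = 5)
  e2 <- simulate_exploration(pfm3, pfm1, is_stim_config("off"),
                             duration_s = 20, seed = 5)
  expect_identical(e1$spikes_ca3, e2$spikes_ca3)
  expect_length(e1$is_times_s, 0)

  e3 <- simulate_exploration(pfm3, pfm1, is_stim_config("clustered"),
                             duration_s = 60, seed = 5)
  expect_gt(length(e3$is_times_s), 0)
  # clustered delivery goes only to active place cells near the locus
  if (nrow(e3$is_deliveries) > 0)
    expect_true(all(!is.na(pfm3$centers[e3$is_deliveries$id])))
})

test_that("STDP closed-form updates match the kernel branches", {
  # one pre spike then one post spike at +tau_plus: dw = lambda * exp(-1)
  p <- stdp_presets()$ca3_ca1
  w <- spikelapse:::stdp_train_cpp(
    c(0, p$tau_plus_ms / 1000), c(0L, 0L), c(1L, 0L), c(0L, 1L),
    1L, 1L, 0L, 0L, 0.5, p$lambda, p$alpha, p$tau_plus_ms, p$tau_minus_ms)
  expect_equal(w, 0.5 + p$lambda * exp(-1), tolerance = 1e-12)

  # asymmetric depression at negative lag: dw = -lambda * alpha * exp(-|dt|/tau-)
  w2 <- spikelapse:::stdp_train_cpp(
    c(0, p$tau_minus_ms / 1000), c(0L, 0L), c(0L, 1L), c(1L, 0L),
    1L, 1L, 0L, 0L, 0.5, p$lambda, p$alpha, p$tau_plus_ms, p$tau_minus_ms)
  expect_equal(w2, 0.5 - p$lambda * p$alpha * exp(-1), tolerance = 1e-12)

  # symmetric preset facilitates at negative lag (alpha = -1)
  ps <- stdp_presets()$ca3_ca3
  w3 <- spikelapse:::stdp_train_cpp(
    c(0, ps$tau_minus_ms / 1000), c(0L, 0L), c(0L, 1L), c(1L, 0L),
    1L, 1L, 0L, 0L, 0.5, ps$lambda, ps$alpha, ps$tau_plus_ms, ps$tau_minus_ms)
  expect_equal(w3, 0.5 + ps$lambda * exp(-1), tolerance = 1e-12)

  # no spikes: weights unchanged
  w4 <- spikelapse:::stdp_train_cpp(
    numeric(0), integer(0), integer(0), integer(0), 1L, 1L, 0L, 0L, 0.37,
    ps$lambda, ps$alpha, ps$tau_plus_ms, ps$tau_minus_ms)
  expect_equal(w4, 0.37)
})

test_that("trained weights stay in [0,1] under heavy random spiking", {
  set.seed(62)
  ns <- 3000
  tt <- sort(runif(ns, 0, 10))
  id <- sample(0:19, ns, replace = TRUE)
  edges <- expand.grid(src = 0:19, dst = 0:19)
  edges <- edges[edges$src != edges$dst, ]
  p <- stdp_presets()$ca3_ca3
  w <- spikelapse:::stdp_train_cpp(tt, as.integer(id), rep(1L, ns), rep(1L, ns),
                                   20L, 20L, as.integer(edges$src),
                                   as.integer(edges$dst),
                                   runif(nrow(edges)), p$lambda, p$alpha,
                                   p$tau_plus_ms, p$tau_minus_ms)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("the offline network is silent without input and drive", {
  pfm <- place_field_map(40)
  weights <- list(ca3_edges = data.frame(src = 1, dst = 2, w = 0),
                  ca1_edges = data.frame(src = 1, dst = 1, w = 0))
  net <- build_offline_network(weights, 40, 40, 5, seed = 1)
  off <- simulate_offline(net, duration_s = 0.5, dg_rate_hz = 0, seed = 1)
  expect_equal(nrow(off$spikes), 0)
  expect_true(all(off$lfp == 0))
})

test_that("integrator step-size halving barely changes spike output", {
  # standard-input benchmark: steady kick barrage onto one neuron
  ch <- rbind(c(1, 9, 0))
  run <- function(dt) {
    steps <- as.integer(seq(0, 1000 / dt - 1, by = 5 / dt))
    out <- spikelapse:::aelif_net_cpp(
      1L, 0L, aelif_param_table(), ch, integer(0), integer(0), numeric(0),
      integer(0), integer(0), steps, rep(0L, length(steps)),
      rep(8, length(steps)), rep(0L, length(steps)), 1000, dt, 0L,
      as.integer(round(1 / dt)), 1, -75)
    length(out$spike_t_ms)
  }
  n1 <- run(0.1); n2 <- run(0.01)
  expect_lt(abs(n1 - n2) / n2, 0.05)
})

test_that("replay detection applies prominence and distance rules", {
  expect_equal(nrow(detect_replays(numeric(3000))), 0)

  bump <- 2e-3 * exp(-(seq(-300, 300))^2 / (2 * 30^2))
  x <- numeric(3000)
  x[500 + seq_along(bump) - 300] <- bump
  x[600 + seq_along(bump) - 300] <- x[600 + seq_along(bump) - 300] + bump
  expect_equal(nrow(detect_replays(x)), 1)   # 100 samples apart: merged

  y <- numeric(3000)
  y[500 + seq_along(bump) - 300] <- bump
  y[800 + seq_along(bump) - 300] <- y[800 + seq_along(bump) - 300] + bump
  expect_equal(nrow(detect_replays(y)), 2)   # 300 samples apart: both kept
})

test_that("population-vector decoding votes by field centers", {
  pfm <- place_field_map(10)
  pfm$centers <- c(50, 50, 50, NA, NA, -30, -30, 120, NA, NA)
  sp <- data.frame(t_s = c(0.01, 0.012, 0.02), id = c(1, 2, 3))
  dec <- decode_position(sp, pfm, 0, 0.025)
  expect_equal(dec$x_hat_cm, 50)

  # tie between +50 (2 votes) and -30 (2 votes): smaller |x| wins
  sp2 <- data.frame(t_s = c(0.01, 0.012, 0.014, 0.016), id = c(1, 2, 6, 7))
  dec2 <- decode_position(sp2, pfm, 0, 0.025)
  expect_equal(dec2$x_hat_cm, -30)

  # sweeping raster decodes a monotone trajectory
  pfm$centers <- seq(-135, 135, length.out = 10)
  sp3 <- data.frame(t_s = seq(0.01, 0.24, length.out = 10), id = 1:10)
  dec3 <- decode_position(sp3, pfm, 0, 0.25)
  xs <- dec3$x_hat_cm[!is.na(dec3$x_hat_cm)]
  expect_true(all(diff(xs) > 0))

  expect_equal(nrow(decode_position(sp3[0, ], pfm, 0, 0)), 0)
})

test_that("contamination counts un-cued-arm place-cell spikes only", {
  pfm <- place_field_map(6)
  pfm$centers <- c(100, 80, -90, -40, NA, NA)
  sp <- data.frame(t_s = rep(0.1, 6), id = 1:6)
  expect_equal(contamination(sp, pfm, cued_sign = 1, 0, 1), 2)
  expect_equal(contamination(sp, pfm, cued_sign = -1, 0, 1), 2)
  expect_equal(contamination(sp[1:2, ], pfm, cued_sign = 1, 0, 1), 0)
})

test_that("a trained network generates spontaneous replay events", {
  rp <- train_replica("control", n_pyr = 1250, n_int = 100, train_s = 120,
                      seed = 3)
  expect_true(all(rp$weights$ca3_edges$w >= 0 & rp$weights$ca3_edges$w <= 1))
  off <- simulate_offline(rp$net, duration_s = 5, seed = 4)
  rw <- detect_replays(off$lfp)
  expect_gt(nrow(rw), 0)
  # LFP scaling: the proxy is inversely proportional to electrode distance
  gain1 <- 1 / (4 * pi * 0.3 * 5e-6)
  gain2 <- 1 / (4 * pi * 0.3 * 1e-5)
  expect_equal(gain1 / gain2, 2)
})
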