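test_that("polarity orientation points the heavy tail upward", {
  cfg <- small_lfp_cfg(seed = 7, duration_s = 30)
  ev <- spaced_events(10, 30)
  tr <- make_lfp(cfg, ev)
  up <- orient_polarity(tr)
  expect_identical(up$samples, tr$samples)           # transients are positive
  flipped <- tr; flipped$samples <- -tr$samples
  expect_identical(orient_polarity(flipped)$samples, tr$samples)

  # skew magnitude is preserved, sign flipped positive
  sk <- spikelapse:::sample_skewness(tr$samples)
  expect_equal(spikelapse:::sample_skewness(orient_polarity(flipped)$samples),
               sk, tolerance = 1e-12)
  expect_error(orient_polarity(lfp_trace(rep(1, 100), 1000)), "constant")
})

test_that("detect_spikes finds planted transients by prominence", {
  expect_length(detect_spikes(lfp_trace(numeric(5000), 1000),
                              detector_config(900, 2, 400)), 0)

  cfg <- small_lfp_cfg(seed = 13, duration_s = 30, is_amp_uV = 1500)
  ev <- spaced_events(5, 30, gap = 4)
  tr <- orient_polarity(make_lfp(cfg, ev))
  det <- detect_spikes(tr, detector_config(900, 2, 400))
  expect_length(det, 5)
  expect_true(all(abs(det - sort(ev)) < 0.015))

  # raising the threshold above the max prominence removes all detections
  expect_length(detect_spikes(tr, detector_config(50000, 2, 400)), 0)

  # detection count is non-increasing in the threshold
  counts <- vapply(c(300, 900, 1500, 2500, 5000),
                   function(th) length(detect_spikes(tr, detector_config(th, 2, 400))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(detect_spikes(tr, detector_config(900, 2, 600)), "passband")
})

test_that("detector scoring implements the window-based TP/FP/FN rules", {
  # windows hit {1, 2, 0} times plus one stray detection
  w <- data.frame(t_start_s = c(1, 3, 5), t_end_s = c(2, 4, 6))
  det <- c(1.5, 3.2, 3.8, 7.0)
  sc <- score_detector(det, w)
  expect_equal(sc$tp, 2)
  expect_equal(sc$fp, 2)
  expect_equal(sc$fn, 1)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$recall, 2 / 3)
  expect_equal(sc$f_beta, 0.526, tolerance = 1e-3)

  sc1 <- score_detector(c(1.5, 3.5, 5.5), w)
  expect_equal(c(sc1$precision, sc1$recall, sc1$f_beta), c(1, 1, 1))

  expect_error(score_detector(det, w, beta = 0), "beta")

  # F_beta with beta = 1/2 rewards precision more than recall
  expect_gt(f_beta(0.9, 0.5), f_beta(0.5, 0.9))
  # and is monotone in both arguments
  expect_gt(f_beta(0.8, 0.6), f_beta(0.7, 0.6))
  expect_gt(f_beta(0.8, 0.6), f_beta(0.8, 0.5))
})

test_that("grid tuning returns the F-score argmax with documented tie-breaks", {
  cfg <- small_lfp_cfg(seed = 17, duration_s = 40, is_amp_uV = 1500)
  ev <- spaced_events(12, 40, gap = 3)
  tr <- orient_polarity(make_lfp(cfg, ev))
  win <- make_labeled_windows(ev)

  grid <- list(threshold_uV = c(700, 1100), low_hz = c(2, 8), high_hz = 400)
  tuned <- tune_detector(tr, win, grid)
  # argmax property: no grid element scores higher
  for (th in grid$threshold_uV) for (lo in grid$low_hz) {
    sc <- score_detector(detect_spikes(tr, detector_config(th, lo, 400)), win)
    expect_lte(sc$f_beta, tuned$score$f_beta + 1e-12)
  }

  single <- list(threshold_uV = 900, low_hz = 4, high_hz = 200)
  t1 <- tune_detector(tr, win, single)
  expect_equal(t1$config$threshold_uV, 900)
  expect_equal(t1$config$low_hz, 4)
  expect_equal(t1$config$high_hz, 200)
})

test_that("event taxonomy splits spikes into solitary IS and BIRDs", {
  e1 <- classify_events(10.0)
  expect_equal(e1$label, "solitary")

  e <- classify_events(c(0, 0.5, 1.0, 10, 20, 20.5))
  expect_equal(e$label, c("bird_first", "bird_within", "bird_last",
                          "solitary", "bird_first", "bird_last"))
  expect_equal(e$bird_id, c(1L, 1L, 1L, NA, 2L, 2L))

  e2 <- classify_events(c(0, 3, 6, 9))
  expect_true(all(e2$label == "solitary"))

  # partition property on random trains
  set.seed(1)
  for (r in 1:20) {
    tt <- sort(runif(50, 0, 100))
    ec <- classify_events(tt)
    expect_equal(nrow(ec), 50)
    in_birds <- sum(!is.na(ec$bird_id))
    expect_equal(in_birds + sum(ec$label == "solitary"), 50)
    for (b in unique(na.omit(ec$bird_id))) {
      lb <- ec$label[which(ec$bird_id == b)]
      expect_gte(length(lb), 2)
      expect_equal(sum(lb == "bird_first"), 1)
      expect_equal(sum(lb == "bird_last"), 1)
    }
  }
})

test_that("seizures are dense trains lasting at least 10 s", {
  s <- detect_seizures(seq(0, 14.5, by = 0.5))
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_s, 14.5)

  expect_equal(nrow(detect_seizures(seq(0, 8, by = 0.5))), 0)
  expect_equal(nrow(detect_seizures(numeric())), 0)
})

test_that("event statistics report pooled, solitary and BIRD rates", {
  ev <- classify_events(seq(0.5, 95, by = 10))   # 10 solitary spikes
  st <- event_statistics(ev, 100)
  expect_equal(st$solitary_rate_hz, 0.1)
  expect_equal(st$rate_hz, 0.1)

  ev2 <- classify_events(c(1, 2, 3, 4, 5))       # one 5-spike BIRD over 4 s
  st2 <- event_statistics(ev2, 100)
  expect_equal(st2$bird_duration_s, 4)
  expect_equal(st2$spikes_per_bird, 5)
  expect_equal(st2$bird_rate_hz, 0.01)
  expect_equal(st2$rate_hz, 0.05)               # pooled rate ignores taxonomy
})

test_that("tuned detector closes the loop on labeled synthetic data", {
  # moderate signal-to-noise: transient amplitude 5x the noise SD
  cfg <- synth_config(seed = 29, duration_s = 90, is_amp_uV = 1000,
                      noise_sd_uV = 200, theta_amp_uV = 100)
  ev <- spaced_events(30, 90, gap = 2.5, seed = 4)
  tr <- orient_polarity(make_lfp(cfg, ev))
  win <- make_labeled_windows(ev)
  tuned <- tune_detector(tr, win, list(threshold_uV = seq(500, 1500, 250),
                                       low_hz = c(2, 8), high_hz = c(200, 400)))
  expect_gte(tuned$score$f_beta, 0.95)
})
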