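#' Extract z-scored IS waveforms
#'
#' For each event, +/-100 ms of the single-channel LFP around the detection
#' time is extracted, resampled to 2,000 Hz (401 samples, inclusive
#' endpoints) and z-scored per waveform. Events closer than 100 ms to the
#' trace edges are dropped with a warning.
#'
#' @param trace an [lfp_trace] (polarity-oriented).
#' @param times_s event times (s).
#' @param labels optional data.frame of per-event labels (e.g., in-reward,
#'   side, correct); subset alongside the kept events.
#' @param half_window_s half-window (s).
#' @param out_fs_hz output sampling rate (Hz).
#' @return list: `waveforms` (events x 401 matrix, each row mean 0 / sd 1),
#'   `times_s` (kept events), `labels` (kept rows).
#' @export
extract_waveforms <- function(trace, times_s, labels = NULL,
                              half_window_s = 0.1, out_fs_hz = 2000) {
  fs <- trace$fs_hz; n <- length(trace$samples)
  hw <- half_window_s
  keep <- times_s - hw >= 0 & times_s + hw <= (n - 1) / fs
  if (any(!keep))
    warning(sum(!keep), " event(s) within 100 ms of the trace edge dropped")
  times_s <- times_s[keep]
  if (!is.null(labels)) labels <- labels[keep, , drop = FALSE]
  n_out <- round(2 * hw * out_fs_hz) + 1L
  t_rel <- seq(-hw, hw, length.out = n_out)
  W <- t(vapply(times_s, function(tt) {
    src_t <- (seq_len(n) - 1) / fs
    seg <- approx(src_t, trace$samples, xout = tt + t_rel)$y
    (seg - mean(seg)) / sd(seg)
  }, numeric(n_out)))
  list(waveforms = W, times_s = times_s, labels = labels)
}

#' 2-D embedding of IS waveforms
#'
#' Non-linear t-SNE embedding (exact gradient, perplexity-calibrated
#' Gaussian affinities) of the z-scored waveform matrix; deterministic given
#' `seed`.
#'
#' @param waveforms events x samples matrix.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (reduced automatically for small n).
#' @param n_iter gradient-descent iterations.
#' @return events x 2 coordinate matrix with attribute `seed`.
#' @export
embed_2d <- function(waveforms, seed = 1L, perplexity = 30, n_iter = 500) {
  Y <- tsne_embed(as.matrix(waveforms), perplexity = perplexity,
                  n_iter = n_iter, seed = seed)
  attr(Y, "seed") <- seed
  Y
}

#' Cross-validated reward-zone classification of embedded IS
#'
#' A bagging ensemble of trees (100 trees, all features available at every
#' split) is trained with stratified k-fold cross-validation; out-of-fold
#' scores are pooled into a single ROC.
#'
#' @param features events x d matrix (2-D embedding or raw waveforms).
#' @param labels logical/two-level class per event.
#' @param k_folds folds (default 5).
#' @param n_trees ensemble size.
#' @param seed fold/forest seed.
#' @return list: `auc`, `roc` (a `pROC::roc`), `scores` (out-of-fold
#'   probabilities), `folds`.
#' @export
classify_reward <- function(features, labels, k_folds = 5, n_trees = 100,
                            seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("both classes must be present")
  X <- as.matrix(features)
  set.seed(seed)
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  scores <- numeric(length(y))
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    fit <- randomForest::randomForest(
      x = X[tr, , drop = FALSE], y = y[tr],
      ntree = n_trees, mtry = ncol(X))   # mtry = all features: pure bagging
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE],
                           type = "prob")[, levels(y)[2]]
  }
  roc <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                   levels = levels(y), direction = "<")
  list(auc = as.numeric(pROC::auc(roc)), roc = roc, scores = scores,
       folds = folds)
}

#' Regression of task performance on per-animal decoding AUC
#'
#' Ordinary linear regression of mean alternation performance on the
#' reward-zone classifier AUC, with the F statistic against the constant
#' model.
#'
#' @param auc per-animal AUC values (>= 3 animals).
#' @param performance per-animal mean performance.
#' @return list: `fit`, `coefficients` (estimate/se/t/p), `f_statistic`,
#'   `p_value`, `r_squared_adj`.
#' @export
auc_vs_performance <- function(auc, performance) {
  stopifnot(length(auc) == length(performance), length(auc) >= 3)
  if (sd(auc) == 0) stop("constant AUC: model is rank-deficient")
  fit <- lm(performance ~ auc)
  sm <- summary(fit)
  co <- sm$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], p = co[, 4],
                                 row.names = NULL),
       f_statistic = unname(sm$fstatistic[1]),
       p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                  sm$fstatistic[3], lower.tail = FALSE)),
       r_squared_adj = sm$adj.r.squared)
}

#' Compare normalized IS amplitudes between groups
#'
#' Each event's RMS amplitude is divided by the standard deviation of RMS
#' amplitudes for its animal, then the two groups are compared with a
#' two-sample t-test.
#'
#' @param rms per-event RMS amplitudes.
#' @param group two-level grouping (e.g., reward vs non-reward).
#' @param animal animal id per event.
#' @return list: `normalized` (per-event normalized amplitudes), `test`
#'   (`htest`), `group_means`.
#' @export
rms_compare <- function(rms, group, animal) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("need two groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 events")
  norm <- rms
  for (a in unique(animal)) {
    idx <- animal == a
    norm[idx] <- rms[idx] / sd(rms[idx])
  }
  tt <- t.test(norm[g == levels(g)[1]], norm[g == levels(g)[2]])
  list(normalized = norm, test = tt,
       group_means = tapply(norm, g, mean))
}
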