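#' Detector configuration
#'
#' @param threshold_uV minimum topographic peak prominence (uV).
#' @param low_hz,high_hz band-pass edges (Hz).
#' @return a `detector_config` object.
#' @export
detector_config <- function(threshold_uV, low_hz, high_hz) {
  stopifnot(threshold_uV > 0, low_hz > 0, high_hz > low_hz)
  structure(list(threshold_uV = threshold_uV, low_hz = low_hz,
                 high_hz = high_hz), class = "detector_config")
}

#' Orient LFP polarity so interictal spikes point positive
#'
#' The sign of the sample skewness estimates which way the heavy tail (the
#' IS transients) points; the trace is multiplied by that sign. A trace with
#' zero skewness is returned unchanged.
#'
#' @param trace an [lfp_trace].
#' @return the polarity-oriented [lfp_trace].
#' @export
orient_polarity <- function(trace) {
  x <- trace$samples
  if (sd(x) == 0) stop("constant trace: polarity is undefined")
  sk <- sample_skewness(x)
  if (sk < 0) trace$samples <- -x
  trace
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

#' Detect interictal spikes in an LFP trace
#'
#' The trace is resampled to 1,000 Hz if needed, band-pass filtered with a
#' zero-phase third-order Butterworth filter in `[low_hz, high_hz]`, and all
#' local maxima whose topographic prominence is at least `threshold_uV` are
#' returned as event times.
#'
#' @param trace an [lfp_trace] (polarity-oriented; see [orient_polarity]).
#' @param cfg a [detector_config].
#' @return sorted numeric vector of detection times (s).
#' @export
detect_spikes <- function(trace, cfg) {
  fs <- 1000
  x <- trace$samples
  if (trace$fs_hz != fs) {
    r <- ratio_approx(fs / trace$fs_hz)
    x <- signal::resample(x, r[1], r[2])
  }
  nyq <- fs / 2
  if (cfg$high_hz >= nyq)
    stop("passband infeasible: high_hz must be < ", nyq, " Hz after resampling")
  bf <- signal::butter(3, c(cfg$low_hz, cfg$high_hz) / nyq, type = "pass")
  xf <- signal::filtfilt(bf, x)
  idx <- peak_indices(xf, cfg$threshold_uV)
  sort((idx - 1) / fs)
}

ratio_approx <- function(r, max_den = 1000) {
  den <- seq_len(max_den)
  num <- round(r * den)
  err <- abs(num / den - r)
  i <- which.min(err)
  c(num[i], den[i])
}

# local maxima with topographic prominence >= thr (C++ helper)
peak_indices <- function(x, thr) {
  pk <- peak_prominences_cpp(as.numeric(x))
  pk$index[pk$prominence >= thr]
}

#' Score detections against labeled windows
#'
#' A window containing at least one detection contributes one true positive;
#' every additional detection inside a window and every detection outside all
#' windows is a false positive; windows with no detection are false
#' negatives. Precision, recall and the F-beta score follow, with beta = 1/2
#' weighting precision over recall.
#'
#' @param detections detection times (s).
#' @param windows data.frame with `t_start_s`, `t_end_s` (non-overlapping).
#' @param beta F-score weight (> 0); default 1/2.
#' @return a `detector_score` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_beta`, `beta`.
#' @export
score_detector <- function(detections, windows, beta = 0.5) {
  if (beta <= 0) stop("beta must be positive")
  nw <- nrow(windows)
  hits <- integer(nw)
  if (nw > 0) {
    o <- order(windows$t_start_s)
    ws <- windows$t_start_s[o]; we <- windows$t_end_s[o]
    if (any(we[-length(we)] > ws[-1])) stop("windows must be non-overlapping")
    for (d in detections) {
      i <- findInterval(d, ws)
      if (i >= 1 && d <= we[i]) hits[i] <- hits[i] + 1L
    }
  }
  inside <- sum(hits)
  tp <- sum(hits >= 1L)
  fp <- (inside - tp) + (length(detections) - inside)
  fn <- sum(hits == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_beta = f_beta(precision, recall, beta),
                 beta = beta),
            class = "detector_score")
}

#' F-beta score from precision and recall
#'
#' `F_beta = (1 + beta^2) * P * R / (beta^2 * P + R)`; beta = 1/2 favors
#' precision roughly twice as much as recall.
#'
#' @param precision,recall fractions in `[0, 1]`.
#' @param beta positive weight.
#' @return the F-beta score (0 when both inputs are 0).
#' @export
f_beta <- function(precision, recall, beta = 0.5) {
  den <- beta^2 * precision + recall
  ifelse(den > 0, (1 + beta^2) * precision * recall / den, 0)
}

#' Tune the detector by exhaustive grid search
#'
#' Evaluates every (threshold, low, high) combination and returns the
#' configuration maximizing the F-1/2 score; ties are broken toward the
#' higher threshold, then the narrower band.
#'
#' @param trace an [lfp_trace].
#' @param windows labeled windows (see [score_detector]).
#' @param grid list with numeric vectors `threshold_uV`, `low_hz`, `high_hz`.
#'   The default spans the tuned per-animal settings: thresholds 500-2,500 uV
#'   in steps of 100, low edge in {1, 2, 4, 8, 16} Hz, high edge in
#'   {200, 400} Hz.
#' @param beta F-score weight.
#' @return list with `config` (the winning [detector_config]) and `score`.
#' @export
tune_detector <- function(trace, windows, grid = default_tuning_grid(),
                          beta = 0.5) {
  stopifnot(length(grid$threshold_uV) > 0, length(grid$low_hz) > 0,
            length(grid$high_hz) > 0)
  best <- NULL
  for (hi in grid$high_hz) for (lo in grid$low_hz) {
    cfg0 <- detector_config(min(grid$threshold_uV), lo, hi)
    # one filter pass per band: thresholding reuses the same peak set
    fs <- 1000
    x <- trace$samples
    if (trace$fs_hz != fs) {
      r <- ratio_approx(fs / trace$fs_hz)
      x <- signal::resample(x, r[1], r[2])
    }
    bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
    xf <- signal::filtfilt(bf, x)
    pk <- peak_prominences_cpp(as.numeric(xf))
    for (thr in grid$threshold_uV) {
      det <- (pk$index[pk$prominence >= thr] - 1) / fs
      sc <- score_detector(det, windows, beta)
      if (is.null(best) || better_config(sc, thr, hi - lo, best)) {
        best <- list(config = detector_config(thr, lo, hi), score = sc,
                     thr = thr, bw = hi - lo)
      }
    }
  }
  list(config = best$config, score = best$score)
}

better_config <- function(sc, thr, bw, best) {
  if (sc$f_beta != best$score$f_beta) return(sc$f_beta > best$score$f_beta)
  if (thr != best$thr) return(thr > best$thr)
  bw < best$bw
}

#' @rdname tune_detector
#' @export
default_tuning_grid <- function() {
  list(threshold_uV = seq(500, 2500, by = 100),
       low_hz = c(1, 2, 4, 8, 16),
       high_hz = c(200, 400))
}
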