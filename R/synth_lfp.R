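#' LFP trace container
#'
#' @param samples numeric vector of voltages (uV).
#' @param fs_hz sampling rate (Hz).
#' @return an `lfp_trace` object.
#' @export
lfp_trace <- function(samples, fs_hz) {
  stopifnot(fs_hz > 0, is.numeric(samples))
  if (any(!is.finite(samples))) stop("LFP samples must be finite")
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  invisible(x)
}

# 1/f^a Gaussian noise by spectral shaping; sd normalized to `sd_uV`
pink_noise <- function(n, exponent, sd_uV) {
  if (sd_uV == 0 || n < 2) return(numeric(n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)              # two-sided frequency index
  shaped <- spec / f^(exponent / 2)
  shaped[1] <- 0
  x <- Re(fft(shaped, inverse = TRUE)) / n
  x * sd_uV / sd(x)
}

# biexponential transient, unit peak, sharp rise / slower decay
biexp_kernel <- function(fs_hz, rise_ms = 2, decay_ms = 15) {
  t <- seq(0, 8 * decay_ms / 1000, by = 1 / fs_hz)
  k <- exp(-t / (decay_ms / 1000)) - exp(-t / (rise_ms / 1000))
  k / max(k)
}

#' Synthesize an LFP trace with embedded interictal transients
#'
#' The trace is the sum of 1/f background noise, a theta-band sinusoid, and
#' one positive biexponential transient (2 ms rise, 15 ms decay, peak
#' `is_amp_uV`) per requested event time. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config].
#' @param event_times numeric vector of IS times (s), inside `[0, duration_s]`.
#' @return an [lfp_trace].
#' @export
make_lfp <- function(cfg, event_times = numeric()) {
  cfg <- validate_synth_config(cfg)
  if (length(event_times) &&
      (min(event_times) < 0 || max(event_times) > cfg$duration_s))
    stop("event_times must lie within [0, duration_s]")
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs_hz)
  t <- seq_len(n) / cfg$fs_hz
  x <- pink_noise(n, cfg$noise_exponent, cfg$noise_sd_uV)
  if (cfg$theta_amp_uV > 0)
    x <- x + cfg$theta_amp_uV * sin(2 * pi * cfg$theta_hz * t)
  if (length(event_times) && cfg$is_amp_uV != 0) {
    k <- cfg$is_amp_uV * biexp_kernel(cfg$fs_hz)
    for (et in event_times) {
      i0 <- round(et * cfg$fs_hz) + 1L
      idx <- i0:min(n, i0 + length(k) - 1L)
      x[idx] <- x[idx] + k[seq_along(idx)]
    }
  }
  lfp_trace(x, cfg$fs_hz)
}

#' Draw manual-labeling windows around event times
#'
#' One window per event. Widths are drawn from a log-normal matched to the
#' manual-labeling statistics (mean 100 ms, SD 92 ms) and truncated to
#' [14, 724] ms; the event sits at a uniformly drawn position inside the
#' window, displaced by up to `jitter_s`.
#'
#' @param event_times event times (s).
#' @param jitter_s nonnegative placement jitter (s).
#' @return data.frame with `t_start_s`, `t_end_s`, `contains_event`.
#' @export
make_labeled_windows <- function(event_times, jitter_s = 0) {
  stopifnot(jitter_s >= 0)
  n <- length(event_times)
  w <- draw_window_widths(n)
  # event placed inside the window: offset from start in (0, w)
  off <- if (jitter_s > 0) {
    pmin(pmax(w / 2 + runif(n, -jitter_s, jitter_s), 0.1 * w), 0.9 * w)
  } else w / 2
  data.frame(t_start_s = event_times - off,
             t_end_s = event_times - off + w,
             contains_event = TRUE)
}

# Truncated log-normal widths (seconds). meanlog/sdlog solved numerically so
# the *truncated* mean/SD match 100/92 ms on [14, 724] ms.
draw_window_widths <- function(n, lo = 0.014, hi = 0.724) {
  mu <- -2.68435; sg <- 0.87238   # see vignette: moment-matched under truncation
  u <- runif(n, plnorm(lo, mu, sg), plnorm(hi, mu, sg))
  qlnorm(u, mu, sg)
}
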