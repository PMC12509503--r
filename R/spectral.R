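#' Welch power spectral density
#'
#' Hann-windowed segment averaging with the replay-analysis defaults
#' (256 samples per segment, 32-sample overlap, 1,024 FFT points). The
#' density is one-sided and scaled so that its integral over frequency
#' approximates the signal variance (Parseval).
#'
#' @param x signal.
#' @param fs_hz sampling rate (Hz).
#' @param nperseg,noverlap,nfft Welch parameters.
#' @return data.frame with `freq_hz` and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs_hz, nperseg = 256, noverlap = 32, nfft = 1024) {
  x <- as.numeric(x)
  if (length(x) < nperseg) stop("signal shorter than one Welch segment")
  x <- x - mean(x)
  step <- nperseg - noverlap
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  U <- sum(w^2)
  acc <- numeric(nfft)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1)] * w
    X <- fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(X)^2
  }
  acc <- acc / (length(starts) * U * fs_hz)
  half <- seq_len(nfft %/% 2 + 1)
  psd <- acc[half]
  psd[2:(length(half) - 1)] <- 2 * psd[2:(length(half) - 1)]
  data.frame(freq_hz = (half - 1) * fs_hz / nfft, psd = psd)
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' Bandwidth 1.5, center frequency 1.0, evaluated at 200 logarithmically
#' spaced bands between 10^1.2 and 10^2.5 Hz by default (FFT convolution).
#'
#' @param x signal.
#' @param fs_hz sampling rate (Hz).
#' @param freqs_hz analysis frequencies (Hz).
#' @param bandwidth,center_freq Morlet parameters.
#' @return list: `freqs_hz`, `power` (frequencies x time magnitude-squared
#'   matrix).
#' @export
morlet_cwt <- function(x, fs_hz,
                       freqs_hz = 10^seq(1.2, 2.5, length.out = 200),
                       bandwidth = 1.5, center_freq = 1.0) {
  x <- as.numeric(x)
  n <- length(x)
  nf <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(nf - n)))
  P <- matrix(NA_real_, length(freqs_hz), n)
  for (i in seq_along(freqs_hz)) {
    scale <- center_freq * fs_hz / freqs_hz[i]
    th <- seq(-ceiling(4 * scale * sqrt(bandwidth)),
              ceiling(4 * scale * sqrt(bandwidth)))
    psi <- (pi * bandwidth)^(-0.5) *
      exp(2i * pi * center_freq * th / scale) * exp(-(th / scale)^2 / bandwidth)
    psi <- psi / sqrt(scale)
    h <- numeric(nf)
    kl <- length(th)
    psi_pad <- c(psi, complex(real = numeric(nf - kl)))
    conv <- fft(fft(psi_pad) * X, inverse = TRUE) / nf
    off <- (kl - 1) %/% 2
    P[i, ] <- Mod(conv[(off + 1):(off + n)])^2
  }
  list(freqs_hz = freqs_hz, power = P)
}

#' Spectral summary of a simulated LFP
#'
#' Welch PSD of the spontaneous LFP plus the CWT of the mean replay
#' waveform, and the peak frequency of the mean replay spectrum within the
#' ripple/fast band.
#'
#' @param lfp numeric LFP (V) at `fs_hz`.
#' @param fs_hz sampling rate (Hz).
#' @param replay_windows data.frame from [detect_replays] (optional).
#' @param band_hz ripple/fast-oscillation band searched for spectral peaks
#'   (Hz); the lower edge excludes the slow sharp-wave envelope.
#' @return list: `psd`, `peak_hz` (PSD peak in band), `cwt` (NULL without
#'   replays), `replay_peak_hz` (CWT peak of the mean replay in band).
#' @export
spectral_summary <- function(lfp, fs_hz, replay_windows = NULL,
                             band_hz = c(80, 400)) {
  if (length(lfp) < 5 * fs_hz) stop("need at least 5 s of LFP")
  psd <- welch_psd(lfp, fs_hz)
  inb <- psd$freq_hz >= band_hz[1] & psd$freq_hz <= band_hz[2]
  peak_hz <- psd$freq_hz[inb][which.max(psd$psd[inb])]
  cwt <- NULL; replay_peak_hz <- NA_real_
  if (!is.null(replay_windows) && nrow(replay_windows) > 0) {
    # only windows fully inside the trace contribute to the mean replay
    ok <- replay_windows$t_start_s >= 0 &
      replay_windows$t_end_s <= (length(lfp) - 1) / fs_hz
    replay_windows <- replay_windows[ok, , drop = FALSE]
  }
  if (!is.null(replay_windows) && nrow(replay_windows) > 0) {
    segs <- lapply(seq_len(nrow(replay_windows)), function(i) {
      i0 <- round(replay_windows$t_start_s[i] * fs_hz) + 1L
      i1 <- round(replay_windows$t_end_s[i] * fs_hz) + 1L
      lfp[i0:i1]
    })
    len <- min(lengths(segs))
    mean_replay <- rowMeans(vapply(segs, function(s) s[seq_len(len)],
                                   numeric(len)))
    cwt <- morlet_cwt(mean_replay, fs_hz)
    mp <- rowMeans(cwt$power)
    inb <- cwt$freqs_hz >= band_hz[1] & cwt$freqs_hz <= band_hz[2]
    replay_peak_hz <- cwt$freqs_hz[inb][which.max(mp[inb])]
  }
  list(psd = psd, peak_hz = peak_hz, cwt = cwt,
       replay_peak_hz = replay_peak_hz)
}
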