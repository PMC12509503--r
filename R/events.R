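#' Classify spikes into solitary IS and BIRDs
#'
#' Maximal runs of consecutive inter-spike intervals below 2 s containing at
#' least two spikes form one BIRD (brief rhythmic interictal discharge); the
#' first and last spikes of each BIRD are labeled `bird_first` / `bird_last`
#' and interior spikes `bird_within`. All remaining spikes are `solitary`.
#'
#' @param times_s sorted spike times (s).
#' @param isi_max_s ISI threshold separating solitary spikes from BIRDs (s).
#' @return `event_series` data.frame: `t_s`, `label`, `bird_id` (NA for
#'   solitary spikes).
#' @export
classify_events <- function(times_s, isi_max_s = 2) {
  n <- length(times_s)
  if (n && is.unsorted(times_s)) stop("times must be sorted")
  if (n == 0L)
    return(structure(data.frame(t_s = numeric(), label = character(),
                                bird_id = integer()), class = c("event_series", "data.frame")))
  grp <- cumsum(c(1, as.integer(diff(times_s) >= isi_max_s)))
  label <- rep("solitary", n)
  bird_id <- rep(NA_integer_, n)
  next_bird <- 1L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) >= 2L) {
      label[idx] <- "bird_within"
      label[idx[1]] <- "bird_first"
      label[idx[length(idx)]] <- "bird_last"
      bird_id[idx] <- next_bird
      next_bird <- next_bird + 1L
    }
  }
  structure(data.frame(t_s = times_s, label = label, bird_id = bird_id),
            class = c("event_series", "data.frame"))
}

#' Detect seizures as long dense spike trains
#'
#' Seizures are trains of spikes with inter-spike intervals below 2 s whose
#' span (first to last spike) is at least 10 s.
#'
#' @param times_s sorted spike times (s).
#' @param isi_max_s within-train ISI bound (s).
#' @param min_duration_s minimum train span to call a seizure (s).
#' @return data.frame with `t_start_s`, `t_end_s`, `duration_s`, `n_spikes`.
#' @export
detect_seizures <- function(times_s, isi_max_s = 2, min_duration_s = 10) {
  if (length(times_s) && is.unsorted(times_s)) stop("times must be sorted")
  out <- data.frame(t_start_s = numeric(), t_end_s = numeric(),
                    duration_s = numeric(), n_spikes = integer())
  if (length(times_s) < 2L) return(out)
  grp <- cumsum(c(1, as.integer(diff(times_s) >= isi_max_s)))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    dur <- times_s[idx[length(idx)]] - times_s[idx[1]]
    if (length(idx) >= 2L && dur >= min_duration_s)
      out <- rbind(out, data.frame(t_start_s = times_s[idx[1]],
                                   t_end_s = times_s[idx[length(idx)]],
                                   duration_s = dur, n_spikes = length(idx)))
  }
  out
}

#' Summary statistics of an event series
#'
#' @param events an `event_series` from [classify_events].
#' @param session_duration_s recording duration (s).
#' @return list: `rate_hz` (all spikes pooled), `solitary_rate_hz`,
#'   `bird_rate_hz` (BIRD onsets per second), `bird_duration_s` (per BIRD,
#'   last minus first spike), `spikes_per_bird`.
#' @export
event_statistics <- function(events, session_duration_s) {
  stopifnot(session_duration_s > 0)
  n <- nrow(events)
  birds <- unique(events$bird_id[!is.na(events$bird_id)])
  dur <- vapply(birds, function(b) {
    tt <- events$t_s[which(events$bird_id == b)]
    max(tt) - min(tt)
  }, numeric(1))
  nsp <- vapply(birds, function(b) sum(events$bird_id == b, na.rm = TRUE),
                numeric(1))
  list(rate_hz = n / session_duration_s,
       solitary_rate_hz = sum(events$label == "solitary") / session_duration_s,
       bird_rate_hz = length(birds) / session_duration_s,
       bird_duration_s = dur,
       spikes_per_bird = nsp)
}

#' Per-event RMS amplitude from the raw trace
#'
#' Root-mean-squared amplitude over +/-100 ms of the (unfiltered,
#' polarity-oriented) trace around each event time.
#'
#' @param trace an [lfp_trace].
#' @param times_s event times (s).
#' @param half_window_s half-window (s).
#' @return numeric vector of RMS amplitudes (uV); NA where the window falls
#'   off the trace edge.
#' @export
event_rms <- function(trace, times_s, half_window_s = 0.1) {
  fs <- trace$fs_hz; n <- length(trace$samples)
  hw <- round(half_window_s * fs)
  vapply(times_s, function(tt) {
    i0 <- round(tt * fs) + 1L
    if (i0 - hw < 1L || i0 + hw > n) return(NA_real_)
    seg <- trace$samples[(i0 - hw):(i0 + hw)]
    sqrt(mean(seg^2))
  }, numeric(1))
}
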