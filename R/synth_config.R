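#' Configuration for the synthetic-data generator
#'
#' Bundles every knob the generator needs: LFP composition (1/f noise, theta,
#' transient amplitude), the non-homogeneous Poisson IS process (baseline rate
#' and zone gains), the figure-8 session layout, and the ground-truth hidden
#' Markov model that drives choice outcomes. The defaults emulate the study
#' conditions: 1 kHz LFP, 7 Hz theta, a ~0.5 Hz baseline IS rate modulated by
#' zone gains elevated at reward and outer arms, 30 s inter-trial delays, and
#' a sticky 3-state engagement HMM with success rates 0.19/0.53/0.75.
#'
#' @param seed integer seed; every generator call is bit-reproducible given it.
#' @param fs_hz LFP sampling rate (Hz).
#' @param duration_s LFP duration (s).
#' @param theta_hz theta oscillation frequency (Hz).
#' @param theta_amp_uV theta amplitude (uV).
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param noise_sd_uV standard deviation of the background noise (uV).
#' @param is_amp_uV peak amplitude of the embedded IS transients (uV).
#' @param zone_gains named positive numeric: multiplicative IS-rate gain per
#'   maze zone (`delay`, `choice`, `outer`, `reward`).
#' @param base_rate_hz baseline IS rate (Hz) during behavior.
#' @param hmm_truth ground-truth [hmm_params] for choice generation.
#' @param n_sessions,trials_per_session session layout.
#' @param run_speed_cms running speed used for trajectories (cm/s).
#' @param pos_fs_hz position-tracking sampling rate (Hz).
#' @param delay_s imposed delay between trials (s).
#' @param pos_jitter_cm optional Gaussian jitter added to positions (cm).
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         fs_hz = 1000,
                         duration_s = 600,
                         theta_hz = 7,
                         theta_amp_uV = 150,
                         noise_exponent = 1,
                         noise_sd_uV = 120,
                         is_amp_uV = 1500,
                         zone_gains = c(delay = 1, choice = 1, outer = 1.3, reward = 1.9),
                         base_rate_hz = 0.5,
                         hmm_truth = hmm_params_truth(),
                         n_sessions = 5L,
                         trials_per_session = 20L,
                         run_speed_cms = 20,
                         pos_fs_hz = 30,
                         delay_s = 30,
                         pos_jitter_cm = 0) {
  cfg <- list(seed = as.integer(seed), fs_hz = fs_hz, duration_s = duration_s,
              theta_hz = theta_hz, theta_amp_uV = theta_amp_uV,
              noise_exponent = noise_exponent, noise_sd_uV = noise_sd_uV,
              is_amp_uV = is_amp_uV, zone_gains = zone_gains,
              base_rate_hz = base_rate_hz, hmm_truth = hmm_truth,
              n_sessions = as.integer(n_sessions),
              trials_per_session = as.integer(trials_per_session),
              run_speed_cms = run_speed_cms, pos_fs_hz = pos_fs_hz,
              delay_s = delay_s, pos_jitter_cm = pos_jitter_cm)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$fs_hz > 0, cfg$duration_s > 0, cfg$base_rate_hz >= 0,
            cfg$trials_per_session >= 1L, cfg$n_sessions >= 1L,
            cfg$pos_fs_hz > 0, cfg$run_speed_cms > 0)
  if (any(cfg$zone_gains <= 0)) stop("all zone_gains must be positive")
  zn <- c("delay", "choice", "outer", "reward")
  if (!all(zn %in% names(cfg$zone_gains)))
    stop("zone_gains must be named with: ", paste(zn, collapse = ", "))
  A <- cfg$hmm_truth$A
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("hmm_truth transition rows must sum to 1")
  cfg
}

#' Ground-truth engagement HMM used by the generator
#'
#' A sticky 3-state chain (diagonal 0.92, off-diagonal 0.04) with the
#' perseveration/guess/engaged success rates 0.19, 0.53 and 0.75.
#'
#' @param diag_p self-transition probability.
#' @param p_s per-state Bernoulli success probabilities.
#' @return an [hmm_params] object.
#' @export
hmm_params_truth <- function(diag_p = 0.92, p_s = c(0.19, 0.53, 0.75)) {
  N <- length(p_s)
  off <- (1 - diag_p) / (N - 1)
  A <- matrix(off, N, N); diag(A) <- diag_p
  hmm_params(A = A, alpha0 = rep(1 / N, N), p_s = p_s)
}
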