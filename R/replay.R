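#' Adaptive exponential integrate-and-fire parameter table
#'
#' One row per neuron class (pyramidal, interneuron): membrane capacitance
#' (pF), leak conductance (nS), leak reversal (mV), spike threshold (mV),
#' threshold sharpness (mV), spike-detection voltage (mV), reset voltage
#' (mV), refractory period (ms), adaptation time constant (ms), subthreshold
#' adaptation (nS) and spike-triggered adaptation increment (pA).
#'
#' @return 2 x 11 numeric matrix, rows `pyr`, `int`.
#' @export
aelif_param_table <- function() {
  m <- rbind(
    pyr = c(180, 4.3, -75, -24,   4.23, -3.25,  -29.7, 5.9, 83.4,  -0.27, 206.84),
    int = c(118, 7.5, -74, -57.7, 4.6,  -34.78, -65,   1,   178.58, 3.05, 0.91))
  colnames(m) <- c("Cm_pF", "gL_nS", "EL_mV", "theta_mV", "DeltaT_mV",
                   "Vpeak_mV", "Vreset_mV", "tref_ms", "tauw_ms", "a_nS",
                   "b_pA")
  m
}

#' Offline-state synaptic parameter table
#'
#' Bi-exponential conductance synapses: weight (nS, `NA` for the
#' STDP-learned projections), delay (ms), rise/decay times (ms) and
#' connection probability per ordered pair.
#'
#' @return data.frame, one row per projection.
#' @export
synapse_table <- function() {
  data.frame(
    pre  = c("ca3_pyr", "ca3_pyr", "ca3_pyr", "ca1_pyr", "ca3_int",
             "ca1_int", "ca3_int", "ca1_int", "dg"),
    post = c("ca3_pyr", "ca1_pyr", "ca3_int", "ca1_int", "ca3_pyr",
             "ca1_pyr", "ca3_int", "ca1_int", "ca3_pyr"),
    weight_nS = c(NA, NA, 0.85, 0.85, 0.65, 0.65, 5, 5, NA),
    delay_ms = 1,
    rise_ms  = c(1, 1, 1, 1, 0.3, 0.3, 0.3, 0.3, 0.65),
    decay_ms = c(9, 9, 9, 9, 3, 3, 3, 3, 5.4),
    prob = c(0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.25, 0.25, 0.25))
}

#' STDP presets for the two plastic projections
#'
#' Normalized weights (w in `[0,1]`, conductance `w * w_max`). CA3->CA3 is
#' symmetrically facilitating (`alpha = -1`, equal time constants); CA3->CA1
#' is asymmetric. `mu_plus = mu_minus = 0` (weight-independent updates).
#'
#' The step sizes are printed in conductance units (0.08 nS and 0.8 nS per
#' pairing) and divided by `w_max` here to act on normalized weights.
#'
#' @return named list of preset lists.
#' @export
stdp_presets <- function() {
  list(
    ca3_ca3 = list(lambda = 0.08 / 40, alpha = -1, tau_plus_ms = 62.5,
                   tau_minus_ms = 62.5, w_max_nS = 40),
    ca3_ca1 = list(lambda = 0.8 / 40, alpha = 0.4, tau_plus_ms = 20,
                   tau_minus_ms = 40, w_max_nS = 40))
}

#' Place-field map for one pyramidal population
#'
#' A fraction of pyramidal cells are place cells with field centers drawn
#' uniformly over the two-arm track `[-track_cm, track_cm]`; the rest fire
#' at a low spatially untuned baseline.
#'
#' @param n_pyr population size.
#' @param frac_place place-cell fraction.
#' @param track_cm arm length (cm); the track spans `[-track_cm, track_cm]`.
#' @param lambda_max_hz peak in-field rate (Hz).
#' @param sigma_cm place-field width (cm).
#' @param f_theta_hz theta frequency for phase precession (Hz).
#' @param baseline_hz non-place-cell rate (Hz).
#' @return `place_field_map` list: `centers` (NA for non-place cells) plus
#'   the tuning parameters.
#' @export
place_field_map <- function(n_pyr, frac_place = 0.3, track_cm = 150,
                            lambda_max_hz = 20, sigma_cm = 7,
                            f_theta_hz = 7, baseline_hz = 0.1) {
  n_place <- round(frac_place * n_pyr)
  centers <- rep(NA_real_, n_pyr)
  idx <- sample.int(n_pyr, n_place)
  centers[idx] <- runif(n_place, -track_cm, track_cm)
  structure(list(centers = centers, track_cm = track_cm,
                 lambda_max_hz = lambda_max_hz, sigma_cm = sigma_cm,
                 f_theta_hz = f_theta_hz, baseline_hz = baseline_hz,
                 n_pyr = n_pyr),
            class = "place_field_map")
}

#' Interictal stimulation configuration for training
#'
#' `clustered`: one IS per arm traversal at the fixed reference points
#' (+/-100 cm), delivered to active place cells. `dispersed`: the IS
#' location is redrawn uniformly over the arm on every trial. `broadcast`:
#' the location is fixed but delivery goes to all CA3 pyramidal cells.
#' `off`: no interictal input.
#'
#' @param mode one of `"off"`, `"clustered"`, `"dispersed"`, `"broadcast"`.
#' @param x_is_cm reference location (cm, per arm) for the clustered mode.
#' @param lambda_max_hz IS burst peak rate (Hz).
#' @param sigma_cm spatial width of the IS locus (cm).
#' @param p_deliver per-neuron delivery probability of each IS spike.
#' @return an `is_stim_config` list.
#' @export
is_stim_config <- function(mode = c("off", "clustered", "dispersed",
                                    "broadcast"),
                           x_is_cm = 100, lambda_max_hz = 2000,
                           sigma_cm = 4, p_deliver = 0.01) {
  structure(list(mode = match.arg(mode), x_is_cm = x_is_cm,
                 lambda_max_hz = lambda_max_hz, sigma_cm = sigma_cm,
                 p_deliver = p_deliver),
            class = "is_stim_config")
}

#' Simulate clamped place-cell spiking during maze exploration
#'
#' The virtual animal runs two 150 cm arms from the midpoint at constant
#' speed, teleporting back after each traversal and alternating arms with
#' 90% probability. Pyramidal cells in CA3 and CA1 fire as inhomogeneous
#' Poisson processes combining place tuning and theta phase precession;
#' interictal bursts (2,000 Hz peak, sigma 4 cm) are drawn as a single
#' train and delivered to CA3 cells per the stimulation mode.
#'
#' @param pfm_ca3,pfm_ca1 [place_field_map]s for the two regions.
#' @param is_cfg an [is_stim_config].
#' @param duration_s exploration duration (s).
#' @param speed_cms running speed (cm/s).
#' @param alternation_p probability of switching arms between trials.
#' @param seed integer seed.
#' @param dt_s thinning resolution (s).
#' @return list with `spikes_ca3`/`spikes_ca1` (data.frames `t_s`, `id`;
#'   CA3 includes delivered IS spikes), `x` (position per step), `dt_s`,
#'   `is_times_s`, `is_deliveries`.
#' @export
simulate_exploration <- function(pfm_ca3, pfm_ca1, is_cfg = is_stim_config(),
                                 duration_s = 600, speed_cms = 35,
                                 alternation_p = 0.9, seed = 1L,
                                 dt_s = 0.001) {
  set.seed(seed)
  L <- pfm_ca3$track_cm
  trial_dur <- L / speed_cms
  n_trials <- ceiling(duration_s / trial_dur)
  dirs <- numeric(n_trials)
  dirs[1] <- sample(c(-1, 1), 1)
  if (n_trials > 1) for (i in 2:n_trials)
    dirs[i] <- if (runif(1) < alternation_p) -dirs[i - 1] else dirs[i - 1]
  steps_per_trial <- round(trial_dur / dt_s)
  x <- unlist(lapply(dirs, function(d)
    d * speed_cms * (seq_len(steps_per_trial) - 0.5) * dt_s))
  x <- x[seq_len(min(length(x), round(duration_s / dt_s)))]

  spikes_for <- function(pfm) {
    pl <- which(!is.na(pfm$centers))
    sp <- place_spikes_cpp(x, dt_s, pfm$centers[pl], pfm$lambda_max_hz,
                           pfm$sigma_cm, pfm$f_theta_hz)
    df <- data.frame(t_s = sp$t_s, id = pl[sp$id])
    npl <- which(is.na(pfm$centers))
    nb <- rpois(length(npl), pfm$baseline_hz * length(x) * dt_s)
    if (sum(nb) > 0)
      df <- rbind(df, data.frame(t_s = runif(sum(nb), 0, length(x) * dt_s),
                                 id = rep(npl, nb)))
    df[order(df$t_s), ]
  }
  sp3 <- spikes_for(pfm_ca3)
  sp1 <- spikes_for(pfm_ca1)

  is_times <- numeric(0); is_del <- data.frame(t_s = numeric(), id = integer())
  if (is_cfg$mode != "off") {
    x_is <- switch(is_cfg$mode,
      clustered = , broadcast = rep(is_cfg$x_is_cm, n_trials),
      dispersed = runif(n_trials, 0, L))
    # per-trial IS locus on the traversed arm
    locus <- dirs * x_is
    step_trial <- pmin(floor((seq_along(x) - 1) / steps_per_trial) + 1,
                       n_trials)
    lam <- is_cfg$lambda_max_hz *
      exp(-(x - locus[step_trial])^2 / (2 * is_cfg$sigma_cm^2))
    k <- rpois(length(lam), lam * dt_s)
    is_times <- sort((which(k > 0) - 0.5) * dt_s)
    if (length(is_times)) {
      active_set <- function(tt) {
        xt <- x[pmin(length(x), floor(tt / dt_s) + 1)]
        if (is_cfg$mode == "broadcast") return(seq_len(pfm_ca3$n_pyr))
        # active place cells: at >= 10% of max rate (spatial envelope)
        which(!is.na(pfm_ca3$centers) &
                abs(pfm_ca3$centers - xt) <=
                  pfm_ca3$sigma_cm * sqrt(2 * log(10)))
      }
      del <- lapply(is_times, function(tt) {
        cand <- active_set(tt)
        got <- cand[runif(length(cand)) < is_cfg$p_deliver]
        if (length(got)) data.frame(t_s = tt, id = got) else NULL
      })
      is_del <- do.call(rbind, del)
      if (is.null(is_del))
        is_del <- data.frame(t_s = numeric(), id = integer())
    }
    if (nrow(is_del)) {
      sp3 <- rbind(sp3, is_del)
      sp3 <- sp3[order(sp3$t_s), ]
    }
  }
  list(spikes_ca3 = sp3, spikes_ca1 = sp1, x = x, dt_s = dt_s,
       is_times_s = is_times, is_deliveries = is_del,
       pfm_ca3 = pfm_ca3, pfm_ca1 = pfm_ca1)
}

#' Train the plastic projections with STDP
#'
#' Builds random 10% connectivity for CA3->CA3 and CA3->CA1, initializes
#' normalized weights as `0.3 * LogNormal(0,1)` (CA3) and `0.7 *
#' LogNormal(0,1)` (CA1) clipped into `[0,1]`, and applies all-pairs
#' trace-based STDP over the exploration spike trains (weights clipped to
#' `[0,1]` after every update).
#'
#' @param explo output of [simulate_exploration].
#' @param n_ca3,n_ca1 pyramidal population sizes.
#' @param seed integer seed (connectivity + initial weights).
#' @param presets STDP presets (see [stdp_presets]).
#' @param conn_p connection probability for both plastic projections.
#' @return list with `ca3_edges` and `ca1_edges` data.frames (`src`, `dst`,
#'   `w` normalized).
#' @export
train_stdp <- function(explo, n_ca3, n_ca1, seed = 1L,
                       presets = stdp_presets(), conn_p = 0.1) {
  set.seed(seed + 7L)
  mk_edges <- function(n_pre, n_post, exclude_self) {
    m <- matrix(runif(n_pre * n_post) < conn_p, n_pre, n_post)
    if (exclude_self) diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    data.frame(src = idx[, 1], dst = idx[, 2])
  }
  e33 <- mk_edges(n_ca3, n_ca3, TRUE)
  e31 <- mk_edges(n_ca3, n_ca1, FALSE)
  # initial weights are drawn in nS (0.3 resp. 0.7 median) and normalized by
  # w_max, clipped into [0,1]
  e33$w <- pmin(1, pmax(0, 0.3 * rlnorm(nrow(e33)) / presets$ca3_ca3$w_max_nS))
  e31$w <- pmin(1, pmax(0, 0.7 * rlnorm(nrow(e31)) / presets$ca3_ca1$w_max_nS))

  s3 <- explo$spikes_ca3
  p <- presets$ca3_ca3
  e33$w <- stdp_train_cpp(s3$t_s, as.integer(s3$id - 1L),
                          rep(1L, nrow(s3)), rep(1L, nrow(s3)),
                          n_ca3, n_ca3,
                          as.integer(e33$src - 1L), as.integer(e33$dst - 1L),
                          e33$w, p$lambda, p$alpha, p$tau_plus_ms,
                          p$tau_minus_ms)
  s1 <- explo$spikes_ca1
  merged <- rbind(data.frame(t_s = s3$t_s, id = s3$id, pre = 1L, post = 0L),
                  data.frame(t_s = s1$t_s, id = s1$id, pre = 0L, post = 1L))
  merged <- merged[order(merged$t_s), ]
  p <- presets$ca3_ca1
  e31$w <- stdp_train_cpp(merged$t_s, as.integer(merged$id - 1L),
                          merged$pre, merged$post, n_ca3, n_ca1,
                          as.integer(e31$src - 1L), as.integer(e31$dst - 1L),
                          e31$w, p$lambda, p$alpha, p$tau_plus_ms,
                          p$tau_minus_ms)
  list(ca3_edges = e33, ca1_edges = e31)
}

#' Assemble the offline CA3-CA1 network
#'
#' Builds the full AELIF network (pyramidal cells and interneurons in both
#' regions) with the offline-state synapse table, the STDP-learned weights
#' for the plastic projections, and dentate background targets. When the
#' populations are scaled down from the reference sizes (1,250 pyramidal +
#' 100 interneurons per region), connection probabilities are multiplied by
#' the presynaptic-count ratio (capped at 1, any remainder applied to the
#' weights) so each neuron's in-degree and per-synapse conductance -- not
#' just the mean input -- are preserved.
#'
#' @param weights output of [train_stdp].
#' @param n_ca3,n_ca1 pyramidal sizes (must match training).
#' @param n_int interneurons per region.
#' @param seed connectivity seed for the static projections.
#' @param ref_pyr,ref_int reference population sizes.
#' @return a `replay_network` list consumed by [simulate_offline].
#' @export
build_offline_network <- function(weights, n_ca3, n_ca1, n_int = 100,
                                  seed = 1L, ref_pyr = 1250, ref_int = 100) {
  set.seed(seed + 13L)
  syn <- synapse_table()
  pops <- list(ca3_pyr = n_ca3, ca3_int = n_int, ca1_pyr = n_ca1,
               ca1_int = n_int)
  offset <- cumsum(c(0, unlist(pops)))[1:4]
  names(offset) <- names(pops)
  n_tot <- sum(unlist(pops))
  type <- integer(n_tot)
  type[offset["ca3_int"] + seq_len(n_int)] <- 1L
  type[offset["ca1_int"] + seq_len(n_int)] <- 1L
  ratio_for <- function(pre) {
    ref <- if (grepl("int", pre)) ref_int else ref_pyr
    ref / pops[[pre]]
  }
  # channels: AMPA (pyr->*), GABA (int->*), DG kinetics
  channels <- rbind(c(1, 9, 0), c(0.3, 3, -90), c(0.65, 5.4, 0))
  w_max <- stdp_presets()$ca3_ca3$w_max_nS
  edges <- list()
  add_edges <- function(src, dst, w, ch, delay_ms = 1) {
    edges[[length(edges) + 1L]] <<- data.frame(
      src = src, dst = dst, w = w, ch = ch, delay = delay_ms)
  }
  # plastic projections: connectivity density was already scaled at training
  add_edges(offset["ca3_pyr"] + weights$ca3_edges$src,
            offset["ca3_pyr"] + weights$ca3_edges$dst,
            weights$ca3_edges$w * w_max, 0L)
  add_edges(offset["ca3_pyr"] + weights$ca1_edges$src,
            offset["ca1_pyr"] + weights$ca1_edges$dst,
            weights$ca1_edges$w * w_max, 0L)
  for (r in seq_len(nrow(syn))) {
    if (syn$pre[r] %in% c("dg") || is.na(syn$weight_nS[r])) next
    np <- pops[[syn$pre[r]]]; nq <- pops[[syn$post[r]]]
    eff_p <- min(1, syn$prob[r] * ratio_for(syn$pre[r]))
    w_scale <- syn$prob[r] * ratio_for(syn$pre[r]) / eff_p
    m <- which(matrix(runif(np * nq) < eff_p, np, nq), arr.ind = TRUE)
    ch <- if (grepl("int", syn$pre[r])) 1L else 0L
    add_edges(offset[syn$pre[r]] + m[, 1], offset[syn$post[r]] + m[, 2],
              rep(syn$weight_nS[r] * w_scale, nrow(m)), ch,
              syn$delay_ms[r])
  }
  ed <- do.call(rbind, edges)
  dg_targets <- which(runif(n_ca3) < syn$prob[syn$pre == "dg"]) +
    offset["ca3_pyr"]
  structure(list(n_neurons = n_tot, type = type,
                 params = aelif_param_table(), channels = channels,
                 edges = ed, pops = pops, offset = offset,
                 dg_targets = dg_targets,
                 dg_channel = 2L, n_ca3 = n_ca3, n_ca1 = n_ca1),
            class = "replay_network")
}

#' Simulate the offline network state
#'
#' Spontaneous mode: every dentate-connected CA3 pyramidal cell receives an
#' independent pooled Poisson background train at 15 nS per spike; the
#' default per-cell rate (60 Hz) is calibrated so the spontaneous CA3
#' pyramidal rate sits near 1-2 Hz and population bursts nucleate at
#' sharp-wave-like rates. Cued mode: the background weight drops to 10 nS
#' and CA3 place cells within a 20 cm window around the cue center receive
#' a 20 ms burst of 30 Hz Poisson spikes at 80 nS.
#'
#' @param net a `replay_network`.
#' @param duration_s simulated time (s).
#' @param pfm_ca3 the CA3 [place_field_map] (needed for cueing).
#' @param cue optional list: `center_cm`, `halfwidth_cm` (default 10),
#'   `t_s` (burst onset), `rate_hz` (30), `dur_s` (0.02), `weight_nS` (80).
#' @param dg_rate_hz dentate background rate (Hz).
#' @param seed integer seed (background train, initial voltages).
#' @param dt_ms Euler step (ms).
#' @return list: `spikes` (data.frame `t_s`, `id`), `lfp` (V, 1 kHz),
#'   `fs_hz`, `cued_ids`.
#' @export
simulate_offline <- function(net, duration_s, pfm_ca3 = NULL, cue = NULL,
                             dg_rate_hz = 60, seed = 1L, dt_ms = 0.1) {
  set.seed(seed + 101L)
  dg_w <- if (is.null(cue)) 15 else 10
  # each connected cell receives its own pooled dentate train
  n_dg <- rpois(length(net$dg_targets), dg_rate_hz * duration_s)
  ext <- data.frame(
    step = round(runif(sum(n_dg), 0, duration_s) * 1000 / dt_ms),
    target = rep(net$dg_targets, n_dg),
    w = rep(dg_w, sum(n_dg)), ch = rep(net$dg_channel, sum(n_dg)))
  cued_ids <- integer(0)
  if (!is.null(cue)) {
    stopifnot(!is.null(pfm_ca3))
    hw <- if (is.null(cue$halfwidth_cm)) 10 else cue$halfwidth_cm
    rate <- if (is.null(cue$rate_hz)) 30 else cue$rate_hz
    dur <- if (is.null(cue$dur_s)) 0.02 else cue$dur_s
    wgt <- if (is.null(cue$weight_nS)) 80 else cue$weight_nS
    cued_ids <- which(!is.na(pfm_ca3$centers) &
                        abs(pfm_ca3$centers - cue$center_cm) <= hw)
    if (!length(cued_ids)) stop("no place cells within the cue window")
    for (cid in cued_ids) {
      nk <- rpois(1, rate * dur)
      if (nk > 0) {
        tt <- cue$t_s + runif(nk, 0, dur)
        ext <- rbind(ext, data.frame(step = round(tt * 1000 / dt_ms),
                                     target = cid + net$offset[["ca3_pyr"]],
                                     w = wgt, ch = net$dg_channel))
      }
    }
  }
  ext <- ext[order(ext$step), ]
  v0 <- net$params[net$type + 1L, "EL_mV"] + runif(net$n_neurons, -3, 3)
  lfp_pool <- net$offset["ca1_pyr"] + seq_len(net$pops$ca1_pyr)
  lfp_ids <- sample(lfp_pool, min(200, length(lfp_pool)))
  gain <- 1 / (4 * pi * 0.3 * 5e-6)
  out <- aelif_net_cpp(
    net$n_neurons, net$type, net$params, net$channels,
    as.integer(net$edges$src - 1L), as.integer(net$edges$dst - 1L),
    net$edges$w, as.integer(net$edges$ch),
    as.integer(pmax(1, round(net$edges$delay / dt_ms))),
    as.integer(ext$step), as.integer(ext$target - 1L),
    ext$w, as.integer(ext$ch),
    duration_s * 1000, dt_ms, as.integer(lfp_ids - 1L),
    as.integer(round(1 / dt_ms)), gain, v0)
  list(spikes = data.frame(t_s = out$spike_t_ms / 1000, id = out$spike_id),
       lfp = out$lfp, fs_hz = 1000, cued_ids = cued_ids)
}

#' Detect replay events in the proxy LFP
#'
#' The LFP is low-pass filtered at 200 Hz with a seventh-order Butterworth
#' filter; peaks with prominence of at least 1 mV separated by at least 200
#' samples become replay events with +/-150 ms windows.
#'
#' @param lfp proxy LFP (V) at `fs_hz`.
#' @param fs_hz sampling rate (1,000 Hz expected).
#' @param prominence_V peak prominence threshold (V).
#' @param min_distance minimum peak separation (samples).
#' @return data.frame: `t_peak_s`, `t_start_s`, `t_end_s`.
#' @export
detect_replays <- function(lfp, fs_hz = 1000, prominence_V = 1e-3,
                           min_distance = 200) {
  x <- abs_orient(as.numeric(lfp))
  bf <- signal::butter(7, 200 / (fs_hz / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  pk <- peak_prominences_cpp(xf)
  keep <- pk$prominence >= prominence_V
  idx <- pk$index[keep]; prm <- pk$prominence[keep]
  if (!length(idx))
    return(data.frame(t_peak_s = numeric(), t_start_s = numeric(),
                      t_end_s = numeric()))
  # enforce the minimum peak distance, keeping the more prominent peak
  o <- order(prm, decreasing = TRUE)
  kept <- integer(0)
  for (i in o) if (!length(kept) || all(abs(idx[i] - idx[kept]) >= min_distance))
    kept <- c(kept, i)
  idx <- sort(idx[kept])
  t_pk <- (idx - 1) / fs_hz
  data.frame(t_peak_s = t_pk, t_start_s = t_pk - 0.15, t_end_s = t_pk + 0.15)
}

# synaptic-current LFP deflections are sign-ambiguous; orient the dominant
# deflection positive so prominence thresholds apply uniformly
abs_orient <- function(x) {
  if (abs(min(x) - median(x)) > abs(max(x) - median(x))) -x else x
}

#' Decode replayed position by the population-vector method
#'
#' Spikes inside the window are binned at 25 ms; in each bin the decoded
#' position is the place-field center receiving the largest spike-weighted
#' vote; ties go to the center with smaller `|x|`; empty bins are `NA`.
#'
#' @param spikes data.frame (`t_s`, `id`) of pyramidal spikes.
#' @param pfm the region's [place_field_map].
#' @param t_start_s,t_end_s replay window (s).
#' @param bin_s bin width (s).
#' @return data.frame: `t_bin_s` (bin centers), `x_hat_cm`, `n_spikes`.
#' @export
decode_position <- function(spikes, pfm, t_start_s, t_end_s, bin_s = 0.025) {
  edges <- seq(t_start_s, t_end_s, by = bin_s)
  if (length(edges) < 2)
    return(data.frame(t_bin_s = numeric(), x_hat_cm = numeric(),
                      n_spikes = integer()))
  sel <- spikes$t_s >= t_start_s & spikes$t_s < edges[length(edges)] &
    !is.na(pfm$centers[spikes$id])
  sp <- spikes[sel, ]
  out <- data.frame(t_bin_s = edges[-length(edges)] + bin_s / 2,
                    x_hat_cm = NA_real_, n_spikes = 0L)
  if (!nrow(sp)) return(out)
  bins <- findInterval(sp$t_s, edges)
  for (b in unique(bins)) {
    ids <- sp$id[bins == b]
    votes <- table(pfm$centers[ids])
    cand <- as.numeric(names(votes)[votes == max(votes)])
    out$x_hat_cm[b] <- cand[which.min(abs(cand))]
    out$n_spikes[b] <- length(ids)
  }
  out
}

#' Replay contamination of the un-cued arm
#'
#' Number of place-cell spikes inside the replay window whose field centers
#' lie on the arm opposite the cued one.
#'
#' @param spikes data.frame (`t_s`, `id`).
#' @param pfm the [place_field_map].
#' @param cued_sign +1 (right/east arm) or -1.
#' @param t_start_s,t_end_s window (s).
#' @return integer spike count.
#' @export
contamination <- function(spikes, pfm, cued_sign, t_start_s, t_end_s) {
  sel <- spikes$t_s >= t_start_s & spikes$t_s <= t_end_s
  ctr <- pfm$centers[spikes$id[sel]]
  sum(!is.na(ctr) & sign(ctr) == -sign(cued_sign) & ctr != 0)
}

#' Train one network replica end to end
#'
#' Convenience wrapper: place-field maps, clamped exploration with the
#' requested interictal mode, STDP training, offline network assembly.
#'
#' @param condition `"control"` (no IS), `"clustered"` (high spatial
#'   information IS) or `"dispersed"` (low spatial information IS).
#' @param n_pyr,n_int population sizes per region.
#' @param train_s exploration duration (s).
#' @param seed integer seed.
#' @param ref_pyr,ref_int reference sizes used for density scaling.
#' @return list: `net`, `weights`, `pfm_ca3`, `pfm_ca1`, `explo`.
#' @export
train_replica <- function(condition = c("control", "clustered", "dispersed"),
                          n_pyr = 1250, n_int = 100, train_s = 600,
                          seed = 1L, ref_pyr = 1250, ref_int = 100) {
  condition <- match.arg(condition)
  set.seed(seed)
  pfm3 <- place_field_map(n_pyr)
  pfm1 <- place_field_map(n_pyr)
  is_cfg <- switch(condition,
                   control = is_stim_config("off"),
                   clustered = is_stim_config("clustered"),
                   dispersed = is_stim_config("dispersed"))
  explo <- simulate_exploration(pfm3, pfm1, is_cfg, duration_s = train_s,
                                seed = seed)
  weights <- train_stdp(explo, n_pyr, n_pyr, seed = seed,
                        conn_p = min(1, 0.1 * ref_pyr / n_pyr))
  net <- build_offline_network(weights, n_pyr, n_pyr, n_int, seed = seed,
                               ref_pyr = ref_pyr, ref_int = ref_int)
  list(net = net, weights = weights, pfm_ca3 = pfm3, pfm_ca1 = pfm1,
       explo = explo, condition = condition)
}

#' Cued-replay contamination sweep
#'
#' Cues place cells at decreasing distances from the interictal reference
#' point (+100 cm) on one arm and counts replay spikes from place cells of
#' the opposite arm within the post-cue window.
#'
#' @param replica a trained replica from [train_replica].
#' @param distances_cm cue distances from the reference point, toward the
#'   maze center.
#' @param reference_cm the interictal reference location (cm).
#' @param cue_t_s cue onset within each short simulation (s).
#' @param window_s length of the post-cue window scored for contamination (s).
#' @param sim_s duration of each cued simulation (s).
#' @param seed integer seed.
#' @return data.frame: `distance_cm`, `cue_center_cm`, `contamination`
#'   (spike count from un-cued-arm place cells).
#' @export
cue_contamination_sweep <- function(replica, distances_cm = seq(0, 80, 20),
                                    reference_cm = 100, cue_t_s = 0.25,
                                    window_s = 0.3, sim_s = 1, seed = 1L) {
  out <- lapply(distances_cm, function(d) {
    ctr <- reference_cm - d
    off <- simulate_offline(replica$net, duration_s = sim_s,
                            pfm_ca3 = replica$pfm_ca3,
                            cue = list(center_cm = ctr, t_s = cue_t_s),
                            seed = seed + round(d))
    cont <- contamination(off$spikes, replica$pfm_ca3, cued_sign = 1,
                          t_start_s = cue_t_s, t_end_s = cue_t_s + window_s)
    data.frame(distance_cm = d, cue_center_cm = ctr, contamination = cont)
  })
  do.call(rbind, out)
}
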