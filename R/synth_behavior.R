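#' Generate a synthetic behavioral dataset
#'
#' Produces everything the analysis pipeline consumes for one animal:
#' a figure-8 trajectory that visits delay -> stem/choice -> outer arm ->
#' reward on every trial, a trial table whose choice outcomes are drawn from
#' the ground-truth engagement HMM (correct = alternation achieved), IS event
#' times drawn from a non-homogeneous Poisson process whose instantaneous
#' rate is `base_rate_hz * zone_gain(current zone)` (gain 1 off-zone), and
#' the ground-truth zone label of every trajectory sample.
#'
#' Delay-zone exit latencies (time to leave the delay zone after the 30 s
#' interval elapses) are drawn state-dependently: slower when perseverating
#' (~12 s) than when guessing (~7.9 s) or engaged (~7.6 s), mirroring the
#' reaction-time/state relationship the engagement analysis targets.
#'
#' @param cfg a [synth_config].
#' @return list with `trajectory` (session, t_s, x_cm, y_cm), `trials`
#'   (incl. ground-truth `state` and `exit_latency_s`), `events` (session,
#'   t_s, zone), `zones` (ground-truth label per trajectory sample), and
#'   `zone_map`.
#' @export
make_behavior <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  set.seed(cfg$seed + 1L)
  zm <- zone_map()
  exit_mu <- c(12, 7.9, 7.6)[seq_len(length(cfg$hmm_truth$p_s))]
  traj_l <- list(); trials_l <- list(); ev_l <- list()
  t0 <- 0
  for (ses in seq_len(cfg$n_sessions)) {
    sim <- simulate_hmm_choices(cfg$hmm_truth, cfg$trials_per_session)
    sides <- sides_from_outcomes(sim$correct)
    lat <- rgamma(cfg$trials_per_session, shape = 9,
                  scale = exit_mu[sim$states] / 9)
    ses_tr <- build_session_trajectory(cfg, zm, sides, lat, t0)
    traj <- ses_tr$traj
    traj$session <- ses
    zones <- assign_zones(traj, zm)
    ev <- draw_zone_poisson_events(traj$t_s, zones, cfg)
    traj_l[[ses]] <- traj
    ev_l[[ses]] <- if (length(ev)) {
      ezone <- zones[nearest_index(ev, traj$t_s)]
      data.frame(session = ses, t_s = ev, zone = ezone)
    } else data.frame(session = integer(), t_s = numeric(), zone = character())
    trials_l[[ses]] <- data.frame(
      session = ses, trial = seq_len(cfg$trials_per_session),
      choice = sides, correct = sim$correct, state = sim$states,
      delay_entry_s = ses_tr$delay_entry, delay_exit_s = ses_tr$delay_exit,
      exit_latency_s = lat)
    t0 <- max(traj$t_s) + 1
  }
  traj <- do.call(rbind, traj_l)
  if (cfg$pos_jitter_cm > 0) {
    traj$x_cm <- traj$x_cm + rnorm(nrow(traj), 0, cfg$pos_jitter_cm)
    traj$y_cm <- traj$y_cm + rnorm(nrow(traj), 0, cfg$pos_jitter_cm)
  }
  list(trajectory = traj[, c("session", "t_s", "x_cm", "y_cm")],
       trials = do.call(rbind, trials_l),
       events = do.call(rbind, ev_l),
       zones = assign_zones(traj, zm),
       zone_map = zm)
}

# map correct/incorrect outcomes to east/west sides under the alternation rule
sides_from_outcomes <- function(correct) {
  n <- length(correct)
  sides <- character(n)
  sides[1] <- sample(c("east", "west"), 1)
  if (n > 1) for (i in 2:n) {
    alt <- if (sides[i - 1] == "east") "west" else "east"
    sides[i] <- if (correct[i]) alt else sides[i - 1]
  }
  sides
}

#' Simulate choice outcomes from a Bernoulli-emission HMM
#'
#' @param params an [hmm_params] ground truth.
#' @param n_trials number of trials.
#' @return list with integer `states` and logical `correct`.
#' @export
simulate_hmm_choices <- function(params, n_trials) {
  N <- length(params$p_s)
  states <- integer(n_trials)
  states[1] <- sample.int(N, 1, prob = params$alpha0)
  if (n_trials > 1) for (i in 2:n_trials)
    states[i] <- sample.int(N, 1, prob = params$A[states[i - 1], ])
  correct <- runif(n_trials) < params$p_s[states]
  list(states = states, correct = correct)
}

# Piecewise-linear waypoint trajectory for one session. The animal dwells in
# the delay zone (30 s + state-dependent latency), runs up the stem through
# the choice box, along the top corridor, down the chosen side arm to the
# reward box (short dwell), then returns along the bottom to the delay zone.
build_session_trajectory <- function(cfg, zm, sides, latencies, t0) {
  spd <- cfg$run_speed_cms; fs <- cfg$pos_fs_hz
  xs <- zm$side_x[1] + zm$choice_size / 2           # side-arm center x
  ry <- mean(zm$reward_y)                            # reward dwell y
  top_y <- zm$height - zm$choice_size / 2
  delay_entry <- numeric(length(sides)); delay_exit <- numeric(length(sides))
  t <- t0
  pos <- c(0, 20)                                    # inside delay zone
  samples <- list()
  emit_run <- function(from, to, t) {
    d <- sqrt(sum((to - from)^2)); dur <- d / spd
    nst <- max(2L, ceiling(dur * fs))
    tt <- seq(t, t + dur, length.out = nst)
    list(t = tt[-1],
         x = seq(from[1], to[1], length.out = nst)[-1],
         y = seq(from[2], to[2], length.out = nst)[-1],
         t_end = t + dur)
  }
  emit_dwell <- function(at, dur, t) {
    nst <- max(1L, round(dur * fs))
    tt <- t + seq_len(nst) / fs
    list(t = tt, x = rep(at[1], nst), y = rep(at[2], nst), t_end = t + nst / fs)
  }
  add <- function(seg) samples[[length(samples) + 1L]] <<- seg
  # initial settle in delay
  seg <- emit_dwell(pos, 1, t); add(seg); t <- seg$t_end
  for (i in seq_along(sides)) {
    delay_entry[i] <- t
    seg <- emit_dwell(pos, cfg$delay_s + latencies[i], t); add(seg); t <- seg$t_end
    delay_exit[i] <- t
    sgn <- if (sides[i] == "east") 1 else -1
    wp <- list(c(0, top_y),                 # up the stem through choice
               c(sgn * xs, top_y),          # along the top corridor
               c(sgn * xs, ry))             # down side arm into reward
    cur <- pos
    for (w in wp) { seg <- emit_run(cur, w, t); add(seg); t <- seg$t_end; cur <- w }
    seg <- emit_dwell(cur, 3, t); add(seg); t <- seg$t_end   # consume reward
    for (w in list(c(sgn * xs, 10), c(0, 10), pos)) {
      seg <- emit_run(cur, w, t); add(seg); t <- seg$t_end; cur <- w
    }
  }
  traj <- data.frame(
    t_s = unlist(lapply(samples, `[[`, "t")),
    x_cm = unlist(lapply(samples, `[[`, "x")),
    y_cm = unlist(lapply(samples, `[[`, "y")))
  list(traj = traj, delay_entry = delay_entry, delay_exit = delay_exit)
}

# exact draw from a piecewise-constant-rate Poisson process on the
# trajectory's time grid
draw_zone_poisson_events <- function(times, zones, cfg) {
  if (length(times) < 2) return(numeric())
  dt <- diff(times)
  gain <- rep(1, length(zones))
  for (z in names(cfg$zone_gains))
    gain[zones == z] <- cfg$zone_gains[[z]]
  lam <- cfg$base_rate_hz * gain[-length(gain)] * dt
  k <- rpois(length(lam), lam)
  idx <- rep(seq_along(k), k)
  if (!length(idx)) return(numeric())
  sort(times[idx] + runif(length(idx)) * dt[idx])
}

nearest_index <- function(x, grid) {
  idx <- findInterval(x, grid, all.inside = TRUE)
  use_right <- idx < length(grid) &
    abs(grid[pmin(idx + 1L, length(grid))] - x) < abs(x - grid[idx])
  idx + as.integer(use_right)
}
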