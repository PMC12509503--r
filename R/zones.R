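#' Maze zone map for the figure-8 alternation apparatus
#'
#' Defines the analysis zones on an 80 x 90 cm figure-8 maze in maze-centered
#' coordinates (x in [-width/2, width/2] cm, y in [0, height] cm, central stem
#' at x = 0): `delay` (the lower 40 cm of the central arm), `choice` (15 x 15 cm
#' box at the top of the stem), `outer` (top corridors and upper side arms
#' leading to reward), and `reward` (15 x 25 cm boxes on each side arm). Zones
#' are disjoint; on-maze points between them map to `"none"`.
#'
#' @param width_cm,height_cm maze bounding rectangle (cm).
#' @param stem_halfwidth_cm half-width of the corridors (cm).
#' @return a `zone_map` object.
#' @export
zone_map <- function(width_cm = 80, height_cm = 90, stem_halfwidth_cm = 7.5) {
  zm <- list(width = width_cm, height = height_cm, hw = stem_halfwidth_cm,
             delay_len = 40,                 # cm of central arm
             choice_size = 15,               # choice box is 15 x 15
             reward_y = c(25, 50),           # reward box is 15 x 25 on side arm
             side_x = c(width_cm / 2 - 15, width_cm / 2))
  class(zm) <- "zone_map"
  zm
}

#' Assign maze zones to positions
#'
#' Each sample is labeled with the zone containing it, or `"none"` for
#' on-maze points outside every zone and for points outside the maze
#' rectangle entirely.
#'
#' @param traj data.frame with columns `x_cm`, `y_cm` (and typically `t_s`).
#' @param zm a [zone_map].
#' @return character vector of zone labels, one per row of `traj`.
#' @export
assign_zones <- function(traj, zm = zone_map()) {
  x <- traj$x_cm; y <- traj$y_cm
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  ax <- abs(x)
  hw <- zm$hw
  z <- rep("none", length(x))
  on_maze <- ax <= zm$width / 2 & y >= 0 & y <= zm$height
  z[on_maze & ax <= hw & y <= zm$delay_len] <- "delay"
  z[on_maze & ax <= zm$choice_size / 2 & y >= zm$height - zm$choice_size] <- "choice"
  rew <- on_maze & ax >= zm$side_x[1] & ax <= zm$side_x[2] &
    y >= zm$reward_y[1] & y <= zm$reward_y[2]
  z[rew] <- "reward"
  top <- on_maze & ax > zm$choice_size / 2 & y >= zm$height - zm$choice_size
  upper_side <- on_maze & ax >= zm$side_x[1] & ax <= zm$side_x[2] &
    y > zm$reward_y[2] & y < zm$height - zm$choice_size
  z[(top | upper_side) & !rew] <- "outer"
  z
}

#' Zone names used throughout the pipeline
#' @return character vector of the four analysis zones.
#' @export
zone_names <- function() c("delay", "choice", "outer", "reward")

#' Parse a zone sequence into trials
#'
#' A trial is one delay -> ... -> reward traversal. The chosen side is the
#' sign of x at the reward visit; a choice is correct iff it differs from the
#' previous trial's side (alternation rule). The first trial, having no
#' predecessor, is counted correct. Delay entry/exit times bracket the visit
#' to the delay zone that precedes each traversal.
#'
#' @param zones character zone labels per sample (from [assign_zones]).
#' @param times sample times (s).
#' @param x x-coordinate per sample (cm), used to determine the side.
#' @param session session id recorded on each trial (scalar).
#' @return data.frame: one row per trial with `session`, `trial`, `choice`
#'   (east/west), `correct`, `delay_entry_s`, `delay_exit_s`, `reward_t_s`.
#' @export
parse_trials <- function(zones, times, x, session = 1L) {
  stopifnot(length(zones) == length(times), length(x) == length(times))
  n <- length(zones)
  if (n == 0L || all(zones == "none"))
    return(empty_trial_table())
  trials <- list()
  in_delay <- zones == "delay"
  i <- 1L
  delay_entry <- NA_real_; delay_exit <- NA_real_
  seen_delay <- FALSE
  for (j in seq_len(n)) {
    if (in_delay[j] && !seen_delay) { delay_entry <- times[j]; seen_delay <- TRUE }
    if (seen_delay && !in_delay[j] && is.na(delay_exit) &&
        j > 1L && in_delay[j - 1L]) delay_exit <- times[j]
    if (zones[j] == "reward" && seen_delay) {
      trials[[length(trials) + 1L]] <- data.frame(
        session = session, trial = length(trials) + 1L,
        choice = if (x[j] >= 0) "east" else "west",
        delay_entry_s = delay_entry, delay_exit_s = delay_exit,
        reward_t_s = times[j])
      seen_delay <- FALSE; delay_entry <- NA_real_; delay_exit <- NA_real_
      # skip ahead past this reward visit
    }
  }
  if (!length(trials)) return(empty_trial_table())
  tt <- do.call(rbind, trials)
  tt$correct <- alternation_correct(tt$choice)
  tt[, c("session", "trial", "choice", "correct",
         "delay_entry_s", "delay_exit_s", "reward_t_s")]
}

empty_trial_table <- function() {
  data.frame(session = integer(), trial = integer(), choice = character(),
             correct = logical(), delay_entry_s = numeric(),
             delay_exit_s = numeric(), reward_t_s = numeric())
}

#' Correctness of a choice sequence under the alternation rule
#'
#' @param sides character vector of chosen sides per trial.
#' @return logical vector; the first trial is counted correct.
#' @export
alternation_correct <- function(sides) {
  n <- length(sides)
  if (n == 0L) return(logical())
  c(TRUE, sides[-1L] != sides[-n])
}

#' Accumulate per-zone spike counts and occupancy
#'
#' Each event is assigned the animal's zone at its timestamp (nearest tracked
#' sample); events falling in `"none"` are excluded (their count is reported
#' in the `n_off_zone` attribute). Occupancy is sample count times the sample
#' period.
#'
#' @param event_times_s IS event times (s).
#' @param zones zone labels per trajectory sample.
#' @param times trajectory sample times (s).
#' @return data.frame with one row per zone: `zone`, `S` (spike count),
#'   `T` (occupancy seconds).
#' @export
count_by_zone <- function(event_times_s, zones, times) {
  stopifnot(length(zones) == length(times))
  dt <- if (length(times) > 1) median(diff(times)) else 0
  zn <- zone_names()
  occ <- vapply(zn, function(z) sum(zones == z) * dt, numeric(1))
  idx <- findInterval(event_times_s, times, all.inside = TRUE)
  # nearest sample, not just left neighbor
  use_right <- idx < length(times) &
    abs(times[pmin(idx + 1L, length(times))] - event_times_s) <
      abs(event_times_s - times[idx])
  idx[use_right] <- idx[use_right] + 1L
  ez <- zones[idx]
  S <- vapply(zn, function(z) sum(ez == z), numeric(1))
  out <- data.frame(zone = zn, S = as.numeric(S), T = occ, row.names = NULL)
  attr(out, "n_off_zone") <- sum(ez == "none")
  out
}

#' Chi-square test of zone occupancy vs spike distribution
#'
#' Expected counts are the percent of time in each zone times the total
#' spike count; observed are the per-zone counts.
#'
#' @param zone_table data.frame from [count_by_zone] (possibly summed over
#'   animals).
#' @return `htest` from [stats::chisq.test] with expected counts attached.
#' @export
zone_chisq <- function(zone_table) {
  p_time <- zone_table$T / sum(zone_table$T)
  stats::chisq.test(zone_table$S, p = p_time)
}

#' Remove tracking outliers by a speed threshold
#'
#' Replaces the manual inspection step used for automated-maze tracking
#' errors: samples whose instantaneous speed exceeds `max_speed_cms` are
#' dropped.
#'
#' @param traj trajectory data.frame (`t_s`, `x_cm`, `y_cm`).
#' @param max_speed_cms speed ceiling (cm/s).
#' @return the filtered trajectory.
#' @export
filter_tracking_outliers <- function(traj, max_speed_cms = 150) {
  n <- nrow(traj)
  if (n < 2) return(traj)
  keep <- logical(n); keep[1] <- TRUE
  last <- 1L
  for (j in 2:n) {
    d <- sqrt((traj$x_cm[j] - traj$x_cm[last])^2 +
                (traj$y_cm[j] - traj$y_cm[last])^2)
    v <- d / max(traj$t_s[j] - traj$t_s[last], .Machine$double.eps)
    if (v <= max_speed_cms) { keep[j] <- TRUE; last <- j }
  }
  traj[keep, , drop = FALSE]
}
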