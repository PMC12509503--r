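#' Build a 15 x 15 occupancy/rate map from events and a trajectory
#'
#' The maze bounding box is divided into a square grid; per-bin occupancy
#' probability is the fraction of tracking samples in the bin and the
#' per-bin event rate is spikes divided by occupancy seconds (no smoothing).
#'
#' @param event_times_s IS event times (s).
#' @param traj trajectory data.frame (`t_s`, `x_cm`, `y_cm`).
#' @param n_bins grid size per axis.
#' @param zm a [zone_map] giving the binning extent.
#' @return an `occupancy_map` list: matrices `P` (probabilities) and
#'   `lambda` (Hz), plus `n_bins`.
#' @export
occupancy_map <- function(event_times_s, traj, n_bins = 15, zm = zone_map()) {
  dt <- median(diff(traj$t_s))
  xb <- seq(-zm$width / 2, zm$width / 2, length.out = n_bins + 1)
  yb <- seq(0, zm$height, length.out = n_bins + 1)
  bx <- cut(traj$x_cm, xb, include.lowest = TRUE, labels = FALSE)
  by <- cut(traj$y_cm, yb, include.lowest = TRUE, labels = FALSE)
  occ <- matrix(0, n_bins, n_bins)
  keep <- !is.na(bx) & !is.na(by)
  for (i in which(keep)) occ[bx[i], by[i]] <- occ[bx[i], by[i]] + 1
  occ_s <- occ * dt
  idx <- nearest_index(event_times_s, traj$t_s)
  cnt <- matrix(0, n_bins, n_bins)
  for (i in idx) if (keep[i]) cnt[bx[i], by[i]] <- cnt[bx[i], by[i]] + 1
  P <- occ / sum(occ)
  lambda <- matrix(0, n_bins, n_bins)
  nz <- occ_s > 0
  lambda[nz] <- cnt[nz] / occ_s[nz]
  structure(list(P = P, lambda = lambda, n_bins = n_bins),
            class = "occupancy_map")
}

#' Skaggs spatial information of an occupancy/rate map
#'
#' Information rate `I = sum_i lambda_i P(x_i) log2(lambda_i / L)` with
#' `L = sum_i lambda_i P(x_i)` the mean rate, summed over occupied bins
#' (`0 log 0 := 0`), and information per spike `I_spike = I / L`.
#'
#' @param map an [occupancy_map] (or any list with matrices `P`, `lambda`).
#' @return list with `I` (bits/s) and `I_spike` (bits/spike).
#' @export
spatial_information <- function(map) {
  P <- as.numeric(map$P); lam <- as.numeric(map$lambda)
  occ <- P > 0
  L <- sum(lam[occ] * P[occ])
  if (L <= 0) stop("all-zero rate map: information per spike is undefined")
  use <- occ & lam > 0
  I <- sum(lam[use] * P[use] * log2(lam[use] / L))
  list(I = I, I_spike = I / L)
}

#' Path length of a BIRD
#'
#' Sum of Euclidean distances along the path defined by the positions of
#' successive spikes; a single spike gives 0. Contrast with net displacement,
#' which can be 0 for a long out-and-back path.
#'
#' @param positions matrix/data.frame of spike positions (columns x, y; cm).
#' @return path length (cm).
#' @export
bird_distance <- function(positions) {
  p <- as.matrix(positions)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Per-session summaries feeding the regression models
#'
#' For each session: spatial information of IS activity, the mean BIRD path
#' length, and alternation performance (fraction of correct trials).
#'
#' @param behavior output of [make_behavior] (or equivalently structured
#'   list with `trajectory`, `trials`, `events`).
#' @return data.frame with `session`, `I`, `I_spike`, `mean_bird_cm`,
#'   `performance`, `n_events`.
#' @export
session_summaries <- function(behavior) {
  out <- lapply(split(seq_len(nrow(behavior$trajectory)),
                      behavior$trajectory$session), function(idx) {
    ses <- behavior$trajectory$session[idx[1]]
    traj <- behavior$trajectory[idx, ]
    ev <- behavior$events[behavior$events$session == ses, ]
    tr <- behavior$trials[behavior$trials$session == ses, ]
    si <- tryCatch(spatial_information(occupancy_map(ev$t_s, traj)),
                   error = function(e) list(I = NA_real_, I_spike = NA_real_))
    es <- classify_events(sort(ev$t_s))
    birds <- unique(es$bird_id[!is.na(es$bird_id)])
    bd <- vapply(birds, function(b) {
      tt <- es$t_s[which(es$bird_id == b)]
      ii <- nearest_index(tt, traj$t_s)
      bird_distance(cbind(traj$x_cm[ii], traj$y_cm[ii]))
    }, numeric(1))
    data.frame(session = ses, I = si$I, I_spike = si$I_spike,
               mean_bird_cm = if (length(bd)) mean(bd) else 0,
               performance = mean(tr$correct), n_events = nrow(ev))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gamma mixed model of spatial information on BIRD path length
#'
#' Fits `I_spike ~ 1 + mean_bird_cm + (1 | animal)` by maximum likelihood
#' with a Gamma family and reciprocal (inverse) link.
#'
#' @param summaries data.frame with columns `I_spike`, `mean_bird_cm`,
#'   `animal` (>= 2 animals and sessions).
#' @return list with `fit` (the `glmerMod`), `coefficients` (fixed effects
#'   table), `ranef_sd` and `dispersion`.
#' @export
fit_si_vs_distance <- function(summaries) {
  stopifnot(length(unique(summaries$animal)) >= 2, nrow(summaries) >= 4)
  if (any(summaries$I_spike <= 0, na.rm = TRUE))
    stop("Gamma family requires positive I_spike values")
  dat <- summaries[complete.cases(summaries[, c("I_spike", "mean_bird_cm")]), ]
  fit <- lme4::glmer(I_spike ~ 1 + mean_bird_cm + (1 | animal), data = dat,
                     family = Gamma(link = "inverse"),
                     control = lme4::glmerControl(check.conv.singular = "ignore"))
  co <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], row.names = NULL),
       ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[1]),
       dispersion = stats::sigma(fit)^2)
}

#' Regression of task performance on spatial information
#'
#' Ordinary fixed-effects regression `performance ~ 1 + I_spike` with the
#' dispersion estimated from the data.
#'
#' @param summaries data.frame with `performance` and `I_spike` (>= 3 rows).
#' @return list with `fit`, `coefficients` (estimate/se/t/p), `r_squared`
#'   and `dispersion`.
#' @export
fit_performance_vs_si <- function(summaries) {
  dat <- summaries[complete.cases(summaries[, c("performance", "I_spike")]), ]
  stopifnot(nrow(dat) >= 3)
  if (sd(dat$I_spike) == 0) stop("constant predictor: model is rank-deficient")
  fit <- glm(performance ~ 1 + I_spike, data = dat)
  co <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], p = co[, 4],
                                 row.names = NULL),
       r_squared = 1 - fit$deviance / sum((dat$performance - mean(dat$performance))^2),
       dispersion = summary(fit)$dispersion)
}
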