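## Motion-state classification of low-frequency bound-molecule tracks:
## sliding-window velocity threshold calibrated on simulations, single-track
## MSD velocimetry, and transition-rate counting.

#' Time-averaged single-track mean squared displacement
#'
#' @param track data frame with columns `x`, `y` (one track), or a
#'   [track_set] containing a single track.
#' @param tau frame interval (s); taken from the `track_set` attribute when
#'   available.
#' @return object of class `msd_curve`: data frame with columns `t` (s),
#'   `msd` (um^2) and `n_pairs`, for lags `1..(n-1)`.
#' @export
single_track_msd <- function(track, tau = NULL) {
  if (is.null(tau)) tau <- attr(track, "tau")
  if (is.null(tau)) stop("tau required")
  n <- nrow(track)
  if (n < 2L) stop("track must have at least 2 points")
  lags <- seq_len(n - 1L)
  msd <- vapply(lags, function(m) {
    i <- seq_len(n - m)
    mean((track$x[i + m] - track$x[i])^2 + (track$y[i + m] - track$y[i])^2)
  }, numeric(1))
  structure(data.frame(t = lags * tau, msd = msd, n_pairs = n - lags),
            class = c("msd_curve", "data.frame"), tau = tau)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$t, x$msd, xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Fit a directed-motion velocity to a single-track MSD
#'
#' Least-squares fit of the quadratic law `MSD(t) = v^2 t^2 + b`, whose
#' offset `b` reflects the localization error. The coefficient of
#' determination of the quadratic fit selects persistently moving tracks
#' (conventionally `R^2 >= 0.9`).
#'
#' @param msd an `msd_curve`.
#' @param max_lags use at most this many lags of the curve (NULL = all).
#' @return list with `v` (um/s, >= 0), `r2`, `offset` (um^2).
#' @export
fit_track_velocity <- function(msd, max_lags = NULL) {
  d <- as.data.frame(msd)
  if (!is.null(max_lags)) d <- d[seq_len(min(nrow(d), max_lags)), , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 MSD lags")
  t2 <- d$t^2
  fit <- stats::lm(msd ~ t2, data = d)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) stop("non-finite velocity fit")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((d$msd - mean(d$msd))^2)
  list(v = sqrt(max(cf[[2]], 0)), r2 = r2, offset = cf[[1]])
}

#' Per-track velocity distribution of persistent motion
#'
#' Applies [single_track_msd] and [fit_track_velocity] to every track whose
#' number of steps lies in `[min_steps, max_steps]` (the upper cap prevents a
#' bias towards slow molecules that stay in the evanescent field longer).
#'
#' @param tracks a [track_set].
#' @param min_steps,max_steps track-length window in steps.
#' @param r2_min optional minimum `R^2`; rows below it are dropped.
#' @return data frame with columns `track_id`, `n_steps`, `v`, `r2`, `offset`.
#' @export
velocity_distribution <- function(tracks, min_steps = 4L, max_steps = 10L,
                                  r2_min = NULL) {
  tau <- track_interval(tracks)
  tl <- track_split(tracks)
  rows <- lapply(tl, function(d) {
    ns <- nrow(d) - 1L
    if (ns < min_steps || ns > max_steps) return(NULL)
    f <- fit_track_velocity(single_track_msd(d, tau))
    data.frame(track_id = d$track_id[1], n_steps = ns,
               v = f$v, r2 = f$r2, offset = f$offset)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no tracks in the length window")
  rownames(out) <- NULL
  if (!is.null(r2_min)) out <- out[out$r2 >= r2_min, , drop = FALSE]
  out
}

#' Classify track time points as immobile or persistent
#'
#' The smoothed local velocity at time point `t` is the displacement between
#' the positions `w/2` steps before and after, divided by `w tau`:
#' `v(t) = |r(t + w/2) - r(t - w/2)| / (w tau)`. Points with `v(t)`
#' strictly above `v_thr` are labeled persistent; a tie is labeled immobile.
#' Labels exist only where the full window fits inside the track.
#'
#' @param track data frame with `x`, `y` for one track.
#' @param w window size in steps (even).
#' @param v_thr velocity threshold (um/s).
#' @param tau frame interval (s).
#' @return object of class `motion_states`: data frame with columns `index`
#'   (position within the track, 1-based), `v` and `state` (factor,
#'   `"immobile"`/`"persistent"`); zero rows if the track is too short.
#' @export
classify_states <- function(track, w = 4L, v_thr = 0.008, tau = NULL) {
  if (is.null(tau)) tau <- attr(track, "tau")
  if (is.null(tau)) stop("tau required")
  if (w %% 2L != 0L || w < 2L) stop("w must be a positive even number of steps")
  h <- w %/% 2L
  n <- nrow(track)
  mk <- function(idx, v, st)
    structure(data.frame(index = idx, v = v,
                         state = factor(st, levels = c("immobile", "persistent"))),
              class = c("motion_states", "data.frame"),
              w = w, v_thr = v_thr, tau = tau)
  if (n < w + 1L) return(mk(integer(0), numeric(0), character(0)))
  idx <- (h + 1L):(n - h)
  v <- sqrt((track$x[idx + h] - track$x[idx - h])^2 +
            (track$y[idx + h] - track$y[idx - h])^2) / (w * tau)
  mk(idx, v, ifelse(v > v_thr, "persistent", "immobile"))
}

#' Classify every track of a set
#'
#' @param tracks a [track_set].
#' @inheritParams classify_states
#' @return named list of `motion_states`, one per track (tracks too short
#'   for the window give zero-row entries).
#' @export
classify_tracks <- function(tracks, w = 4L, v_thr = 0.008) {
  tau <- track_interval(tracks)
  lapply(track_split(tracks), classify_states, w = w, v_thr = v_thr, tau = tau)
}

## absorb intermittent (interior) label runs of a single evaluated time
## step into their flanking states; runs at the series ends are not
## intermittent and stay
merge_single_steps <- function(labels) {
  labels <- as.character(labels)
  repeat {
    r <- rle(labels)
    len <- length(r$lengths)
    if (len <= 2L) return(labels)
    interior <- which(r$lengths == 1L & seq_len(len) > 1L & seq_len(len) < len)
    if (!length(interior)) return(labels)
    r$values[interior[1]] <- r$values[interior[1] - 1L]
    labels <- inverse.rle(r)
  }
}

#' Transition rates between immobile and persistent states
#'
#' Counts label transitions after merging intermittent single-time-step
#' segments into their flanking states. Rates are transition counts divided
#' by the total dwell time in the source state (evaluated points times
#' `tau`); a state never visited yields an undefined (NA) outgoing rate.
#' Transitions at track ends are not counted.
#'
#' @param series a `motion_states` object or a list of them (e.g. from
#'   [classify_tracks]).
#' @param tau frame interval (s).
#' @return object of class `transition_rates`: list with `k_ip`, `k_pi`
#'   (1/s), transition counts `n_ip`, `n_pi`, dwell times `t_immobile`,
#'   `t_persistent` (s) and `persistent_fraction`.
#' @export
estimate_transition_rates <- function(series, tau) {
  if (inherits(series, "motion_states")) series <- list(series)
  n_ip <- n_pi <- 0L
  t_imm <- t_per <- 0
  for (s in series) {
    if (nrow(s) == 0L) next
    lab <- merge_single_steps(s$state)
    t_imm <- t_imm + sum(lab == "immobile") * tau
    t_per <- t_per + sum(lab == "persistent") * tau
    if (length(lab) > 1L) {
      a <- lab[-length(lab)]; b <- lab[-1]
      n_ip <- n_ip + sum(a == "immobile" & b == "persistent")
      n_pi <- n_pi + sum(a == "persistent" & b == "immobile")
    }
  }
  structure(list(k_ip = if (t_imm > 0) n_ip / t_imm else NA_real_,
                 k_pi = if (t_per > 0) n_pi / t_per else NA_real_,
                 n_ip = n_ip, n_pi = n_pi,
                 t_immobile = t_imm, t_persistent = t_per,
                 persistent_fraction = if (t_imm + t_per > 0) t_per / (t_imm + t_per) else NA_real_),
            class = "transition_rates")
}

#' @export
print.transition_rates <- function(x, ...) {
  cat(sprintf("transition rates: k_ip = %s 1/s (%d events / %.0f s), k_pi = %s 1/s (%d events / %.0f s)\n",
              format(x$k_ip, digits = 3), x$n_ip, x$t_immobile,
              format(x$k_pi, digits = 3), x$n_pi, x$t_persistent))
  cat(sprintf("persistent fraction: %.3f\n", x$persistent_fraction))
  invisible(x)
}

#' Calibrate the velocity-threshold classifier on simulations
#'
#' Simulates pure immobile and pure persistent track populations under the
#' experimental conditions and evaluates the per-evaluated-time-point
#' accuracy of [classify_states] over a grid of window sizes and velocity
#' thresholds. Returns all combinations meeting the target accuracy on both
#' classes and the combination maximizing the smaller of the two accuracies.
#'
#' @param v persistent speed (um/s).
#' @param sigma localization accuracy (um).
#' @param tau frame interval (s).
#' @param mean_steps mean exponential track length (steps).
#' @param n_tracks simulated tracks per class.
#' @param w_grid window sizes (even steps).
#' @param vthr_grid velocity thresholds (um/s).
#' @param target required per-class accuracy.
#' @param seed integer seed.
#' @return list with `table` (data frame: `w`, `v_thr`, `acc_immobile`,
#'   `acc_persistent`), `passing` (subset meeting the target on both
#'   classes; zero rows with a warning if none does) and `chosen` (one row).
#' @export
calibrate_classifier <- function(v = 0.014, sigma = 0.025, tau = 3.6,
                                 mean_steps = 3.5, n_tracks = 3000L,
                                 w_grid = c(2L, 4L, 6L),
                                 vthr_grid = seq(0.002, 0.014, by = 0.002),
                                 target = 0.99, seed = 1L) {
  stopifnot(length(w_grid) > 0, length(vthr_grid) > 0)
  imm <- simulate_bound_motion_tracks(n_tracks, v = 0, k_ip = 0, k_pi = 0,
                                      sigma_loc = sigma, tau = tau,
                                      mean_steps = mean_steps,
                                      state0 = "immobile", seed = seed)
  per <- simulate_bound_motion_tracks(n_tracks, v = v, k_ip = 0, k_pi = 0,
                                      sigma_loc = sigma, tau = tau,
                                      mean_steps = mean_steps,
                                      state0 = "persistent", direction = "x",
                                      seed = seed + 1L)
  acc <- function(tracks, w, v_thr, truth) {
    lab <- unlist(lapply(classify_tracks(tracks, w = w, v_thr = v_thr),
                         function(s) as.character(s$state)), use.names = FALSE)
    if (!length(lab)) return(NA_real_)
    mean(lab == truth)
  }
  grid <- expand.grid(w = w_grid, v_thr = vthr_grid)
  grid$acc_immobile <- NA_real_; grid$acc_persistent <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$acc_immobile[i] <- acc(imm, grid$w[i], grid$v_thr[i], "immobile")
    grid$acc_persistent[i] <- acc(per, grid$w[i], grid$v_thr[i], "persistent")
  }
  pass <- grid[!is.na(grid$acc_immobile) & !is.na(grid$acc_persistent) &
               grid$acc_immobile >= target & grid$acc_persistent >= target, ,
               drop = FALSE]
  if (nrow(pass) == 0L)
    warning("no (w, v_thr) combination meets the target accuracy; reporting best")
  pool <- if (nrow(pass)) pass else grid
  score <- pmin(pool$acc_immobile, pool$acc_persistent)
  chosen <- pool[which.max(score), , drop = FALSE]
  list(table = grid, passing = pass, chosen = chosen)
}

#' Orientation of persistent tracks relative to the cell axis
#'
#' Angle between the end-to-end vector of each track and the cell long axis,
#' folded into `[0, 90]` degrees.
#'
#' @param tracks a [track_set].
#' @param cell_axis unit vector (length 2) of the cell long axis.
#' @return numeric vector of angles in degrees, one per track.
#' @export
orientation_distribution <- function(tracks, cell_axis) {
  if (is.null(cell_axis) || length(cell_axis) != 2L)
    stop("cell_axis must be a length-2 vector")
  ax <- cell_axis / sqrt(sum(cell_axis^2))
  tl <- track_split(tracks)
  ang <- vapply(tl, function(d) {
    v <- c(d$x[nrow(d)] - d$x[1], d$y[nrow(d)] - d$y[1])
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NA_real_)
    acos(pmin(1, abs(sum(v * ax)) / nv)) * 180 / pi
  }, numeric(1))
  unname(ang)
}
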