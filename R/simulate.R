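## Synthetic-data generators. All generators take an integer seed and are
## bit-reproducible for identical arguments. Lengths in um, times in s,
## rates in 1/s.

## rounded-exponential track length; zero-step draws are redrawn
draw_track_lengths <- function(n, mean_steps) {
  stopifnot(mean_steps > 0)
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    k <- as.integer(round(stats::rexp(length(todo), rate = 1 / mean_steps)))
    ok <- k >= 1L
    out[todo[ok]] <- k[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a mixed bound/diffusive tracked population
#'
#' Generates trajectories of a population in which a fraction `b` of molecules
#' is bound (immobile) and the remainder diffuses with one or more diffusion
#' constants. Per-axis Brownian increments have standard deviation
#' `sqrt(2 D tau)`; every localization is perturbed by isotropic Gaussian
#' noise of standard deviation `sigma_loc`. The per-track ground-truth state
#' is recorded in column `true_state`.
#'
#' @param n_tracks number of tracks.
#' @param b bound (immobile) fraction, in `[0, 1]`.
#' @param D diffusion constant(s) of the mobile state(s), um^2/s.
#' @param D_fractions population fractions of the mobile states; must sum to
#'   `1 - b`. Defaults to a single mobile state holding all mobile mass.
#' @param sigma_loc localization accuracy (um, per coordinate).
#' @param tau frame interval (s).
#' @param mean_steps mean of the rounded-exponential track-length
#'   distribution (steps, minimum 1).
#' @param steps optional integer vector of track lengths (steps) overriding
#'   the exponential draw; sampled with replacement if shorter than
#'   `n_tracks`. Used to match an empirical length distribution.
#' @param fov extent of the (square) region in which tracks start, um.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a [track_set] with ground-truth column `true_state`
#'   (`"bound"` or `"mobile<j>"`).
#' @export
simulate_tracked_population <- function(n_tracks, b, D, D_fractions = NULL,
                                        sigma_loc = 0.025, tau = 0.06,
                                        mean_steps = 3.5, steps = NULL,
                                        fov = 5, seed = NULL) {
  stopifnot(n_tracks >= 1, tau > 0, sigma_loc >= 0)
  if (b < 0 || b > 1) stop("b must be in [0, 1]")
  if (any(D < 0)) stop("diffusion constants must be >= 0")
  if (is.null(D_fractions)) {
    if (length(D) != 1L && b < 1)
      stop("D_fractions required when more than one mobile state is given")
    D_fractions <- 1 - b
  }
  if (length(D_fractions) != length(D))
    stop("D and D_fractions must have equal length")
  if (abs(b + sum(D_fractions) - 1) > 1e-8)
    stop("b + sum(D_fractions) must equal 1")
  if (!is.null(seed)) set.seed(seed)

  n_steps <- if (is.null(steps)) draw_track_lengths(n_tracks, mean_steps)
             else as.integer(sample(rep(steps, length.out = max(n_tracks, length(steps))),
                                    n_tracks, replace = TRUE))
  probs <- c(b, D_fractions)
  state <- sample.int(length(probs), n_tracks, replace = TRUE, prob = probs)
  Dtrk <- c(0, D)[state]
  lab <- c("bound", paste0("mobile", seq_along(D)))[state]

  npts <- n_steps + 1L
  total <- sum(npts)
  id <- rep.int(seq_len(n_tracks), npts)
  frame <- unlist(lapply(npts, function(k) 0:(k - 1L)), use.names = FALSE)
  x0 <- stats::runif(n_tracks, 0, fov)
  y0 <- stats::runif(n_tracks, 0, fov)
  sd_step <- sqrt(2 * Dtrk * tau)
  dx <- stats::rnorm(total, sd = rep.int(sd_step, npts))
  dy <- stats::rnorm(total, sd = rep.int(sd_step, npts))
  first <- frame == 0L
  dx[first] <- 0; dy[first] <- 0
  x <- rep.int(x0, npts) + ave(dx, id, FUN = cumsum)
  y <- rep.int(y0, npts) + ave(dy, id, FUN = cumsum)
  if (sigma_loc > 0) {
    x <- x + stats::rnorm(total, sd = sigma_loc)
    y <- y + stats::rnorm(total, sd = sigma_loc)
  }
  out <- track_set(data.frame(track_id = id, frame = frame, x = x, y = y,
                              true_state = rep.int(lab, npts)), tau = tau)
  attr(out, "sim") <- list(generator = "tracked_population", b = b, D = D,
                           sigma_loc = sigma_loc, seed = seed)
  out
}

#' Simulate bound molecules switching between immobile and persistent states
#'
#' Each track alternates immobile (zero true displacement) and persistently
#' moving (constant speed `v` along a fixed direction per run) segments with
#' exponential dwell times at rates `k_ip` (immobile to persistent) and
#' `k_pi` (persistent to immobile). The continuous-time state process is
#' sampled at the frame interval; localization noise is added to every point.
#' Ground-truth state at each frame time is recorded. Optional per-frame
#' bleaching, exponential unbinding and exit from a finite field of view
#' truncate tracks.
#'
#' @param n_tracks number of tracks.
#' @param v persistent speed (um/s).
#' @param k_ip,k_pi switching rates (1/s); either may be 0.
#' @param sigma_loc localization accuracy (um).
#' @param tau frame interval (s).
#' @param mean_steps mean of the rounded-exponential track-length
#'   distribution (steps).
#' @param state0 initial state: `"stationary"` draws from the stationary
#'   distribution of the switching process, otherwise force `"immobile"` or
#'   `"persistent"`.
#' @param direction direction of persistent runs: `"x"` (always +x, the
#'   classifier-calibration convention), `"random"` (uniform angle per run) or
#'   `"perp"` (a random sign along x per run, the field-of-view convention).
#' @param k_bd optional unbinding rate (1/s); tracks end at an exponential
#'   unbinding time.
#' @param p_b optional bleaching probability per frame.
#' @param fov_width optional field-of-view width (um). Tracks start at a
#'   uniform x in `(-fov_width/2, fov_width/2)` and end when the true x
#'   coordinate leaves the strip.
#' @param record_dwells also return the completed (uncensored) state dwell
#'   times in attribute `dwells` (list with elements `immobile`,
#'   `persistent`).
#' @param seed integer seed.
#' @return a [track_set] with ground-truth column `true_state`
#'   (`"immobile"` or `"persistent"`). Tracks truncated to fewer than two
#'   localizations are dropped.
#' @export
simulate_bound_motion_tracks <- function(n_tracks, v, k_ip, k_pi,
                                         sigma_loc = 0.025, tau = 3.6,
                                         mean_steps = 3.5,
                                         state0 = c("stationary", "immobile", "persistent"),
                                         direction = c("x", "random", "perp"),
                                         k_bd = NULL, p_b = NULL,
                                         fov_width = NULL,
                                         record_dwells = FALSE, seed = NULL) {
  state0 <- match.arg(state0)
  direction <- match.arg(direction)
  stopifnot(v >= 0, k_ip >= 0, k_pi >= 0, tau > 0, sigma_loc >= 0)
  if (!is.null(p_b) && (p_b < 0 || p_b > 1)) stop("p_b must be in [0, 1]")
  if (!is.null(k_bd) && k_bd < 0) stop("k_bd must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  n_steps <- draw_track_lengths(n_tracks, mean_steps)
  res <- vector("list", n_tracks)
  dw_imm <- list(); dw_per <- list()
  for (i in seq_len(n_tracks)) {
    n <- n_steps[i]
    dur <- n * tau
    if (!is.null(k_bd) && k_bd > 0) dur <- min(dur, stats::rexp(1, k_bd))
    ## initial state
    p_stat <- if (k_ip + k_pi > 0) k_ip / (k_ip + k_pi) else 0
    pers <- switch(state0,
                   stationary = stats::runif(1) < p_stat,
                   immobile = FALSE, persistent = TRUE)
    x <- if (is.null(fov_width)) 0 else stats::runif(1, -fov_width / 2, fov_width / 2)
    y <- 0
    tt <- 0
    times <- seq(0, n * tau, by = tau)
    px <- py <- numeric(length(times)); st <- character(length(times))
    px[1] <- x; py[1] <- y; st[1] <- if (pers) "persistent" else "immobile"
    j <- 2L
    theta <- NA_real_
    new_dir <- function() switch(direction,
                                 x = 0,
                                 random = stats::runif(1, 0, 2 * pi),
                                 perp = if (stats::runif(1) < 0.5) 0 else pi)
    if (pers) theta <- new_dir()
    dwell <- function(p) {
      r <- if (p) k_pi else k_ip
      if (r > 0) stats::rexp(1, r) else Inf
    }
    t_next <- cur_dwell <- dwell(pers)
    ended <- FALSE
    while (j <= length(times) && !ended) {
      target <- times[j]
      while (tt + t_next < min(target, dur)) {
        if (pers) { x <- x + v * cos(theta) * t_next; y <- y + v * sin(theta) * t_next }
        tt <- tt + t_next
        if (record_dwells) {
          if (pers) dw_per[[length(dw_per) + 1L]] <- cur_dwell
          else dw_imm[[length(dw_imm) + 1L]] <- cur_dwell
        }
        pers <- !pers
        if (pers) theta <- new_dir()
        t_next <- cur_dwell <- dwell(pers)
      }
      if (dur < target && dur >= tt) { ended <- TRUE; break }
      adv <- target - tt
      if (pers) { x <- x + v * cos(theta) * adv; y <- y + v * sin(theta) * adv }
      t_next <- t_next - adv
      tt <- target
      if (!is.null(fov_width) && abs(x) > fov_width / 2) { ended <- TRUE; break }
      px[j] <- x; py[j] <- y; st[j] <- if (pers) "persistent" else "immobile"
      j <- j + 1L
      if (!is.null(p_b) && stats::runif(1) < p_b) { ended <- TRUE; break }
    }
    k <- j - 1L
    if (k < 2L) { res[[i]] <- NULL; next }
    res[[i]] <- data.frame(track_id = i, frame = 0:(k - 1L),
                           x = px[1:k], y = py[1:k], true_state = st[1:k])
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) stop("all simulated tracks were shorter than 2 points")
  if (sigma_loc > 0) {
    out$x <- out$x + stats::rnorm(nrow(out), sd = sigma_loc)
    out$y <- out$y + stats::rnorm(nrow(out), sd = sigma_loc)
  }
  ts <- track_set(out, tau = tau)
  attr(ts, "sim") <- list(generator = "bound_motion", v = v, k_ip = k_ip,
                          k_pi = k_pi, sigma_loc = sigma_loc, seed = seed)
  if (record_dwells)
    attr(ts, "dwells") <- list(immobile = unlist(dw_imm),
                               persistent = unlist(dw_per))
  ts
}

#' Lifetime histogram container
#'
#' Counts of observed track lengths (number of steps) at a given frame
#' interval, the input of the joint bleaching/termination lifetime fit.
#'
#' @param counts non-negative counts, one per value of `steps`.
#' @param tau frame interval (s).
#' @param steps integer vector of step numbers corresponding to `counts`.
#' @return object of class `lifetime_histogram`.
#' @export
lifetime_histogram <- function(counts, tau, steps = seq_along(counts) - 1L) {
  stopifnot(length(counts) == length(steps), all(counts >= 0), tau > 0)
  structure(list(steps = as.integer(steps), counts = as.numeric(counts), tau = tau),
            class = "lifetime_histogram")
}

#' @export
print.lifetime_histogram <- function(x, ...) {
  cat(sprintf("lifetime_histogram: %d tracks, tau = %g s, steps %d-%d\n",
              round(sum(x$counts)), x$tau, min(x$steps), max(x$steps)))
  invisible(x)
}

#' Simulate observed track-length (lifetime) data
#'
#' Tracks terminate each frame with probability `1 - q` where the per-frame
#' survival is `q = (1 - p_b) * exp(-k_a * tau)`: photobleaching with
#' probability `p_b` per frame plus an apparent termination process of rate
#' `k_a`. Observed lengths (number of surviving steps) are geometric.
#'
#' @param p_b bleaching probability per frame, in `[0, 1]`.
#' @param k_a apparent termination rate (1/s).
#' @param tau frame interval (s).
#' @param n_tracks number of tracks.
#' @param max_steps censoring horizon (steps).
#' @param seed integer seed.
#' @return a [lifetime_histogram].
#' @export
simulate_track_lifetimes <- function(p_b, k_a, tau, n_tracks,
                                     max_steps = 200L, seed = NULL) {
  if (p_b < 0 || p_b > 1) stop("p_b must be in [0, 1]")
  stopifnot(k_a >= 0, tau > 0, n_tracks >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- (1 - p_b) * exp(-k_a * tau)
  n <- if (q >= 1) rep.int(max_steps, n_tracks)
       else pmin(stats::rgeom(n_tracks, prob = 1 - q), max_steps)
  lifetime_histogram(tabulate(n + 1L, nbins = max_steps + 1L), tau = tau,
                     steps = 0:max_steps)
}

#' Simulate a bound-molecule FRAP experiment
#'
#' After bleaching, all bound molecules in the field of view are dark; the
#' measured bound fraction recovers as unbleached diffusive molecules bind.
#' The generator simulates the two-state occupancy mechanistically: each
#' molecule starts diffusive and switches diffusive -> bound at rate `k_db`
#' and bound -> diffusive at `k_bd = k_db * (1 - b_eq) / b_eq` (detailed
#' balance at the equilibrium bound fraction `b_eq`). At each lag the
#' binomially sampled bound fraction over `n_molecules` is reported.
#'
#' @param k_db binding rate, diffusive to bound (1/s).
#' @param b_eq equilibrium bound fraction, in `(0, 1)`.
#' @param lags lag times after bleaching (s); must be nonempty.
#' @param n_molecules molecules measured per lag.
#' @param seed integer seed.
#' @return object of class `frap_data`: data frame with columns `lag`,
#'   `bound_fraction`, `n`.
#' @export
simulate_frap_experiment <- function(k_db, b_eq, lags, n_molecules = 500L,
                                     seed = NULL) {
  stopifnot(k_db >= 0, b_eq > 0, b_eq < 1, n_molecules >= 1)
  if (length(lags) == 0L) stop("empty lag list")
  if (!is.null(seed)) set.seed(seed)
  k_bd <- k_db * (1 - b_eq) / b_eq
  bf <- vapply(lags, function(lag) {
    bound <- logical(n_molecules)
    for (m in seq_len(n_molecules)) {
      tt <- 0; state_bound <- FALSE
      repeat {
        r <- if (state_bound) k_bd else k_db
        if (r <= 0) break
        tt <- tt + stats::rexp(1, r)
        if (tt > lag) break
        state_bound <- !state_bound
      }
      bound[m] <- state_bound
    }
    mean(bound)
  }, numeric(1))
  structure(data.frame(lag = lags, bound_fraction = bf, n = n_molecules),
            class = c("frap_data", "data.frame"))
}

## heading integration of a centerline with curvature profile kappa(s)
integrate_centerline <- function(s, kappa) {
  theta <- c(0, cumsum(kappa[-length(kappa)] * diff(s)))
  x <- c(0, cumsum(cos(theta[-length(theta)]) * diff(s)))
  y <- c(0, cumsum(sin(theta[-length(theta)]) * diff(s)))
  list(x = x, y = y, theta = theta)
}

#' Generate a synthetic bent rod cell with a boundary intensity profile
#'
#' Builds a closed contour of a bent rod with hemispherical poles from a
#' centerline curvature profile, and a per-contour-point intensity coupled to
#' centerline bending: `I = I0 * (1 + alpha * side * kappa * w) * (1 + noise)`
#' where `side` is +1 on the right and -1 on the left of the centerline, so
#' the inner face of a bend is enriched by `alpha * |kappa| * w`. Optional
#' curvature-neutral bulges/indentations perturb the local half-width without
#' any intensity coupling. Ground truth (centerline curvature, side labels,
#' local widths, pole flags, centerline arclength) is recorded.
#'
#' @param length pole-to-pole centerline length (um).
#' @param width cell width (um).
#' @param kappa centerline curvature: a scalar (1/um) or a function of
#'   arclength `kappa(s)`. Positive values bend the cell to the right of the
#'   direction of travel (the convention of [centerline_curvature]), so the
#'   right side (`side = +1`) is the inner face of a right bend.
#' @param alpha intensity-bending coupling coefficient (dimensionless).
#' @param bulge_amplitude amplitude of curvature-neutral half-width bumps
#'   (um); 0 disables bulges.
#' @param n_bulges number of bulges per side (random positions on the side
#'   walls, random sign).
#' @param bulge_sd Gaussian arclength width of each bulge (um).
#' @param contour_step spacing of contour points (um).
#' @param contour_noise s.d. of sub-pixel segmentation jitter applied to
#'   every contour point along its normal (um); mimics the curvature noise
#'   floor of real segmented contours.
#' @param intensity_noise relative s.d. of multiplicative intensity noise.
#' @param I0 baseline intensity (a.u.).
#' @param seed integer seed.
#' @return list with elements `geometry` (class `cell_geometry`: `contour`
#'   n x 2, `centerline` m x 2, per-contour-point `s`, `side`, `width_local`,
#'   `pole`, `kappa_true`, scalar `width`, `L`) and `intensity` (numeric
#'   vector, one value per contour point).
#' @export
generate_synthetic_cell <- function(length = 6, width = 1, kappa = 0,
                                    alpha = 0.2, bulge_amplitude = 0,
                                    n_bulges = 2, bulge_sd = 0.15,
                                    contour_step = 0.032,
                                    contour_noise = 0.002,
                                    intensity_noise = 0.02, I0 = 1,
                                    seed = NULL) {
  stopifnot(length > width, width > 0, contour_step > 0)
  if (!is.null(seed)) set.seed(seed)
  kfun <- if (is.function(kappa)) kappa else function(s) rep(kappa, length.out = base::length(s))
  L <- length
  s_cl <- seq(0, L, by = 0.032)
  kap_cl <- kfun(s_cl)
  if (any(abs(kap_cl) * width / 2 >= 1))
    stop("curvature too high for width: |kappa| * w / 2 must be < 1")
  ## right-positive curvature = clockwise heading change
  cl <- integrate_centerline(s_cl, -kap_cl)
  centerline <- cbind(x = cl$x, y = cl$y)

  ## side walls live on s in [w/2, L - w/2]
  r <- width / 2
  s_side <- seq(r, L - r, by = contour_step)
  kap_side <- kfun(s_side)
  th_side <- stats::approx(s_cl, cl$theta, s_side)$y
  cx <- stats::approx(s_cl, cl$x, s_side)$y
  cy <- stats::approx(s_cl, cl$y, s_side)$y
  ## right normal of heading theta is (sin(theta), -cos(theta))
  half_r <- rep(r, base::length(s_side))
  half_l <- rep(r, base::length(s_side))
  if (bulge_amplitude > 0 && n_bulges > 0) {
    for (side in 1:2) {
      pos <- stats::runif(n_bulges, r + 2 * bulge_sd, L - r - 2 * bulge_sd)
      amp <- bulge_amplitude * sample(c(-1, 1), n_bulges, replace = TRUE)
      bump <- rowSums(vapply(seq_len(n_bulges), function(k)
        amp[k] * exp(-(s_side - pos[k])^2 / (2 * bulge_sd^2)), numeric(base::length(s_side))))
      if (side == 1) half_r <- half_r + bump else half_l <- half_l + bump
    }
    if (any(half_r <= 0.05) || any(half_l <= 0.05))
      stop("bulge amplitude produces a degenerate contour")
  }
  right <- cbind(cx + sin(th_side) * half_r, cy - cos(th_side) * half_r)
  left  <- cbind(cx - sin(th_side) * half_l, cy + cos(th_side) * half_l)

  ## hemispherical caps around the pole centers (s = r and s = L - r)
  cap <- function(center, theta_mid, n) {
    ## endpoints excluded: they coincide with side-wall endpoints
    ang <- theta_mid + seq(-pi / 2, pi / 2, length.out = n + 2)[2:(n + 1)]
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  }
  n_cap <- max(5L, ceiling(pi * r / contour_step))
  th0 <- th_side[1]; thL <- th_side[base::length(th_side)]
  cap_start <- cap(c(cx[1], cy[1]), th0 + pi, n_cap)          # around s = r
  cap_end   <- cap(c(cx[base::length(cx)], cy[base::length(cy)]), thL, n_cap) # s = L - r

  ## assemble counter-clockwise: right wall forward, far cap, left wall back,
  ## near cap. Right side of the heading is below the centerline for theta=0,
  ## so traversing right-forward then left-backward runs clockwise; fix below.
  m <- base::length(s_side)
  contour <- rbind(right,
                   cap_end,
                   left[m:1, , drop = FALSE],
                   cap_start)
  ## cap arclengths sweep out to the pole tip (s = L resp. s = 0) and back
  out_back <- function(s0, tip) {
    frac <- seq_len(n_cap) / (n_cap + 1)
    s0 + (tip - s0) * (1 - abs(2 * frac - 1))
  }
  s_i <- c(s_side, out_back(L - r, L), rev(s_side), out_back(r, 0))
  side_i <- c(rep(1, m), rep(0, n_cap), rep(-1, m), rep(0, n_cap))
  pole_i <- side_i == 0
  wl <- half_r + half_l
  width_i <- c(wl, rep(width, n_cap), rev(wl), rep(width, n_cap))
  kap_i <- c(kap_side, rep(0, n_cap), rev(kap_side), rep(0, n_cap))

  ## enforce counter-clockwise orientation
  area2 <- sum(contour[, 1] * c(contour[-1, 2], contour[1, 2]) -
               contour[, 2] * c(contour[-1, 1], contour[1, 1]))
  if (area2 < 0) {
    idx <- nrow(contour):1
    contour <- contour[idx, , drop = FALSE]
    s_i <- s_i[idx]; side_i <- side_i[idx]; pole_i <- pole_i[idx]
    width_i <- width_i[idx]; kap_i <- kap_i[idx]
  }

  if (contour_noise > 0) {
    nrm <- contour_normals(contour)
    eps <- stats::rnorm(nrow(contour), sd = contour_noise)
    contour <- contour + nrm * eps
  }

  intensity <- I0 * (1 + alpha * side_i * kap_i * width_i)
  if (intensity_noise > 0)
    intensity <- intensity * (1 + stats::rnorm(nrow(contour), sd = intensity_noise))

  geometry <- structure(list(contour = unname(contour), centerline = unname(centerline),
                             s = s_i, side = side_i, pole = pole_i,
                             width_local = width_i, kappa_true = kap_i,
                             width = width, L = L), class = "cell_geometry")
  list(geometry = geometry, intensity = intensity)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: L = %g um, width = %g um, %d contour points, %d centerline points\n",
              x$L, x$width, nrow(x$contour), nrow(x$centerline)))
  invisible(x)
}
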