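## Binding/unbinding kinetics: joint bleaching + termination lifetime fit,
## bound-molecule FRAP recovery, detailed balance, and the field-of-view
## simulations (escape time; apparent termination vs true unbinding).

## log-linear slope of a lifetime histogram over a step window -> per-frame
## survival q; count weights give the Poisson-motivated weighting of the
## log counts
survival_slope <- function(hist, n_range) {
  idx <- match(n_range, hist$steps)
  idx <- idx[!is.na(idx)]
  cnt <- hist$counts[idx]
  keep <- cnt > 0
  if (sum(keep) < 2L) stop("too few populated bins in the fitting window")
  n <- hist$steps[idx][keep]
  fit <- stats::lm(log(cnt[keep]) ~ n, weights = cnt[keep])
  exp(stats::coef(fit)[[2]])
}

#' Joint bleaching + termination fit of two lifetime histograms
#'
#' Observed track lengths decay per frame with survival
#' `q(tau) = (1 - p_b) * exp(-k_a * tau)`: a bleaching probability `p_b`
#' per frame shared between acquisition intervals, and an apparent
#' termination rate `k_a`. Fitting the exponential decay of two histograms
#' acquired at different intervals (least squares on log counts over the
#' step window) separates the two processes; with a single interval the
#' model has a flat direction and the fit refuses to run.
#'
#' @param hist_a,hist_b [lifetime_histogram] objects at distinct intervals.
#' @param n_range step window used for fitting (tracks of 3 to 7 steps by
#'   default).
#' @param n_boot multinomial bootstrap replicates for confidence intervals.
#' @param seed integer seed for the bootstrap.
#' @return object of class `lifetime_fit`: `p_b`, `k_a`, per-interval
#'   survivals `q`, `ci` (95% percentile bootstrap), `n_range`.
#' @export
fit_lifetime_model <- function(hist_a, hist_b, n_range = 3:7,
                               n_boot = 200L, seed = 1L) {
  stopifnot(inherits(hist_a, "lifetime_histogram"),
            inherits(hist_b, "lifetime_histogram"))
  if (isTRUE(all.equal(hist_a$tau, hist_b$tau)))
    stop("intervals are identical: p_b and k_a are not separable")
  est <- function(ha, hb) {
    q1 <- survival_slope(ha, n_range); q2 <- survival_slope(hb, n_range)
    k_a <- (log(q1) - log(q2)) / (hb$tau - ha$tau)
    p_b <- 1 - exp(log(q1) + k_a * ha$tau)
    c(p_b = p_b, k_a = k_a, q1 = q1, q2 = q2)
  }
  e <- est(hist_a, hist_b)
  ci <- NULL
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    resample <- function(h) {
      n <- sum(h$counts)
      h$counts <- as.numeric(stats::rmultinom(1, n, h$counts / n))
      h
    }
    bs <- replicate(n_boot, tryCatch(
      est(resample(hist_a), resample(hist_b))[1:2], error = function(e) c(NA, NA)))
    ci <- apply(bs, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    colnames(ci) <- c("p_b", "k_a")
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(p_b = unname(e["p_b"]), k_a = unname(e["k_a"]),
                 q = unname(e[c("q1", "q2")]),
                 tau = c(hist_a$tau, hist_b$tau), n_range = n_range, ci = ci),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("lifetime fit (steps %d-%d, intervals %g / %g s):\n",
              min(x$n_range), max(x$n_range), x$tau[1], x$tau[2]))
  cat(sprintf("  p_b = %.3f per frame, k_a = %.4f 1/s\n", x$p_b, x$k_a))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI: p_b [%.3f, %.3f], k_a [%.4f, %.4f]\n",
                x$ci[1, "p_b"], x$ci[2, "p_b"], x$ci[1, "k_a"], x$ci[2, "k_a"]))
  }
  invisible(x)
}

#' @export
coef.lifetime_fit <- function(object, ...) c(p_b = object$p_b, k_a = object$k_a)

#' Mean lifetime of the bound state
#'
#' @param k_bd unbinding rate (1/s), positive.
#' @return `1 / k_bd` in seconds.
#' @export
mean_bound_lifetime <- function(k_bd) {
  if (!is.numeric(k_bd) || any(k_bd <= 0)) stop("k_bd must be > 0")
  1 / k_bd
}

#' Fit bound-fraction recovery after bleaching
#'
#' Weighted least-squares fit of `b(t) = a1 - a2 * exp(-rate * t)` to
#' measured bound fractions; weights are inverse binomial variances of the
#' measured fractions. In a closed two-state system relaxing towards the
#' equilibrium bound fraction, the observed relaxation rate is the sum of
#' binding and unbinding rates, `rate = k_db + k_bd = k_db / b_eq`, so the
#' binding rate is recovered as `k_db = rate * a1` with the plateau `a1`
#' estimating `b_eq`. Both the raw fitted rate and `k_db` are returned. A
#' flat series (no recovery signal) is flagged as unidentifiable instead of
#' fitted.
#'
#' @param data a `frap_data` object (columns `lag`, `bound_fraction`,
#'   optionally `n`), at least 4 lags including one near zero.
#' @param weighted use inverse-variance weights.
#' @return object of class `frap_fit`: `rate` (fitted exponential rate,
#'   1/s), `k_db` (`rate * a1`, 1/s), `a1`, `a2`, standard errors, `ci`
#'   (normal 95%, for `rate`, `k_db`, `a1`, `a2`), `identifiable` flag.
#' @export
fit_frap_recovery <- function(data, weighted = TRUE) {
  stopifnot(all(c("lag", "bound_fraction") %in% names(data)))
  if (nrow(data) < 4L) stop("need at least 4 lag points")
  if (min(data$lag) > 0.1 * max(data$lag))
    warning("no lag point near t = 0; the amplitude a2 may be poorly constrained")
  b <- data$bound_fraction
  if (stats::sd(b) < 1e-6 || diff(range(b)) < 1e-6)
    return(structure(list(rate = NA_real_, k_db = NA_real_, a1 = mean(b),
                          a2 = 0, se = NULL, ci = NULL,
                          identifiable = FALSE, fit = NULL),
                     class = "frap_fit"))
  n <- if ("n" %in% names(data)) data$n else rep(100, nrow(data))
  bw <- pmin(pmax(b, 0.02), 0.98)
  wts <- if (weighted) n / (bw * (1 - bw)) else rep(1, nrow(data))
  a1_0 <- max(b); a2_0 <- max(a1_0 - b[which.min(data$lag)], 0.01)
  k_0 <- 2 / max(data$lag)
  fit <- minpack.lm::nlsLM(bound_fraction ~ a1 - a2 * exp(-rate * lag),
                           data = data, weights = wts,
                           start = list(a1 = a1_0, a2 = a2_0, rate = k_0),
                           lower = c(0, 0, 0), upper = c(1, 1, Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  k_db <- cf[["rate"]] * cf[["a1"]]
  ## delta-method s.e. for the product (covariance term from vcov)
  V <- stats::vcov(fit)
  se_kdb <- sqrt(cf[["a1"]]^2 * V["rate", "rate"] +
                 cf[["rate"]]^2 * V["a1", "a1"] +
                 2 * cf[["a1"]] * cf[["rate"]] * V["rate", "a1"])
  est <- c(rate = cf[["rate"]], k_db = k_db, a1 = cf[["a1"]], a2 = cf[["a2"]])
  ses <- c(rate = se[["rate"]], k_db = se_kdb, a1 = se[["a1"]], a2 = se[["a2"]])
  ci <- rbind(est - 1.96 * ses, est + 1.96 * ses)
  rownames(ci) <- c("2.5%", "97.5%")
  identifiable <- cf[["a2"]] > 2 * se[["a2"]]
  structure(list(rate = cf[["rate"]], k_db = k_db, a1 = cf[["a1"]],
                 a2 = cf[["a2"]], se = ses, ci = ci,
                 identifiable = identifiable, fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$identifiable)
    cat("FRAP recovery fit: no recovery signal; rate unidentifiable\n")
  else
    cat(sprintf("FRAP recovery fit: rate = %.4g 1/s, k_db = rate * a1 = %.4g 1/s (a1 = %.3f, a2 = %.3f)\n",
                x$rate, x$k_db, x$a1, x$a2))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...)
  c(rate = object$rate, k_db = object$k_db, a1 = object$a1, a2 = object$a2)

#' Unbinding rate from binding rate and bound fraction (detailed balance)
#'
#' At equilibrium the fluxes between diffusive and bound pools balance:
#' `k_bd = k_db * (1 - b) / b`.
#'
#' @param k_db binding rate (1/s).
#' @param b equilibrium bound fraction, strictly inside (0, 1).
#' @return unbinding rate `k_bd` (1/s).
#' @export
detailed_balance <- function(k_db, b) {
  if (any(k_db < 0)) stop("k_db must be >= 0")
  if (any(b <= 0 | b >= 1)) stop("b must be strictly inside (0, 1)")
  k_db * (1 - b) / b
}

#' Mean time for a bound molecule to leave the evanescent field of view
#'
#' Event-driven simulation of bound molecules switching between immobile and
#' persistent states inside a strip of width `fov_width` (the illuminated
#' band at the bottom of the cell; the orthogonal direction is unbounded).
#' Molecules start immobile at uniform positions; each persistent run moves
#' at speed `v` along a direction drawn per run; the first time the position
#' crosses the strip boundary is the escape time.
#'
#' @param k_ip,k_pi switching rates (1/s).
#' @param v persistent speed (um/s), positive.
#' @param fov_width strip width (um).
#' @param direction `"random"` (uniform angle), `"perp"` (random sign along
#'   the strip normal) or `"outward"` (always towards the nearest edge).
#' @param n number of molecules.
#' @param batches independent batches for the standard error.
#' @param max_time censoring horizon (s).
#' @param seed integer seed.
#' @return object of class `fov_escape`: `mean` (s), `se`, `times`,
#'   `censored` fraction. `k_ip = 0` returns infinite mean with a flag.
#' @export
simulate_fov_escape <- function(k_ip, k_pi, v, fov_width = 0.6,
                                direction = c("random", "perp", "outward"),
                                n = 5000L, batches = 10L, max_time = 36000,
                                seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(k_ip >= 0, k_pi >= 0, v > 0, fov_width > 0)
  if (k_ip == 0)
    return(structure(list(mean = Inf, se = NA_real_, times = numeric(0),
                          censored = 1, never_escapes = TRUE),
                     class = "fov_escape"))
  if (!is.null(seed)) set.seed(seed)
  half <- fov_width / 2
  times <- numeric(n); cens <- logical(n)
  for (i in seq_len(n)) {
    x <- stats::runif(1, -half, half)
    tt <- 0; escaped <- FALSE
    while (tt < max_time) {
      tt <- tt + stats::rexp(1, k_ip)               # immobile dwell
      if (tt >= max_time) break
      run <- if (k_pi > 0) stats::rexp(1, k_pi) else Inf
      vx <- switch(direction,
                   random = v * cos(stats::runif(1, 0, 2 * pi)),
                   perp = v * sample(c(-1, 1), 1),
                   outward = v * sign(x + stats::runif(1, -1e-12, 1e-12)))
      if (vx > 0) tc <- (half - x) / vx
      else if (vx < 0) tc <- (-half - x) / vx
      else tc <- Inf
      if (tc <= run) { tt <- tt + tc; escaped <- TRUE; break }
      x <- x + vx * run
      tt <- tt + run
    }
    times[i] <- min(tt, max_time)
    cens[i] <- !escaped
  }
  grp <- rep(seq_len(batches), length.out = n)
  bm <- tapply(times, grp, mean)
  structure(list(mean = mean(times), se = stats::sd(bm) / sqrt(batches),
                 times = times, censored = mean(cens), never_escapes = FALSE),
            class = "fov_escape")
}

#' @export
print.fov_escape <- function(x, ...) {
  if (isTRUE(x$never_escapes)) cat("field-of-view escape: never (k_ip = 0)\n")
  else cat(sprintf("field-of-view escape: mean %.1f s (se %.2f, censored %.1f%%)\n",
                   x$mean, x$se, 100 * x$censored))
  invisible(x)
}

## apparent termination rate from a simulated track set inside the field of
## view, bleaching probability known
apparent_termination_rate <- function(tracks, p_b, n_range = 3:7) {
  len <- tabulate(factor(tracks$track_id)) - 1L    # steps per track
  tau <- track_interval(tracks)
  h <- lifetime_histogram(tabulate(len + 1L, nbins = max(len) + 1L),
                          tau = tau, steps = 0:max(len))
  q <- survival_slope(h, n_range)
  -log(q / (1 - p_b)) / tau
}

#' Bound on the unbinding rate from the apparent termination rate
#'
#' Simulates bound molecules in the field of view (switching, persistent
#' motion perpendicular to the cell axis, per-frame bleaching, exponential
#' unbinding, absorbing strip edges) over a grid of candidate unbinding
#' rates, measures the apparent termination rate `k_a` of each simulated
#' lifetime distribution, and inverts the mapping at the measured `k_a`.
#' Either switching rate can be corrected to maintain a target persistent
#' fraction (`k_ip' = k_pi p/(1-p)` or `k_pi' = k_ip (1-p)/p`).
#'
#' @param kbd_grid candidate unbinding rates (1/s), increasing.
#' @param k_a_measured measured apparent termination rate (1/s).
#' @param k_ip,k_pi switching rates (1/s).
#' @param p_target optional persistent fraction to enforce.
#' @param correct which rate to adjust when `p_target` is given.
#' @param p_b bleaching probability per frame.
#' @param v persistent speed (um/s).
#' @param fov_width strip width (um).
#' @param tau frame interval of the simulated movie (s).
#' @param n_tracks simulated tracks per grid point.
#' @param mean_steps simulated maximum track duration scale (steps); tracks
#'   are terminated by bleaching/unbinding/exit well before this horizon.
#' @param n_range step window for the apparent-rate fit.
#' @param seed integer seed.
#' @return object of class `kbd_bound`: `mapping` (data frame `k_bd`,
#'   `k_a`), `k_bd_inferred` (interpolated at the measured `k_a`; NA with a
#'   warning if the grid does not bracket it), inputs.
#' @export
bound_unbinding_rate <- function(kbd_grid, k_a_measured, k_ip, k_pi,
                                 p_target = NULL,
                                 correct = c("kip", "kpi"),
                                 p_b, v = 0.014, fov_width = 0.6, tau = 12,
                                 n_tracks = 3000L, mean_steps = 60,
                                 n_range = 3:7, seed = 1L) {
  correct <- match.arg(correct)
  stopifnot(all(diff(kbd_grid) > 0), all(kbd_grid >= 0))
  if (!is.null(p_target)) {
    if (p_target <= 0 || p_target >= 1) stop("p_target must be inside (0,1)")
    if (correct == "kip") k_ip <- k_pi * p_target / (1 - p_target)
    else k_pi <- k_ip * (1 - p_target) / p_target
  }
  ka <- vapply(seq_along(kbd_grid), function(i) {
    trk <- simulate_bound_motion_tracks(
      n_tracks, v = v, k_ip = k_ip, k_pi = k_pi, sigma_loc = 0, tau = tau,
      mean_steps = mean_steps, state0 = "stationary", direction = "perp",
      k_bd = if (kbd_grid[i] > 0) kbd_grid[i] else NULL,
      p_b = p_b, fov_width = fov_width, seed = seed + i)
    apparent_termination_rate(trk, p_b = p_b, n_range = n_range)
  }, numeric(1))
  mapping <- data.frame(k_bd = kbd_grid, k_a = ka)
  k_inf <- NA_real_
  if (k_a_measured < min(ka) || k_a_measured > max(ka))
    warning("measured k_a not bracketed by the simulated grid")
  else
    k_inf <- stats::approx(ka, kbd_grid, xout = k_a_measured, ties = mean)$y
  structure(list(mapping = mapping, k_bd_inferred = k_inf,
                 k_a_measured = k_a_measured, k_ip = k_ip, k_pi = k_pi,
                 p_b = p_b, v = v, fov_width = fov_width, tau = tau),
            class = "kbd_bound")
}

#' @export
print.kbd_bound <- function(x, ...) {
  cat("apparent termination rate vs unbinding rate:\n")
  print(x$mapping, row.names = FALSE)
  cat(sprintf("measured k_a = %.4f 1/s -> inferred k_bd = %s 1/s\n",
              x$k_a_measured, format(x$k_bd_inferred, digits = 3)))
  invisible(x)
}
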