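## Bound/diffusive decomposition of high-frequency track sets:
## (a) jump-length-distribution mixture fit across lags 1..5,
## (b) distribution of single-track effective diffusion constants (D_eff).

#' Jump-length distributions over multiple lags
#'
#' For each lag `m` in `1..max_lag`, collects all displacement magnitudes
#' `|r(t + m tau) - r(t)|` (overlapping start points) from tracks with at
#' least `min_len` localizations, and bins them with a fixed bin width.
#'
#' @param tracks a [track_set].
#' @param max_lag largest lag in frame intervals.
#' @param min_len minimum number of localizations per track (4 for
#'   PAmCherry-like data, 7 for GFP-like data).
#' @param bin_width histogram bin width (um).
#' @param r_max upper edge of the histogram (um); default covers the data.
#' @return object of class `jump_length_data`: list with `edges`, per-lag
#'   `counts`, `n_jumps`, `tau`, `n_tracks`.
#' @export
jump_length_distributions <- function(tracks, max_lag = 5L, min_len = 4L,
                                      bin_width = 0.010, r_max = NULL) {
  tau <- track_interval(tracks)
  tl <- track_split(tracks)
  tl <- tl[vapply(tl, nrow, integer(1)) >= min_len]
  if (!length(tl)) stop("no tracks with at least min_len localizations")
  jumps <- lapply(seq_len(max_lag), function(m) {
    unlist(lapply(tl, function(d) {
      n <- nrow(d)
      if (n <= m) return(numeric(0))
      i <- seq_len(n - m)
      sqrt((d$x[i + m] - d$x[i])^2 + (d$y[i + m] - d$y[i])^2)
    }), use.names = FALSE)
  })
  if (is.null(r_max)) r_max <- max(unlist(jumps)) + bin_width
  edges <- seq(0, r_max + bin_width, by = bin_width)
  counts <- lapply(jumps, function(v)
    graphics::hist(v[v < max(edges)], breaks = edges, plot = FALSE)$counts)
  structure(list(edges = edges, counts = counts,
                 n_jumps = vapply(jumps, length, integer(1)),
                 tau = tau, n_tracks = length(tl)),
            class = "jump_length_data")
}

#' @export
print.jump_length_data <- function(x, ...) {
  cat(sprintf("jump_length_data: %d lags, tau = %g s, %d tracks, %s jumps\n",
              length(x$counts), x$tau, x$n_tracks,
              paste(x$n_jumps, collapse = "/")))
  invisible(x)
}

## model bin probabilities of the no-transition diffusion mixture:
## P(r in bin | lag) = sum_j f_j [exp(-lo^2/(4 s_j)) - exp(-hi^2/(4 s_j))],
## s_j = D_j * lag + sigma^2
mixture_bin_prob <- function(edges, dt, f, D, sigma) {
  lo <- edges[-length(edges)]; hi <- edges[-1]
  p <- numeric(length(lo))
  for (j in seq_along(f)) {
    ## guard: numerical-gradient probes may step just outside the box
    s <- max(D[j] * dt + sigma^2, 1e-12)
    p <- p + f[j] * (exp(-lo^2 / (4 * s)) - exp(-hi^2 / (4 * s)))
  }
  p
}

#' Fit a multi-state diffusion mixture to jump-length distributions
#'
#' Least-squares fit of binned jump-length densities, jointly over all lags,
#' to the analytical no-transition mixture
#' `P(r, dt) = sum_j f_j * r / (2 (D_j dt + sigma^2)) * exp(-r^2 / (4 (D_j dt + sigma^2)))`
#' with a shared localization error `sigma`. With `fix_bound_zero = TRUE`
#' (the default) the slowest state is pinned at `D = 0` and its fraction is
#' the bound fraction `b`. Multi-start optimization avoids local minima.
#'
#' @param data a `jump_length_data` object (at least 2 lags).
#' @param n_states 2 or 3 diffusive states (bound state included).
#' @param fix_bound_zero pin the slowest state at `D = 0`.
#' @param n_starts number of seeded optimizer restarts.
#' @param n_boot multinomial bootstrap replicates for confidence intervals
#'   (0 disables).
#' @param seed seed for restarts and bootstrap.
#' @return object of class `diffusion_fit` with elements `fractions`, `D`,
#'   `sigma`, `chi2_norm`, `n_states`, `convergence` and (if requested) `ci`.
#' @export
fit_multistate_diffusion <- function(data, n_states = 2L, fix_bound_zero = TRUE,
                                     n_starts = 10L, n_boot = 0L, seed = 1L) {
  stopifnot(inherits(data, "jump_length_data"), n_states %in% 2:3)
  if (length(data$counts) < 2L) stop("need jump-length data for at least 2 lags")
  if (all(unlist(data$counts) == 0)) stop("degenerate data: no jumps")
  edges <- data$edges
  dts <- seq_along(data$counts) * data$tau
  dens <- lapply(seq_along(data$counts), function(m) {
    n <- sum(data$counts[[m]])
    if (n == 0) stop("degenerate data: empty lag ", m)
    data$counts[[m]] / n / diff(edges)
  })
  bw <- diff(edges)

  n_mob <- n_states - 1L
  ## parameter vector: b, (split), D_1..D_nmob, sigma [, D_bound]
  unpack <- function(p) {
    b <- p[1]
    if (n_mob == 1L) { f <- c(b, 1 - b); D <- c(0, p[2]); sigma <- p[3]; i <- 4L }
    else {
      f <- c(b, (1 - b) * p[2], (1 - b) * (1 - p[2]))
      D <- c(0, p[3], p[4]); sigma <- p[5]; i <- 6L
    }
    if (!fix_bound_zero) D[1] <- p[i]
    list(f = f, D = D, sigma = sigma)
  }
  npar <- (if (n_mob == 1L) 3L else 5L) + (!fix_bound_zero)
  lower <- c(0, if (n_mob == 2L) 0, rep(1e-6, n_mob), 0, if (!fix_bound_zero) 0)
  upper <- c(1, if (n_mob == 2L) 1, rep(0.5, n_mob), 0.1, if (!fix_bound_zero) 0.05)

  obj <- function(p) {
    m <- unpack(p)
    rss <- 0
    for (k in seq_along(dens)) {
      mod <- mixture_bin_prob(edges, dts[k], m$f, m$D, m$sigma) / bw
      rss <- rss + sum((dens[[k]] - mod)^2)
    }
    rss
  }
  fit_once <- function(p0) {
    stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = 500))
  }
  run_fit <- function() {
    starts <- lapply(seq_len(n_starts), function(i)
      lower + stats::runif(npar) * (upper - lower))
    starts[[1]] <- (lower + upper) / 2
    fits <- lapply(starts, function(s) tryCatch(fit_once(s), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("multi-state diffusion fit failed to converge")
    fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  best <- run_fit()
  m <- unpack(best$par)
  ord <- order(m$D)
  f <- m$f[ord]; D <- m$D[ord]
  n_bins <- length(edges) - 1L
  chi2_norm <- best$value / (n_bins * length(dens))

  ci <- NULL
  if (n_boot > 0L) {
    nm <- c("b", paste0("D", seq_len(n_mob)), "sigma")
    bp <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
    for (bidx in seq_len(n_boot)) {
      bd <- data
      for (k in seq_along(bd$counts)) {
        n <- sum(bd$counts[[k]])
        bd$counts[[k]] <- as.numeric(stats::rmultinom(1, n, bd$counts[[k]] / n))
      }
      bf <- tryCatch(fit_multistate_diffusion(bd, n_states, fix_bound_zero,
                                              n_starts = 4L, n_boot = 0L,
                                              seed = seed + bidx),
                     error = function(e) NULL)
      if (!is.null(bf)) bp[bidx, ] <- c(bf$fractions[1], bf$D[-1], bf$sigma)
    }
    ci <- apply(bp, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  structure(list(fractions = f, D = D, sigma = m$sigma, chi2_norm = chi2_norm,
                 rss = best$value, n_states = n_states,
                 fix_bound_zero = fix_bound_zero,
                 convergence = best$convergence, ci = ci, data = data),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("%d-state diffusion mixture fit\n", x$n_states))
  for (j in seq_along(x$D))
    cat(sprintf("  state %d: f = %.3f, D = %.4f um^2/s\n", j, x$fractions[j], x$D[j]))
  cat(sprintf("  sigma = %.4f um, chi2_norm = %.3g\n", x$sigma, x$chi2_norm))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(b = unname(object$fractions[1]),
    stats::setNames(object$D[-1], paste0("D", seq_along(object$D[-1]))),
    sigma = object$sigma)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  cat("Bound fraction b =", round(object$fractions[1], 3), "\n")
  print(object)
  if (!is.null(object$ci)) { cat("bootstrap 95% CI:\n"); print(object$ci) }
  invisible(object)
}

#' @export
plot.diffusion_fit <- function(x, ...) {
  data <- x$data
  edges <- data$edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bw <- diff(edges)
  nlag <- length(data$counts)
  oldpar <- graphics::par(mfrow = c(1, nlag), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (k in seq_len(nlag)) {
    dens <- data$counts[[k]] / sum(data$counts[[k]]) / bw
    mod <- mixture_bin_prob(edges, k * data$tau, x$fractions, x$D, x$sigma) / bw
    plot(mids, dens, type = "h", xlab = "jump length (um)", ylab = "density",
         main = sprintf("lag %d", k), ...)
    graphics::lines(mids, mod, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Single-track effective diffusion constants
#'
#' For every track with at least `n_lags + 1` localizations, computes the
#' time-averaged MSD at lags `1..n_lags` and fits
#' `MSD(t) = 4 D_eff t + 4 sigma^2` by least squares; `D_eff` is the slope
#' divided by 4 and may be negative for immobile molecules.
#'
#' @param tracks a [track_set].
#' @param n_lags number of MSD lags used (default first 4 steps).
#' @return numeric vector of per-track `D_eff` (um^2/s) with attributes
#'   `tau` and `track_lengths` (numbers of localizations).
#' @export
effective_diffusion_constants <- function(tracks, n_lags = 4L) {
  tau <- track_interval(tracks)
  tl <- track_split(tracks)
  tl <- tl[vapply(tl, nrow, integer(1)) >= n_lags + 1L]
  if (!length(tl)) stop("no tracks with at least n_lags + 1 localizations")
  tvec <- seq_len(n_lags) * tau
  tc <- tvec - mean(tvec)
  sxx <- sum(tc^2)
  deff <- vapply(tl, function(d) {
    msd <- vapply(seq_len(n_lags), function(m) {
      i <- seq_len(nrow(d) - m)
      mean((d$x[i + m] - d$x[i])^2 + (d$y[i + m] - d$y[i])^2)
    }, numeric(1))
    sum(tc * msd) / sxx / 4                    # least-squares slope / 4
  }, numeric(1))
  structure(unname(deff), tau = tau,
            track_lengths = vapply(tl, nrow, integer(1)))
}

## histogram over the D_eff comparison window; bin centers at multiples of
## `bin` so that D_eff = 0 is a bin center
deff_hist <- function(deff, range = c(-0.015, 0.055), bin = 0.005) {
  centers <- seq(range[1], range[2], by = bin)
  edges <- c(centers - bin / 2, centers[length(centers)] + bin / 2)
  h <- graphics::hist(deff[deff >= edges[1] & deff < edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  list(centers = centers, prop = h$counts / length(deff))
}

#' Fit the bound fraction from the D_eff distribution by grid search
#'
#' Compares the empirical distribution of single-track effective diffusion
#' constants with simulated reference distributions `p(D_eff | D, sigma)` on
#' a (D, sigma) grid. For each grid point the bound fraction `b` is set by
#' matching the `D_eff = 0` bin of the two-component model
#' `p = b p(D_eff | 0, sigma) + (1 - b) p(D_eff | D, sigma)` to the data;
#' the grid point minimizing the residual sum of squares over the window
#' `range` is returned.
#'
#' @param deff output of [effective_diffusion_constants].
#' @param D_grid,sigma_grid grids of diffusion constant (um^2/s) and
#'   localization error (um).
#' @param range,bin comparison window and bin width for `D_eff` (um^2/s).
#' @param n_ref simulated reference tracks per grid point and component.
#' @param mean_steps mean track length used for the reference simulations
#'   when `deff` carries no track-length attribute.
#' @param seed integer seed for the reference simulations.
#' @return object of class `deff_fit`: `b`, `D`, `sigma`, `rss` (matrix over
#'   the grid), `boundary` flag.
#' @export
fit_deff_mixture <- function(deff,
                             D_grid = seq(0.015, 0.060, by = 0.005),
                             sigma_grid = seq(0, 0.040, by = 0.005),
                             range = c(-0.015, 0.055), bin = 0.005,
                             n_ref = 2000L, mean_steps = 7, seed = 1L) {
  tau <- attr(deff, "tau")
  if (is.null(tau)) stop("deff must come from effective_diffusion_constants()")
  lens <- attr(deff, "track_lengths")
  hd <- deff_hist(deff, range, bin)
  i0 <- which(abs(hd$centers) < bin / 4)
  rss <- matrix(NA_real_, length(D_grid), length(sigma_grid),
                dimnames = list(D = D_grid, sigma = sigma_grid))
  bmat <- rss
  ref <- function(D, sigma, sd) {
    trk <- simulate_tracked_population(n_ref, b = if (D == 0) 1 else 0,
                                       D = max(D, 1e-9), sigma_loc = sigma,
                                       tau = tau, steps = if (!is.null(lens)) lens - 1L else NULL,
                                       mean_steps = mean_steps, seed = sd)
    deff_hist(effective_diffusion_constants(trk), range, bin)$prop
  }
  for (si in seq_along(sigma_grid)) {
    p_imm <- ref(0, sigma_grid[si], seed + 1000L * si)
    for (di in seq_along(D_grid)) {
      p_mob <- ref(D_grid[di], sigma_grid[si], seed + 1000L * si + di)
      denom <- p_imm[i0] - p_mob[i0]
      b <- if (abs(denom) < 1e-12) 0 else (hd$prop[i0] - p_mob[i0]) / denom
      b <- min(max(b, 0), 1)
      model <- b * p_imm + (1 - b) * p_mob
      rss[di, si] <- sum((hd$prop - model)^2)
      bmat[di, si] <- b
    }
  }
  ij <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  boundary <- ij[1] %in% c(1L, length(D_grid)) || ij[2] %in% c(1L, length(sigma_grid))
  if (boundary) warning("grid minimum on the boundary; widen the (D, sigma) grid")
  structure(list(b = bmat[ij[1], ij[2]], D = D_grid[ij[1]], sigma = sigma_grid[ij[2]],
                 rss = rss, b_grid = bmat, boundary = boundary,
                 hist = hd), class = "deff_fit")
}

#' @export
print.deff_fit <- function(x, ...) {
  cat(sprintf("D_eff-distribution fit: b = %.3f, D = %.3f um^2/s, sigma = %.3f um%s\n",
              x$b, x$D, x$sigma, if (x$boundary) " (boundary minimum)" else ""))
  invisible(x)
}

#' @export
coef.deff_fit <- function(object, ...) {
  c(b = object$b, D = object$D, sigma = object$sigma)
}
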