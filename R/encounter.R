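## Brownian-dynamics target-search simulation: can freely diffusing enzymes
## sustain the physiological cross-linking rate? Optional facilitated 1D
## diffusion along filaments centered at the target sites.

#' Run the Brownian-dynamics encounter simulation
#'
#' `N` enzymes diffuse with constant `D` in a periodic rectangular domain
#' (the unrolled cylindrical cell surface); `n_sites` circular target sites
#' of diameter `a` are placed at random non-overlapping positions. Entering
#' a site disc while active registers an encounter, after which the enzyme
#' is inactive for the deterministic latency `t_off` (it keeps diffusing).
#' Re-registration at the same site requires exiting and re-entering the
#' disc. In facilitated mode a filament of length `l` oriented along y is
#' centered at every site: enzymes cannot cross filaments (a crossing step
#' attaches them at the crossing point), diffuse one-dimensionally along
#' them with the same `D`, leave at the ends, or are pushed off laterally by
#' `2 a` at rate `k_off`. The per-site encounter rate is
#' `gamma = encounters / (n_sites * T)`.
#'
#' @param N number of enzymes.
#' @param D diffusion constant (um^2/s).
#' @param domain domain size `c(Lx, Ly)` in um, periodic.
#' @param n_sites number of target sites (ignored if `sites` given).
#' @param sites optional matrix of site centers (um).
#' @param a site diameter (um).
#' @param t_off deterministic latency after an encounter (s); at least 1e-4.
#' @param dt integration step (s); the RMS step `sqrt(4 D dt)` must not
#'   exceed `a / 2`.
#' @param T simulated time (s).
#' @param facilitated enable 1D diffusion along filaments.
#' @param l filament length (um).
#' @param k_off filament detachment rate (1/s).
#' @param n_snapshots number of stored unwrapped-position snapshots (for
#'   per-axis MSD curves).
#' @param seed integer seed.
#' @return object of class `encounter_result`: `gamma` (1/s per site),
#'   `counts` per site, `run_length_hist` (table of successive encounters by
#'   one enzyme at one site, censored runs included), `msd` (data frame `t`,
#'   `msd_x`, `msd_y`), `sites`, and the configuration.
#' @export
run_encounter_simulation <- function(N = 100L, D = 0.06, domain = c(3, 3),
                                     n_sites = 10L, sites = NULL, a = 0.010,
                                     t_off = 1e-3, dt = 1e-5, T = 10,
                                     facilitated = FALSE, l = 0.5, k_off = 0,
                                     n_snapshots = 50L, seed = 1L) {
  stopifnot(N >= 1, D >= 0, length(domain) == 2L, all(domain > 0),
            a > 0, T > 0, dt > 0)
  if (t_off < 1e-4) stop("t_off must be at least 1e-4 s")
  if (D > 0 && sqrt(4 * D * dt) > a / 2)
    stop("dt too coarse: RMS step sqrt(4 D dt) exceeds a/2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sites)) {
    sites <- matrix(NA_real_, n_sites, 2)
    placed <- 0L
    while (placed < n_sites) {
      cand <- c(stats::runif(1, 0, domain[1]), stats::runif(1, 0, domain[2]))
      ok <- TRUE
      if (placed > 0L) {
        dx <- (sites[seq_len(placed), 1] - cand[1])
        dx <- dx - domain[1] * round(dx / domain[1])
        dy <- (sites[seq_len(placed), 2] - cand[2])
        dy <- dy - domain[2] * round(dy / domain[2])
        ok <- all(dx^2 + dy^2 > (2 * a)^2)     # overlapping sites re-drawn
      }
      if (ok) { placed <- placed + 1L; sites[placed, ] <- cand }
    }
  } else {
    sites <- as.matrix(sites)
    n_sites <- nrow(sites)
  }
  res <- encounter_sim_cpp(as.integer(N), D, domain[1], domain[2], sites,
                           a, t_off, dt, T, facilitated, l, k_off,
                           as.integer(n_snapshots))
  gamma <- sum(res$counts) / (n_sites * res$T)
  msd <- data.frame(t = res$snap_t,
                    msd_x = rowMeans(res$snap_x^2),
                    msd_y = rowMeans(res$snap_y^2))
  structure(list(gamma = gamma, counts = res$counts,
                 run_length_hist = table(res$run_lengths),
                 msd = msd, sites = sites,
                 config = list(N = N, D = D, domain = domain, a = a,
                               t_off = t_off, dt = dt, T = res$T,
                               facilitated = facilitated, l = l,
                               k_off = k_off, seed = seed)),
            class = "encounter_result")
}

#' @export
print.encounter_result <- function(x, ...) {
  cat(sprintf("encounter simulation: %d enzymes, %d sites, T = %g s%s\n",
              x$config$N, nrow(x$sites), x$config$T,
              if (x$config$facilitated) " (facilitated)" else ""))
  cat(sprintf("  gamma = %.3f encounters per site per second (%d encounters)\n",
              x$gamma, sum(x$counts)))
  invisible(x)
}

#' Physiological cross-linking rate from synthesis speed and spacing
#'
#' A synthesis machine moving at `speed` and forming a cross link every
#' `crosslink_spacing` along the glycan strand cross-links at rate
#' `lambda = speed / crosslink_spacing`.
#'
#' @param speed synthesis speed (um/s), e.g. 0.030.
#' @param crosslink_spacing distance between cross links (um), e.g. 0.002.
#' @return rate `lambda` in 1/s.
#' @export
crosslink_rate <- function(speed, crosslink_spacing) {
  if (any(crosslink_spacing <= 0)) stop("crosslink_spacing must be > 0")
  if (any(speed < 0)) stop("speed must be >= 0")
  speed / crosslink_spacing
}

#' Per-axis diffusion constants (displacement anisotropy)
#'
#' Estimates effective diffusion constants along and across a reference
#' axis. For an `encounter_result` the per-axis ensemble MSD curves are
#' used (`MSD_x = 2 D_x t`); for a [track_set] the per-axis MSD is pooled
#' over all frame-to-frame displacements after projecting onto the axis.
#'
#' @param x an `encounter_result` or a [track_set].
#' @param cell_axis unit vector of the reference (long) axis; default x.
#' @param ... unused.
#' @return named vector `c(D_x, D_y)` in um^2/s.
#' @export
displacement_anisotropy <- function(x, ...) UseMethod("displacement_anisotropy")

#' @rdname displacement_anisotropy
#' @export
displacement_anisotropy.encounter_result <- function(x, ...) {
  m <- x$msd[x$msd$t > 0, , drop = FALSE]
  c(D_x = unname(stats::coef(stats::lm(msd_x ~ t + 0, data = m))[1] / 2),
    D_y = unname(stats::coef(stats::lm(msd_y ~ t + 0, data = m))[1] / 2))
}

#' @rdname displacement_anisotropy
#' @export
displacement_anisotropy.track_set <- function(x, cell_axis = c(1, 0), ...) {
  if (is.null(cell_axis)) stop("cell_axis required")
  ax <- cell_axis / sqrt(sum(cell_axis^2))
  pe <- c(-ax[2], ax[1])
  tau <- track_interval(x)
  tl <- track_split(x)
  da <- dp <- numeric(0)
  for (d in tl) {
    if (nrow(d) < 2L) next
    dx <- diff(d$x); dy <- diff(d$y)
    da <- c(da, dx * ax[1] + dy * ax[2])
    dp <- c(dp, dx * pe[1] + dy * pe[2])
  }
  c(D_x = mean(da^2) / (2 * tau), D_y = mean(dp^2) / (2 * tau))
}
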