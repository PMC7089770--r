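# shared fixture builders (all fixtures are generated in code)

# pooled boundary profiles over several synthetic cells with identical
# parameters but different seeds
pool_cells <- function(n_cells = 6, seed0 = 100, length = 10, width = 1,
                       kappa = function(s) 0.25 * sin(pi * s / 2.5),
                       alpha = 0.2, bulge_amplitude = 0, n_bulges = 4,
                       intensity_noise = 0.01) {
  out <- list(I = c(), cc = c(), kappa = c(), width = c(), side = c(),
              sidewall = c(), straight = c())
  for (i in seq_len(n_cells)) {
    cl <- generate_synthetic_cell(length = length, width = width,
                                  kappa = kappa, alpha = alpha,
                                  bulge_amplitude = bulge_amplitude,
                                  n_bulges = n_bulges,
                                  intensity_noise = intensity_noise,
                                  seed = seed0 + i)
    g <- cl$geometry
    cc <- contour_curvature(g)
    kap <- contour_point_kappa(g)
    m <- region_masks(g, kappa = kap)
    out$I <- c(out$I, cl$intensity)
    out$cc <- c(out$cc, cc)
    out$kappa <- c(out$kappa, kap)
    out$width <- c(out$width, g$width_local)
    out$side <- c(out$side, g$side)
    out$sidewall <- c(out$sidewall, m$sidewall)
    out$straight <- c(out$straight, m$straight)
  }
  out$sidewall <- as.logical(out$sidewall)
  out$straight <- as.logical(out$straight)
  out
}

# render an image with 2D Gaussian spots on a constant background
render_spots <- function(nr = 64, nc = 64, centers = NULL, amplitude = 40,
                         sd_px = 1.3, background = 100, noise_sd = 2,
                         seed = 1) {
  set.seed(seed)
  img <- matrix(background, nr, nc)
  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  if (!is.null(centers)) {
    xs <- outer(rep(1, nr), 0:(nc - 1))
    ys <- outer(0:(nr - 1), rep(1, nc))
    for (i in seq_len(nrow(centers)))
      img <- img + amplitude * exp(-((xs - centers[i, 1])^2 +
                                     (ys - centers[i, 2])^2) / (2 * sd_px^2))
  }
  img
}
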