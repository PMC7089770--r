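## Spot detection, nearest-neighbour linking, localization-accuracy
## estimation. Image dialect: numeric matrix, row = y, column = x, pixel
## centers at integer 0-based coordinates, x = (col - 1), y = (row - 1);
## pixel size 65 nm by default for conversion to um.

#' Separable Gaussian blur of an image matrix
#'
#' Edge handling replicates border pixels. `sigma = 0` returns the input.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix of the same dimension.
#' @export
gauss_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur1 <- function(m) {              # along rows (down columns)
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in -r:r) out <- out + k[j + r + 1L] * mp[(1L + r + j):(n + r + j), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

## difference-of-Gaussians bandpass, clipped at zero
bandpass <- function(img, low, high) {
  pmax(gauss_blur(img, low) - gauss_blur(img, high), 0)
}

## 2D Gaussian least-squares fit on a square window; returns center (0-based
## pixel coordinates), amplitude, sd, residual ratio
fit_gaussian_2d <- function(win, x0, y0) {
  nr <- nrow(win); nc <- ncol(win)
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  bg0 <- min(win); a0 <- max(win) - bg0
  obj <- function(p) {
    mu <- p[5] + p[1] * exp(-((xs - p[2])^2 + (ys - p[3])^2) / (2 * p[4]^2))
    sum((win - mu)^2)
  }
  fit <- stats::optim(c(a0, x0, y0, 1.2, bg0), obj, method = "L-BFGS-B",
                      lower = c(1e-12, -1, -1, 0.3, -Inf),
                      upper = c(Inf, nc, nr, 10, Inf))
  p <- fit$par
  mu <- p[5] + p[1] * exp(-((xs - p[2])^2 + (ys - p[3])^2) / (2 * p[4]^2))
  list(amplitude = p[1], x = p[2], y = p[3], sd = p[4], offset = p[5],
       residual_ratio = mean(abs(win - mu)) / p[1])
}

#' Detect fluorescent spots in a single-channel image
#'
#' Candidate peaks are local maxima of the bandpass-filtered (difference of
#' Gaussians) image whose raw intensity exceeds `intensity_factor` times the
#' image background noise. Candidates closer than `nn_min` pixels to another
#' candidate are discarded, remaining peaks are refined by a 2D Gaussian fit,
#' and fits failing quality control (fit s.d. above `max_sd` pixels, or mean
#' absolute residual divided by peak amplitude above `max_residual_ratio`)
#' are removed. Optionally peaks with signal-to-local-noise below `snr_min`
#' and the brightest `drop_brightest` fraction (candidate molecule clusters)
#' are removed as well.
#'
#' @param image numeric matrix (one frame) or a list of matrices (a stack).
#' @param band_low,band_high bandpass Gaussian sigmas in pixels (noise and
#'   object scale).
#' @param intensity_factor peak threshold in units of the image background
#'   noise (median absolute deviation of the raw image).
#' @param nn_min minimum nearest-neighbour distance between candidates, px.
#' @param max_sd,max_residual_ratio Gaussian-fit quality thresholds.
#' @param snr_min optional minimum ratio of fitted amplitude to local
#'   background noise (s.d. of pixels 3-4 px from the peak).
#' @param drop_brightest fraction of brightest accepted peaks to drop (0
#'   disables).
#' @param window half-width of the Gaussian-fit window, px.
#' @param pixel_size pixel size in um.
#' @return data frame of localizations with columns `frame`, `x`, `y` (um),
#'   `x_px`, `y_px`, `intensity`, `fit_sd`, `fit_residual_ratio`.
#' @export
detect_spots <- function(image, band_low = 1, band_high = 3,
                         intensity_factor = 3.5, nn_min = 3.5,
                         max_sd = 3, max_residual_ratio = 0.2,
                         snr_min = NULL, drop_brightest = 0,
                         window = 3L, pixel_size = 0.065) {
  if (is.list(image)) {
    out <- lapply(seq_along(image), function(f) {
      d <- detect_spots(image[[f]], band_low, band_high, intensity_factor,
                        nn_min, max_sd, max_residual_ratio, snr_min,
                        drop_brightest, window, pixel_size)
      if (nrow(d)) d$frame <- f - 1L
      d
    })
    return(do.call(rbind, out))
  }
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("non-finite pixels in image")
  if (length(image) == 0L) stop("empty image")
  stopifnot(intensity_factor > 0)

  bp <- bandpass(image, band_low, band_high)
  nr <- nrow(bp); nc <- ncol(bp)
  ## strict local maxima over the 8-neighbourhood (interior pixels only)
  ok <- matrix(FALSE, nr, nc)
  ii <- 2:(nr - 1); jj <- 2:(nc - 1)
  ctr <- bp[ii, jj]
  ismax <- ctr > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (ctr > bp[ii + di, jj + dj])
  }
  ok[ii, jj] <- ismax
  noise <- stats::mad(as.numeric(image))
  thr <- intensity_factor * noise
  ok <- ok & (image - stats::median(image) > thr)
  cand <- which(ok, arr.ind = TRUE)
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      x_px = numeric(), y_px = numeric(), intensity = numeric(),
                      fit_sd = numeric(), fit_residual_ratio = numeric())
  if (nrow(cand) == 0L) return(empty)

  ## nearest-neighbour exclusion
  if (nrow(cand) > 1L) {
    dmat <- as.matrix(stats::dist(cand))
    diag(dmat) <- Inf
    keep <- apply(dmat, 1, min) > nn_min
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)

  res <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r0 <- cand[k, 1]; c0 <- cand[k, 2]
    ri <- max(1, r0 - window):min(nr, r0 + window)
    ci <- max(1, c0 - window):min(nc, c0 + window)
    win <- image[ri, ci, drop = FALSE]
    g <- fit_gaussian_2d(win, x0 = c0 - min(ci), y0 = r0 - min(ri))
    x_px <- g$x + (min(ci) - 1)        # 0-based pixel coordinates
    y_px <- g$y + (min(ri) - 1)
    if (g$sd > max_sd || g$residual_ratio > max_residual_ratio) next
    if (!is.null(snr_min)) {
      dr <- sqrt(outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+"))
      ring <- image[dr >= 3 & dr <= 4]
      if (length(ring) > 3 && stats::sd(ring) > 0 &&
          g$amplitude / stats::sd(ring) <= snr_min) next
    }
    res[[k]] <- data.frame(frame = 0L, x = x_px * pixel_size, y = y_px * pixel_size,
                           x_px = x_px, y_px = y_px, intensity = g$amplitude,
                           fit_sd = g$sd, fit_residual_ratio = g$residual_ratio)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  if (drop_brightest > 0 && nrow(out) > 1L) {
    cut <- stats::quantile(out$intensity, 1 - drop_brightest)
    out <- out[out$intensity <= cut, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Link localizations into trajectories
#'
#' Nearest-neighbour linking with a hard displacement threshold and strict
#' ambiguity termination: a localization is connected to a localization in
#' the next frame only if exactly one candidate lies within `max_disp`, and
#' that candidate is claimed by no other current track; any ambiguity
#' (several candidates, or one candidate claimed by several tracks) ends the
#' trajectories involved. Unassigned localizations start new tracks. No gap
#' closing. Default thresholds used in practice are 0.600 um at
#' `tau` = 60 ms, 0.1125 um at 1 s and 0.225 um at 3.6 s.
#'
#' @param locs data frame with columns `frame`, `x`, `y` (um).
#' @param max_disp maximum frame-to-frame displacement (um).
#' @param tau frame interval (s).
#' @param min_length minimum number of localizations per returned track.
#' @return a [track_set].
#' @export
link_localizations <- function(locs, max_disp, tau, min_length = 2L) {
  stopifnot(all(c("frame", "x", "y") %in% names(locs)), max_disp > 0)
  if (is.unsorted(locs$frame)) locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  next_id <- 1L
  active <- list()   # each: list(id, x, y)
  rows <- vector("list", 0L)
  add_row <- function(id, frame, x, y) {
    rows[[length(rows) + 1L]] <<- data.frame(track_id = id, frame = frame, x = x, y = y)
  }
  prev_frame <- NULL
  for (f in frames) {
    P <- locs[locs$frame == f, , drop = FALSE]
    if (!is.null(prev_frame) && f != prev_frame + 1L) active <- list()  # gap: all end
    if (length(active) && nrow(P)) {
      ax <- vapply(active, `[[`, numeric(1), "x")
      ay <- vapply(active, `[[`, numeric(1), "y")
      dmat <- sqrt(outer(ax, P$x, "-")^2 + outer(ay, P$y, "-")^2)  # tracks x peaks
      within <- dmat <= max_disp
      cand_per_track <- rowSums(within)
      claims_per_peak <- colSums(within)
      assigned_peak <- rep(NA_integer_, length(active))
      for (i in seq_along(active)) {
        if (cand_per_track[i] == 1L) {
          j <- which(within[i, ])
          if (claims_per_peak[j] == 1L) assigned_peak[i] <- j
        }
      }
      used <- rep(FALSE, nrow(P))
      new_active <- list()
      for (i in seq_along(active)) {
        j <- assigned_peak[i]
        if (!is.na(j)) {
          add_row(active[[i]]$id, f, P$x[j], P$y[j])
          used[j] <- TRUE
          new_active[[length(new_active) + 1L]] <- list(id = active[[i]]$id,
                                                       x = P$x[j], y = P$y[j])
        }
      }
      for (j in which(!used)) {
        add_row(next_id, f, P$x[j], P$y[j])
        new_active[[length(new_active) + 1L]] <- list(id = next_id, x = P$x[j], y = P$y[j])
        next_id <- next_id + 1L
      }
      active <- new_active
    } else if (nrow(P)) {
      active <- list()
      for (j in seq_len(nrow(P))) {
        add_row(next_id, f, P$x[j], P$y[j])
        active[[length(active) + 1L]] <- list(id = next_id, x = P$x[j], y = P$y[j])
        next_id <- next_id + 1L
      }
    } else active <- list()
    prev_frame <- f
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no localizations to link")
  len <- table(out$track_id)
  keep <- names(len)[len >= min_length]
  out <- out[out$track_id %in% keep, , drop = FALSE]
  ## renumber frames per track to start at their first appearance
  track_set(out, tau = tau)
}

#' Estimate localization accuracy from immobile tracks
#'
#' Tracks are selected as immobile when their end-to-end distance is below
#' `max_e2e` and they have at least `min_steps` steps. The per-axis
#' frame-to-frame displacements of the selected tracks have standard
#' deviation `sigma_d = sqrt(2) * sigma`; the localization accuracy
#' `sigma = sigma_d / sqrt(2)` is returned.
#'
#' @param tracks a [track_set].
#' @param min_steps minimum number of steps of a qualifying track.
#' @param max_e2e maximum end-to-end distance (um) of a qualifying track.
#' @param min_tracks minimum number of qualifying tracks; fewer is an error.
#' @return estimated localization accuracy sigma (um), with attributes
#'   `n_tracks` and `n_displacements`.
#' @export
estimate_localization_accuracy <- function(tracks, min_steps = 7L,
                                           max_e2e = 0.200, min_tracks = 20L) {
  tl <- track_split(tracks)
  disp <- list()
  n_sel <- 0L
  for (d in tl) {
    if (nrow(d) - 1L < min_steps) next
    e2e <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
    if (e2e >= max_e2e) next
    n_sel <- n_sel + 1L
    disp[[length(disp) + 1L]] <- c(diff(d$x), diff(d$y))
  }
  if (n_sel < min_tracks)
    stop(sprintf("only %d immobile tracks selected (need >= %d)", n_sel, min_tracks))
  v <- unlist(disp, use.names = FALSE)
  sigma <- stats::sd(v) / sqrt(2)
  structure(sigma, n_tracks = n_sel, n_displacements = length(v))
}
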