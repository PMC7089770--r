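## Contour/centerline curvature, boundary-intensity sampling, region masks,
## bending corrections, curvature-intensity enrichment curves, and boundary
## peak / colocalization statistics.

## circular Gaussian smoothing of a closed profile (sigma in points)
circ_gauss_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  n <- length(v)
  r <- min(max(1L, ceiling(4 * sigma)), n %/% 2)
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  idx <- outer(seq_len(n), -r:r, function(i, j) ((i + j - 1L) %% n) + 1L)
  as.numeric(matrix(v[idx], n) %*% k)
}

## open-profile Gaussian smoothing with reflected ends
open_gauss_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  n <- length(v)
  r <- min(max(1L, ceiling(4 * sigma)), n - 1L)
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  vp <- c(v[(r + 1):2], v, v[(n - 1):(n - r)])
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
}

## signed three-point (circumscribed-circle) curvature; duplicate-point
## triples give zero
curv_three_point <- function(prev, cur, nxt) {
  ax <- cur[, 1] - prev[, 1]; ay <- cur[, 2] - prev[, 2]
  bx <- nxt[, 1] - cur[, 1]; by <- nxt[, 2] - cur[, 2]
  cx <- nxt[, 1] - prev[, 1]; cy <- nxt[, 2] - prev[, 2]
  cross <- ax * by - ay * bx
  den <- sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2) * sqrt(cx^2 + cy^2)
  out <- ifelse(den > 0, 2 * cross / den, 0)
  out[!is.finite(out)] <- 0
  out
}

## TRUE if the closed polygon is counter-clockwise (positive signed area)
is_ccw <- function(P) {
  sum(P[, 1] * c(P[-1, 2], P[1, 2]) - P[, 2] * c(P[-1, 1], P[1, 1])) > 0
}

contour_matrix <- function(geometry) {
  if (inherits(geometry, "cell_geometry")) geometry$contour
  else as.matrix(geometry)
}

#' Signed contour curvature
#'
#' Three-point circumscribed-circle curvature at every contour point,
#' Gauss-filtered circularly. Positive values correspond to bulges and
#' poles, negative values to indentations, independent of the traversal
#' direction of the contour. Consecutive duplicate points are collapsed
#' before fitting (collinear or degenerate triples give curvature 0).
#'
#' @param geometry a `cell_geometry` or an n x 2 matrix of closed-contour
#'   points (um).
#' @param smooth_sigma Gaussian filter width in contour steps (2 steps, i.e.
#'   about 65 nm, by default); 0 disables smoothing.
#' @return numeric vector of curvatures (1/um), one per input contour point.
#' @export
contour_curvature <- function(geometry, smooth_sigma = 2) {
  P <- contour_matrix(geometry)
  n0 <- nrow(P)
  if (n0 < 3L) stop("need at least 3 contour points")
  dup <- c(FALSE, rowSums(abs(diff(P))) == 0)
  Q <- P[!dup, , drop = FALSE]
  n <- nrow(Q)
  if (n < 3L) stop("contour degenerate after duplicate removal")
  sgn <- if (is_ccw(Q)) 1 else -1
  prev <- Q[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- Q[c(2:n, 1), , drop = FALSE]
  craw <- sgn * curv_three_point(prev, Q, nxt)
  csm <- circ_gauss_smooth(craw, smooth_sigma)
  out <- numeric(n0)
  out[!dup] <- csm
  if (any(dup)) out[dup] <- out[which(!dup)[findInterval(which(dup), which(!dup))]]
  out
}

#' Signed centerline curvature
#'
#' Curvature of the Gauss-smoothed centerline. Positive values correspond to
#' a cell bent to the right along the direction of the centerline, negative
#' to the left.
#'
#' @param geometry a `cell_geometry` or an m x 2 matrix of ordered
#'   centerline points (um).
#' @param smooth_sigma Gaussian filter width in centerline steps.
#' @return numeric vector of curvatures (1/um), one per centerline point
#'   (ends copy their nearest interior value).
#' @export
centerline_curvature <- function(geometry, smooth_sigma = 3.5) {
  P <- if (inherits(geometry, "cell_geometry")) geometry$centerline else as.matrix(geometry)
  n <- nrow(P)
  if (n < 5L) stop("need at least 5 centerline points")
  Q <- cbind(open_gauss_smooth(P[, 1], smooth_sigma),
             open_gauss_smooth(P[, 2], smooth_sigma))
  i <- 2:(n - 1)
  ## turning right along the direction of travel = negative cross product
  k <- -curv_three_point(Q[i - 1, , drop = FALSE], Q[i, , drop = FALSE],
                         Q[i + 1, , drop = FALSE])
  c(k[1], k, k[length(k)])
}

## outward unit normals of a closed contour (central differences)
contour_normals <- function(P) {
  n <- nrow(P)
  nxt <- P[c(2:n, 1), , drop = FALSE]
  prev <- P[c(n, 1:(n - 1)), , drop = FALSE]
  tx <- nxt[, 1] - prev[, 1]; ty <- nxt[, 2] - prev[, 2]
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  sgn <- if (is_ccw(P)) 1 else -1
  cbind(sgn * ty / len, -sgn * tx / len)   # rotate tangent by -90 deg (CCW: outward)
}

## bilinear interpolation of an image at continuous 0-based pixel
## coordinates; x along columns, y along rows
bilinear <- function(img, x_px, y_px) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x_px < 0 | x_px > nc - 1 | y_px < 0 | y_px > nr - 1))
    stop("sampling point outside the image")
  x0 <- pmin(floor(x_px), nc - 2); y0 <- pmin(floor(y_px), nr - 2)
  fx <- x_px - x0; fy <- y_px - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Sample an intensity field along a (corrected) cell contour
#'
#' Each contour point is shifted by the channel-registration vector
#' `delta_r` and by `s` inward along the outward normal, then the intensity
#' is averaged over the corrected point and two flanking points `delta`
#' inward and outward along the normal (so slightly displaced boundary
#' signal is still captured).
#'
#' @param field either a vectorized function `f(x, y)` or a list
#'   `list(image = matrix, pixel_size = um, smooth_sigma = px)` (image
#'   smoothed with a Gaussian before interpolation; bilinear interpolation,
#'   pixel centers at 0-based integer coordinates).
#' @param geometry a `cell_geometry` or contour matrix (um).
#' @param delta_r registration shift `c(dx, dy)` in um.
#' @param s inward shift along the normal (um).
#' @param delta flanking-point spacing along the normal (um).
#' @return numeric vector of intensities, one per contour point.
#' @export
sample_boundary_intensity <- function(field, geometry, delta_r = c(0, 0),
                                      s = 0.140, delta = 0.065) {
  P <- contour_matrix(geometry)
  nrm <- contour_normals(P)
  pc <- cbind(P[, 1] + delta_r[1] - nrm[, 1] * s,
              P[, 2] + delta_r[2] - nrm[, 2] * s)
  pts <- list(cbind(pc[, 1] - nrm[, 1] * delta, pc[, 2] - nrm[, 2] * delta),
              pc,
              cbind(pc[, 1] + nrm[, 1] * delta, pc[, 2] + nrm[, 2] * delta))
  if (is.function(field)) {
    vals <- lapply(pts, function(q) field(q[, 1], q[, 2]))
  } else {
    img <- field$image
    if (!is.null(field$smooth_sigma) && field$smooth_sigma > 0)
      img <- gauss_blur(img, field$smooth_sigma)
    ps <- field$pixel_size
    vals <- lapply(pts, function(q) bilinear(img, q[, 1] / ps, q[, 2] / ps))
  }
  (vals[[1]] + vals[[2]] + vals[[3]]) / 3
}

#' Side-wall and straight-segment masks
#'
#' The side-wall mask removes `pole_cut` of centerline arclength from each
#' pole and `septum_cut` from the middle of the cell (potential septa); the
#' straight-segment mask additionally requires the local centerline
#' curvature magnitude to be below `straight_kappa`.
#'
#' @param geometry a `cell_geometry` (with per-contour-point centerline
#'   arclength `s` and total length `L`).
#' @param kappa centerline curvature per contour point; computed from the
#'   geometry when `NULL`.
#' @param pole_cut arclength removed from each pole (um).
#' @param septum_cut arclength removed around mid-cell (um).
#' @param straight_kappa curvature threshold (1/um).
#' @return list with logical vectors `sidewall` and `straight` (one entry
#'   per contour point; `straight` is a subset of `sidewall`).
#' @export
region_masks <- function(geometry, kappa = NULL, pole_cut = 2.0,
                         septum_cut = 0.650, straight_kappa = 0.05) {
  stopifnot(inherits(geometry, "cell_geometry"))
  s <- geometry$s; L <- geometry$L
  if (L <= 2 * pole_cut) {
    warning("cell shorter than twice the pole cut; empty side-wall mask")
    z <- rep(FALSE, nrow(geometry$contour))
    return(list(sidewall = z, straight = z))
  }
  sidewall <- s >= pole_cut & s <= L - pole_cut &
    abs(s - L / 2) >= septum_cut / 2 & !geometry$pole
  if (is.null(kappa)) kappa <- contour_point_kappa(geometry)
  straight <- sidewall & abs(kappa) < straight_kappa
  list(sidewall = sidewall, straight = straight)
}

#' Map centerline curvature to contour points
#'
#' @param geometry a `cell_geometry`.
#' @param smooth_sigma filter width passed to [centerline_curvature].
#' @return centerline curvature interpolated at each contour point's
#'   centerline arclength.
#' @export
contour_point_kappa <- function(geometry, smooth_sigma = 3.5) {
  kcl <- centerline_curvature(geometry, smooth_sigma)
  scl <- c(0, cumsum(sqrt(rowSums(diff(geometry$centerline)^2))))
  stats::approx(scl, kcl, xout = pmin(pmax(geometry$s, 0), max(scl)), rule = 2)$y
}

#' Correct contour curvature or boundary intensity for cell bending
#'
#' Cell bending contributes `-side * kappa / (1 - side * kappa * w / 2)` to
#' the contour curvature of the side walls (the offset-curve curvature of
#' the bent centerline) and a factor `(1 + alpha * side * kappa * w)` to the
#' boundary intensity, where `side` is +1 on the right and -1 on the left of
#' the centerline, so the inner face of a bend appears indented and
#' enriched. Curvature mode adds the bending term back; intensity mode
#' divides it out.
#'
#' @param values contour curvature (`mode = "curvature"`, 1/um) or boundary
#'   intensity (`mode = "intensity"`, a.u.), one per contour point.
#' @param kappa centerline curvature per contour point (1/um).
#' @param width local cell width per contour point (um).
#' @param side +1 (right of centerline), -1 (left), 0 (pole; returned
#'   unchanged).
#' @param mode `"curvature"` or `"intensity"`.
#' @param alpha intensity-bending coupling (intensity mode).
#' @return corrected values.
#' @export
correct_for_bending <- function(values, kappa, width, side,
                                mode = c("curvature", "intensity"),
                                alpha = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(kappa), length(kappa) == length(width),
            length(width) == length(side))
  if (any(abs(kappa * width) / 2 >= 1))
    stop("bending correction diverges: |kappa| * width / 2 must be < 1")
  sk <- side * kappa
  if (mode == "curvature") values + ifelse(side == 0, 0, sk / (1 - sk * width / 2))
  else {
    den <- 1 + alpha * sk * width
    if (any(den <= 0)) stop("intensity correction factor not positive")
    ifelse(side == 0, values, values / den)
  }
}

#' Curvature-intensity enrichment curve
#'
#' Intensities are normalized by their mean over the near-zero-curvature
#' anchor window `|c| < anchor` and averaged within curvature bins centered
#' on multiples of `bin_width`; bins holding less than `min_frac` of the
#' points are dropped. With the default `bin_width = 2 * anchor` the anchor
#' window coincides with the central bin, whose value is exactly 1.
#'
#' @param intensity,curvature per-contour-point values (equal length).
#' @param mask optional logical mask applied first.
#' @param bin_width curvature bin width (1/um).
#' @param min_frac minimum fraction of points per retained bin.
#' @param anchor half-width of the normalization window (1/um).
#' @return object of class `enrichment_curve`: data frame with columns
#'   `center`, `mean_intensity`, `count`; attributes `slope` (weighted
#'   least-squares slope of the binned curve) and `point_slope` (slope of
#'   the underlying point cloud).
#' @export
enrichment_curve <- function(intensity, curvature, mask = NULL,
                             bin_width = 0.1, min_frac = 0.001,
                             anchor = 0.05) {
  stopifnot(length(intensity) == length(curvature))
  if (!is.null(mask)) { intensity <- intensity[mask]; curvature <- curvature[mask] }
  if (!length(intensity)) stop("masked profile is empty")
  in_anchor <- abs(curvature) < anchor
  if (!any(in_anchor)) stop("empty normalization anchor window")
  I <- intensity / mean(intensity[in_anchor])
  ctr <- round(curvature / bin_width)
  agg <- tapply(I, ctr, mean)
  cnt <- tapply(I, ctr, length)
  keep <- cnt >= max(1, min_frac * length(I))
  d <- data.frame(center = as.numeric(names(agg)) * bin_width,
                  mean_intensity = as.numeric(agg),
                  count = as.integer(cnt))[keep, , drop = FALSE]
  d <- d[order(d$center), , drop = FALSE]
  rownames(d) <- NULL
  slope <- if (nrow(d) > 1L)
    stats::coef(stats::lm(mean_intensity ~ center, data = d, weights = d$count))[[2]]
  else NA_real_
  pslope <- if (length(unique(curvature)) > 1L)
    stats::coef(stats::lm(I ~ curvature))[[2]] else NA_real_
  structure(d, class = c("enrichment_curve", "data.frame"),
            slope = slope, point_slope = pslope,
            bin_width = bin_width, anchor = anchor)
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment curve: %d bins, slope = %.4g per (1/um)\n",
              nrow(x), attr(x, "slope")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.enrichment_curve <- function(x, ...) {
  plot(x$center, x$mean_intensity, type = "b",
       xlab = "contour curvature (1/um)", ylab = "normalized intensity", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Gaussian-curvature proxy on the cylindrical side wall
#'
#' On the side wall of a rod of width `width`, the contour curvature `c` is
#' a proxy for the Gaussian curvature: `G = 2 c / width`.
#'
#' @param c contour curvature (1/um).
#' @param width cell width (um), positive.
#' @return Gaussian curvature proxy (1/um^2).
#' @export
gaussian_curvature_proxy <- function(c, width) {
  if (any(width <= 0)) stop("width must be > 0")
  2 * c / width
}

#' Detect intensity peaks along a cell boundary
#'
#' The circular intensity profile is Gauss-smoothed, the per-cell median is
#' subtracted, and peaks are positive-valued strict local maxima. Peaks with
#' height above `noise_factor * noise_sigma` are counted towards the peak
#' density (count per um of contour).
#'
#' @param intensity per-contour-point intensity (closed profile).
#' @param contour_length total contour length (um), or a `cell_geometry`
#'   from which it is computed.
#' @param noise_sigma intensity noise level (see [noise_floor]).
#' @param noise_factor threshold in units of `noise_sigma`.
#' @param smooth_sigma Gaussian filter width in contour points.
#' @return list with `peaks` (data frame `index`, `height`), `density`
#'   (above-noise peaks per um) and `density_all` (all positive maxima
#'   per um).
#' @export
boundary_peaks <- function(intensity, contour_length, noise_sigma,
                           noise_factor = 3, smooth_sigma = 0.5) {
  if (inherits(contour_length, "cell_geometry")) {
    P <- contour_length$contour
    contour_length <- sum(sqrt(rowSums((P - P[c(2:nrow(P), 1), ])^2)))
  }
  v <- circ_gauss_smooth(intensity, smooth_sigma)
  v <- v - stats::median(v)
  n <- length(v)
  prev <- v[c(n, 1:(n - 1))]; nxt <- v[c(2:n, 1)]
  is_peak <- v > 0 & v > prev & v > nxt
  idx <- which(is_peak)
  above <- idx[v[idx] > noise_factor * noise_sigma]
  list(peaks = data.frame(index = above, height = v[above]),
       density = length(above) / contour_length,
       density_all = length(idx) / contour_length)
}

#' Pixel-noise floor of a fluorescence image
#'
#' Difference of the image filtered at two Gaussian widths isolates
#' pixel-scale noise; the standard deviation of the difference, averaged
#' over cells (or taken over the whole image), is the noise readout used to
#' threshold boundary peaks.
#'
#' @param image numeric matrix.
#' @param cells optional list of pixel-index matrices (as from `which(...,
#'   arr.ind = TRUE)`), one per cell.
#' @param sigma_small,sigma_large filter widths in px.
#' @return noise standard deviation (a.u.).
#' @export
noise_floor <- function(image, cells = NULL, sigma_small = 0.5, sigma_large = 3) {
  d <- gauss_blur(image, sigma_small) - gauss_blur(image, sigma_large)
  if (is.null(cells)) return(stats::sd(as.numeric(d)))
  mean(vapply(cells, function(ix) stats::sd(d[ix]), numeric(1)))
}

#' Per-cell Pearson colocalization of two boundary profiles
#'
#' @param profile_a,profile_b numeric vectors on the same contour, or lists
#'   of per-cell vectors.
#' @return a single correlation, or for lists a list with per-cell `r`,
#'   `median` and `mad`.
#' @export
pearson_colocalization <- function(profile_a, profile_b) {
  one <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance profile: correlation undefined")
    stats::cor(a, b)
  }
  if (is.list(profile_a)) {
    stopifnot(is.list(profile_b), length(profile_a) == length(profile_b))
    r <- mapply(one, profile_a, profile_b)
    list(r = r, median = stats::median(r), mad = stats::mad(r))
  } else one(profile_a, profile_b)
}
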