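test_that("contour curvature of a circle is 1/R with positive sign", {
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  for (R in c(0.5, 2)) {
    circ <- cbind(R * cos(th), R * sin(th))
    cc <- contour_curvature(circ)
    expect_equal(mean(cc), 1 / R, tolerance = 0.01)
    expect_true(all(abs(cc - 1 / R) / (1 / R) < 0.01))
    ## orientation-independent sign
    cc_rev <- contour_curvature(circ[nrow(circ):1, ])
    expect_equal(mean(cc_rev), 1 / R, tolerance = 0.01)
  }
})

test_that("straight and collinear segments give zero curvature", {
  ## thin rectangle: the long straight flanks have c = 0
  x <- seq(0, 5, by = 0.05)
  rect <- rbind(cbind(x, 0), cbind(5, c(0.25, 0.5, 0.75)),
                cbind(rev(x), 1), cbind(0, c(0.75, 0.5, 0.25)))
  cc <- contour_curvature(rect, smooth_sigma = 0)
  mid <- which(rect[, 2] == 0 & rect[, 1] > 1 & rect[, 1] < 4)
  expect_true(all(abs(cc[mid]) < 1e-9))
})

test_that("centerline curvature recovers the arc radius with the right sign", {
  ## arc of radius 5 bending right: kappa = +0.2
  s <- seq(0, 4, by = 0.032)
  arc_r <- cbind(5 * sin(s / 5), 5 * cos(s / 5) - 5)    # turns clockwise
  k_r <- centerline_curvature(arc_r)
  inner <- seq(15, length(k_r) - 15)
  expect_equal(mean(k_r[inner]), 0.2, tolerance = 0.02)
  ## mirrored arc bends left: kappa = -0.2
  arc_l <- cbind(arc_r[, 1], -arc_r[, 2])
  k_l <- centerline_curvature(arc_l)
  expect_equal(mean(k_l[inner]), -0.2, tolerance = 0.02)
  ## straight centerline: zero
  line <- cbind(seq(0, 3, 0.032), 0)
  expect_true(all(abs(centerline_curvature(line)) < 1e-9))
})

test_that("generator side walls carry the offset-curve curvature of the bend", {
  cell <- generate_synthetic_cell(length = 8, width = 1, kappa = 0.2,
                                  alpha = 0.2, intensity_noise = 0,
                                  contour_noise = 0, seed = 1)
  g <- cell$geometry
  cc <- contour_curvature(g)
  sw <- region_masks(g, kappa = g$kappa_true)$sidewall
  expected <- -g$side * 0.2 / (1 - g$side * 0.2 * g$width_local / 2)
  expect_lt(max(abs(cc[sw] - expected[sw])), 0.01)
  ## recovered centerline curvature matches the generator profile
  kap <- contour_point_kappa(g)
  expect_lt(max(abs(kap[sw] - 0.2)) / 0.2, 0.05)
})

test_that("boundary sampling reproduces uniform and banded fields", {
  cell <- generate_synthetic_cell(length = 6, width = 1, kappa = 0,
                                  contour_noise = 0, seed = 2)
  g <- cell$geometry
  ## uniform field: constant intensity; identity configuration = plain sampling
  u <- sample_boundary_intensity(function(x, y) rep(7, length(x)), g,
                                 s = 0.14, delta = 0.065)
  expect_true(all(abs(u - 7) < 1e-12))
  ## a field peaked a fixed depth inside the boundary is maximal when the
  ## inward shift s centers on the band
  band_depth <- 0.14
  field <- function(x, y) {
    ## distance from the straight-cell midline (y = 0): band at |y| = w/2 - depth
    exp(-((abs(y) - (0.5 - band_depth))^2) / (2 * 0.03^2))
  }
  sw <- region_masks(g)$sidewall
  vals <- vapply(c(0, 0.07, 0.14, 0.21),
                 function(s) mean(sample_boundary_intensity(field, g,
                                                            s = s,
                                                            delta = 0)[sw]),
                 numeric(1))
  expect_equal(which.max(vals), 3L)
  ## image-based sampling agrees with the functional field
  px <- 0.065
  nc <- ceiling(10 / px); nr <- ceiling(4 / px)
  xs <- outer(rep(1, nr), (0:(nc - 1)) * px)
  ys <- outer((0:(nr - 1)) * px, rep(1, nc))
  img <- 2 + 0.5 * xs
  gi <- g; gi$contour[, 1] <- g$contour[, 1] + 1.5; gi$contour[, 2] <- g$contour[, 2] + 1.5
  ii <- sample_boundary_intensity(list(image = img, pixel_size = px), gi,
                                  s = 0.1, delta = 0.065)
  fi <- sample_boundary_intensity(function(x, y) 2 + 0.5 * x, gi,
                                  s = 0.1, delta = 0.065)
  expect_equal(ii, fi, tolerance = 1e-6)
})

test_that("region masks implement the stated arclength cuts", {
  cell <- generate_synthetic_cell(length = 10, width = 1, kappa = 0,
                                  contour_noise = 0, seed = 3)
  g <- cell$geometry
  m <- region_masks(g, pole_cut = 2, septum_cut = 0.65)
  s_in <- g$s[m$sidewall]
  expect_gte(min(s_in), 2)
  expect_lte(max(s_in), 8)
  expect_true(all(s_in <= 4.675 | s_in >= 5.325))
  ## straight cell: straight mask equals the side-wall mask
  expect_equal(m$straight, m$sidewall)
  ## strongly bent cell: straight mask empty on the bend
  bent <- generate_synthetic_cell(length = 10, width = 1, kappa = 0.2,
                                  contour_noise = 0, seed = 4)
  mb <- region_masks(bent$geometry)
  expect_equal(sum(mb$straight), 0L)
  ## masks are nested
  expect_true(all(!mb$straight | mb$sidewall))
  ## short cell warns and returns empty side wall
  short <- generate_synthetic_cell(length = 3.5, width = 1, kappa = 0,
                                   contour_noise = 0, seed = 5)
  expect_warning(ms <- region_masks(short$geometry), "pole cut")
  expect_equal(sum(ms$sidewall), 0L)
})

test_that("bending corrections are exact on generator cells and identity when straight", {
  ## straight cell: both modes are the identity
  st <- generate_synthetic_cell(length = 8, width = 1, kappa = 0,
                                intensity_noise = 0, contour_noise = 0,
                                seed = 6)
  gs <- st$geometry
  cc <- contour_curvature(gs)
  z <- rep(0, length(cc))
  expect_equal(correct_for_bending(cc, z, gs$width_local, gs$side,
                                   "curvature"), cc)
  expect_equal(correct_for_bending(st$intensity, z, gs$width_local, gs$side,
                                   "intensity"), st$intensity)
  ## pure bend: corrected side-wall curvature collapses to zero and
  ## corrected intensity is uniform
  be <- generate_synthetic_cell(length = 8, width = 1, kappa = 0.2,
                                alpha = 0.2, intensity_noise = 0,
                                contour_noise = 0, seed = 7)
  gb <- be$geometry
  ccb <- contour_curvature(gb)
  kap <- contour_point_kappa(gb)
  sw <- region_masks(gb, kappa = kap)$sidewall
  ccorr <- correct_for_bending(ccb, kap, gb$width_local, gb$side, "curvature")
  expect_lt(max(abs(ccorr[sw])), 0.01)
  icorr <- correct_for_bending(be$intensity, kap, gb$width_local, gb$side,
                               "intensity", alpha = 0.2)
  expect_lt(diff(range(icorr[sw])), 1e-3)
  ## divergence guard
  expect_error(correct_for_bending(1, kappa = 2.5, width = 1, side = 1,
                                   "curvature"), "diverges")
})

test_that("enrichment curves are anchored at one and flat for uniform intensity", {
  set.seed(8)
  curv <- rnorm(5000, 0, 0.3)
  ec <- enrichment_curve(rep(2.5, 5000), curv)
  expect_equal(ec$mean_intensity[ec$center == 0], 1)
  expect_true(all(abs(ec$mean_intensity - 1) < 1e-12))
  ## low-population bins are dropped
  curv2 <- c(rnorm(5000, 0, 0.1), 5)
  ec2 <- enrichment_curve(rep(1, 5001), curv2, min_frac = 0.001)
  expect_false(any(ec2$center > 4))
  expect_error(enrichment_curve(1:5, rep(3, 5)), "anchor")
})

test_that("bending corrections remove the curvature-intensity correlation", {
  ## pure-bend cells with the default contour-noise floor
  p <- pool_cells(n_cells = 6, seed0 = 100, bulge_amplitude = 0)
  s <- function(e) attr(e, "point_slope")
  raw <- enrichment_curve(p$I, p$cc, mask = p$sidewall)
  expect_lt(s(raw), -0.02)                     # enrichment at negative c
  cc_corr <- correct_for_bending(p$cc, p$kappa, p$width, p$side, "curvature")
  ec_cc <- enrichment_curve(p$I, cc_corr, mask = p$sidewall)
  I_corr <- correct_for_bending(p$I, p$kappa, p$width, p$side, "intensity")
  ec_ic <- enrichment_curve(I_corr, p$cc, mask = p$sidewall)
  ec_st <- enrichment_curve(p$I, p$cc, mask = p$straight)
  expect_lt(abs(s(ec_cc) / s(raw)), 0.10)
  expect_lt(abs(s(ec_ic) / s(raw)), 0.10)
  expect_lt(abs(s(ec_st) / s(raw)), 0.10)
})

test_that("bulged cells keep a bending signal that the correction removes", {
  p <- pool_cells(n_cells = 6, seed0 = 200, bulge_amplitude = 0.06)
  s <- function(e) attr(e, "point_slope")
  raw <- enrichment_curve(p$I, p$cc, mask = p$sidewall)
  I_corr <- correct_for_bending(p$I, p$kappa, p$width, p$side, "intensity")
  cor_ec <- enrichment_curve(I_corr, p$cc, mask = p$sidewall)
  expect_lt(s(raw), 0)
  expect_lt(abs(s(cor_ec)), 0.2 * abs(s(raw)))
})

test_that("Gaussian-curvature proxy arithmetic", {
  expect_equal(gaussian_curvature_proxy(0.1, 1), 0.2)
  expect_equal(gaussian_curvature_proxy(0, 2), 0)
  expect_error(gaussian_curvature_proxy(0.1, 0))
  ## straight-cell side walls have near-zero Gaussian curvature proxy
  st <- generate_synthetic_cell(length = 8, width = 1, kappa = 0,
                                contour_noise = 0, seed = 9)
  sw <- region_masks(st$geometry)$sidewall
  G <- gaussian_curvature_proxy(contour_curvature(st$geometry)[sw], 1)
  expect_lt(max(abs(G)), 0.05)
})

test_that("boundary peaks are counted above the noise floor", {
  ## flat profile: no peaks
  flat <- boundary_peaks(rep(1, 300), contour_length = 10, noise_sigma = 0.1)
  expect_equal(nrow(flat$peaks), 0L)
  ## five clear bumps on a 10-um contour: density 0.5 per um
  n <- 300
  prof <- rep(0, n)
  at <- round(seq(30, 270, length.out = 5))
  for (a in at) prof <- prof + 3 * exp(-((seq_len(n) - a)^2) / (2 * 2^2))
  pk <- boundary_peaks(prof, contour_length = 10, noise_sigma = 0.2)
  expect_equal(pk$density, 0.5)
  ## bumps below the noise threshold are excluded
  weak <- boundary_peaks(0.1 * prof, contour_length = 10, noise_sigma = 0.2)
  expect_equal(nrow(weak$peaks), 0L)
})

test_that("the noise floor scales linearly with pixel noise", {
  lv <- c(1, 2, 4)
  est <- vapply(seq_along(lv), function(i) {
    set.seed(20 + i)
    img <- matrix(100 + rnorm(64 * 64, 0, lv[i]), 64, 64)
    noise_floor(img)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est[2] / est[1], 2, tolerance = 0.1)
  expect_equal(est[3] / est[2], 2, tolerance = 0.1)
  ## noise-free flat image: exactly zero
  expect_equal(noise_floor(matrix(100, 64, 64)), 0)
})

test_that("per-cell Pearson colocalization behaves on constructed profiles", {
  set.seed(30)
  a <- rnorm(200)
  expect_equal(pearson_colocalization(a, a), 1)
  b <- rnorm(200)
  expect_lt(abs(pearson_colocalization(a, b)), 0.25)
  ## circularly shifted smooth profile: r drops by a computable amount
  sm <- as.numeric(stats::filter(rnorm(200), rep(1 / 15, 15), circular = TRUE))
  shifted <- sm[c(11:200, 1:10)]
  r_obs <- pearson_colocalization(sm, shifted)
  r_brute <- cor(sm, shifted)
  expect_equal(r_obs, r_brute)
  expect_lt(r_obs, 1)
  expect_error(pearson_colocalization(a, rep(1, 200)), "zero-variance")
  ## list interface summarizes per cell
  res <- pearson_colocalization(list(a, sm), list(a, shifted))
  expect_equal(res$r[1], 1)
  expect_equal(res$median, median(res$r))
})
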