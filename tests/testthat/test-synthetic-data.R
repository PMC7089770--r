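test_that("identical seeds and configs reproduce generator output exactly", {
  a <- simulate_tracked_population(50, b = 0.3, D = 0.04, sigma_loc = 0.02,
                                   tau = 0.06, seed = 42)
  b <- simulate_tracked_population(50, b = 0.3, D = 0.04, sigma_loc = 0.02,
                                   tau = 0.06, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  m1 <- simulate_bound_motion_tracks(30, v = 0.014, k_ip = 0.03, k_pi = 0.02,
                                     seed = 7)
  m2 <- simulate_bound_motion_tracks(30, v = 0.014, k_ip = 0.03, k_pi = 0.02,
                                     seed = 7)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  c1 <- generate_synthetic_cell(seed = 3)
  c2 <- generate_synthetic_cell(seed = 3)
  expect_identical(c1$geometry$contour, c2$geometry$contour)
  expect_identical(c1$intensity, c2$intensity)
})

test_that("population generator matches Brownian and pure-noise identities", {
  ## all-bound: per-axis step s.d. is sigma * sqrt(2)
  imm <- simulate_tracked_population(300, b = 1, D = numeric(0),
                                     D_fractions = numeric(0),
                                     sigma_loc = 0.025, tau = 0.06,
                                     mean_steps = 6, seed = 1)
  steps <- unlist(tapply(imm$x, imm$track_id, diff))
  expect_equal(sd(steps), 0.025 * sqrt(2), tolerance = 0.05)
  ## all-mobile, no noise: mean squared jump = 4 D tau
  mob <- simulate_tracked_population(3000, b = 0, D = 0.04, sigma_loc = 0,
                                     tau = 0.06, mean_steps = 5, seed = 2)
  dx <- unlist(tapply(mob$x, mob$track_id, diff))
  dy <- unlist(tapply(mob$y, mob$track_id, diff))
  expect_equal(mean(dx^2 + dy^2), 4 * 0.04 * 0.06, tolerance = 0.03)
  ## invalid configs rejected
  expect_error(simulate_tracked_population(10, b = 1.2, D = 0.04))
  expect_error(simulate_tracked_population(10, b = 0.5, D = -0.01))
})

test_that("empirical jump lengths of diffusive tracks match the analytic mixture law", {
  ## independent lag-1 jumps (no localization noise) vs the closed-form
  ## magnitude distribution F(r) = 1 - exp(-r^2 / (4 D tau))
  D <- 0.04; tau <- 0.06
  trk <- simulate_tracked_population(11000, b = 0, D = D, sigma_loc = 0,
                                     tau = tau, mean_steps = 10, seed = 9)
  tl <- split(as.data.frame(trk), trk$track_id)
  jumps <- unlist(lapply(tl, function(d)
    sqrt(diff(d$x)^2 + diff(d$y)^2)), use.names = FALSE)
  jumps <- jumps[seq_len(min(length(jumps), 1e5))]
  ks <- suppressWarnings(
    ks.test(jumps, function(r) 1 - exp(-r^2 / (4 * D * tau))))
  expect_gt(ks$p.value, 0.01)
})

test_that("bound-motion generator reproduces ballistic and immobile limits", {
  ## immobile limit: zero true displacement, MSD flat at 4 sigma^2
  imm <- simulate_bound_motion_tracks(400, v = 0.014, k_ip = 0, k_pi = 0,
                                      sigma_loc = 0.025, tau = 3.6,
                                      mean_steps = 8, state0 = "immobile",
                                      seed = 4)
  expect_true(all(imm$true_state == "immobile"))
  msds <- unlist(lapply(split(as.data.frame(imm), imm$track_id), function(d) {
    if (nrow(d) < 5) return(NULL)
    single_track_msd(d, tau = 3.6)$msd[1:3]
  }))
  expect_equal(mean(msds), 4 * 0.025^2, tolerance = 0.1)
  ## ballistic limit, no noise: end-to-end distance = v * n * tau exactly
  per <- simulate_bound_motion_tracks(50, v = 0.014, k_ip = 0, k_pi = 0,
                                      sigma_loc = 0, tau = 3.6,
                                      mean_steps = 6, state0 = "persistent",
                                      direction = "x", seed = 5)
  for (d in split(as.data.frame(per), per$track_id)) {
    n <- nrow(d) - 1
    e2e <- sqrt((d$x[n + 1] - d$x[1])^2 + (d$y[n + 1] - d$y[1])^2)
    expect_equal(e2e, 0.014 * n * 3.6, tolerance = 1e-10)
  }
})

test_that("state dwell times are exponential with the configured means", {
  bm <- simulate_bound_motion_tracks(80, v = 0.014, k_ip = 0.03, k_pi = 0.02,
                                     sigma_loc = 0, tau = 3.6,
                                     mean_steps = 3000,
                                     record_dwells = TRUE, seed = 3)
  dw <- attr(bm, "dwells")
  expect_gt(length(dw$immobile), 1e4)
  expect_equal(mean(dw$immobile), 1 / 0.03, tolerance = 0.05)
  expect_equal(mean(dw$persistent), 1 / 0.02, tolerance = 0.05)
})

test_that("track lifetimes follow the per-frame survival law", {
  ## no termination: all tracks at the censoring horizon
  h0 <- simulate_track_lifetimes(0, 0, tau = 1, n_tracks = 200,
                                 max_steps = 50, seed = 1)
  expect_equal(sum(h0$counts[h0$steps < 50]), 0)
  ## pure bleaching p_b = 0.5: geometric lengths with mean q/(1-q) = 1
  h1 <- simulate_track_lifetimes(0.5, 0, tau = 1, n_tracks = 2e4, seed = 2)
  expect_equal(sum(h1$steps * h1$counts) / sum(h1$counts), 1, tolerance = 0.05)
  ## joint survival: empirical per-frame survival = (1 - p_b) exp(-k_a tau)
  p_b <- 0.3; k_a <- 0.05; tau <- 2
  h2 <- simulate_track_lifetimes(p_b, k_a, tau = tau, n_tracks = 5e4, seed = 3)
  q_true <- (1 - p_b) * exp(-k_a * tau)
  surv <- rev(cumsum(rev(h2$counts)))
  q_emp <- surv[h2$steps == 1] / surv[h2$steps == 0]
  expect_equal(unname(q_emp), q_true, tolerance = 0.02)
})

test_that("FRAP generator recovers from zero towards the equilibrium bound fraction", {
  fd <- simulate_frap_experiment(4.3e-3, b_eq = 0.22,
                                 lags = c(0, 5, 2000), n_molecules = 2000,
                                 seed = 6)
  expect_equal(fd$bound_fraction[fd$lag == 0], 0)
  expect_lt(fd$bound_fraction[fd$lag == 5], 0.05)
  expect_equal(fd$bound_fraction[fd$lag == 2000], 0.22, tolerance = 0.12)
  expect_error(simulate_frap_experiment(4.3e-3, 0.22, lags = numeric(0)))
})

test_that("synthetic cells couple boundary intensity to bending as specified", {
  ## straight cell: uniform intensity up to noise
  st <- generate_synthetic_cell(length = 6, width = 1, kappa = 0, alpha = 0.2,
                                intensity_noise = 0.02, contour_noise = 0,
                                seed = 1)
  expect_equal(sd(st$intensity) / mean(st$intensity), 0.02, tolerance = 0.3)
  ## bent cell: inner/outer mean intensity ratio (1 + akw)/(1 - akw)
  be <- generate_synthetic_cell(length = 8, width = 1, kappa = 0.2,
                                alpha = 0.2, intensity_noise = 0,
                                contour_noise = 0, seed = 2)
  g <- be$geometry
  sw <- region_masks(g, kappa = g$kappa_true)$sidewall
  inner <- mean(be$intensity[sw & g$side == 1])   # right side of a right bend
  outer <- mean(be$intensity[sw & g$side == -1])
  expect_equal(inner / outer, 1.04 / 0.96, tolerance = 1e-6)
  ## geometry invariants
  expect_error(generate_synthetic_cell(width = 1, kappa = 2.5))
  expect_true(all(g$width_local > 0))
})
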