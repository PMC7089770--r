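test_that("single-track MSD matches ballistic and noise-only closed forms", {
  tau <- 1
  d <- data.frame(x = 0.02 * (0:10), y = 0)
  msd <- single_track_msd(d, tau = tau)
  expect_equal(msd$msd, (0.02 * msd$t)^2, tolerance = 1e-12)
  fit <- fit_track_velocity(msd)
  expect_equal(fit$v, 0.02, tolerance = 1e-6)
  expect_gt(fit$r2, 0.999)
  ## noise-only track: low R2, v near zero on average
  set.seed(1)
  vs <- replicate(50, {
    dn <- data.frame(x = rnorm(12, 0, 0.025), y = rnorm(12, 0, 0.025))
    f <- fit_track_velocity(single_track_msd(dn, tau = 3.6))
    c(f$v, f$r2)
  })
  expect_lt(median(vs[1, ]), 0.008)
})

test_that("fitted speeds of persistent tracks match the simulated speed", {
  per <- simulate_bound_motion_tracks(1200, v = 0.014, k_ip = 0, k_pi = 0,
                                      sigma_loc = 0.025, tau = 3.6,
                                      mean_steps = 6, state0 = "persistent",
                                      direction = "x", seed = 2)
  vd <- velocity_distribution(per, min_steps = 4, max_steps = 10,
                              r2_min = 0.9)
  expect_gt(nrow(vd), 20)
  expect_equal(mean(vd$v), 0.014, tolerance = 0.1)
})

test_that("velocity-threshold classification separates the two motion states", {
  imm <- simulate_bound_motion_tracks(2500, v = 0, k_ip = 0, k_pi = 0,
                                      sigma_loc = 0.025, tau = 3.6,
                                      mean_steps = 3.5, state0 = "immobile",
                                      seed = 3)
  lab_i <- unlist(lapply(classify_tracks(imm, w = 4, v_thr = 0.008),
                         function(s) as.character(s$state)))
  expect_gte(mean(lab_i == "immobile"), 0.99)
  per <- simulate_bound_motion_tracks(2500, v = 0.014, k_ip = 0, k_pi = 0,
                                      sigma_loc = 0.025, tau = 3.6,
                                      mean_steps = 3.5, state0 = "persistent",
                                      direction = "x", seed = 4)
  lab_p <- unlist(lapply(classify_tracks(per, w = 4, v_thr = 0.008),
                         function(s) as.character(s$state)))
  expect_gte(mean(lab_p == "persistent"), 0.99)
})

test_that("a velocity exactly at threshold is labeled immobile", {
  tau <- 1; v_thr <- 0.008; w <- 4
  ## displacement over w steps exactly w * tau * v_thr
  d <- data.frame(x = v_thr * (0:6), y = 0)
  s <- classify_states(d, w = w, v_thr = v_thr, tau = tau)
  expect_true(all(abs(s$v - v_thr) < 1e-12))
  expect_true(all(s$state == "immobile"))
  ## just above threshold becomes persistent
  d2 <- data.frame(x = (v_thr + 1e-6) * (0:6), y = 0)
  s2 <- classify_states(d2, w = w, v_thr = v_thr, tau = tau)
  expect_true(all(s2$state == "persistent"))
  ## too-short tracks give an empty series, not an error
  expect_equal(nrow(classify_states(d[1:3, ], w = 4, tau = tau)), 0L)
})

test_that("classification is invariant under translation and rotation", {
  per <- simulate_bound_motion_tracks(60, v = 0.014, k_ip = 0.03, k_pi = 0.02,
                                      sigma_loc = 0.025, tau = 3.6,
                                      mean_steps = 10, seed = 5)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (d in head(split(as.data.frame(per), per$track_id), 10)) {
    s0 <- classify_states(d, tau = 3.6)
    xy <- as.matrix(d[c("x", "y")]) %*% t(R)
    d2 <- data.frame(x = xy[, 1] + 5, y = xy[, 2] - 3)
    s1 <- classify_states(d2, tau = 3.6)
    expect_equal(as.character(s0$state), as.character(s1$state))
  }
})

test_that("classifier calibration reproduces the chosen window and threshold", {
  cal <- calibrate_classifier(v = 0.014, sigma = 0.025, tau = 3.6,
                              mean_steps = 3.5, n_tracks = 1500,
                              w_grid = c(2L, 4L),
                              vthr_grid = c(0.004, 0.008, 0.012),
                              seed = 6)
  hit <- cal$passing[cal$passing$w == 4 &
                     abs(cal$passing$v_thr - 0.008) < 1e-9, ]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$acc_immobile, 0.99)
  expect_gte(hit$acc_persistent, 0.99)
  ## threshold above the speed collapses persistent accuracy
  cal2 <- calibrate_classifier(v = 0.014, sigma = 0.025, tau = 3.6,
                               n_tracks = 400, w_grid = 4L,
                               vthr_grid = 0.02, seed = 7)
  expect_lt(cal2$table$acc_persistent, 0.5)
})

test_that("single-step label segments merge into their flanking states", {
  lab <- c("immobile", "immobile", "persistent", "immobile", "immobile")
  s <- structure(data.frame(index = 1:5, v = 0,
                            state = factor(lab, c("immobile", "persistent"))),
                 class = c("motion_states", "data.frame"))
  r <- estimate_transition_rates(s, tau = 3.6)
  expect_equal(r$n_ip + r$n_pi, 0)            # blip removed, no transitions
  expect_equal(r$persistent_fraction, 0)
  ## a genuine two-step visit survives merging
  lab2 <- c("immobile", "immobile", "persistent", "persistent", "immobile")
  s2 <- structure(data.frame(index = 1:5, v = 0,
                             state = factor(lab2, c("immobile", "persistent"))),
                  class = c("motion_states", "data.frame"))
  r2 <- estimate_transition_rates(s2, tau = 3.6)
  expect_equal(r2$n_ip, 1L)
  expect_equal(r2$n_pi, 1L)
})

test_that("transition rates are recovered from ground-truth state series", {
  k_ip <- 0.03; k_pi <- 0.02; tau <- 3.6
  bm <- simulate_bound_motion_tracks(500, v = 0.014, k_ip = k_ip, k_pi = k_pi,
                                     sigma_loc = 0, tau = tau,
                                     mean_steps = 60, seed = 8)
  series <- lapply(split(as.data.frame(bm), bm$track_id), function(d)
    structure(data.frame(index = seq_len(nrow(d)), v = 0,
                         state = factor(d$true_state,
                                        c("immobile", "persistent"))),
              class = c("motion_states", "data.frame")))
  r <- estimate_transition_rates(series, tau = tau)
  ## frame sampling and blip merging bias the counting estimator low by
  ## O(k * tau); at tau = 3.6 s that is roughly 20%
  expect_equal(r$k_ip, k_ip, tolerance = 0.3)
  expect_equal(r$k_pi, k_pi, tolerance = 0.3)
  expect_equal(r$persistent_fraction, k_ip / (k_ip + k_pi), tolerance = 0.1)
  ## all-immobile data: k_ip = 0, k_pi undefined
  lab <- structure(data.frame(index = 1:10, v = 0,
                              state = factor(rep("immobile", 10),
                                             c("immobile", "persistent"))),
                   class = c("motion_states", "data.frame"))
  r0 <- estimate_transition_rates(lab, tau = tau)
  expect_equal(r0$k_ip, 0)
  expect_true(is.na(r0$k_pi))
})

test_that("rate estimates stabilize with increasing track counts", {
  ## the counting estimator converges to a value within the frame-sampling
  ## bias of the truth; its spread shrinks with sample size
  k_ip <- 0.03; k_pi <- 0.02
  est <- function(n, seed) {
    bm <- simulate_bound_motion_tracks(n, v = 0.014, k_ip = k_ip,
                                       k_pi = k_pi, sigma_loc = 0, tau = 3.6,
                                       mean_steps = 60, seed = seed)
    series <- lapply(split(as.data.frame(bm), bm$track_id), function(d)
      structure(data.frame(index = seq_len(nrow(d)), v = 0,
                           state = factor(d$true_state,
                                          c("immobile", "persistent"))),
                class = c("motion_states", "data.frame")))
    r <- estimate_transition_rates(series, tau = 3.6)
    c(r$k_ip, r$k_pi)
  }
  spread <- vapply(c(25, 900), function(n) {
    e <- vapply(1:6, function(s) est(n, 9 + s), numeric(2))
    mean(apply(e, 1, sd))
  }, numeric(1))
  expect_lt(spread[2], spread[1])
  big <- est(2000, 9)
  expect_equal(big[1], k_ip, tolerance = 0.3)
  expect_equal(big[2], k_pi, tolerance = 0.3)
})

test_that("average MSD of labeled segments separates the two states", {
  bm <- simulate_bound_motion_tracks(800, v = 0.012, k_ip = 0.03, k_pi = 0.02,
                                     sigma_loc = 0.025, tau = 3.6,
                                     mean_steps = 12, seed = 10)
  tau <- 3.6; sigma <- 0.025
  ## displacement over 3 frames within constant-label stretches: ballistic
  ## motion grows quadratically while immobile stays at the noise floor
  seg_disp <- function(want, lag = 3L) {
    out <- c()
    for (d in split(as.data.frame(bm), bm$track_id)) {
      s <- classify_states(d, tau = tau)
      if (nrow(s) < lag + 1) next
      i <- s$index
      lab <- as.character(s$state)
      for (k in seq_len(length(i) - lag)) {
        if (all(lab[k:(k + lag)] == want)) {
          out <- c(out, (d$x[i[k + lag]] - d$x[i[k]])^2 +
                        (d$y[i[k + lag]] - d$y[i[k]])^2)
        }
      }
    }
    mean(out)
  }
  msd_imm1 <- seg_disp("immobile", 1L)
  expect_lt(msd_imm1, 2 * 4 * sigma^2)            # flat at the noise floor
  msd_imm3 <- seg_disp("immobile", 3L)
  msd_per3 <- seg_disp("persistent", 3L)
  expect_gt(msd_per3, msd_imm3 * 3)               # grows quadratically
})

test_that("track orientations fold into [0, 90] degrees about the cell axis", {
  tau <- 3.6
  along <- track_set(data.frame(track_id = 1, frame = 0:4,
                                x = 0.01 * (0:4), y = 0), tau)
  perp <- track_set(data.frame(track_id = 1, frame = 0:4,
                               x = 0, y = 0.01 * (0:4)), tau)
  expect_equal(orientation_distribution(along, c(1, 0)), 0, tolerance = 1e-9)
  expect_equal(orientation_distribution(perp, c(1, 0)), 90, tolerance = 1e-9)
  expect_error(orientation_distribution(along, NULL))
  ## circumferential runs with angular noise peak near 90 degrees
  set.seed(11)
  rows <- do.call(rbind, lapply(1:200, function(i) {
    th <- pi / 2 + rnorm(1, 0, 10 * pi / 180)
    data.frame(track_id = i, frame = 0:4,
               x = cos(th) * 0.01 * (0:4), y = sin(th) * 0.01 * (0:4))
  }))
  ang <- orientation_distribution(track_set(rows, tau), c(1, 0))
  expect_gt(median(ang), 75)
})
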