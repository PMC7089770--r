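# rodtrack

Single-molecule tracking and binding kinetics of bacterial cell-wall
synthesis enzymes.

Rod-shaped bacteria elongate through the Rod complex, a processive
cell-wall synthesis machine (MreB, RodA, the transpeptidase PBP2, ...)
that moves circumferentially around the cell. Sparse single-particle
tracking (sptPALM) of a fluorescently tagged enzyme such as PBP2 yields
thousands of short trajectories that mix three kinds of motion: fast
diffusion in the membrane, immobile binding, and slow persistent motion
at Rod-complex speed. rodtrack turns such trajectory tables into the
quantities that characterize the enzyme's binding cycle, and ships seeded
generators for every input so that each estimator can be validated
against ground truth.

What the package computes:

- **Bound/diffusive decomposition** of high-frequency tracks, two ways:
  a joint fit of jump-length distributions over lags 1–5 to the mixture
  law *P(r, Δt) = Σⱼ fⱼ · r/(2(DⱼΔt+σ²)) · exp(−r²/(4(DⱼΔt+σ²)))* with
  the bound state pinned at *D* = 0, and a grid fit of the distribution
  of single-track effective diffusion constants (*MSD = 4 D_eff t + 4σ²*
  over the first four lags) against simulated references.
- **Motion-state classification** of low-frequency bound-molecule tracks
  by a sliding-window velocity threshold (*v(t) = |r(t+w/2) −
  r(t−w/2)|/(wτ)*), calibrated on simulations, plus per-track velocity
  fits (*MSD = v²t² + b*), orientation distributions, and
  immobile↔persistent transition rates.
- **Binding kinetics**: the joint two-interval lifetime fit separating
  per-frame bleaching *p_b* from the apparent termination rate *k_a*
  (per-frame survival *q = (1−p_b)·exp(−k_a τ)*), bound-molecule FRAP
  recovery (*b(t) = a₁ − a₂·exp(−rate·t)*), the detailed-balance relation
  *k_bd = k_db(1−b)/b*, mean escape times from the evanescent field, and
  an upper bound on the unbinding rate by inverting forward simulations.
- **Brownian-dynamics target search**: can ~100 freely diffusing enzymes
  sustain the physiological cross-linking rate *λ = v/δ* (15/s at
  30 nm/s over 2 nm)? With optional facilitated 1D diffusion along
  filaments. Compiled core (Rcpp).
- **Curvature–intensity analysis** of cell boundaries: contour and
  centerline curvature, boundary-intensity sampling, pole/septum and
  straight-segment masks, two bending-correction schemes, enrichment
  curves, boundary peak densities and per-cell colocalization.
- **Synthetic data** for all of the above: mixed Brownian/immobile
  populations, two-state switching tracks, lifetime and FRAP datasets,
  and bent rod-shaped cells with curvature-coupled boundary intensity.

## Worked example

Simulate a mixed population at a 60 ms frame interval — 22% bound, the
rest diffusing at 0.042 µm²/s with 25 nm localization error — and
decompose it again from the trajectories alone:

```r
library(rodtrack)

trk <- simulate_tracked_population(n_tracks = 5000, b = 0.22, D = 0.042,
                                   sigma_loc = 0.025, tau = 0.06,
                                   mean_steps = 6, seed = 1)
trk
#> track_set: 5000 tracks, 37827 localizations, tau = 0.06 s
#>   track length (points): median 6, range 2-56

jumps <- jump_length_distributions(trk, max_lag = 5, min_len = 4)
fit <- fit_multistate_diffusion(jumps, n_states = 2, seed = 1)
fit
#> 2-state diffusion mixture fit
#>   state 1: f = 0.227, D = 0.0000 um^2/s
#>   state 2: f = 0.773, D = 0.0417 um^2/s
#>   sigma = 0.0256 um, chi2_norm = 0.00677
```

The fit recovers the bound fraction (0.227 vs 0.22 simulated), the
diffusion constant (0.0417 vs 0.042 µm²/s) and the localization error
(25.6 vs 25 nm). `plot(fit)` overlays the fitted mixture on the binned
jump-length densities per lag.

Low-frequency tracks of bound molecules switch between immobile and
persistent states; classify them and count transitions:

```r
low <- simulate_bound_motion_tracks(n_tracks = 4000, v = 0.014, k_ip = 0.03,
                                    k_pi = 0.02, sigma_loc = 0.025,
                                    tau = 3.6, mean_steps = 8, seed = 2)
rates <- estimate_transition_rates(classify_tracks(low, w = 4, v_thr = 0.008),
                                   tau = 3.6)
rates
#> transition rates: k_ip = 0.0182 1/s (650 events / 35737 s), k_pi = 0.0131 1/s (637 events / 48470 s)
#> persistent fraction: 0.576
```

The counting estimator carries the frame-sampling bias discussed in the
methods vignette (`vignettes/rodtrack-methods.Rmd`), which also explains
every model, default and numerical choice in the package.

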