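---
title: "Models and methods behind rodtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rodtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rodtrack analyses sparse single-particle tracking (sptPALM) data of
membrane-bound bacterial enzymes — the motivating system is the
transpeptidase PBP2 of the *E. coli* Rod complex — and provides seeded
generators for every kind of input the analyses consume. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic data do and do not capture.

## Trajectory containers and units

All positions are micrometres, times are seconds, rates are 1/s. A
`track_set` is a data frame of localizations (`track_id`, `frame`, `x`,
`y`) with a frame-interval attribute `tau`; frames must be consecutive
within a track because the linker performs no gap closing.

## Bound/diffusive decomposition

High-frequency movies (`tau` around 60 ms) mix freely diffusing and bound
(immobile) molecules. Two independent decompositions are implemented.

**Jump-length mixture.** For a molecule with diffusion constant $D_j$ and
localization error $\sigma$ per coordinate, the magnitude $r$ of a
displacement over lag $\Delta t$ has density

$$P(r, \Delta t) = \sum_j f_j \frac{r}{2 (D_j \Delta t + \sigma^2)}
  \exp\!\left(-\frac{r^2}{4 (D_j \Delta t + \sigma^2)}\right),$$

the no-transition approximation: a molecule keeps its state over the lags
used (1–5 frame intervals). `fit_multistate_diffusion()` fits binned
empirical densities jointly over all lags by least squares, with the
slowest state pinned at $D = 0$ (its fraction is the bound fraction $b$)
unless `fix_bound_zero = FALSE`. Model bin masses are computed from the
closed-form CDF, not midpoint densities. Choices: bin width 10 nm
(exposed; the histogram resolution is not critical at the jump counts
involved), shared $\sigma$ across lags and states, box constraints
$f \in [0,1]$, $D \in [10^{-6}, 0.5]$, $\sigma \in [0, 0.1]$, and 10
seeded optimizer restarts (L-BFGS-B) because the 3-state objective has
local minima. The normalized residual `chi2_norm` divides the residual sum
of squares by the number of bins and the number of lags. Confidence
intervals are multinomial bootstrap (resampling histogram counts),
disabled by default.

**Effective-diffusion-constant distribution.** For every track with at
least five localizations, `effective_diffusion_constants()` fits
$\mathrm{MSD}(t) = 4 D_\mathrm{eff} t + 4\sigma^2$ to the time-averaged
MSD of the first four lags; $D_\mathrm{eff}$ may be negative for immobile
molecules, which is essential — clipping would distort the immobile peak.
`fit_deff_mixture()` compares the empirical $D_\mathrm{eff}$ histogram
(window $[-0.015, 0.055]$ µm²/s, bin 0.005, so that 0 is a bin center)
with simulated reference distributions $p(D_\mathrm{eff} \mid D, \sigma)$
on a grid ($D$ from 0.015 to 0.06 step 0.005 µm²/s, $\sigma$ from 0 to
40 nm step 5 nm by default). At each grid point the bound fraction is set
by matching the $D_\mathrm{eff} = 0$ bin of
$b\,p(\cdot \mid 0, \sigma) + (1-b)\,p(\cdot \mid D, \sigma)$
to the data, and the grid point with the lowest residual sum of squares
wins. Reference simulations resample the observed track-length
distribution so that the per-track estimator noise is matched. A boundary
minimum triggers a warning rather than silent acceptance.

The two methods agree on $b$ to within a few percentage points on common
synthetic data; the package tests assert agreement within 0.05.

## Motion-state classification of bound molecules

Low-frequency movies (`tau` = 3.6 s) show bound molecules either immobile
or moving persistently at Rod-complex speed (10–40 nm/s).
`classify_states()` computes the smoothed local velocity
$v(t) = |r(t + w/2) - r(t - w/2)| / (w\tau)$ and labels a time point
persistent when $v(t)$ strictly exceeds `v_thr`; the tie goes to immobile
(the threshold definition leaves the equality case open; immobile is the
conservative choice). The window is even so the two probe points are
symmetric about $t$; evaluated points therefore exclude $w/2$ steps at
each track end. `calibrate_classifier()` reproduces the parameter choice
on simulations: with speed 14 nm/s, localization noise 25 nm and
exponential track lengths of mean 3.5 steps, the combination $w = 4$,
`v_thr` = 8 nm/s classifies over 99% of evaluated points correctly in both
classes. The closed-form expectation makes the numbers transparent: for
immobile tracks $v(t)$ is Rayleigh with scale
$\sigma\sqrt{2}/(w\tau) \approx 2.5$ nm/s, so the misclassification
probability is $\exp(-(v_\mathrm{thr} w \tau)^2 / (4\sigma^2)) \approx
0.005$.

`estimate_transition_rates()` counts label transitions after absorbing
intermittent single-time-step segments into their flanking states
(segments at series ends are not intermittent and are kept), and divides
by the dwell time in the source state. Two biases are inherent to this
counting estimator and documented rather than corrected, because the
estimator definition is part of the method: frame sampling misses
within-frame double flips, and blip merging removes genuine one-frame
visits. At `tau` = 3.6 s and rates of 0.02–0.03 1/s both effects together
bias the rates low by roughly 20%; the tests assert recovery within 30%
on ground-truth labels.

`fit_track_velocity()` fits the quadratic MSD law
$\mathrm{MSD}(t) = v^2 t^2 + b$ per track; persistent tracks are
conventionally selected at $R^2 \ge 0.9$ with 4–10 steps (the upper cap
avoids enrichment of slow molecules that stay in the evanescent field
longer).

## Binding kinetics

**Lifetime model.** Observed track lengths terminate each frame with
survival $q(\tau) = (1 - p_b)\,e^{-k_a \tau}$: bleaching with probability
$p_b$ per frame plus an apparent termination rate $k_a$ (unbinding plus
persistent exit from the evanescent field). A single interval cannot
separate the two (the likelihood has a flat direction), so
`fit_lifetime_model()` requires two histograms at distinct intervals
(1 s and 12 s in practice) sharing $p_b$. Each histogram contributes a
log-linear slope over the step window 3–7 (count-weighted least squares,
the Poisson-motivated weighting; an unweighted fit is unbiased but has
three times the variance), and the two slopes solve for $p_b$ and $k_a$
in closed form. Uncertainty is multinomial bootstrap.

**Bound-molecule FRAP.** After bleaching every fluorophore in the field
of view, the measured bound fraction recovers as unbleached diffusive
molecules bind. The generator simulates the two-state occupancy
mechanistically (binding at $k_{db}$, unbinding at
$k_{bd} = k_{db}(1-b_{eq})/b_{eq}$, molecules starting diffusive), so the
fitting stage is tested against a process it does not assume.
`fit_frap_recovery()` fits $b(t) = a_1 - a_2 e^{-\mathrm{rate}\, t}$ by
weighted least squares (inverse binomial variance). In a closed two-state
system the fitted relaxation rate is the *sum* $k_{db} + k_{bd} =
k_{db}/b_{eq}$, so the binding rate is reported as
$k_{db} = \mathrm{rate} \times a_1$, with the plateau $a_1$ estimating
$b_{eq}$; both the raw rate and $k_{db}$ are returned, with a
delta-method interval for the product. A flat series is flagged
unidentifiable instead of fitted.

**Detailed balance.** `detailed_balance()` is the equilibrium flux
balance $k_{bd} = k_{db}(1-b)/b$; with $k_{db} = 4.3\times10^{-3}$ 1/s and
$b = 0.22$ it gives about 0.015 1/s, i.e. a mean bound lifetime around a
minute.

**Field-of-view simulations.** `simulate_fov_escape()` is event-driven
(exact exponential dwells, analytic strip-crossing times within a
persistent run), so no integration step is involved. The illuminated
region is a strip: escape happens through the coordinate across the
strip; the orthogonal direction is unbounded. Direction conventions are
explicit (`"random"` uniform angle, `"perp"` a random sign across the
strip, `"outward"` towards the nearest edge) because the closed-form
means differ: with uniform starts, always-persistent motion gives
$W/(4v)$ outward and $W/(2v)$ with a random sign.
`bound_unbinding_rate()` maps candidate unbinding rates to apparent
termination rates by forward simulation (switching, perpendicular
persistent motion, per-frame bleaching, absorbing strip edges), then
inverts the monotone mapping at the measured $k_a$; either switching rate
can be adjusted to hold a target persistent fraction
($k_{ip}' = k_{pi}\,p/(1-p)$ or $k_{pi}' = k_{ip}(1-p)/p$). The forward
tracks carry a long length horizon (mean 60 steps) so the horizon
contributes a negligible extra termination rate, identical across the
grid, and the inversion is self-consistent by construction.

## Brownian-dynamics target search

`run_encounter_simulation()` integrates overdamped Brownian motion
(per-axis Gaussian steps of s.d. $\sqrt{2 D\,dt}$) of $N$ enzymes in a
periodic rectangle — the unrolled cylindrical cell surface — with
circular target sites of diameter $a$ = 10 nm. Entering a site disc while
active registers an encounter; the enzyme then stays inactive for the
deterministic latency `t_off` but keeps diffusing. Defaults: $N = 100$,
$D = 0.06$ µm²/s, 3 µm × 3 µm, 10 sites, `dt` = $10^{-5}$ s (RMS step
1.5 nm, enforced to stay below $a/2$), latency at least $10^{-4}$ s (the
time to explore an enzyme-sized area).

One numerical point deserves emphasis. A pure threshold rule
("re-registration requires exiting and re-entering the disc") makes the
registered count grow without bound as `dt` shrinks, because the number
of boundary re-crossings of a Brownian path diverges with resolution.
Registration therefore uses hysteresis: after an encounter, the same site
re-arms only once the enzyme has moved one site diameter away from the
site center. The diameter is the enzyme-size scale that also motivates
the latency floor; with it, the encounter rate is robust to `dt` and the
per-site rate stays below the physiological cross-linking rate
$\lambda = v/\delta = 15$ 1/s (30 nm/s over 2 nm) by a factor of three or
more. The rate still declines severalfold as the latency grows from
$10^{-4}$ to $10^{-1}$ s — a weak dependence compared with the
exponential suppression of rebinding in three-dimensional geometries, but
not a flat curve.

In facilitated mode a filament of length $l$ along $y$ is centered at
every site. Enzymes cannot cross filaments: a step whose segment crosses
one attaches the enzyme at the crossing point (deterministic on contact).
On the filament the enzyme diffuses one-dimensionally with the same $D$,
leaves at the ends, or is displaced off laterally by $2a$ at rate
`k_off`. Facilitation raises the encounter rate and makes diffusion
anisotropic ($D_y > D_x$), which is the observable the mode exists to
produce.

Successive-reaction runs (consecutive encounters of one enzyme at one
site, uninterrupted by a different site) are recorded; runs still open at
the end of the simulation are counted as censored run lengths.

## Cell-contour curvature and boundary intensity

Contour curvature uses the circumscribed circle of each point and its two
neighbours, with the sign arranged so bulges and poles are positive and
indentations negative regardless of traversal direction; the raw values
are Gauss-filtered circularly with $\sigma$ = 2 contour steps (about
65 nm). Centerline curvature smooths the coordinates at $\sigma$ = 3.5
steps first and is signed positive for cells bent to the right of the
direction of travel. Curvature at duplicate contour points is defined by
collapsing the duplicates first.

Boundary intensity sampling shifts each contour point by a
channel-registration vector and a fixed distance $s$ = 140 nm inward
along the outward normal, then averages interpolations at the corrected
point and ±65 nm along the normal. The registration vector defaults to
zero for synthetic data; the microscope-specific value belongs to the
instrument, not the method.

Masks: 2 µm of centerline arclength is removed at each pole (segmentation
software misplaces poles often enough that a generous cut is safer) and
650 nm around mid-cell (potential septa); the straight-segment mask
additionally requires $|\kappa| < 0.05$ 1/µm.

**Bending corrections.** On the side wall of a cell whose centerline has
curvature $\kappa$, the bending contribution to contour curvature is the
offset-curve value $-s_i\kappa/(1 - s_i\kappa w_i/2)$ with $s_i = \pm 1$
the side label; `correct_for_bending(mode = "curvature")` adds the term
back, which cancels the bend exactly on both sides of an ideal bent rod.
Note the side sign appears in the denominator too — with it only in the
numerator the outer wall retains an $O((\kappa w)^2)$ residual that would
defeat the correction's own purpose. Intensity mode divides by
$(1 + \alpha s_i \kappa_i w_i)$, removing a linear coupling of boundary
intensity to bending with coefficient $\alpha \approx 0.2$. The side
label is computed from the cross product of the centerline tangent and
the point's normal offset.

`enrichment_curve()` normalizes intensity by its mean over
$|c| < 0.05$ 1/µm, bins curvature in 0.1 1/µm bins centered on multiples
of the bin width (so the anchor window is exactly the central bin, whose
value is 1 by construction), and drops bins holding less than 0.1% of the
points. The curve carries two slopes: the count-weighted slope of the
binned means and the slope of the underlying point cloud; tests use the
point slope, which is insensitive to binning.

## The synthetic-data generators

The generators define the study conditions and are first-class, tested
code:

- `simulate_tracked_population()`: immobile plus Brownian states,
  isotropic Gaussian localization noise on every point (including the
  first), rounded-exponential track lengths of mean 3.5 steps with
  zero-step draws redrawn, ground-truth state per track.
- `simulate_bound_motion_tracks()`: a continuous-time two-state process
  (exponential dwells at `k_ip`, `k_pi`) sampled at the frame interval;
  persistent runs move at constant speed along +x (the calibration
  convention), a uniform random direction, or a random sign across the
  field of view; optional per-frame bleaching, exponential unbinding and
  absorbing strip edges. Completed dwell times can be returned for
  distribution checks.
- `simulate_track_lifetimes()`: geometric lengths with per-frame survival
  $(1-p_b)e^{-k_a\tau}$.
- `simulate_frap_experiment()`: mechanistic two-state occupancy, binomial
  sampling of the measured bound fraction.
- `generate_synthetic_cell()`: a bent rod with hemispherical poles built
  from a centerline curvature profile (right-positive convention,
  contour well-defined only while $|\kappa| w/2 < 1$), intensity
  $I_0 (1 + \alpha s_i \kappa_i w_i)$ with multiplicative noise, optional
  curvature-neutral Gaussian bulges/indentations of the local half-width,
  and sub-pixel contour jitter (2 nm by default) applied along the
  normals. The jitter mimics the curvature noise floor of real segmented
  contours; without it an ideal bent rod has zero curvature variance
  after correction and enrichment slopes become ratios of noise.

What the generators do not emulate: fluorophore blinking (only per-frame
bleaching), defocus and depth effects of the evanescent field (the field
of view is a binary strip), realistic point-spread-function rendering,
three-dimensional membrane geometry, and motion during camera exposure.
Passing tests on these data therefore validate the estimators under the
stated statistical models, not the upstream imaging chain.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes on one core: classifier accuracy on
10,000 tracks per class, mixture fits on a few thousand tracks, lifetime
fits on 30,000 tracks per interval, Brownian dynamics for 5–10 simulated
seconds at `dt` = $10^{-5}$ s with the encounter rate averaged over four
independent site placements, and six pooled synthetic cells per
enrichment analysis. All stochastic stages take explicit integer seeds.

## Known limitations

- The jump-length model ignores state transitions within the lag window;
  at the default lags and measured rates the approximation is standard
  practice, but it biases fits for fast-exchanging systems.
- The transition-rate estimator carries the frame-sampling bias discussed
  above.
- The curvature correction assumes locally circular bending and breaks
  down as $\kappa w \to 2$ (a guard raises an error well before).
- The encounter simulation treats target sites as static and enzymes as
  non-interacting points.
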