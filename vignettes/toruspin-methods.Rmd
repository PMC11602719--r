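---
title: "Tracking and modelling the grid-cell attractor state on the twisted torus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and modelling the grid-cell attractor state on the twisted torus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toruspin)
```

## The model

Grid cells in the medial entorhinal cortex fire at the vertices of a
hexagonal spatial lattice. An idealized grid cell is the sum of three plane
waves with unit wavevectors at 0, 60 and 120 degrees,
$r_i(\vec x) = \sum_{a=1}^{3}\cos(\vec k_a\cdot\vec x - \phi_a^i)$,
so each cell of a module is identified by its phase triplet
$(\phi_1,\phi_2,\phi_3)$, which carries only two degrees of freedom because
$\vec k_1+\vec k_3=\vec k_2$ forces $\phi_3=\phi_2-\phi_1 \pmod{2\pi}$.
On a one-dimensional track running at slice angle $\gamma$ through the
lattice, the three wavevectors project to three scalar spatial frequencies
$f_a = F\cos(\gamma - \{0,60,120\}^\circ)$ with $F = 100/\lambda$ cycles per
metre for a grid scale of $\lambda$ cm; those are the three peaks the
spectral classifier looks for.

The joint activity of a module is summarized by a bump on a twisted torus:
the periodic sheet spanned by $(\theta_1,\theta_2)$ with
$\theta_1=\psi_1-\psi_2/2$, $\theta_2=(\sqrt3/2)\,\psi_2$ and lattice
generators $(2\pi, 0)$ and $(-\pi,\sqrt3\pi)$. The package tracks the bump
as the rate-weighted circular mean of the cell phases,
$\psi_a(x)=\operatorname{atan2}\big(\sum_i \sin(\phi_a^i)r_i(x),
\sum_i \cos(\phi_a^i)r_i(x)\big)$.

The dynamical model drives the bump as

$$\frac{d\vec\theta}{dx} = \vec v(\gamma) +
  \sum_i \alpha_i\, d(\vec\rho_i, \vec\theta)\, F(p_i - x),$$

where $|\vec v| = (\sqrt3/2)\,2\pi/\lambda$ sheet-radians per cm (one torus
revolution per $\lambda$ cm along each lattice axis), $d(\cdot,\cdot)$ is
the minimal-image displacement on the twisted torus, $F$ is a boxcar
covering the 50 cm leading up to landmark $i$, $\rho_i$ is the landmark's
pinning phase, and $\alpha_i$ its strength (per cm). In darkness the slice
angle $\gamma$ performs a Gaussian random walk with variance
$D\cdot\mathrm{distance}$; with visual input the angle is held by landmarks
and optic flow, and pinning supplies the distortion instead. That split is
what makes landmark blocks stable trial after trial while dark running
drifts diffusively — the behaviour both halves of the analysis assume.

### What the generator emulates, and what it does not

The synthetic sessions reproduce the statistical structure the analyses
rely on: Poisson spiking around an idealized bump code, diffusive dark
drift at $D = 1.16\ \mathrm{deg^2\,m^{-1}}$, weak landmark pinning,
50 Hz behaviour traces with anticipatory and consummatory licking, and the
three track designs (build-up, random-environment, hidden-reward, with the
hidden-reward blocks A,B,C,dark,C,B,A and 35-cm shifts). They do *not*
contain conjunctive or non-grid cells by default (those are constructed
explicitly in tests), theta-rhythmic spike timing, slow rate drift,
behavioural speed variation, or recording artifacts. Passing tests
therefore validate the estimators against the model's own assumptions, not
against every failure mode of real recordings.

## Numerical choices that matter

* **Integration.** Forward stepping in travelled distance with 2-cm steps
  (the analysis bin width). The pinning pull uses the exact relaxation
  factor $1-e^{-\alpha\,\Delta x}$ per step rather than the raw Euler term
  $\alpha\,\Delta x$; the two agree to first order, but the exponential form
  stays stable for arbitrarily strong pins.
* **Trailing distance.** The pull $\alpha\,d(\rho,\theta)$ must balance the
  drive $|\vec v|$, so a pinned bump trails its attractor by
  $\approx|\vec v|/\alpha$ radians. Two consequences: the bump position at
  a landmark passage is *not* $\rho_i$ but $\rho_i$ plus the lag, and the
  passage-centroid estimator of $\rho_i$ inherits that bias. `refine_pins()`
  removes it by simulating the fitted model on the held-in blocks and
  shifting each $\hat\rho_i$ by the discrepancy between observed and
  model-predicted passage centroids (a fixed-point iteration on the moment
  condition). The strength $\alpha_i$ is estimated directly from the
  observed trajectory: within one landmark's window the pull relaxes toward
  a fixed target, so consecutive bump steps obey
  $\Delta\mathrm{step} = -(1-e^{-\alpha\,\Delta x})\,\mathrm{step}$,
  and regressing step differences on steps recovers $\alpha$ per landmark
  without knowing $\rho$ or the drive velocity. The stability-based affine
  map of `fit_pins()` (cross-environment correlation of the landmark-
  anchored code, scaled into $[0,\alpha_{max}]$) provides the
  initialization and the qualitative ordering.
* **Pin-strength regime.** The default generator strength
  (`pin_alpha = 0.05` per cm, ~92% gap closure per 50-cm window) places lit
  blocks in the entraining regime: each block settles onto a trial-periodic
  orbit, which is what produces one-shot remapping, whole-number winding
  and high within-block map stability. Much weaker pins
  (≲ 0.015 per cm) can instead settle onto multi-trial limit cycles —
  the minimal-image pull switches lattice images from lap to lap — an
  interesting regime of the model, but not the condition the analyses
  assume, so it is not the default.
* **Spectral estimation.** Rates are z-scored and cut into boxcar segments
  (default 1,600 two-cm bins = 32 m, stepped every 4 m). Boxcar windows keep
  the phase estimate identical to the plain windowed Fourier integral
  $\hat\phi_a = \arg\int e^{+i2\pi x\hat f_a} r(x)\,dx$, whose sign
  convention is fixed so that $r(x)=\cos(2\pi\hat f_a x - \phi)$ returns
  $\phi$; positions are absolute, so phases from different windows combine
  by a circular mean. Zero-occupancy bins are linearly interpolated before
  z-scoring because the spectral pipeline needs gapless series.
* **Module clustering.** K-means (10 restarts, fixed seed) on z-scored,
  window-averaged PSD vectors; a cluster is accepted as a module only if
  the mean pairwise spectrogram correlation of its members exceeds 0.3.
  Window-averaged features are the default (concatenated windows are
  available) because they are stable at small session sizes.
* **Diffusion estimator.** The slice angle is measured over 4-m spans of
  the unwrapped trajectory. A span-averaged angle of a diffusing direction
  satisfies $\mathrm{Var}[A(x+c)-A(x)] = D\,(c-\mathrm{span}/3)$; the
  estimator pools squared differences over the first lags and fits $D$
  through the origin of that relation, which makes it unbiased (verified
  across generating values 0.5–2.0 deg²/m). Measurement noise in the bump
  adds a positive offset at all lags that a through-origin fit cannot
  remove; the latent-trajectory fit is therefore the reference, and
  spike-level estimates are expected to run slightly high.
* **Curvature.** The printed planar-curvature numerator is implemented as
  $\theta_1'\theta_2''-\theta_2'\theta_1''$ with central differences after
  a 3-bin boxcar (curvature is noise-amplifying; the width is exposed).
* **Circular–linear decoder.** Least squares onto
  $\cos(2\pi x/L), \sin(2\pi x/L)$ with a tiny ridge ($10^{-6}$) for
  conditioning; the atan2 argument order is fixed by requiring that
  noiseless data decode to themselves. At least two modules are required
  for uniqueness on tracks longer than one period; the decoding experiments
  use three (scales 50, 70.7, 100 cm, the $\sqrt2$ ladder).
* **Plastic readout.** The downstream decoder potentiates toward the cells
  active at rewarded licks, $w \leftarrow w + \eta\,r(x)\,l(x)$ with
  consummatory lick counts $l(x)$ and $\eta=1$. Potentiation alone can
  never unlearn: with an idealized code whose post-shift tuning is an exact
  translate of the pre-shift tuning, the old weights' drive persists and
  the argmax prediction flips only after roughly as many trials as the
  pre-shift block contained. The behavioural-timescale plasticity this
  readout models is bidirectional — new induction depresses previously
  potentiated synapses — so each rewarded lick also scales existing
  weights by $(1-0.05)$. Setting $\eta=0$ knocks out both terms. The
  readout is a logistic function of the standardized drive; the predicted
  lick location is the argmax (a first-threshold-crossing variant is also
  returned), computed after a light spatial smoothing of the drive, since
  a biological readout integrates neighbouring positions rather than
  single 2-cm bins.
* **Unwrapping.** Per 5-trial window, a grid of global phase-origin shifts
  is tried, each candidate is unwrapped and scored by the across-trial
  variance of the within-trial trajectory, and the best origin is kept;
  windows are stitched by congruent continuation. Stationary periods
  (speed below 2 cm/s) can be masked out of trajectory statistics.

## Design decisions that were genuinely open

* The session container is an in-memory R list with plain-text export
  (CSV event tables, JSON configuration); all analyses operate on it
  directly and the pipeline writes its artifacts as text.
* `sigma_l^2` (pinning dispersion) uses the squared minimal-image
  Euclidean distance about the circular mean on the twisted torus.
* The per-trial landmark offset of the hidden-reward task exists to defeat
  dead-reckoning in animals; the decoding experiments run with the offset
  disabled so that predictions and the reward zone live in one coordinate
  frame. The reward zone is fixed at 160–170 cm with the automatic reward
  at the zone end.
* `lick_near`/`lick_far` rates are per unit distance (the task is
  distance-binned); a per-time variant would only rescale both rates
  equally at constant speed.
* Consummatory licks are licks after reward delivery on that trial, in or
  just past the reward zone; only non-consummatory licks enter the
  licking-error and anticipation metrics.
* Simulation problem sizes used throughout the tests and the acceptance
  analyses — e.g. 100 dark sessions of 100 m, 64 cells per module,
  12-environment sessions at 48 cells, 40-trial shift blocks — are desk
  scale re-creations of the study conditions chosen so the estimators'
  sampling error is well below the tolerances being asserted.

## Known limitations

* The bump is simulated directly; there is no spiking attractor network,
  so network-level phenomena (e.g. bump deformation) are out of scope.
* Phase estimates are identifiable only up to a global origin and a sign
  per slice frequency (negative projected frequencies appear at $|f_a|$
  with conjugated phase); all downstream geometry is invariant to this,
  and tests compare relative phases.
* The passage-centroid/lag-correction estimator assumes a single pinning
  phase per landmark and windows that are at least partially isolated;
  on very short tracks where all windows overlap everywhere, $\rho$ is
  only identified up to the overlap mixture, and held-out predictivity —
  not parameter recovery — is the meaningful score there.
* The 2D grid score uses annulus radii from the first autocorrelogram
  trough (outer radius 4x), and a smoothed random walk as the foraging
  model; it is a classification utility, not a full open-field analysis
  suite.

## A small worked example

```{r example, eval = FALSE}
track <- make_track("build_up")
params <- sim_params(n_cells_per_module = 32, grid_scales_cm = c(50, 70.7))
session <- simulate_session(track, params, seed = 1)
rm <- compute_ratemap(session)
modules <- classify_gridcells(session, k = 5, seed = 1)
rates <- population_rates(rm, modules[[1]]$unit_ids)
bump <- bump_com(rates, modules[[1]]$phases)
unw <- unwrap_trajectory(bump$psi, bins_per_trial = 160)
anisometry(unw$theta_unwrapped, mask = bump$mask)
```
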