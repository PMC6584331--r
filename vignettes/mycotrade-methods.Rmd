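---
title: "Methods: quantifying quantum-dot-tagged phosphorus in mycorrhizal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying quantum-dot-tagged phosphorus in mycorrhizal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotrade)
```

## The experimental system

Arbuscular mycorrhizal fungi trade soil phosphorus for plant carbon across
continuous, aseptate hyphal networks. In the experiment this package
supports, phosphorus is supplied as hydroxyapatite crystallised around
fluorescent quantum-dot cores (QD-apatite, ~708 nmol P per nmol QD), in two
emission colors (cyan, 488 nm; red, 666 nm). A three-compartment plate
confines the host root to one compartment while the fungus forages in two
fungus-only compartments injected with a fixed total of 0.18 nmol QD-apatite
split 90:10, 70:30 or 50:50 — high, medium or no resource inequality. After
60 days, fluorescence measurements in roots and hyphae answer: how much
phosphorus was *transferred* to the root, how much was *retained* (hoarded)
in hyphae, and how much was *translocated* between rich and poor patches
before trade.

The package implements the five quantitative stages of that analysis plus
synthetic-data generators with exact ground truth for every stage. Nothing
here depends on the original raw data; the generators emulate the
statistical structure each estimator assumes, which is exactly what makes
estimator correctness testable.

## Emission fingerprinting (spectra module)

A plate reader records emission from 450 to 800 nm in 2 nm steps (176
points). A tissue spectrum is modelled as a nonnegative linear combination
of reference spectra — cyan QD-apatite, red QD-apatite, tissue
autofluorescence — on top of a buffer background:

\[ y(\lambda) = \beta_c R_c(\lambda) + \beta_r R_r(\lambda) +
   \beta_a R_a(\lambda) + b(\lambda) + \varepsilon. \]

`subtract_background()` removes \(b\) (floored at zero — photon counts are
nonnegative, and flooring stabilises the constrained fit), and `unmix()`
solves for \(\beta \ge 0\) by nonnegative least squares. The nonnegativity
constraint is a deliberate design choice: abundances are physical masses,
and control samples report *below detection*, never negative amounts. An
unconstrained mode (`nonneg = FALSE`) is kept for comparison; when the true
solution is strictly positive the two coincide, which is how the tests
validate the solver against ordinary least squares.

Unmixed curves may be smoothed (`smooth_curve()`, centred moving average,
default 5 points = 10 nm; the smoother itself is not prescribed by the
measurement, so the window is a documented parameter), integrated
(`integrate_photons()`, the grid sum), and converted to specific uptake via
an eight-point linear calibration (`fit_calibration()`,
`specific_uptake()`). Inversion clips photon counts below the calibration
intercept to zero rather than extrapolating negative amounts, and flags
values under the detection limit of 1e-6 nmol QD per mg tissue. Five
subsamples per sample are averaged (`aggregate_subsamples()`); by default a
below-detection subsample contributes zero (switchable to exclusion), which
matches treating "not detected" as "absent" rather than "missing".

The simulator (`simulate_spectra()`) uses Gaussian QD peaks (sd 15 nm) and a
broad log-normal autofluorescence curve. These shapes are choices — linear
unmixing is shape-agnostic, so any smooth positive shapes exercise the same
algebra; what the simulator does *not* emulate is wavelength-dependent
detector response or spectral drift between the reference and sample
measurements.

## RICS particle counting (rics module)

Raster image correlation spectroscopy extracts the number of fluorescent
particles in the confocal observation volume from the spatial
autocorrelation of raster-scanned images (default geometry: 256 x 256
pixels of 16 nm, 20 us dwell, 1.248 ms line time, 0.250 um beam waist, 40
frames). The pipeline is:

1. `moving_average_subtract()` — each frame minus its 4-frame local temporal
   average (grand mean restored), removing static background and non-moving
   hyphal autofluorescence.
2. `rics_autocorrelation()` — per frame,
   \(G(\xi,\psi) = \langle \delta I(x,y)\,\delta I(x+\xi, y+\psi)\rangle /
   \langle I \rangle^2\), averaged over frames.
3. `estimate_particle_number()` — \(N = \gamma / G(0,0)\).

Two numerical conventions deserve care, and both are explicit parameters:

* **Gamma factor and volume.** For a 3D Gaussian detection profile
  \(\exp(-2r^2/w_0^2 - 2z^2/w_z^2)\) the amplitude satisfies
  \(G(0,0) = 1/(c\,\pi^{3/2} w_0^2 w_z)\) for concentration \(c\). With
  \(\gamma = 2^{-3/2} \approx 0.3536\), \(N = \gamma/G(0,0)\) therefore
  estimates the mean count in the *effective* volume
  \(V_\mathrm{eff} = (\pi/2)^{3/2} w_0^2 w_z\) (the integral of the
  profile), and `density = N / V_eff` recovers \(c\) exactly. The
  conventional \(V_\mathrm{obs} = \pi^{3/2} w_0^2 w_z\) is reported
  alongside; using it for the density would leave a constant factor
  \(\gamma\) between recovered and true concentration. The axial waist
  defaults to \(w_z = 3 w_0\); both \(\gamma\) and the ratio are arguments.
* **Detrending correction.** Subtracting a w-frame moving average that
  includes the current frame deflates the fluctuation variance by
  \((w-1)/w\) when frames are temporally independent (which holds here:
  at the default frame time a particle with \(D \ge 1\;\mu m^2/s\)
  diffuses far beyond the beam waist between frames). The ACF amplitude is
  therefore multiplied by \(w/(w-1)\), carried as an attribute so the
  correction exists only when the detrending actually happened. Without it
  the particle count would be biased high by a third.

Only the zero-lag amplitude is used; fitting the full correlation surface
for a diffusion coefficient is out of scope. Counts are converted to
retention (`retention()`): dry biomass → fresh mass (60% water weight) →
fresh volume (1.1 g/cm^3) → particles → nmol via Avogadro's number. Percent
vacuole area (`vacuole_fraction()`) thresholds intensities inside a hyphal
mask, by default with Otsu's method — the original manual color-threshold
adjustment is not reproducible, so an automatic, deterministic rule replaces
it.

The raster simulator places particles uniformly in a periodic box (axial
extent \(\pm 3 w_z\), each particle carrying a fixed axial weight
\(e^{-2z^2/w_z^2}\)), moves them by Brownian steps plus optional drift, and
images them through the lateral Gaussian point-spread function. Dynamics are
advanced per block of 32 scan lines rather than per pixel: motion during a
single line is far below one pixel for all relevant diffusion coefficients,
and the zero-lag amplitude that the estimator consumes is independent of
intra-frame motion. The simulator omits shot noise by default because shot
noise adds a delta at zero lag that would have to be removed by amplitude
extrapolation — a documented limitation of using \(G(0,0)\) directly.

## Particle tracking and the speed mixture (tracking module)

Movies of cytoplasmic streaming (200 frames at 10 Hz in the original
protocol) pass through:

1. `track_preprocess()` — FFT bandpass (difference of Gaussians) removing
   structures larger than 40 px and smoothing features below 3 px, then
   subtraction of the minimum projection as background, floored at zero.
2. `track_detect()` — Laplacian-of-Gaussian blob detection at the scale of
   10 px objects (\(\sigma = d/2\sqrt{2}\)), strict 8-neighbour maxima, a
   0.995 response-quantile threshold plus a 20%-of-peak relative threshold,
   and quadratic sub-pixel refinement.
3. `track_link()` — constant-velocity prediction with greedy
   nearest-neighbour assignment within a 15 px/frame gate and no gap
   closing. The gate exceeds the fastest plausible displacement (>50 um/s at
   10 Hz and 0.4 um/px is ~12.5 px/frame). The original analysis delegated
   to an external Kalman tracker whose internals are not published; this
   linker reimplements the behaviour that matters for along-axis linear
   motion.
4. `filter_tracks()` — keep tracks with \(\ge 5\) frames and end-to-end
   displacement \(\ge 10\) px (both inclusive, since the exclusion rules are
   strictly "fewer than 5" and "shorter than 10 px").
5. `track_speeds()` — per-step speeds
   (\(|\Delta x| \cdot \mathrm{px} \cdot \mathrm{fps}\)) with direction from
   the sign of the projection onto a lab-frame axis; negative points toward
   the host root. Per-step speeds are pooled rather than per-track means,
   matching the pooled-sample structure of the original distributions
   (~1350 observations per direction).

Pooled speeds are decomposed by `fit_speed_mixture()` into a three-component
mixture of normals truncated at zero — low-, intermediate- and
high-mobility fractions centered near 5, 20 and 30 um/s. The fit is
maximum likelihood by generalized EM: responsibilities use the truncated
densities; each M-step maximises the weighted truncated-normal
log-likelihood numerically (Nelder-Mead warm-started at the current
parameters, O(1) per evaluation via sufficient statistics), which guarantees
a monotone observed-data log-likelihood — asserted in the tests. Twenty
restarts (quantile-bin moment initialisation, then jittered) guard against
local maxima; convergence is a 1e-8 relative log-likelihood change;
components are reported in ascending mean order with ties broken by the
first-attained maximum.

**Identifiability caveat.** With overlapping intermediate/high components
(e.g. sds 5 and 8 around centers 20 and 30), the likelihood surface near the
maximum is nearly flat along a ridge trading the high center against its
weight and sd. At n = 3000 the ML estimate of the high center scatters by
several um/s between datasets even though it is unbiased on average. The
package's parameter-recovery checks therefore average recovered centers
across 10 replicate datasets — the bias of the estimator is the scientific
claim being tested, not the per-dataset scatter, which is a property of the
model, not of the optimizer (verified: restarted EM attains likelihoods at
or above those of fits started at the truth).

The track simulator draws one mixture speed per particle, flips its
direction by a constant-hazard telegraph process (default 0.2 /s —
reversals on the order of seconds), and optionally adds Brownian jitter and
renders Gaussian spots. The default pixel size is 0.4 um/px, chosen for
consistency with the 15 px/frame gate rationale; the real tracking camera's
pixel size is instrument-specific and is always an explicit argument to
`track_speeds()`. The simulator does not emulate hyphal branching, spot
shape variability, or crossing trajectories — the analysis assumes 1D
motion along the hyphal axis, and so does the generator.

## Advection versus diffusion (transport module)

Could QD-apatite cross the \(L_\mathrm{min} = 3\) cm to the other
compartment by Brownian motion within the \(T_H = 60\) day experiment?
`stokes_einstein()` gives \(D = k_B T / 6\pi\eta a\); for radii 4-104 nm at
\(\eta = 10^{-3}\) N s/m^2 this spans ~2-50 um^2/s (one significant
figure). `crossing_time()` gives \(\tau = L^2/2D\): roughly 100 days for the
smallest particle and 2600 days for the largest (the upper bound is printed
at two significant figures of the rounded \(D = 2\), matching the reporting
convention of the source analysis; raw values are always retained).
`transport_report()` assembles the bounds, the displacement curves
\(\sqrt{2Dt}\) vs \(v t\) (with the conservative \(v_\mathrm{min} = 0.1\)
um/s), and the verdict: since even the fastest diffusive crossing takes
about 1.7x the experiment duration, observed cross-compartment transport
requires advection. Temperature is not stated in the source analysis; the
default 298.15 K (25 C culture conditions) is a parameter, and the
one-significant-figure comparisons are insensitive to 293-303 K. The bare
Stokes-Einstein estimate is used deliberately — no confinement or
non-Newtonian corrections.

## Trade accounting (trade module)

A plate record stores per-color QD measurements; color is metadata mapped to
source compartments by the `color_swap` flag (cyan = rich source by
default; the swap mirrors the color-switch control experiment, and all
derived quantities are invariant under it). Derived quantities, computed per
plate and then averaged (matching the plate-level structure of the original
mixed models), are:

* `transfer_to_root()` — nmol QD per mg root by source and total, with the
  708:1 P:QD conversion applied only at reporting time;
* `translocation_percentages()` — in each compartment's hyphae, the
  percentage of QD originating from the other compartment;
* `net_movement()` — rich-to-poor minus poor-to-rich, in percentage points
  (zero under symmetric 50:50 conditions; antisymmetric under relabeling);
* `relative_contribution()` — each source's share of root QD against the
  injected share (over/under-contribution of the poor patch);
* `exchange_rate()` — \(\ln(\mathrm{mg\ biomass} / \mathrm{nmol\ QD\
  transferred})\), the carbon-per-phosphorus proxy (valid because the
  fungus is an obligate biotroph).

Zero denominators yield explicit `NA` flags, never infinities, and flagged
plates are excluded from group means with reported counts
(`summarize_trade()`). Statistical inference (Gamma GLMs, mixed models) is
deliberately delegated to standard tools; `trade_summary()` emits the tidy
long table they consume.

The plate simulator's bookkeeping is: injected amounts split by treatment
ratio; a fraction (`uptake_fraction`, default 0.6) taken up by hyphae with
the remainder unrecovered in the medium; translocation fractions (defaults
0.20 rich-to-poor, 0.05 poor-to-rich) moving holdings between compartments;
transfer fractions (defaults 0.35 rich, 0.45 poor — the poor side
over-contributes) splitting holdings between root and retention. Mass
balance is exact by construction in every noise-free simulation, and the
truth record carries the implied value of every downstream quantity, making
the whole trade pipeline testable to machine precision. Measurement noise is
multiplicative Gamma (mean 1, shape 25) with Gamma-distributed biomasses —
the original analysis models plate measurements with Gamma GLMs but states
no generative noise model, so these defaults are package choices, flagged
here. The `uptake_fraction` parameter exists because exact mass balance
requires an explicit unrecovered pool.

## Problem sizes and reproducibility

All tests and the acceptance script generate their data programmatically
under fixed seeds. Chosen problem sizes: mixture recovery uses 10 replicate
datasets of n = 3000 speeds with 20 EM restarts; RICS recovery uses 5
stacks of 20 frames at the default 256 x 256 geometry per occupancy
(N = 2, 10, 50), with median-vs-truth within 20%; tracking fixtures use 8
constant-velocity particles over 40 frames. Every stochastic generator
accepts a single integer seed threaded through all draws; fixed seeds give
bit-identical output.

## Known limitations

* Unmixing assumes reference spectra measured on the same grid and
  instrument as samples; no wavelength registration is attempted.
* The RICS estimator uses the raw zero-lag amplitude and is therefore
  biased by uncorrected shot noise; real detector data would need amplitude
  extrapolation from small nonzero lags.
* The linker has no gap closing or merge/split handling; occlusions
  fragment tracks (fragments are then subject to the 5-frame filter).
* The mixture's high-speed component is weakly identified at realistic
  sample sizes (see above); confidence statements about single-dataset
  center estimates should come from resampling, not the point fit.
* The plate simulator conserves mass exactly and ignores plate-to-plate
  correlation in uptake; real plates share culture batches, which the
  original analysis handled with random intercepts.
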