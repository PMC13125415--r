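---
title: "The flashbp transport and delivery model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flashbp transport and delivery model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashbp)
```

# Scope

`flashbp` models a single-energy Bragg-peak (SEBP) proton FLASH delivery
chain at desk scale: a 250 MeV scanned pencil beam passes a PMMA universal
range shifter (URS), crosses an air gap that may contain a 5 cm brass
aperture, and stops in a phantom. The package quantifies how much the
aperture sharpens the lateral 80–20% penumbra, and what minimum-MU spot
optimization and spot-by-spot delivery imply for per-voxel FLASH dose rates.
Everything is analytic — no Monte Carlo — so a full 108-cell water-phantom
sweep runs in well under a minute and the three-field head case in minutes.

# Machine model

`beam_model()` captures the machine constants: 250 MeV single energy with a
379 mm range in water, 3.5 mm spot sigma at isocenter, 3 mrad beam
divergence, 6.09e6 protons per MU, a 400 MU minimum spot weight, a 0.5 ms
minimum spot time (MST), and an 8e5 MU/s MU rate (the unique rate at which
the minimum spot exactly saturates the MST). The residual energy at depth
follows a Bragg–Kleeman relation `R = alpha E^1.77` anchored so 250 MeV maps
exactly to 379 mm.

The pristine depth–dose is a Bortfeld-style analytic curve convolved with
the range-straggling Gaussian, positioned so its distal 80% falloff sits at
the nominal range, and scaled so its depth integral equals the beam energy
per unit mass column (energy conservation):

```{r bragg}
z <- seq(0, 400, by = 1)
d <- bragg_depth_dose(z)
bragg_peak_depth()
plot(z, d, type = "l", xlab = "depth [mm]", ylab = "Gy mm^2 / proton")
```

# Lateral transport

Lateral spread is propagated with Fermi–Eyges moments over a slab stack
(PMMA URS, air, phantom), using the differential Highland scattering power
with the standard logarithmic thickness correction. Two calibrations are
fixed once, against independent benchmarks, and never adjusted per
experiment:

* **Scattering-power normalization.** The uncalibrated differential-Highland
  integral overestimates the end-of-range in-water sigma by a few percent;
  a single factor normalizes it to the classic benchmark that the MCS sigma
  at the end of range is 2.1% of the range (`0.021 * 379 mm ≈ 7.96 mm`).
* **Diverging source.** The "3 mrad divergence" is modelled as a fully
  correlated diverging source: the free-space spot sigma is
  `3.5 mm + 0.003 z` at distance `z` upstream of the isocenter, which sets
  the source covariance (`Sxx`, `Sxt`, `Stt`) at every upstream plane.

Two halo terms account for non-elastic and large-angle processes that a
Gaussian core misses:

* **Degrader halo.** A fixed 10% of protons leave the URS with a 3x angular
  sigma. This double-Gaussian degrader emittance is what makes thick-URS
  no-aperture penumbras grow as strongly as they should.
* **In-phantom halo.** At depth `z` a fraction `min(0.15, 4e-4 z)` of the
  local dose is carried by a halo of extra sigma `0.05 z`.

```{r sigma}
lateral_sigma(wet_depth = c(10, 100, 200, 300), urs_wet = 100,
              air_gap = 100)
```

# Thick-aperture transmission

Brass is a perfect absorber at this energy (a 5 cm block exceeds the proton
range in brass), so the aperture acts on the phase space, not the energy.
For each Gauss–Hermite node of the angular distribution, the conditional
position Gaussian at the aperture entrance face is truncated to the
interval accepted by **both** faces of the 5 cm block
(`[max(lo, lo - T*theta), min(hi, hi - T*theta)]` for opening `[lo, hi]`
and thickness `T`), drifted to depth, and convolved with the scattering
accumulated downstream of the aperture — all in closed form. This
theta-resolved two-face model reproduces the collimator's depth-dependent
shadow: razor-sharp at the surface, progressively washed out toward the
Bragg peak.

```{r aperture-profile, fig.width = 6}
tm <- transport_model(urs_wet = 300, air_gap = 100, depths = c(1, 75))
x <- seq(-40, 40, by = 0.25)
off <- spot_axis_profiles(tm, 1, centers = 0, x)
on <- spot_axis_profiles(tm, 1, centers = 0, x, aperture = 20)
matplot(x, cbind(off, on), type = "l", lty = 1,
        xlab = "x [mm]", ylab = "fluence profile",
        main = "entrance profile, 20 mm half-opening")
```

Because square fields and openings factorize, the 2-D profile is the
product of two such axis factors; the 3-D engine
(`compute_field_dose()`) exploits that separability, handling non-square
openings by each spot's opening slab intervals.

# Devices and planning

* `design_urs()` picks the plate subset (10/20/50/100/150/200/300 mm WET)
  that maximizes pullback while keeping the deepest target ray reachable.
* `design_rc()` ray-traces the distal target surface in beam's-eye view and
  assigns `rc = range - urs - distal WET` per ray.
* `design_aperture()` dilates the target's BEV projection by the margin
  (default 5 mm).
* `optimize_spot_weights()` solves non-negative least squares (exact
  active-set for small systems, FISTA for large ones) and enforces the
  400 MU minimum either by deleting/raising spots (`"sparse"`) or by a
  `w = 400 + v` substitution (`"floor"`, used in the water sweep).

# Delivery and dose rate

`build_timeline()` lays the spots out in serpentine order with dwell
`max(MST, mu / mu_rate)` and inter-spot travel at 8 m/s. `compute_adr()`
builds each voxel's piecewise-linear cumulative dose curve and reports the
average dose rate over the window that excludes `window_dose` at each end
(with a zero window: total dose over the first-to-last accrual span). `v40()`
is the pooled fraction of eligible (voxel, field) observations at
40 Gy/s or more, with eligibility set by a per-field dose threshold.

# The two experiments

`run_water_sweep()` measures the 80–20 penumbra of flattened square fields
(3x3 and 5x5 cm²) at three depths (entrance, mid-range, Bragg peak), three
URS pullbacks (10/20/30 cm), three air gaps (5/10/15 cm), with and without
a square aperture at the field edge + 5 mm — 108 penumbra values.
`run_head_case()` plans three orthogonal fields on a synthetic head
phantom, jointly optimizes the spot MUs to 30 Gy(RBE), normalizes to 95%
coverage, and compares dose and dose-rate metrics with and without
apertures.

# Limitations

* The transport is Gaussian-mixture analytic; nuclear secondaries, fluence
  perturbation by the RC, and aperture-edge-scattered protons are only
  represented through the two fixed halo terms.
* The aperture model treats non-square openings as locally rectangular
  (per-spot slab intervals) inside the 3-D engine.
* The head phantom is an invented geometry; only directional comparisons
  (aperture on vs off) are meaningful there, never absolute values.
* RBE is a constant 1.1; no FLASH-specific biological modelling.
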