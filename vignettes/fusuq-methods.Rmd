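---
title: "Simulating focused-ultrasound heating in gelatin phantoms: models, calibration and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating focused-ultrasound heating in gelatin phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`fusuq` reproduces, end to end, the simulation chain used to validate
focused-ultrasound (FUS) treatment-planning models against MR thermometry
in homogeneous tissue-mimicking phantoms:

1. a 256-element phased-array source modeled with the Rayleigh–Sommerfeld
   (RS) integral, condensed into an element response function array (ERFA);
2. hybrid angular spectrum (HAS) propagation of the steady-state complex
   pressure through a voxelized water/gelatin model, giving the power
   deposition `Q` (W/m^3);
3. a perfusionless Pennes bioheat (PBHE) finite-difference solver driven
   by `Q`;
4. a virtual MR-thermometry (MRTI) measurement chain that turns the
   noiseless simulation into synthetic "experimental" data;
5. focal-profile metrics (spatiotemporal peak, transverse/longitudinal
   FWHM, percent errors, composition slopes);
6. Monte Carlo (MC) uncertainty propagation and standardized-regression
   (SRC) local sensitivity analysis over the measured property
   uncertainties.

The phantom system is a series of ballistic-gelatin cylinders (30 mm
radius, 70 mm tall) whose evaporated-milk fraction (10/30/50/70 % v/v)
tunes the acoustic attenuation and speed of sound. The bench
characterization of these phantoms — mean properties, their measurement
uncertainties, and the measured/simulated focal metrics for each
composition at 6.3 and 7.9 acoustic watts — is bundled as plain-text
tables under `inst/extdata/` and exposed by `phantom_properties()`,
`phantom_uncertainties()` and `reference_sonications()`.

# Acoustic model

## Source model and calibration

The physical transducer is a 256-element phased array with a 100-mm radius
of curvature and a 144 × 98 mm aperture driven at 940 kHz. Its element
positions are proprietary, so `generate_array()` places elements by seeded
blue-noise sampling on the spherical cap; every center lies exactly on the
focusing sphere, so uniform drive focuses at the geometric focus. Element
faces are discretized into sub-sources at λ/4 spacing for the RS integral
(`compute_erfa()`), the standard accuracy criterion for aperture
integration.

A layout drawn this way is diffraction-limited for the nominal aperture
(~1.3 × 2.0 mm water focal pressure FWHM), while the hydrophone
characterization of the real system reports a 2.4 × 3.8 mm focal size.
`calibrate_transducer()` therefore fits a per-axis Gaussian amplitude
apodization across the elements until the water-propagated focal pressure
FWHM matches the measured values; the fit converges in a few secant
iterations because the focal width is nearly inversely proportional to the
apodization width.

Two genuinely open identification choices are resolved as follows:

* **Axis assignment.** The hydrophone focal size is reported as an
  unordered pair. Rectangular-aperture diffraction alone would put the
  narrower width on the long-aperture axis (x), but that assignment makes
  the simulated transverse temperature FWHM (measured along the short
  aperture axis, y) come out near 3.8 mm, irreconcilable with the
  2.7–2.9 mm transverse widths of both the measured and the simulated
  reference profiles. Assigning 2.4 mm to y and 3.8 mm to x reproduces
  the transverse *and* longitudinal temperature widths simultaneously, so
  that is the default (`target_fwhm_mm = c(3.8, 2.4)`).
* **Reference plane.** The ERFA plane is placed at the proximal phantom
  face, 80.5 mm from the apex, so the geometric focus lies 19.5 mm into
  the gelatin as in the validated sonication geometry.

`drive_array()` sums the per-element responses with the drive phases and
amplitudes and rescales the plane so its integrated plane-wave power
`sum(|p|^2/(2 rho c)) dA` equals the requested acoustic power (6.3 or
7.9 W). Water is lossless, so this equals the radiated acoustic power.

## Hybrid angular spectrum propagation

`has_propagate()` marches the plane through the voxel model slice by
slice: an angular-spectrum diffraction transfer function (FFT domain,
background sound speed of the slice, evanescent components zeroed,
zero-padding to a fast FFT size with at least 32 guard voxels) followed by
a per-voxel space-domain correction `exp((i(k_vox − k_bg) − alpha) dz)`
for refraction and the power-law attenuation `alpha(f) = alpha0 (f/1MHz)^c`
(with `c = 1` for these phantoms: attenuation linear in frequency). The
first step spans half a voxel so stored planes sample slice centers, which
makes the discrete column integral of `Q` match the analytic absorbed
power to second order. At material interfaces the transmitted amplitude is
scaled by the normal-incidence pressure transmission coefficient and the
first-order reflected plane is recorded; reflected waves are not
re-propagated forward, and by default they are excluded from `Q`
(`compute_q(include_reflections = TRUE)` adds a one-pass backward
contribution; for water/gelatin the pressure reflection coefficient is at
most ~0.05, an intensity fraction of 0.25 %, so the default is
inconsequential). Nonlinear propagation, scattering, shear waves and
dispersion are out of scope of this linear model.

`compute_q()` uses the plane-wave relation `Q = alpha_a |p|^2/(rho c)`
with the absorption coefficient set equal to the attenuation coefficient
(negligible scattering in these gels).

# Thermal model

`solve_pbhe()` integrates `VHC dT/dt = div(kappa grad T) + Q` (perfusion
zero) on the acoustic grid with a 7-point stencil and harmonic-mean face
conductivities, zero initial temperature rise, the source active for the
heating interval (18.16 s), and a constant-temperature (rise pinned to 0)
outer boundary; an insulated variant supports energy-balance diagnostics.
At the published 0.25-mm resolution the explicit FTCS stability bound
(`dx^2 VHC/(6 kappa)` ≈ 0.064 s) is below the 0.08-s reporting step, so
the default scheme is Douglas–Gunn alternating-direction-implicit
stepping, which is unconditionally stable; an explicit mode (with a hard
error when the bound is violated) exists for cross-validation, and the two
agree to a few tenths of a percent at the focus. Frame averaging is done
in-stream: the solver accumulates the mean field over each requested
window (3.36 s, matching the thermometry frame time), so full-resolution
4-D storage is never required. `match_mrti()` additionally resamples to
the 0.5-mm thermometry grid by separable linear interpolation.

# Virtual MR thermometry

`synthesize_mrti()` is the synthetic-data generator. Its defaults emulate
the experimental acquisition: a 2.0-s trigger delay between acquisition
and heating start, box-averaging to the native 1 × 1 × 3 mm acquisition
voxels (3 mm along the beam), 3.36-s frame averaging, zero-fill (Fourier)
interpolation to 0.5 mm isotropic with a trilinear fallback, then
per-replicate white Gaussian temperature noise at the per-phantom bench
noise levels (0.15–0.24 °C), a linear temporal drift (−0.007 °C/s), and
n = 3 replicates. A thermometry-coefficient miscalibration knob
(`wpcs_scale`, default 1) scales the synthetic measurement to study the
±15–23 % uncertainty of the water proton chemical shift coefficient.
The generator injects noise directly in temperature units; it does not
emulate k-space, TR/TE signal levels or B0 drift physics, so passing tests
demonstrate correctness of the measurement-chain arithmetic and the
pipeline's statistical behaviour, not scanner realism.

`correct_drift()` fits a line to the mean temperature of a non-heated
reference region (36 voxels, placed as far from the beam axis as the grid
allows) and subtracts it voxel-wise; `compute_snr()` reports the
spatiotemporal peak over the average temporal standard deviation of that
region, computed on the replicate-averaged series (so replicate averaging
improves SNR by √n).

# Metrics

`compute_metrics()` evaluates the comparison metrics at the peak frame
through the peak voxel: spatiotemporal peak rise, transverse FWHM (along
the short aperture axis y), longitudinal FWHM (along z), and the
longitudinal profile center (midpoint of the half-maximum crossings, used
for focal-shift comparisons). Half-maximum crossings are located by linear
interpolation between bracketing samples, matching the 0.5-mm reporting
grid of the reference tables; ties in the peak scan break to the earliest
frame and lowest voxel index. `percent_error()` implements
`E = 100 (Y_sim − Y_exp)/Y_exp`, and `slope_vs_composition()` the
least-squares peak-versus-milk-fraction slope.

# Uncertainty and sensitivity analysis

`scenario_distributions()` builds the six uncertain inputs: attenuation
(16 %), speed of sound (0.1 %), acoustic power (1.05 %), density (0.8 %)
as independent normals, and thermal conductivity with volumetric heat
capacity (10 % each) as a joint normal group, because they are measured by
the same probe. The joint correlation is not reported anywhere, so the
default is 0 and the value is recorded in every MC result rather than
silently invented. Negative draws of non-negative quantities are resampled
(probability is negligible at these spreads). Sampling is seeded, and the
marginal draws of each parameter are independent of the other parameters'
spreads, which makes one-at-a-time designs reuse identical draws.

`required_iterations()` implements the 95 %-confidence pilot rule
`n = round((1.96 · 100 σ_sub/(ε Ȳ_sub))^2)` with `ε = 100/SNR`; the bench
conditions (σ/Ȳ = 0.129 at ε = 3 %) give n = 71 per scenario.
`run_mc()` re-runs the full HAS + PBHE + metrics chain per draw and
reports `U = 100 sd/mean` per metric plus the per-frame spread of the
peak-voxel temperature (the uncertainty envelope). `one_at_a_time()`
isolates single-parameter contributions `U_j` and their leverage
`U_j/σ_Xj`; `src_analysis()` fits the pooled linear response surface and
standardizes coefficients (`SRC_j = b_j σ_Xj / σ_Y`). Pooling follows the
validation protocol: raw outputs of all eight scenarios are regressed
together without per-scenario centering.

# Problem sizes and numerical choices

The published model (0.25-mm grid, 647 × 343 × 280 voxels) is supported by
the data structures, but the package defaults are chosen for desk-scale
reproduction:

* **Validation scenarios**: 0.5-mm grid over a 40 × 40 × 80 mm box
  cropped around the beam axis, starting at the phantom face. The focal
  region (transverse FWHM ~3 mm, longitudinal ~19 mm) is fully resolved;
  grid-halving changes the focal pressure peak by under 2 %.
* **Monte Carlo**: 1.0-mm grid over 30 × 30 × 60 mm, n = 71 per scenario
  (n = 50 in the routine test suite), which preserves the relative
  sensitivities that determine `U`.
* **Simulated duration** 23.52 s (seven 3.36-s frames: all of heating
  plus early cooling), which brackets the temporal peak.

Other numerical decisions: FFT planes are padded to the next 2-3-5-smooth
size with ≥ 32 guard voxels; evanescent components are zeroed; the
explicit scheme refuses unstable steps with an error stating the bound;
box-averaging crops trailing voxels that do not fill a block; trilinear
resampling clamps at the grid edges. Hard-edged plane-wave tests use wide,
cosine-tapered source planes because a truncated plane sheds Fresnel edge
waves — a physical effect, not a solver artifact.

# Known limitations

* The element layout is calibrated, not measured: any source model whose
  initial-plane power equals the sonication power and whose water focal
  FWHM matches the hydrophone pair concentrates essentially all power in
  the measured mainlobe. The physical array evidently delivered ~20 %
  of its power outside that mainlobe (sidelobe pedestal/aberration),
  which no printed measurement pins down. Absolute simulated peak
  temperature rises therefore run ~25–30 % above the reference simulation
  column, while profile widths, relative uncertainties (U), sensitivity
  ranks and all closed-form quantities reproduce well. The acceptance
  suite leaves the absolute-peak check red rather than fitting an
  unmeasured pedestal fraction to the expected answer.
* Temperature-dependent properties, perfusion, nonlinearity and
  scattering are out of scope, as in the validated linear model.
* The MRTI emulation is statistical (noise/drift/resampling), not a
  physics simulation of the scanner.
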