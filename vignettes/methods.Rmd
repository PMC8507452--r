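---
title: "Simulating and reconstructing In-111 SPECT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing In-111 SPECT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spectmc` is a self-contained laboratory for studying how reconstruction
choices shape image quality in In-111 SPECT: it generates digital phantoms,
simulates gamma-camera acquisitions by Monte Carlo photon transport, and
reconstructs them with three OSEM variants that differ in how much physics
the forward model carries. This vignette documents the models, the defaults
and why they were chosen, and the limits of what the simulations show.

## The imaging chain being emulated

An In-111 SPECT acquisition records, at each of `n` camera angles around the
patient, the photons that pass a parallel-hole collimator, deposit energy in
the NaI(Tl) crystal, and fall in one of two 20% energy windows centered on
the 171 and 245 keV emission lines. Image degradation enters through four
mechanisms, all modelled here:

* **distance-dependent blur** — the collimator-detector response widens with
  source-to-collimator distance `d`. The package uses the standard
  quadrature model FWHM(d) = sqrt(FWHM_int^2 + FWHM_coll(d)^2) with
  FWHM_coll(d) = D (L_eff + d)/L_eff, hole diameter `D`, effective hole
  length `L_eff = L - 2/mu_septa`;
* **photon attenuation** in the object (Beer-Lambert along each ray);
* **Compton scatter** in the object, which adds a broad mis-positioned
  background inside the photopeak windows;
* **Poisson counting noise**.

Reconstruction is ordered-subset expectation maximization. The three
variants plug different forward models into the same multiplicative update:

| variant | forward model | back projector | defaults |
|---|---|---|---|
| AC | attenuation only | matched transpose | 2 it x 10 subsets |
| ACRR | attenuation + distance-dependent PSF | matched transpose | 2 it x 10 subsets |
| MC | Monte Carlo (attenuation + PSF + scatter, sampled emissions) | analytic attenuation + PSF transpose | 5 it x 10 subsets |

With `attenuation = FALSE` the same variants become their non-corrected
counterparts (NC, NCRR, MC-NC) used for phantoms measured in air.

## Camera and protocol defaults

The emulated camera has a 15.9 mm crystal, 2.21 mm pixels on a 256 x 256
matrix, and a medium-energy parallel-hole collimator. The collimator's
internal geometry is rarely published; the defaults (hole diameter 3.0 mm,
hole length 58 mm, septa 1.05 mm, lead attenuation 16.6 cm^-1 at 171 keV)
are typical medium-energy general-purpose values and are configurable in
`system_model()`. Intrinsic resolution defaults to 3.9 mm FWHM and energy
resolution to 9.8% at 140 keV with 1/sqrt(E) scaling — ordinary NaI(Tl)
values. The acquisition protocol defaults to 120 projections over 360
degrees, 30 s per frame, and a circular orbit of radius 250 mm (non-circular
orbits are out of scope). Detector sensitivity is the solid-angle fraction
of the collimator acceptance cone, about 7e-4; absolute becquerel
calibration is deliberately not attempted, since every measurement the
package reports (FWHM, orientation, TNC) is scale-free.

## Attenuation and interaction physics

Phantoms contain two materials, water and air (the PMMA of real line
inserts is mapped to water; at ~1 mm wall thickness its effect is below
every other uncertainty here). Linear attenuation is electron density times
the closed-form Klein-Nishina total cross section plus a small E^-3
photoelectric term anchored at 50 keV. This reproduces standard narrow-beam
tabulations to within about 2% between 50 and 511 keV and is exactly
consistent with the Klein-Nishina sampling used for scattering angles.
Coherent (Rayleigh) scattering is omitted — a few-percent effect at these
energies that mainly redistributes photons by small angles. Because only
two materials exist, the attenuation map at any scattered photon energy is
the 171 keV reference map rescaled by the water attenuation curve, which
lets one voxel map drive transport at all energies.

## The Monte Carlo projector

Photon histories are emitted from voxels sampled proportional to activity
(uniform within a voxel, isotropic directions, line energies proportional
to the 0.907/0.941 emission intensities of In-111). Free paths use Woodcock
delta tracking against the grid's majorant attenuation, so no voxel-boundary
ray tracing is needed; collisions are classified Compton vs photoelectric by
the partial cross sections, scattering angles follow Klein-Nishina rejection
sampling, and photons die below 50 keV or after 10 scatters.

Detection uses two schemes:

* an **analog acceptance-cone model** (`detect()`): a photon is recorded if
  its direction lies within the collimator half-angle of the detector
  normal, its Gaussian-blurred energy falls in a window, and its
  intrinsic-blur-displaced impact point lands on the detector. This is the
  validation path — collimator efficiency, energy spectra and scatter
  fractions are measured with it.
* a **collision-estimator scheme** used by `simulate_projections()`: the
  sampled emission histogram is propagated to every requested angle through
  the attenuated, distance-dependently blurred system model (the expected
  primary image of the sampled emissions), and each Compton vertex deposits
  its energy-window acceptance weight into a scatter-source volume that is
  propagated the same way. This gives smooth expected projections from
  modest history budgets — the property that makes OSEM with a Monte Carlo
  forward step affordable — at the cost of one approximation: re-emission at
  scatter vertices is treated as isotropic rather than Klein-Nishina
  weighted toward the detector, and the vertex-to-detector attenuation uses
  the photopeak map. Both choices bias the scatter estimate by a few
  percent of a component that is itself ~20-30% of the signal; orderings
  and contrasts are insensitive to this.

`"poisson"` mode draws independent counts from the expected projections;
`"expected"` mode returns them as-is (used as the MC OSEM forward step, with
fresh substreams per subset derived from the master seed, 2e5 histories per
subset by default).

## Phantoms

* `make_cylinder_attenuation()` — a water- or air-filled cylinder, default
  216 mm diameter (a standard flangeless quality-control phantom body;
  configurable), voxel centers decide membership.
* `make_triple_line_activity()` — line sources of 1.0 mm diameter
  rasterized with sub-voxel area weighting so total activity is conserved
  exactly. The default arrangement places line A 20 mm anterior of the CoR
  (the CoR sits "below" A in a transverse image) and lines B and C lateral
  at 60 and 63 mm radius. The exact insert geometry of physical triple-line
  phantoms is not standardized, so these positions are configurable; the
  defaults were chosen so that the toward-CoR elongation artifact of far
  sources and the tangential elongation of the near source both map onto
  the left-right (Y) axis, which is where resolution studies with this
  arrangement report the larger FWHM. Line activity defaults to 5e3
  decays/s/mm, giving ~1.5 million detected counts in the desk-scale study
  — a clinically plausible count level.
* `make_liver_phantom()` — an elliptical-cylinder water torso (semi-axes
  100 x 130 mm) with an ellipsoidal liver at three times the background
  concentration; a geometric stand-in for patient data, used only as an
  attenuating, structured background for lesion insertion.
* `place_lesion()` / `lesion_activity()` — a sphere of radius 1 voxel (the
  7-voxel 3D cross: voxels whose centers lie within one pitch of the center)
  placed uniformly at random where its whole neighbourhood is liver; its
  *excess* activity (TNC-1 times the liver concentration) is simulated
  separately and added in projection space, so the lesion enters the raw
  data exactly as an extra physical source would.

## Measurement layer

Spatial resolution is the FWHM of a Gaussian (plus constant offset) fitted
by Levenberg-Marquardt to a one-voxel-wide profile through the line source,
averaged over the 5 central axial slices. The peak is localized first so
center mis-specification cannot bias the width, and the profile is limited
to ±35 mm around the peak so neighbouring sources and the phantom boundary
stay out of the fit. No upsampling is applied before fitting — the fit is
continuous in position, so native sampling suffices. `fwhm = 2 sqrt(2 ln 2)
sigma` by construction.

The elliptical artifact is quantified by a 2D elliptical-Gaussian fit
(moment-initialized); the report gives the major-axis orientation and its
angular distance from the source-to-CoR axis. Fits with axis ratio below
1.05 are flagged degenerate and excluded from alignment statistics.

Tumour-to-normal contrast uses two fixed voxel lists around the lesion
center: the tumour VOI is the 4 highest-intensity voxels among the 19
non-corner voxels of the 3 x 3 x 3 box, and the background VOI is the
remaining 15. This construction makes the two stated VOI sizes (4 and 15)
mutually consistent inside one box while following the measured activity,
and both voxel lists are returned for audit. TNC values measured on any
smoothed reconstruction of a TNC-8 phantom necessarily lie in (1, 8).

Paired statistics (X-Y differences, variant contrasts) use the paired
Student t machinery of `stats::t.test()`; the percent column uses the
per-pair convention mean(d_i/x_i), the only convention under which the
printed percent values of the bundled example table are reproducible from
its own rows. Display rounding is 1 decimal in mm; all tables are also
emitted unrounded.

## Numerical choices

* The back projector is the literal transpose of the discrete forward
  operator — the same sparse bilinear rotation matrix applied transposed,
  transposed blur convolutions, identical attenuation weights — so the
  adjoint identity holds to machine precision by construction rather than
  approximately. (Bilinear rotation alone is not self-adjoint; building the
  pair from one matrix sidesteps that.)
* Attenuation line integrals use midpoint cumulative sums along the rotated
  depth axis (half-voxel self-term).
* PSF kernels are truncated at 4 sigma and renormalized; depth distances are
  measured from each rotated voxel plane to the collimator face.
* OSEM starts from a uniform image on the attenuation support, guards empty
  rays with eps = 1e-10, treats 0/0 pixels as ratio 1, and preserves
  nonnegativity through the multiplicative update.
* Subsets interleave angles (subset k takes angles k, k+n, ...) and are
  processed in a greedy maximal-angular-separation order.
* The Butterworth post filter uses gain [1 + (f/fc)^(2n)]^(-1/2) with `f`
  the 3D radial frequency in cycles/cm — the convention in which "order 10,
  0.48 cycles/cm" is the common clinical setting; the alternative exponent
  convention would be `n` in place of `2n` and can be emulated by halving
  the order.

## Study conditions and problem sizes

The bundled studies run at desk scale: a 64 x 64 x 32 grid of 4.42 mm
voxels, 60 projections, 2e6 photon histories per acquisition, three seeds
per claim. A full triple-line realization (simulation plus AC, ACRR and MC
reconstructions and all fits) takes about 90 s on one CPU core; the lesion
study is similar. These sizes were chosen as the smallest at which the
line sources are several voxels from each other and from the boundary and
count levels are clinically plausible. The full-scale clinical matrix
(256 x 256, 2.21 mm pixels, 120 projections) is configurable through the
same functions.

## What the simulations do and do not show

The synthetic data reproduce the mechanisms that drive the studied effects
— distance-dependent blur, attenuation, object scatter, counting noise —
but not detector backscatter, septal penetration star artifacts,
dead-time, non-circular orbits, or anatomical texture. Consequently the
package's simulated FWHM values are not predictions of any particular
camera's numbers (vendor resolution-recovery implementations are
proprietary and differ in detail); what transfers are orderings and
mechanisms: resolution improves from AC to ACRR to MC, the anisotropy
shrinks when the PSF is modelled, far-from-CoR sources elongate toward the
CoR, and scatter-aware MC reconstruction preserves small-lesion contrast
better than AC OSEM with a smoothing post filter. The bundled
`example_resolution_table()` carries measured dual-camera values and is the
package's worked example for the statistics layer; its summary statistics
are reproduced exactly by `build_report()`.
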