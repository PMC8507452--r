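# spectmc

Monte Carlo simulation and iterative reconstruction of In-111 SPECT, built
to study how much image quality a reconstruction recovers when its forward
model carries progressively more physics.

Single-photon emission computed tomography with In-111-octreotide (somatostatin
receptor imaging of neuroendocrine tumours) suffers from depth-dependent
collimator blur, photon attenuation and Compton scatter. Clinical
reconstructions correct attenuation (AC OSEM), sometimes also model the
distance-dependent point-spread function (resolution recovery, ACRR OSEM);
the most complete option simulates photon transport inside the forward
projection of the iterative loop itself (MC OSEM). `spectmc` implements all
three over one simulation back end so their effects on spatial resolution
and lesion contrast can be quantified — by medical physicists, algorithm
developers, or anyone who wants a transparent, dependency-light SPECT
sandbox in R.

## What is inside

* **Phantoms** — a triple-line resolution insert (~1 mm lines) in a
  water-filled cylinder or in air; a torso/liver phantom with an insertable
  spherical lesion of true tumour-to-normal concentration ratio (TNC) 8.
* **Monte Carlo projector** — emission sampling, Woodcock delta tracking,
  Klein-Nishina Compton scattering, photoelectric absorption, parallel-hole
  collimator acceptance, Gaussian energy response with dual 20% windows at
  171/245 keV, Poisson counting noise.
* **OSEM engine** — ordered subsets with the standard multiplicative update
  `x <- x * A'(y / A x) / A'(1)`; variants AC (2 it x 10 subsets), ACRR
  (adds distance-dependent PSF, 2 x 10), MC (Monte Carlo forward projection
  with PSF-corrected back projection, 5 x 10); Butterworth post filter
  (gain `[1 + (f/fc)^(2n)]^(-1/2)`).
* **Measurement layer** — FWHM of Gaussian-fitted line profiles
  (`fwhm = 2 sqrt(2 ln 2) sigma`), elliptical-Gaussian fits of the
  toward-CoR elongation artifact, TNC from fixed 4-voxel tumour and
  15-voxel background VOIs.
* **Statistics** — means ± sample SD, paired Student t-tests of X-Y
  resolution differences with 95% CIs, machine-readable reports; a bundled
  dual-camera example resolution table as the worked example.

## Worked example: the statistics layer

The bundled table holds per-line FWHM values (lines A-C, X and Y
directions, two cameras, three reconstruction variants):

```r
library(spectmc)
tab <- example_resolution_table()
rep <- build_report(tab, variant_pairs = list(c("ACRR", "MC")))
rep$overall
#>   variant   mean_mm    sd_mm  n
#> 1      AC 12.225000 3.716578 12
#> 2    ACRR  9.258333 2.514488 12
#> 3      MC  8.225000 2.003690 12
rep$xy_paired[, c("variant", "mean_diff_mm", "sd_diff_mm", "p")]
#>   variant mean_diff_mm sd_diff_mm            p
#> 1      AC     5.383333  1.6999020 0.0005693908
#> 2    ACRR     3.083333  0.8183316 0.0002508056
#> 3      MC     2.916667  0.6462714 0.0001054933
print(paired_t_ci(tab$fwhm_mm[tab$variant == "ACRR"],
                  tab$fwhm_mm[tab$variant == "MC"]))
#> paired diff 1.0 +/- 0.7 (12%), t(11) = 5.20, p = 0.000293, 95% CI [0.6, 1.5]
```

Reading: across both cameras and all lines, resolution improves from
12.2 mm (AC) through 9.3 mm (ACRR) to 8.2 mm (MC); the Y direction is
3-5 mm worse than X for every variant (the elliptical artifact); the
ACRR-to-MC improvement of about 1 mm is significant with 95% CI
0.6-1.5 mm.

## Worked example: a full simulation study

```r
res <- run_resolution_experiment(seed = 1)   # ~90 s on one core
aggregate(fwhm_mm ~ variant, res$fwhm, mean)
#>   variant   fwhm_mm
#> 1      AC 15.765093
#> 2    ACRR 10.768523
#> 3      MC  7.617478
print(measure_ellipses(res$recons$AC, res$line_specs[c("B", "C")]), digits = 4)
#>   line radius_mm major_fwhm minor_fwhm orientation radial_misalignment degenerate
#> B    B     60.03      16.79      14.41       61.31              0.9226      FALSE
#> C    C     63.16      16.21      13.90      104.47              7.6903      FALSE

les <- run_lesion_experiment(seed = 1)       # ~90 s
les$tnc
#>       AC       MC
#> 1.115939 1.242285
```

The simulated study (64 x 64 x 32 grid, 4.42 mm voxels, 60 projections,
2e6 photon histories) reproduces the qualitative findings: MC < ACRR < AC
in mean FWHM, Y worse than X, the far line sources elongated toward the
center of rotation in the PSF-free reconstruction, and better preservation
of an inserted TNC-8 lesion's contrast by MC OSEM than by AC OSEM with the
clinical Butterworth filter (both far below 8 after partial-volume and
scatter losses).

A thin CLI wraps the same functions
(`inst/exec/spectmc run-experiment --config cfg.yaml --out dir`); volumes
travel as NIfTI with exact-geometry JSON sidecars.

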