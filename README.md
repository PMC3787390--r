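# stedspot

Simulation and shape analysis of sub-diffraction membrane carriers in STED
microscopy.

## The problem

Golgi-derived transport intermediates — candidate COPI vesicles of roughly
70–110 nm — are smaller than the diffraction limit. STED microscopy with an
effective lateral point spread function (PSF) of ~80 nm full width at half
maximum (FWHM) renders each carrier as a single fittable spot, but two
questions then need quantitative machinery:

* **Shape.** Could an apparently round ~110 nm spot actually be a short
  tubule seen at an unfavorable orientation? At what tubule length does the
  fitted spot become measurably asymmetric?
* **Content.** Given a reference (coat-protein) channel and two cargo
  channels, what fraction of size-gated carriers contain cargo A only,
  cargo B only, or both?

`stedspot` answers both on fully synthetic data with known ground truth. It
simulates surface-labeled vesicles (spheres) and tubules (capsules) as
binary shells (surface ± 5 nm) on a 3D voxel grid (default 200³ voxels of
5 nm), rotates them isotropically, projects them into the focal plane,
convolves with a radially symmetric Lorentzian STED PSF
`k(r) ∝ 1/(1 + (2r/Γ)²)` (Γ = 80 nm FWHM; Gaussian for confocal), and
applies Poisson signal and background noise. Spots are measured by bounded
least-squares fitting of an elliptical 2D Lorentzian/Gaussian

```
f(x, y) = offset + A · g(u² + v²),   g(ρ²) = 1/(1 + 4ρ²)  or  exp(−4 ln2 ρ²)
```

with sub-pixel center, major/minor FWHM and orientation; each spot reports
`size = √(FWHM_maj · FWHM_min)` and `axis ratio = FWHM_maj / FWHM_min`. A
threshold-based colocalization classifier (background-ROI cutoffs at
mean + 1 SD of 100 ROI maxima, local-maximum detection, 150 nm size gate)
scores multi-channel fields, and small kinetic utilities compute ROI
timecourses, fold increases, FRAP recovery percentages and the naive
dots-per-cell extrapolation.

## Worked example

```r
library(stedspot)

# a 110 nm vesicle imaged by simulated STED, then measured
g   <- grid_params(200, 5)                   # 1 um field, 5 nm voxels
ves <- render_structure(structure_spec("vesicle", 110), g)
img <- image_structure(project_grid(ves), psf_spec("lorentzian", 80))
summary(fit_spot(img, "lorentzian", crop = Inf))
#> Elliptical 2D lorentzian fit (converged)
#>          x          y fwhm_major fwhm_minor      theta  amplitude     offset
#>     0.0000     0.0000   114.3726   114.3726     1.5708     2.1103     0.0000
#> size (geometric-mean FWHM): 114.37 nm
#> axis ratio (major/minor):   1.0000
#> relative residual norm:     0.1821
```

The noise-free 110 nm shell fits at 114.4 nm — the apparent (raw, not
PSF-deconvolved) FWHM under the 80 nm Lorentzian PSF. A point source fits at
exactly 80 nm, the PSF itself.

```r
# vesicle vs tubule discrimination at the standard design, 50 frames/class
rep <- run_shape_experiment(shape_experiment_config(n_per_class = 50, seed = 201))
print(rep)
#>   vesicle_110     n= 50  size  131.4 +/-  0.7 nm   axis ratio 1.006 +/- 0.004
#>   tubule_30x150   n= 50  size  112.7 +/-  9.5 nm   axis ratio 1.198 +/- 0.092
#>   tubule_30x300   n= 50  size  151.0 +/- 21.1 nm   axis ratio 1.596 +/- 0.215
#>   ...
#>   tubule_30x300   axis_ratio diff  0.59 (pooled sd 0.15), p_holm 2.8e-17 -> distinguishable
```

(Under Poisson noise the fitted vesicle size rises to ~131 nm: with heavy
Lorentzian tails the free offset and the width trade off against the
background level.) Mean axis ratio grows monotonically with tubule length;
300 nm tubules separate cleanly from vesicles by asymmetry, while short
tubules stay round to within a few percent.

```r
# two-cargo colocalization with known truth fractions
res <- run_classification_experiment(
  spot_field_config(n_spots = 200, fractions = c(0.66, 0.20, 0.15), seed = 401))
print(res$summary)
#> <classification_summary> 200 detected, 3 excluded by size, 0 fit failures
#>   A_only 136 (69.0%), B_only 36 (18.3%), both 25 (12.7%); none 0

# ~20,000 carriers per fused cell over 30 min
estimate_total_dots(6, 5, 30, 500, 5)
#> $unrounded 21600   $rounded 20000   $n_frames 360   $n_slabs 10
```

A thin command-line front end (`inst/scripts/stedspot.R`) exposes the
experiment drivers and the dot extrapolation as subcommands.

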