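# sfphase

Spatial-frequency spectra of cortical phase dynamics on sparse,
irregular sensor arrays.

## What this solves, and for whom

Stereotactic EEG (sEEG) measures local field potentials *inside* the
gray matter through depth electrodes — linear runs of contacts at 5 mm
spacing, placed clinically, so the resulting array is sparse, irregular,
and embedded in a folded cortical sheet. For researchers asking how the
power of cortical phase patterns is distributed over spatial scale —
in particular whether large-scale traveling waves (wavelengths > 8 cm)
dominate — no standard Fourier method applies to such sampling.

`sfphase` estimates the spatial-frequency (SF) spectrum of phase by:

1. extracting complex phase φ = e<sup>−iθ</sup> with two-cycle Morlet
   wavelets at log-spaced temporal frequencies (1–97 Hz, 34 steps);
2. decomposing each contacts × samples phase matrix
   Φ = Σᵢ ςᵢ uᵢ vᵢ\* by complex SVD, keeping the leading spatial
   covariance patterns (left singular vectors ζ with magnitudes
   aₛ = |ζₛ| and angles ωₛ = ∠ζₛ; default rank 14);
3. regrouping contacts into approximately equilateral triangles (minimum
   interior angle > π/4) with **geodesic** edge lengths on the cortical
   mesh, flattening each triangle, and fitting the phase plane from
   circular differences: the local SF is ξ = |∇ω| / 2π (cycles/m);
4. accumulating the weights W = ς · ⟨a⟩ · N<sub>T</sub> (singular value ×
   mean vertex magnitude × triangle-size normalization) into 32 SF bins;
5. testing the wavelength–power trend with log-log regressions and
   two-tailed permutation tests (10,000 permutations).

It also ships the validation machinery: spherical phase-gradient
surrogates injected at known SF and mixing ratio, singular-weight
reversal (turning a 1/k spectrum into a k spectrum), contact
sparsification, average-reference loading, standing-wave (DC) removal,
and a synthetic-data generator (two-hemisphere spheroid meshes, depth
electrode layouts, wave recordings and phase fields with exact ground
truth).

## Worked example

```r
library(sfphase)

# a synthetic study: distorted two-hemisphere shell, 16 depth electrodes
mesh <- make_spheroid_mesh(distortion = 0.05, seed = 11)
contacts <- make_depth_electrodes(mesh, 16, 12, cap_half_angle = pi / 5,
                                  seed = 12)
wav <- make_wave_recording(
  mesh, contacts,
  components = data.frame(tf = c(8, 8.6), sf = c(6, 14),
                          direction = c("ap", "lr"),
                          amplitude = c(1, 0.4)),
  noise_sd = 0.1, fs = 500, duration = 4, seed = 41)

res <- run_pipeline(wav$recording, contacts, mesh,
                    config = list(n_perm = 1000, rank = 8),
                    frequencies = c(6, 8, 10.5))
res$triangles
#> <triangle_set> 1065 triangles (min angle > 0.785 rad); 56 triplet(s)
#>   rejected by triangle inequality; below the 1500-triangle practical cut-off
res$spectra[[2]]
#> <sf_spectrum> 32 bins over [16.7, 50] cycles/m @ f = 8 Hz (rank 8,
#>   dc_removal TRUE); peak 21.6 at 17.2 cycles/m
res$regressions[[2]]
#> <sfp_regression> log(power) ~ log(wavelength): slope 3.217, offset 11.63,
#>   r = 0.7926, p = 0.000999 (n = 30, 2 zero bins dropped)
```

Reading the output: the pipeline rejected artifacts, re-referenced the
gray contacts against the quiet half of the white-matter contacts,
enumerated 1065 equilateral geodesic triangles, and built one spectrum
per analysis frequency. At 8 Hz the positive slope (power rising with
wavelength, r = 0.79, permutation p ≈ 0.001) says the planted long-
wavelength component dominates the measurable band — the spectral
signature of large-scale phase organization.

Lower-level entry points (`morlet_phase()`, `complex_svd()`,
`enumerate_triangles()`, `build_spectrum()`, `spherical_gradient_basis()`,
`inject_surrogate()`, `reverse_singular_weights()`, ...) expose every
stage individually; `vignettes/sf-spectra-methods.Rmd` documents the
model, conventions and limitations.

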