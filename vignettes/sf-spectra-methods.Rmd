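---
title: "Estimating spatial-frequency spectra of cortical phase dynamics on irregular arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatial-frequency spectra of cortical phase dynamics on irregular arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depth-electrode (sEEG) recordings sample the local field potential *inside*
the gray matter, with excellent spatial resolution but on an extremely
sparse and irregular array: linear runs of contacts at 5 mm spacing,
placed clinically, embedded in a folded two-dimensional sheet. Classical
Fourier analysis — even its non-uniform variants — cannot turn such a
sampling pattern into a spatial-frequency (SF) spectrum. Yet that spectrum
is exactly what is needed to decide whether large-scale traveling waves
(wavelengths above ~8 cm) are a real, dominant feature of cortical
activity or an artifact of extracranial blurring.

`sfphase` implements an estimator built from three ingredients:

1. **Complex phase at each temporal frequency (TF).** Phase is represented
   as a unit phasor `exp(-1i * theta)` and extracted with very short
   (two-cycle) Morlet wavelets at 34 log-spaced center TFs between 1 and
   97 Hz. Short windows trade TF resolution for temporal resolution,
   which suits waves that last only a cycle or two.
2. **Complex SVD of the phase matrix.** The contacts-by-samples phase
   matrix is decomposed into left singular vectors (LSVs — spatial
   covariance patterns of phase), singular values (their weights), and
   right singular vectors (their time courses). For smooth fields the
   LSVs approximate sinusoidal (Fourier-like) components; for irregular
   arrays they additionally encode low-rank corrections for the sampling
   geometry. Retaining the leading components (default rank 14 of a
   trialed 10–40 range) discards phase estimates that never form
   consistent spatial covariance.
3. **Multi-scale triangle differencing.** Contacts are projected to the
   cortical mesh, all within-hemisphere triplets whose geodesic edge
   lengths form an approximately equilateral triangle (minimum interior
   angle above pi/4) are enumerated, and each triangle is flattened into
   the plane. The circular phase differences of an LSV across a
   triangle's vertices give an exact three-point plane fit of the phase
   gradient; its norm over 2*pi is a local SF in cycles/m. Each estimate
   is weighted by the component's singular value, the mean LSV magnitude
   at the three vertices, and a normalization that makes the triangle
   *size* distribution effectively uniform (each occupied size bin
   carries unit total weight). Accumulating weights over K = 32 SF bins
   yields the spectrum.

A log-log regression of power on wavelength (1/SF), with a two-tailed
permutation test on the correlation between data and fit (10,000
permutations, add-one correction), quantifies the spectral trend.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_cycles` | 2 | periods | Morlet support; sets TF resolution |
| `fmin`, `fmax`, `n_freq` | 1, 97, 34 | Hz | log-spaced analysis TFs |
| `rank` | 14 | — | retained SVD components (robust over 10–40) |
| `angle_min` | pi/4 | rad | equilateral acceptance threshold |
| `n_size_bins`, `size_range` | 32, 32→1 cm | — | triangle-size normalization grid (+1 undersized bin) |
| `K` | 32 | — | spectrum bins |
| `sf_range` | [1/max size, 50] | cycles/m | regression range; plotting uses 1/(2 max size) |
| `n_perm` | 10,000 | — | permutation count |
| `n_steiner` | 3 | — | geodesic graph refinement |

## Numerical conventions

* **Wavelet calibration.** The kernel is a complex exponential under a
  Gaussian envelope, truncated to exactly two periods, zero-meaned
  against the envelope, and scaled to unit total absolute weight. The
  Gaussian width is fixed at `sigma_t = 0.27 / f`, calibrated once so
  that the realized discrete 4.5 Hz kernel has a half-power band of
  (2.77, 6.84) Hz — the closest this family comes to the nominal
  (2.5, 6.8) Hz band of a two-cycle wavelet at that frequency; the
  zero-mean correction (required so the DC component cannot leak into
  phase) floors the lower crossing near 2.77 Hz. The ratio is then used
  at every frequency, so bandwidth scales proportionally with the
  center TF. A side effect of the heavy truncation is a small
  negative-frequency ripple (about 0.06 rad peak) in the phase of a pure
  sinusoid; it has zero circular mean and is invisible to the
  covariance-based decomposition.
* **Edges.** Convolution uses reflect padding; samples within half a
  kernel of a recording edge carry a validity mask and are dropped
  before the SVD by default.
* **Gauge fixing.** Each LSV is rotated so its largest-magnitude entry is
  real-positive (the matched rotation is applied to its right singular
  vector), pinning the SVD's global-phase freedom for reproducible
  serialization. All downstream quantities are built from phase
  *differences* and are gauge invariant regardless.
* **Standing-wave (DC) removal.** Each LSV can be split into traveling
  and globally synchronous parts: the vector is extended over one full
  temporal cycle (`round(fs/f)` samples of unit phase), the real part of
  the extension is decomposed, and the first two singular vectors are
  recombined into a unit phasor. The sign ambiguity (two propagation
  orientations) is resolved by choosing the orientation that best
  matches the input's phase pattern. Exactly constant inputs are flagged
  as purely standing and contribute nothing downstream. On re-referenced
  empirical data this step empties the DC bin; on clean synthetic fields
  it slightly biases peaks upward (the second singular vector is then
  noise-like), so the synthetic recovery benchmarks in the test suite
  run with `dc_removal = FALSE`.
* **Geodesics.** No exact polyhedral-geodesic solver is available in
  this toolchain, so distances are computed on a Steiner-point graph:
  three extra nodes per mesh edge, every face fully connected
  internally, query points tied into their face (and to co-facial query
  points directly), Dijkstra over the result. Against the closed-form
  great-circle distance on a subdivision-4 icosphere the error is below
  1%.
* **Binning.** Spectrum bins are half-open `[kw, (k+1)w)` with the last
  bin closed, with exact real-valued width `w = (max - min)/K` (a
  ceiling only makes sense on integer grids). Estimates outside
  `sf_range` are excluded and their mass reported, not clamped.
  Per-triangle estimates whose vertex phase differences exceed pi in
  magnitude are aliased and contribute wherever the wrapped differences
  imply — exactly as in any finite-difference scheme; nothing is
  silently filtered.
* **Surrogate weights.** Surrogate strengths are quoted as mixture
  fractions (a 2/3 ratio makes the surrogate twice the empirical
  signal); `ratio_to_weight()` converts them to the additive weight used
  by `inject_surrogate()`, which renormalizes the phasor sum to unit
  modulus. Surrogate time series reverse and conjugate an empirical
  right singular vector and are themselves unit-modulus phase signals.

## What the synthetic data emulate — and what they do not

`make_spheroid_mesh()` builds two closed, optionally distorted icosphere
shells at a hemispheric scale (default radius 9 cm, so geodesic extents
reach ~28 cm, matching wide clinical coverage).
`make_depth_electrodes()` plants straight contact runs at exact 5 mm
spacing entering through a lateral cap, aimed at a second nearby surface
point so the run grazes the shell — on a smooth shell this grazing chord
reproduces the gray/white mix that folded cortex gives real depth
electrodes (gray = within a 3 mm band of the surface). Across seeds an
8x12 layout yields gray-contact counts broadly inside the 31–108 range
typical of clinical cohorts; the bundled study-scale fixture uses 16
electrodes (~75 gray contacts, ~1000 triangles), respecting the
practical guidance that ~50+ gray contacts are needed for low-noise
spectra.

`make_wave_recording()` synthesizes plane waves in surface arc-length
coordinates (geodesic distance from a direction pole, so the planted SF
lives in the same metric the estimator uses), with exact per-contact
phase ground truth in a sidecar. `make_phase_field()` builds phase
matrices directly: mixtures of spherical gradient components with known
SFs, 1/f^alpha amplitude profiles, per-component temporal-frequency
offsets (dispersion) that decorrelate the time courses so the SVD can
separate components, optional site-level phase jitter emulating the
sampling-displacement corrections an irregular array imprints on the
LSVs, and optional retention of complex amplitude (`normalize = FALSE`),
in which case planted components stay exactly rank one.

Passing tests on these fixtures show that the estimator recovers known
gradients, orderings and trends under realistic geometry, noise and
sparsity. They do not certify behavior under real cortical folding,
volume conduction, non-stationary artifacts, or clinical contact
localization error beyond the jitter model.

## Design choices in open territory

* **Rejection thresholds.** The three-stage artifact screen uses
  multiples of the stage mean for trials (x3) and sensors (x1.5) and a
  deviation in cell-SD units (x3) for trial-by-sensor cells, with
  recalculation between stages. A z-score reading of the trial rule
  cannot fire on small trial counts (the maximum z in n trials is
  `(n-1)/sqrt(n)`), whereas the multiplicative rule both matches the
  stated convention and behaves sensibly on homogeneous data.
* **Stage-3 replacement axis.** The "average signal" that replaces a hot
  cell is the per-sensor mean across retained trials, computed after
  excluding all over-threshold cells; the choice is recorded in the
  rejection report.
* **White-matter reference ties.** The bottom 50% of white contacts by
  signal SD is the lower `floor(n/2)`, ties broken by contact index, for
  deterministic reproducibility.
* **Analysis ranges.** The regression excludes SFs below the reciprocal
  of the maximum triangle size (estimates there are not meaningful on
  broadband signals); plotting ranges start at half that SF. Individual
  analyses may cap the upper bound at the array's resolvable band — for
  example the singular-weight-reversal benchmark caps at the highest
  planted SF, because bins beyond the field's support contain only noise
  whose logarithm would dominate the fit.
* **Sweep readout.** The surrogate-recovery sweep reads spectrum peaks at
  K = 128 bins over [1, 50] cycles/m: its 14 steps are ~1.08 cycles/m
  apart, which the default 32-bin resolution cannot resolve.
  `spectrum_peak_sf()` also offers standard parabolic sub-bin
  interpolation.
* **Demonstrations.** The random-walk Hankel demonstration uses a
  Gaussian window of `sigma = w/3`: wide enough that the quadrature
  partners of each singular-vector pair stay strongly correlated under a
  quarter-period shift, while still tapering segment edges. The wave
  image demonstration replaces a photograph with a synthetic diagonal
  wave mixture (wavenumbers 1–6 cycles per 512-pixel array, 1/k
  amplitudes, slightly offset TFs standing in for natural dispersion)
  and decomposes the amplitude-retaining band signal: entrywise
  normalization of a dominant wave plus weaker components provably
  mirrors each component about the dominant wavenumber (sidebands at k
  and 2-k), which would split every planted wavenumber into a degenerate
  pair; the complex band signal is one-sided and the components read off
  cleanly as incrementing wavenumbers with decreasing singular values.

## Known limitations

* **Aliasing pedestal.** Triangles larger than half a wavelength wrap;
  their estimates pile up at low apparent SFs. The regression's lower
  bound excludes most of this mass, but fields dominated by high SFs
  (e.g. after singular-weight reversal) retain a pedestal inside the
  window, which weakens — and on sparse arrays can defeat — the expected
  slope reversal. Reversal is therefore demonstrated on a dense
  mixed-spacing array whose resolvable band covers the planted
  components.
* **Array-size resolution limit.** Spatial components closer than
  ~1/(array span) in SF cannot be separated by the SVD; synthetic
  mixtures are planted on a coarser SF grid than that limit.
* **DC-removal bias.** On fields with no standing content the removal
  step's second singular vector is noise, nudging peaks upward; prefer
  `dc_removal = FALSE` when the data were not average-referenced.
* **Problem sizes.** The test suite runs at deliberately modest sizes
  chosen as the package's reference conditions: meshes at icosphere
  subdivision 3–4, 96–240 contacts, 1200–1500 phase samples, 1000–10,000
  permutations. The estimator itself handles the ~120-contact,
  10^6-sample scale of real recordings; only the geodesic graph and the
  exhaustive C(n,3) triangle enumeration grow combinatorially, and both
  remain comfortable for n <= ~300 contacts.

## Reproducing the numbers

`scripts/acceptance.R` recomputes the package's deterministic reference
quantities (the realized half-power band of the two-cycle wavelet at
4.5 Hz) from the installed package and writes them as JSON; the test
suite under `tests/testthat` re-derives every other claim — surrogate
recovery, slope reversal, sparsity robustness, triangle-size tuning,
type-I calibration, and planted-wave localization — from synthetic data
generated at run time.
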