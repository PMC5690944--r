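---
title: "Methods: CBCT noise simulation and DIR error quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBCT noise simulation and DIR error quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirqc)
```

`dirqc` implements two workflows that are usually coupled in practice:
turning a planning CT into a pseudo-CBCT by adding noise matched in
magnitude and texture to a clinical cone-beam protocol, and quantifying how
well a deformable registration reproduces a known ground truth. This
vignette is the package's own account of the underlying models, the
numerical choices, and what the synthetic test conditions do and do not
demonstrate.

## Noise power spectrum measurement

Image noise has a magnitude (the standard deviation σ over a uniform
region, in HU) and a texture (how that variance is distributed over spatial
frequency). Both are captured by the noise power spectrum. The measurement
follows the standard CT procedure: a uniform phantom is scanned (twice, if
subtraction detrending is wanted), square ROIs are sampled at a fixed
radius from the slice centre — the default geometry is 16 ROIs of 40 px on
a radius-80 px circle over ~20 slices, giving 320 patches — each ROI is
detrended, and the scaled periodogram

$$S(u, v) = \frac{\Delta_x \Delta_y}{N_x N_y}\,\bigl|\mathrm{DFT}(p)\bigr|^2$$

is averaged over all patches. With this normalisation the Cartesian sum
$\sum S \,\delta u\, \delta v$ equals the mean patch variance exactly
(Parseval), and the units come out as HU² mm² against mm⁻¹. Because CT
reconstruction is (approximately) rotationally symmetric in-plane, the 2D
spectrum is reduced to a 1D radial profile by averaging over annuli one DFT
bin wide, from 0 to the Nyquist frequency $1/(2\Delta)$.

Numerical notes, all visible in the test suite:

* **Annular truncation.** A radial profile that stops at Nyquist covers only
  the inscribed disc of the DFT square. For band-limited spectra (every
  spectrum this package synthesizes) that is lossless and the polar
  integral $2\pi\int f\,S(f)\,df$ (`nps_variance()`) equals the variance.
  For *white* noise, which fills the whole square, the disc holds exactly
  $\pi/4 \approx 78.5\%$ of the power; variance bookkeeping for such spectra
  must use the 2D Cartesian integral (`nps2d_integral()`), which is what the
  white-noise recovery checks assert.
* **Annulus discreteness.** The annular mean at the lowest few frequencies
  averages over only a handful of DFT cells and over radii that differ
  noticeably from the bin centre; where the spectrum is steep (the ramp-up
  region) this produces a few-percent bias in the first bins. Tests compare
  profiles away from those bins.
* **Detrending.** The order-2 polynomial surface fit (default) removes the
  cupping-like low-frequency structure a uniform phantom shows; it is an
  orthogonal projection, so it necessarily also absorbs genuine noise power
  in the two lowest annuli. Subtraction detrending — the co-located ROI of a
  repeat scan, divided by $\sqrt 2$ so the result has single-scan power —
  keeps those bins but needs two acquisitions. Above the affected bins the
  two routes agree to a few percent RMS on simulated scans, which is why
  either is acceptable; polynomial detrending is the default because it
  needs one scan. The polynomial order is fixed at 2: enough for cupping,
  low enough not to eat the stochastic texture.
* **No window.** ROI patches are not tapered before the DFT. A window would
  reduce spectral leakage between bins at the cost of an effective-area
  correction; for the smooth, broad spectra of CT noise the leakage is
  negligible and the unwindowed estimator keeps Parseval exact.

## The parametric spectral model

Measured radial profiles are summarised by

$$f(x) = a_1\, e^{-\left((x - a_2)/a_3\right)^2}\,\bigl(1 - e^{-a_4 x}\bigr),$$

a Gaussian bell (centre $a_2$ in mm⁻¹, width $a_3$) carrying the
mid-frequency peak and high-frequency roll-off of the reconstruction
apodisation, multiplied by an exponential ramp-up (rate $a_4$, mm) from the
ramp filter's suppression of low frequencies; $f(0) = 0$ always. $a_1$
(HU² mm²) sets the scale, and because the model's variance is linear in
$a_1$, rescaling to any target magnitude is exact arithmetic:
`scale_to_sigma()` multiplies $a_1$ by $\sigma_\text{target}^2 /
\sigma_\text{current}^2$, with the current variance computed by the polar
integral on a 512-point profile out to the synthesis grid's Nyquist.

Fitting is bounded Levenberg–Marquardt least squares with uniform weights
(`minpack.lm`), at most 2000 model evaluations and a cost tolerance of
1e-10. Initialisation: $a_2$ at the profile peak, $a_1$ at the peak power,
$a_3$ from the half width at half maximum, $a_4 = 5/a_2$. Degenerate inputs
(all-zero profiles, fewer than 8 points) are refused.

**The $(a_1, a_4)$ ridge.** The product
$a_1(1 - e^{-a_4 x})$ is nearly invariant when $a_1$ is raised and $a_4$
lowered together, so these two coefficients are poorly conditioned
individually: under independent few-percent perturbations of the profile the
fitted curve and its integral are recovered to better than a percent while
$a_4$ alone can move by tens of percent, and occasionally the global optimum
sits far along the ridge. Users should treat $a_2$, $a_3$ and derived
quantities (curve, σ) as the reliable outputs of a fit; the tests encode
exactly this.

## Noise synthesis and pseudo-CBCTs

A 1D profile (measured or modelled) is expanded to a 2D spectrum by
evaluating it at each DFT bin's radial frequency (linear interpolation;
zero beyond the profile's range, so synthesized spectra are band-limited to
the Nyquist disc). A complex spectrum is then built with **fixed**
magnitude $\sqrt{S \cdot N_x N_y / (\Delta_x \Delta_y)}$ and uniformly
random phases under Hermitian symmetry (self-conjugate bins get a random
sign), the DC bin is zeroed, and the inverse FFT gives a real, exactly
zero-mean noise slice. Fixed amplitudes — rather than the Rayleigh-random
amplitudes a Gaussian random field would have — mean every single
realization carries exactly the requested spectrum and variance; only the
phases (hence the visual pattern) differ between slices. This makes texture
and magnitude tests sharp, at the cost of marginally non-Gaussian
single-bin statistics; the alternative would only spread the same expected
power across realizations.

`make_pseudo_cbct()` adds an independent realization to each axial slice
(slice *k* seeded with `seed + k − 1`, so volumes are reproducible and
parallel-safe); there is no through-slice noise correlation, consistent
with a slice-wise 2D measurement. When a target σ is requested the model is
first rescaled analytically and the gridded spectrum then renormalised so
its discrete integral equals $\sigma^2$ exactly, removing the residual
quadrature error of the 1D→2D gridding. Spacing, origin and shape are never
altered; HU are not clipped unless asked (clipping would distort the noise
distribution in air and bone).

What this emulates — and what it does not: the generator reproduces the
*stochastic* component of CBCT image quality. Cupping, ring and streak
artifacts, aliasing, and scatter-induced HU shifts are deliberately out of
scope; a registration pipeline that passes the tests here has been shown
robust to CBCT-like noise, not to CBCT artifacts in general.

## Registration error quantification

With a ground-truth field mapping the primary grid to the secondary image
and a test field mapping the (colocated) deformed-secondary grid to the
same secondary image, both vector sets start at the same points, and the
per-voxel registration error is the Euclidean norm of their difference —
the distance between the two mapped endpoints in mm. Direction bookkeeping
is mandatory: fields carry `"A->B"` tags and comparisons with different
target images are refused rather than silently flipped. Landmark error is
the distance between a point propagated by trilinear interpolation of the
displacement and its reference position; trilinear interpolation reproduces
affine fields exactly, which the tests exploit as an exactness oracle.

Statistics follow registration-QA conventions: mean, median and max error
and the percentage of voxels/points with error **strictly** below 2 mm
(the digital-phantom goal in registration QA is 95%). For even counts the
median is the lower of the two central order statistics by default —
deterministic on integer-valued toy fixtures — with the conventional
midpoint available as an option. Contour masks restrict any of these to a
structure; reports add a whole-grid row.

## Local refinement

The refinement primitives mirror user-guided correction tools in commercial
DIR software: `box_ssd_align()` performs an exhaustive integer-voxel
translation search minimizing the *mean* squared intensity difference of a
user box (mean rather than sum, so scores are comparable across box sizes),
with ties broken by smallest translation norm and then lexicographically on
(z, y, x); `apply_locks()` replaces individual DVF vectors, later locks
winning at duplicate positions. Rotation, sub-voxel optimisation and the
propagation of a lock's influence through a deformable solver are
intentionally not implemented — the last is the job of the (typically
proprietary) DIR engine that consumes the locked field.

## Synthetic fixtures

All tests run on generated data. Uniform-phantom pairs share a
deterministic quadratic trend (cupping-like) and carry independent noise —
white Gaussian at a chosen σ, or spectrum-shaped via the synthesis path.
Displacement fields are sums of closed-form components (constant, affine,
Gaussian bump), so the exact displacement is available at every point, not
just on the grid; registration cases add a constant bias plus iid Gaussian
perturbation, for which the error magnitude follows a (noncentral) 3D chi
distribution with closed-form mean, median and tail probabilities. The
default geometry mirrors clinical CBCT head protocols (512², 0.475 mm
pixels); test runs use 128²–256² grids and the full 512² × 20 geometry only
where the measurement chain itself is under test, sizes chosen to keep the
suite desk-scale. The bump-peak default of 14 mm reflects the
large-deformation end of 4D-CT lung motion; typical lung cases are nearer
7 mm.

What passing these tests shows: the estimator chain is unbiased and
Parseval-consistent, synthesis reproduces requested spectra exactly in
ensemble, the error metrics agree with closed forms and brute-force
recomputation, and the whole pipeline is seed-deterministic. What they do
not show: behaviour on real scanner data with non-stationary noise,
off-centre radius-dependent spectra, or CBCT artifacts — and nothing here
validates any particular deformable algorithm.

## Known limitations

* NPS is measured and synthesized in 2D per slice; no 3D spectrum.
* Only axis-aligned, identity-orientation grids are accepted; anything else
  errors rather than resamples.
* The DICOM reader handles uncompressed explicit-VR little-endian CT slices
  only.
* `fit_nps_model()` reports, but cannot remove, the $(a_1, a_4)$
  ill-conditioning discussed above.
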