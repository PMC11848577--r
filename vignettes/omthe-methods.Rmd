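---
title: "Optical time-harmonic elastography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical time-harmonic elastography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`opelast` implements the computational core of optical multifrequency
time-harmonic elastography (OMTHE): stiffness mapping from shear waves that
are optically encoded as sub-pixel motion in camera movies. This vignette
explains the models, the parameters that matter, and the design choices made
where the method description leaves the design open. It states no empirical
result beyond what the package's own tests and acceptance script compute.

## The physical model

A sample vibrated at a drive frequency $f$ carries time-harmonic shear
waves. Writing $\omega = 2\pi f$ and using the ansatz
$u(r, t) = \mathrm{Re}\,\hat u(r)\,e^{i\omega t} =
\hat u' \cos\omega t - \hat u'' \sin\omega t$, the in-plane displacement
field is fully described by the complex amplitude
$\hat u = \hat u' + i \hat u''$ per component. All modules share this sign
convention.

In a locally homogeneous, incompressible medium the shear wave speed obeys
$\mathrm{SWS} = \sqrt{G'/\rho}$, and the magnitude shear modulus follows
from the Helmholtz relation $|G^*|\,|\nabla^2 \hat u| = \rho\,\omega^2
|\hat u|$. The density default is $\rho = 1000$ kg/m$^3$ (1 kg/L), the
standard assumption for soft biological tissue.

### Wave simulation (`solve_helmholtz`)

Per in-plane component the package solves the scalar heterogeneous
Helmholtz equation
$$\nabla\!\cdot\!\left(G \nabla \hat u\right) + \rho \omega^2 \hat u = 0,
\qquad G = \rho\,\mathrm{SWS}^2 (1 + i\eta),$$
with second-order central differences in flux form on the pixel grid, a
uniform Dirichlet source line on one boundary edge (top edge for the
x-component, left edge for the y-component — a planar source perpendicular
to the main propagation direction), and first-order Sommerfeld radiation
conditions $\partial \hat u/\partial n = -ik\hat u$ with local
$k=\omega/\mathrm{SWS}$ on the remaining edges. The complex sparse system is
solved exactly (sparse LU on the equivalent real system of twice the size).

*Loss factor.* The choice of damping model is open; a complex modulus
$G(1+i\eta)$ with default $\eta = 0.05$ is used: it reproduces the qualitative wave damping expected in soft regions at
high frequency and keeps the discrete system away from resonances. $\eta$
is a configuration parameter.

*Accuracy.* On homogeneous media the simulated wavelength matches
$\mathrm{SWS}/f$ within 2% once the domain is wide enough; a narrow domain
shows a slightly longer apparent wavelength because the absorbing side
walls impose lateral decay (a waveguide effect, not a discretization
error). The wavelength fidelity test uses a wide domain for that reason.

### Acquisition model (`build_schedule`, `encode_motion`)

The camera runs at a fixed frame rate (default 4500 fps) while each drive
frequency is excited in turn; 8 frames per vibration cycle over 3 cycles
are recorded after skipping 4 settling cycles. For drive frequencies above
half the frame rate the sampling is stroboscopic (sub-Nyquist): the wave is
aliased, but since the motion is time-harmonic at a known frequency, the
exact phase $\phi_j = 2\pi f t_j \bmod 2\pi$ of every frame is known. The
schedule records these phases, and *every* downstream consumer uses the
recorded phases rather than assuming uniform spacing — this contract is
what makes aliased acquisition exact. A schedule whose phases collapse
(drive frequency an exact multiple of the frame rate) is rejected.

Movies are rendered by resampling a texture image at $r - u(r, t_j)$
(pull-back warp) with Catmull–Rom bicubic interpolation; the field is
rescaled so the maximum instantaneous displacement over all frames and
pixels equals 10% of the pixel size (the reference operating point).
Following the simulation protocol, the configured white noise (default
10%) is added to the real-valued *displacement* time series before
warping, not to image intensities. Intensities are quantized to 16-bit
levels by default so that TIFF round trips are bit-exact.

*Texture.* The synthetic texture is a unit background plus Gaussian
features of 2 px FWHM. The feature density default is 0.2 features/px.
A sparser texture (e.g., 0.02/px) leaves most pixels without gradient
information; the optical-flow solution then interpolates harmonically
between features and the recovered amplitude sags measurably between
them. At 0.2/px essentially every pixel carries texture and the
plane-wave fidelity tests pass with <10% amplitude error.

### Harmonic optical flow (`solve_hof`)

Inserting the harmonic ansatz into the Horn–Schunck objective and
integrating over one period yields per-pixel normal equations built from
two period statistics: the structure tensor $m[\nabla I \nabla I^\top]$
(temporal mean) and the complex harmonic coefficient of
$(\partial I/\partial t)\,\nabla I$ at the drive frequency. The temporal
derivative is taken analytically from the per-pixel harmonic fit of $I$
against the recorded phases — exact for time-harmonic signals and robust
under stroboscopic sampling — and the projection is divided by $i\omega$'s
phase factor so the unknown is a displacement. The field is obtained by
iterating
$$\hat u^{(n+1)} = \left(m[\nabla I \nabla I^\top] + \lambda
\mathbb{I}\right)^{-1}\left(\lambda \bar{\hat u}^{(n)} - F\right),$$
a closed-form 2×2 solve per pixel, where $\bar{\hat u}$ is the
center-excluded uniform mean over a $(2N+1)\times(2N+1)$ window and a
median filter is applied to the real and imaginary parts of each component
every iteration. Iteration starts from zero and stops at `max_iter`
(default 100) or relative change below `tol` (default $10^{-4}$).

*Kernel size.* $N = \mathrm{round}(64\,\mu m / h)$, clamped to $\ge 3$,
keeps the physical smoothing span constant across magnifications.

*Regularization weight.* $\lambda$ defaults to $0.03\times$ the spatial
mean of the tensor trace, making it invariant to intensity rescaling.
Horn–Schunck smoothing attenuates wavelengths comparable to the kernel:
the fixed-point gain per pixel is roughly $m/(m + \lambda(1-g(k)))$ with
$g$ the window's response. Fidelity sweeps on noise-free encoded plane
waves showed that a weight of $0.1\times$ trace costs >20% amplitude at
wavelengths a few kernel widths long, while $0.03$ keeps the loss below
~10% without visible noise breakthrough; $0.03$ is therefore the package
default. Note that a *global* amplitude attenuation cancels in the MDEV
ratio, so SWS maps are far less sensitive to this choice than raw
amplitudes.

*Median filter.* The per-iteration median window is
$\min(N, 11)$ px: a 32-px median (the formula value at $h = 2\,\mu m$)
destroys fine structure, so the window is capped and configurable.

*Operating regime.* Like all Horn–Schunck-type estimators, HOF is accurate
for waves long compared to its smoothing kernel; the intended data have
wavelength-to-kernel ratios of roughly 10–30. Fidelity contracts are
therefore tested at $\lambda \gtrsim 10N$, and decoding accuracy should
not be expected at wavelengths approaching the kernel size.

### MDEV inversion (`mdev_modulus`)

The multifrequency dual elasto-visco estimator compounds magnitudes
*before* dividing:
$$|G^*| = \rho\,\frac{\sum_{j}\sum_m \omega_m^2\,
|\hat u_j(\omega_m)|}{\sum_{j}\sum_m |\nabla^2 \hat u_j(\omega_m)|},$$
summing both in-plane components $j$ and all band frequencies $\omega_m$.
Standing-wave nodes, where a single-frequency inversion is undefined or
noise-dominated, are filled by the other frequencies whose nodes lie
elsewhere. No spatial bandpass filter is applied anywhere between decoding
and inversion; noise suppression comes from long-lag derivative kernels.

*Gradients.* The long-lag gradient averages lagged central differences
over an optional neighborhood and is implemented verbatim (lags
$s_1 = s_2 = 10$ px by default, averaging radii $r_1 = r_2 = 0$ at the
module level). The *pipeline* default uses $r_1 = r_2 = 1$: averaging the
lagged differences over a 3×3 neighborhood is the scheme's own mechanism
for robust differentiation, and it is what makes the compound map over a
homogeneous medium meet the package's uniformity contract (relative
standard deviation below 5% at the reduced reference scale; without it
the magnitude-rectified decode error in the Laplacian denominator leaves
~7% speckle in the map). Averaging radii much larger than 1 over-smooth
the derivative response and bias SWS upward.

*Laplacian.* The derivative kernel of the inversion spans 20 px. Applying
the long-lag gradient twice would span 40 px and carry the spectral
response $-(\sin(ksh)/(sh))^2$, which overestimates in-band SWS by up to
~30% at the highest band frequency on the reference phantom — incompatible
with the observed in-band plateau. The default Laplacian is therefore the
lagged second central difference
$(y_{k+s} - 2y_k + y_{k-s})/(sh)^2$ per direction: it spans exactly
$2s = 20$ px, is exact on quadratics, and its response
$-(2\sin(ksh/2)/(sh))^2$ keeps the worst-case in-band bias under ~12%.
The gradient-twice variant remains available
(`laplacian(..., method = "gradient_twice")`).

*Guards.* Pixels whose compound Laplacian magnitude falls below
$10^{-9}\times$ its spatial median are masked, as is the stencil border;
SWS maps carry the mask as `NA`.

### Preprocessing

Exposure series are merged by tent-weighted averaging of
intensity/exposure (saturation threshold 0.98 of full scale). Contrast
normalization is plain CLAHE (clipped tile histograms, bilinear mapping
interpolation; defaults 8×8 tiles, clip 0.01, 256 bins). Note that tiled
CLAHE is only *approximately* idempotent: the bilinear blending of
neighboring tile mappings reshapes local histograms, and the clip limit
contracts the mapping only geometrically, so repeated passes converge to
a fixed point rather than stopping after one; exact one-pass idempotency
holds for the global (1×1-tile) limit, and the tests check exactly that.
Rigid registration estimates translations by Hann-windowed phase
correlation with local DFT upsampling (0.02 px grid) and resamples with
the same bicubic warp as the encoder; it cancels bulk motion and the
spatially uniform translation produced by compression waves, which is why
no compression-wave bandpass is needed later.

For *synthetic* movies the reference pipeline applies registration but
not CLAHE: a uniformly lit synthetic movie has no illumination changes to
remove, and per-frame equalization injects temporal intensity modulation
(local histograms shift as features move) that measurably degrades
decoding. For real acquisitions with varying illumination CLAHE remains
the default.

## The reference experiment

`reference_config()` assembles the full study conditions: a 500×500 px phantom
at 29.609 µm pixels (background 3.6 m/s, one soft 2.7 m/s and one stiff
4.5 m/s circular inclusion of radius 12% of the grid), twelve drive
frequencies 0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.7, 1.9, 2.1,
2.4 kHz at 4500 fps, 10%-of-pixel amplitude, 10% displacement noise, and
compounding over 800–2400 Hz. `grid_scale = 0.5` runs the same physical
experiment on a 250×250 grid: the pixel size doubles so the field of view,
the waves-per-image counts and the physical span of the derivative kernel
(the lags scale as `round(10 * grid_scale)`) are unchanged. The acceptance
script and the end-to-end tests use this reduced grid; the full-size grid
is configuration only, not a different model.

Inclusion centers are placed at 30%/70% of the grid diagonal. The exact
positions are not stated with the source material; they only need to keep
the inclusions disjoint and away from the masked border.

## What the synthetic data do and do not emulate

The generator reproduces: piecewise-constant stiffness with damping,
planar-source multifrequency excitation, stroboscopic sampling with exact
phase bookkeeping, sub-pixel speckle motion at 10% of a pixel, additive
displacement noise, and 16-bit quantization. It does not emulate: camera
shot noise and sensor nonlinearity, rolling shutter, illumination drift,
out-of-plane (z) motion, surface-wave modes (Rayleigh/Lamb/Love), or
viscosity dispersion (the loss factor is frequency-independent). Passing
tests therefore demonstrate correctness of the decoding/inversion chain
under the stated acquisition model, not robustness to every real-camera
artifact.

## Numerical choices and degenerate inputs

* Complex sparse systems are solved via the augmented real form (exact LU).
* The harmonic fit requires ≥3 distinct phases; rank-deficient designs are
  rejected with an explicit error, as are schedules whose phases collapse.
* `encode_motion` refuses displacements beyond 2 px (sanity bound).
* A zero movie decodes to exactly zero; a zero field has SNR $-\infty$.
* Region statistics exclude masked (`NA`) pixels; empty regions report
  `n = 0` with `NA` statistics.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; identical configurations reproduce bit-identical outputs.

## Problem sizes used by the test suite

Unit tests run on grids between 20² and 160²; the end-to-end acceptance
checks use the 250×250 reduced reference grid with all twelve band
frequencies plus one frequency below (400 Hz) and above (3.2 kHz) the band
to exhibit the expected under/overestimation outside the plateau. These
sizes were chosen as the smallest that leave the physics (waves per
image, kernel-to-wavelength ratios) unchanged.

## Known limitations

* Scalar (per-component) wave physics: mode conversion and compressional
  coupling are outside the model, matching the xy-plane-strain assumption.
* HOF accuracy degrades for wavelengths comparable to its smoothing
  kernel (see operating regime above); at the reference resolution this
  matters only above ~3 kHz.
* The loss modulus G″ is not mapped; the inversion returns |G*| and SWS
  only.
* Registration is translation-only by default; rotation is carried in the
  transform record but not estimated.
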