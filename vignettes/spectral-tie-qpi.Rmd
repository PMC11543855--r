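---
title: "Spectral transport-of-intensity phase retrieval: model, solver and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral transport-of-intensity phase retrieval: model, solver and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(spectralTIE)
```

## The physical model

A transparent microscopic object of height $h(x,y)$ and refractive-index
contrast $\delta n$ delays a coherent wavefront by a phase
$\phi = \frac{2\pi}{\lambda}\, h\, \delta n$. The scalar field
$\tilde E = \sqrt{I}\,e^{i\phi}$ propagates paraxially; in this package the
forward convention is $e^{+ikz}$ and a converging lens multiplies the field
by $e^{-i\phi_\text{lens}(r)}$. Fresnel propagation over a distance $z$ is a
convolution with the chirp kernel
$h_z = \frac{e^{ikz}}{i\lambda z} e^{ik(x^2+y^2)/2z}$, implemented as a
frequency-domain transfer function when the sampling criterion
$\lambda|z| \le N\,\Delta^2$ holds ($\Delta$ the pixel pitch, $N$ the padded
side length), and as a convolutional chirp otherwise. Mirror padding
(factor 2, on by default) suppresses FFT wrap-around for compact fields;
tests that need exact unitarity use periodic screens without padding.

To first order in $z$ the intensity and phase obey the transport pair

$$\frac{\partial I}{\partial z} = -\frac{\lambda}{2\pi}\nabla\!\cdot\!\big(I\nabla\phi\big),
\qquad
\frac{\partial \phi}{\partial z} = \frac{1}{2k}\Big(-|\nabla\phi|^2
 + \frac{\nabla^2 I}{2I} - \frac{|\nabla I|^2}{4I^2}\Big).$$

The phase-transport normalization deserves a note: the literature sometimes
prints the right-hand side with $k$ rather than $2k$. We fix the constant by
requiring that `tpe_rhs()` equal the finite-difference phase evolution of
`fresnel_propagate()` on smooth fields — the package's own propagator is the
arbiter, and the test suite enforces agreement within 2%.

## Chromatic defocus multiplexing

A hyperboloid metalens imprints the fixed (wavelength-independent, in
radians) profile $\phi(r) = \frac{2\pi}{\lambda_0}(\sqrt{r^2+f_0^2}-f_0)$.
Treated as a diffractive element, its focal length obeys
$\lambda f = \text{const}$: red light focuses shorter than green, blue
longer. With the sensor fixed at the green image plane of a 2f–2f train,
each color channel of one RGB exposure records the object at a different
defocus — a through-focus stack in a single shot.

Two distinct "defocus" numbers describe each channel, and the package keeps
both explicit:

* the **physical defocus** $z_c = f(\lambda_G) - f(\lambda_c)$ from the
  exact product law (+152 µm for red, −165 µm for blue at $f = 1$ mm),
  which is what the simulator propagates and what divides the intensity
  difference in the solver; and
* the **green-equivalent (stack) position** $z_c\lambda_c/\lambda_G$
  implied by the $\zeta = \lambda z$ equivalence of Fresnel patterns
  (+179 µm / −141 µm), which is where a channel plane matches a green
  through-focus stack, and equals the linearized focal shift
  $f\,\delta\lambda/\lambda$.

`calibrate_channel_defocus()` measures the second and, by default, rescales
to the first. The distinction is invisible to first order in
$\delta\lambda/\lambda$ — which is why single numbers near 180–190 µm are
commonly quoted for this geometry — but at $\delta\lambda/\lambda = 18\%$
the two differ measurably, and conflating them skews recovered heights by
the same ratio.

## The inverse solver

`qpi_retrieve()` estimates the phase from one capture in three stages.

**Derivative estimation.** `estimate_dI()` forms the spectral intensity
derivative from two channels (red–green by default; the blue channel of
real sensors has the poorest signal-to-noise ratio) or from a
weighted pairwise-slope combination of all three (exact for planes linear
in wavelength). The axial derivative follows from the channels' physical
defocus spacing.

**Regularized double Poisson inversion.** With the Helmholtz substitution
$I\nabla\phi = \nabla\psi$ the transport equation becomes two nested
Poisson problems, solved in the Fourier domain by dividing by
$k_x^2+k_y^2+\epsilon$. The Tikhonov constants default to four times the
fundamental mode, $\epsilon = \epsilon' = 4\,(2\pi/N\Delta)^2$, and stay
fixed between calibration and measurement. Zero frequency is unobservable:
every solve subtracts the mean, and all comparisons are gauge-free
(mean-removed, or plateau-minus-gap for step targets). Spectral (FFT)
gradients are used inside the solver so the per-mode attenuation is exactly
$k^2/(k^2+\epsilon)$ per stage; this is tested to machine precision.

**Iterative refinement.** The first inversion linearizes both in defocus
and in phase. Refinement iterations forward-propagate the current field
estimate (with the object's $1/\lambda$ phase dispersion) to every channel
plane with the full Fresnel propagator, re-estimate the derivative, and
feed the residual back through the inversion. Two numerical devices make
this iteration reliable:

* each update is preconditioned per Fourier mode by the Wiener-regularized
  inverse of the exact linearized contrast transfer $s(k)$ of the
  finite-defocus difference ($s/(s^2+\delta)$, $\delta = 0.05$), and
  band-limited at the first zero of the contrast transfer function,
  $k_\text{max} = 2\pi/\sqrt{\lambda z_\text{max}}$ — beyond it a
  finite-defocus pair simply carries no invertible phase contrast;
* after the residual loop, an amplitude-projection stage (60 cycles by
  default) enforces the measured modulus at every defocused plane by
  propagate / replace-modulus / back-propagate, accumulating wrap-safe,
  band-limited phase increments. Derivative-only iterations stagnate for
  strong binary phase objects at a twin-image mixture some 25% low in step
  height; the projection stage resolves this because the raw moduli, unlike
  the differences, discriminate the twin.

Because the solver integrates derivative data rather than wrapping an
arctangent, the recovered phase is unwrapped by construction; ranges of
many $2\pi$ are returned directly. Divergence (two consecutive residual
increases) stops the loop and keeps the best iterate, flagged in the
result.

```{r small-example}
grid <- sampled_grid(128, pixel_pitch = 2)
star <- siemens_star(grid, n_spokes = 8, height = 0.25, index_contrast = 0.52)
train <- optical_train(aperture_radius = 250, focal_length = 1000)
capture <- simulate_capture(star, train)
fit <- qpi_retrieve(capture, qpi_params(max_iterations = 6, projection_iterations = 20),
                    index_contrast = 0.52)
fit
star_step_height(fit$height, star)   # um; ground truth 0.25
```

## What the generator emulates — and what it does not

The phantoms are pure-phase height maps with known $\delta n$:

* `siemens_star()` — binary radial target (250 nm tall, $n = 1.52$ by
  convention for the validation scenario); hard edges so ground truth is
  exact.
* `precision_diffuser()` — Gaussian random screen with Gaussian
  autocorrelation (1/e width = feature size, 7 µm default). The divergence
  contract maps the quoted scatter angle to a per-axis RMS phase slope
  $\tan\theta \cdot 2\pi/\lambda$; the far-field beam then has that RMS
  angular half-width, verified by simulation. A caveat discovered while
  validating: a Gaussian random field with 5° divergence over 7 µm features
  has curvature tails far beyond the "lenslet" estimate, so caustics form
  at ~30–40 µm rather than the $2p^2/\lambda \approx 185$ µm scale of the
  periodic-feature estimate — engineered diffusers control their slope
  distribution; a Gaussian field does not.
* `filament_phantom()` — overlapping cylindrical-profile ribbons with
  helical modulation, peak-to-peak phase calibrated at the nominal
  wavelength. The chord profile has an edge cusp of unbounded slope, which
  no grid can represent; a small Gaussian `smoothing` (default 1 px) and a
  Tukey `edge_window` (default on) keep phantoms representable and
  compatible with Fourier-periodic solvers.

The sensor chain adds Bayer RGGB mosaic/bilinear demosaic (off by default:
the solver assumes co-registered planes), Poisson photon + Gaussian read
noise under a fixed seed, and intensity-only transmission through a
hexagonal fiber bundle (8 µm pitch reconciling 3 µm cores with
18,000 cores/mm²; cores average intensity over their disk, cladding is
dark). Not modeled: fabrication nonidealities (e.g. secondary foci),
per-channel magnification disparity (an optional concern the solver does
not correct by default), fiber bending or cross-talk, camera nonlinearity,
volumetric scattering.

## Validity regimes and test design

Passing tests demonstrate correctness of the implementation inside the
transport model's validity envelope, not performance on arbitrary real
scenes. The envelope matters:

* **Weak-to-moderate phase** ($\sigma_\phi \lesssim 1$ rad for random
  textures): the spectral depletion of the in-band linear term
  ($\langle e^{i\phi}\rangle$-type factors) is small and recovery is
  quantitative. The 20-seed diffuser-ensemble test therefore uses 1°
  screens at short defocus; 5° screens ($\sigma_\phi \approx 5$ rad)
  measurably violate the linearization in-band — their in-band derivative
  is tens of percent below the transport value even at numerically exact,
  vanishing defocus — and develop localized $2\pi$ slips. The 5° contract
  itself is exercised where the instrument uses such screens: correlation-based
  calibration, where no inversion is involved.
* **Strong smooth phase** (the ~10π filament): quantitative as long as
  $|\nabla\phi|$ stays well below the grid Nyquist and the defocus keeps
  $\pi\lambda z f^2$ small for the object's feature content; the test runs
  at ±6 µm defocus, 80 µm ribbons.
* **Strong binary phase** (the validation star at 1.54 rad): the
  projection stage is required; the plateau is measured as the gauge-free
  median difference between eroded spoke interiors and gaps, restricted to
  radii whose local period exceeds the transport blur scale
  $\sqrt{\lambda z}$.

Problem sizes used by the shipped checks: unit tests run on 32–256 px
grids; the end-to-end validation scenario uses a 512×512 grid at 1 µm
pitch (star radius 200 µm, 16 spokes); the diffuser ensemble uses twenty
128 px screens. These sizes put every relevant length scale (feature,
blur scale $\sqrt{\lambda z}$, field of view) in the same ratios as the
tabletop geometry while remaining convenient to recompute.

## Numerical choices

* Lengths are micrometres internally; wavelengths cross the API in
  nanometres.
* Discrete gradients in the *rate evaluators* (`tie_rhs`, `tpe_rhs`) are
  second-order central differences with one-sided edge stencils; the
  *solver* uses spectral derivatives to stay consistent with its spectral
  Laplacian inversion.
* `intensity_floor` (default 0.05) clamps the central intensity before the
  $\nabla\psi/I$ division; dark-cladding captures rely on it.
* Contrast curves use 5th/95th percentile extrema along each circle with a
  single global baseline shift (map 1st percentile to zero). A per-circle
  baseline would make any blurred pattern score ≈ 1 — the shift removes
  exactly the rising gap level that encodes the blur — so the global
  anchor is used; the exact binary target still scores exactly 1, and
  regularization can push low-frequency contrast above unity, as observed.
  The resolution estimate is the largest radius below which contrast stays
  under a threshold (default just below 1; a 0.5 threshold reproduces the
  classic half-contrast criterion and matches $\lambda/2\mathrm{NA}$ on an
  incoherent diffraction-limited simulation within a few percent).
* Degenerate inputs: all-zero derivatives return zero phase with a notice;
  featureless (exactly in-focus) planes calibrate by minimum stack
  contrast; boundary correlation peaks are errors, not extrapolations.

## Known limitations

The equivalent-defocus reduction replaces the full conjugate-plane imaging
(with its per-channel magnification and field curvature) by pure defocus of
the in-focus field; this is the same reduction the solver inverts, so the
package is self-consistent, but real single-lens data additionally carry
magnification disparity between channels. Two-plane one-sided data leave
modes near contrast-transfer zeros unrecoverable in principle; more
spectral channels would fill them. The fiber-bundle model transmits only
~13% of the area (dark cladding at the stated core/pitch numbers), a
harsher regime than real bundles whose cores nearly tile the facet.
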