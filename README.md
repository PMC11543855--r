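# spectralTIE

Single-shot quantitative phase imaging (QPI) by spectral multiplexing of
defocus through a chromatically dispersive hyperboloid metalens — a forward
optical simulator plus the spectral transport-of-intensity inverse solver,
for imaging scientists studying propagation-based phase retrieval and
computational endoscopy.

## The idea

A transparent object of height $h$ and index contrast $\delta n$ shifts the
phase of a wavefront by $\phi = \frac{2\pi}{\lambda} h\,\delta n$ without
changing its intensity at focus. Away from focus, phase turns into
measurable intensity contrast according to the transport of intensity
equation (TIE)

$$\frac{\partial I}{\partial z} = -\frac{\lambda}{2\pi}\,\nabla\cdot(I\nabla\phi).$$

A hyperboloid metalens is strongly chromatic: its focal length obeys
$\lambda f = \mathrm{const}$, so the red, green and blue channels of an
ordinary color camera record three *different defocus planes* in one
exposure. The spectral intensity derivative $\mathrm{d}I/\mathrm{d}\lambda$
then stands in for the axial derivative ($\lambda\,\mathrm{d}z = -z\,
\mathrm{d}\lambda$), and the TIE is inverted by two regularized FFT Poisson
solves ($\psi$ from $I\nabla\phi = \nabla\psi$, then $\phi$), followed by
iterative refinement against the full Fresnel forward model. The recovered
phase is unwrapped by construction and converts to physical height as
$h = \phi\lambda/(2\pi\,\delta n)$. Because each fiber of a coherent
endoscope bundle preserves per-color intensity while scrambling phase, the
scheme survives transmission through an intensity-only fiber bundle.

The package provides:

* **optics** — sampled complex fields, alias-safe Fresnel propagation
  (transfer-function / impulse-response kernels), hyperboloid lens phase,
  the chromatic focal law, TIE/TPE rate evaluators, digital refocusing;
* **phantoms** — Siemens star, precision-diffuser random screens, filament
  (alga-like) ribbons, all pure-phase with exactly known ground truth;
* **sensor model** — effective channel wavelengths from source × Bayer
  curves, single-shot three-channel capture, RGGB mosaic/demosaic, photon +
  read noise, hexagonal fiber-bundle transmission;
* **solver** — `qpi_retrieve()`, a fitting function returning a classed
  object with `print`, `summary`, `coef`, `fitted`, `residuals`,
  `predict` (digital refocusing) and `plot` methods; plus channel-defocus
  calibration against a through-focus stack;
* **metrics** — gauge-free phase RMSE, the Siemens-star contrast transfer
  curve, step-height measurement, honeycomb spectral power, and the
  closed-form optical budget (NA, lateral resolution, height sensitivity,
  sampling).

## Worked example

Simulate the validation scenario — a 250 nm tall Siemens star of index 1.52
imaged through a 1 mm, NA 0.25 metalens train — and recover its height from
the single synthetic RGB capture:

```r
library(spectralTIE)

grid  <- sampled_grid(256, pixel_pitch = 1)              # 256 um field
star  <- siemens_star(grid, n_spokes = 16, height = 0.25, index_contrast = 0.52)
train <- optical_train(aperture_radius = 250, focal_length = 1000)

capture <- simulate_capture(star, train)   # channels at 625/530/455 nm
capture
#> spectral_capture: 256 x 256 px, pitch 1 um
#>   R: 625 nm, equivalent defocus +152.0 um, mean intensity 1
#>   G: 530 nm, equivalent defocus +0.0 um, mean intensity 1
#>   B: 455 nm, equivalent defocus -164.8 um, mean intensity 1

fit <- qpi_retrieve(capture, qpi_params(max_iterations = 8), index_contrast = 0.52)
fit
#> Spectral TIE phase retrieval
#>   grid: 256 x 256 px, pitch 1 um
#>   central wavelength: 530 nm; derivative mode: two_channel_RG
#>   iterations: 8; final relative residual: 0.589
#>   phase range: [-1.477, 1.530] rad (mean-zero gauge)
#>   height range: [-0.2396, 0.2482] um (dn = 0.52)

star_step_height(fit$height, star)         # um, ground truth 0.25
#> [1] 0.2698712
```

The red channel records the star ~152 µm past its own focus, the blue
channel ~165 µm before; their difference drives the inversion, and the
plateau-minus-gap median recovers the fabricated step within 8% at this
compact 256-pixel setting (about 3% at the 512-pixel validation scale).
`predict(fit, wavelength = 578, distance = 120)` refocuses the recovered
field to any other wavelength/defocus plane (holographic reconstruction).

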