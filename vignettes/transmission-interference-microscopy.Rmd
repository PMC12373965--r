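---
title: "Transmission interference microscopy of the anterior eye: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission interference microscopy of the anterior eye: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeye)
```

## The imaging principle

In transmission interference microscopy of the anterior eye, a near-infrared
beam is focused through the eye's own optics onto the retina/sclera. The
sclera scatters the light diffusely, and part of it returns through the
cornea and crystalline lens, illuminating them *from behind*. The scattering
spot on the sclera therefore acts as a secondary, partially coherent source
— the in vivo analogue of the condenser aperture of a classical transmission
microscope. A small spot means a small illumination numerical aperture
(NA), high spatial coherence, and strong interference contrast between the
wave transmitted past a cell and the wave diffracted by it; a large spot
washes the contrast out but shortens the depth of field.

The package implements this computational chain end to end: the closed-form
geometry of the secondary source, an ocular light-safety budget for the
pulsed illumination, a two-dimensional scalar-wave simulation of the 4F
imaging geometry, a fast analytic model of the defocus contrast, the
raw-frame processing chain, morphometric quantification, and seeded
synthetic phantoms that stand in for in vivo data.

## Closed-form secondary-source model

All lengths are stored in mm and wavelengths in µm, matching the units in
which every formula of the model is usually written.

1. **Spot projection.** An LED of visible size $s$ (1.8 mm: a 1 mm chip
   magnified by its aspheric dome) relayed by a lens pair $f_1/f_2$ into an
   objective of focal length $f_o$ and focused by an eye of focal length
   $f_e$ gives a scleral spot $s \cdot (f_2/f_1)(f_e/f_o)$. An aperture in
   front of the LED replaces $s$.
2. **Scleral diffusion.** With reduced scattering coefficient
   $\mu_s' = 30\,\mathrm{cm}^{-1}$ the transport mean free path is
   $l^* = 1/\mu_s' = 1/3$ mm, and forward-plus-backward diffusion through a
   sclera of thickness $z = 1$ mm broadens an incident spot of radius
   $\sigma_0$ to a source of diameter
   $D = 2\sqrt{\sigma_0^2 + 2 z l^*}$.
3. **Illumination NA.** The source sits one eye length $L \approx 23$ mm
   behind the imaged plane, inside a medium of index $n = 1.4$:
   $\mathrm{NA}_i = n \sin[\arctan(D/2L)]$.
4. **Effective NA, resolution, DOF.**
   $\mathrm{NA}_{\mathrm{eff}} = (\min(\mathrm{NA}_i, \mathrm{NA}_d) +
   \mathrm{NA}_d)/2$,
   $\Delta x = 0.61\lambda/\mathrm{NA}_{\mathrm{eff}}$ and
   $\mathrm{DOF} = n\lambda/\mathrm{NA}_{\mathrm{eff}}^2$. Illumination
   outside the acceptance cone of the objective is not collected, hence the
   clamp; it lives in `effective_na()` so that `illumination_na()` stays a
   pure geometry function. The mean-NA formula is an approximation whose
   validity depends on the scattering regime of the sample; no alternative
   closed form exists, so only this arithmetic is implemented.

```{r}
optics_chain(1.7, detection_config(0.3))
```

The `child` preset scales the axial eye length with the focal length
(15/17 of the adult values); only the focal length enters the safety
budget, the axial length matters only if illumination NA is computed for a
child eye. The étendue diagnostic (`illumination_etendue()`) is informative
only: conservation of $A\Omega$ bounds the spot size achievable from an
extended LED, but no imaging quantity is derived from it.

## Light-safety budget

The budget reproduces the instrument's pulsed-illumination safety
arithmetic with its exact conventions:

* The retinal spot "area" is entered as $(d\,\mathrm{in\,cm})^2$, not as the
  circular area — this is the convention under which the published
  time-averaged weighted irradiance (~220 mW/cm²) and radiant exposure
  (~4.4 J/cm²) follow from 100 mW, a 10 ms/90 ms pulse train and $R = 0.63$.
  A circular-area option exists (`effective_area(..., circular = TRUE)`)
  but is off by default.
* The spectral weighting coefficient defaults to 0.63 (the tabulated value
  for 800 nm, applied to the 850 nm LED, following the instrument's own
  budget).
* The pulsed retinal limit is $(10/d)\,t^{3/4}N^{-1/4}$ J/cm², the
  continuous-wave retinal irradiance limit $1.2/d$ W/cm², and the corneal
  irradiance limit 100 mW/cm².
* The corneal pulse-exposure limit is modeled as $1.8\,t^{1/4}$ J/cm² —
  the unique power law through the tabulated 1.8 J/cm² (1 s) and
  3.8 J/cm² (20 s) values. This functional form is reconstructed, not
  quoted from the standard.
* In the alternative mode (1 s pulse / 19 s dark), the time-averaged
  retinal irradiance of ~170 mW/cm² is an *unweighted* value; the
  assessment reports both conventions.

`assess_mode()` evaluates every check for the standard and alternative
pulse schedules, both eye geometries, and sweeps the exposure time over
(0, 20] s, accumulating the actual light-on time of the pulse train and
counting $N$ pulses as the number of (possibly partial) pulses started by
time $t$, so the single-pulse checks of the alternative mode use $N = 1$.

## Wave simulation

`propagate()` solves the 2D scalar wave equation with an explicit
second-order leapfrog update on a regular grid (wavelength = length unit,
$c_0 = 1$), with exponential-damping sponge layers on all boundaries and a
soft monochromatic line source. The Courant number defaults to 0.7
($\le 1/\sqrt{2}$ for 2D stability); an unstable step is rejected. The
default spatial step is $\lambda/20$; the imaging experiments below run at
$\lambda/10$, which keeps the numerical phase-speed error below ~1% and
the full test battery within minutes on one CPU.

`four_f_system()` builds the imaging geometry: two identical lenses in 4F
arrangement ($f = 13\lambda$, half-aperture $9\lambda$, detection NA
$\approx 0.57$), absorbing aperture stops around both lenses, a sample
plane one focal length before the first lens and a camera plane one focal
length after the second. Design choices that implementation forced:

* **Aspheric lens profiles.** Lenses are glass ($n = 1.5$) thickness
  profiles with equal optical path from a plane wave to the focal point,
  exact for the collimated-to-point conjugates a 4F relay uses. A
  parabolic thin-lens sag at NA ≈ 0.6 carries enough spherical aberration
  to destroy the camera-plane uniformity the no-scatterer test checks.
* **Quasi-incoherent source.** The extended incoherent source is realized
  as an ensemble of plane waves with stratified tilts spanning the source
  half-angle and stratified ±3% frequency jitter (the LED's finite
  coherence length; without it, etalon fringes between the lens surfaces
  dominate the background). Intensities are averaged over realizations.
  A diffuser assembly of quarter-wavelength particles (`add_diffuser()`)
  is also provided and produces the same physics, but the tilt ensemble
  gives deterministic, low-variance control of the divergence, which the
  ordering tests need.
* **Weak default scatterer.** The default sample is a disc of $n = 1.15$,
  diameter $1\lambda$ — a weak phase object in the Born regime, for which
  the interference term between transmitted and diffracted waves dominates
  and the bright/dark contrast flips antisymmetrically across focus. With
  a high-index ($n = 2.5$) scatterer of the same size, the
  $|u_s|^2$ blocking term dominates in this 2D geometry and the feature is
  dark at every defocus; `add_scatterer()` keeps $n = 2.5$ as its default
  for strongly contrasted single-shot visualization (e.g. the back-focal-
  plane diagnostic).
* **Contrast metric.** Feature contrast is
  $(I_{\mathrm{feat}} - I_{\mathrm{bg}})/I_{\mathrm{bg}}$ at the conjugate
  pixel; the background is the median camera intensity over the central
  analysis window, or — in axial scans — the pixel-wise intensity of a
  matched no-scatterer reference run with the identical realization
  ensemble, which removes the residual structure of the finite ensemble
  exactly.
* **Axial extent.** At this domain size the self-normalized FWHM of the
  axial profile discriminates poorly between source sizes (the lobe shape
  is set by the detection NA; the source size scales its depth and its
  fade rate). The sweep therefore also reports the *defocus persistence* —
  the fraction of the peak |contrast| surviving at the largest scanned
  defocus — which is the direct analogue of the observation that
  scatterers fade faster with defocus under a larger source. Persistence
  decreasing with source size is the DOF-shrinkage signature the ordering
  tests assert; FWHM is still computed and reported.

Problem sizes used by the tests: domain ≈ 80λ × 32λ at $\lambda/10$
(~260k cells), 8–16 realizations per configuration, axial scans of 9
offsets over ±8λ. One realization takes a fraction of a second; the full
wave-property battery runs in a few minutes on a single CPU. Convergence
of the ensemble was checked by doubling the realization count (contrast
changes well under 10%).

## Analytic defocus-contrast model

For fast, quantitative work the package models the on-axis intensity
offset of a small scatterer at defocus $z$ under a tilted illumination
plane wave as

$$ m(z, \theta) = A \,\sin\!\big(\arctan(z/z_R)\big)\,
   e^{-z^2/4z_R^2}\, e^{-(z\tan\theta)^2/2w_0^2}, $$

with $z_R = \mathrm{DOF}/2$ and $w_0 = 0.61\lambda/\mathrm{NA}_d$. The
sine of the Gouy-type phase makes the profile antisymmetric with a zero at
focus; the axial envelope width is chosen so the extrema sit exactly one
DOF apart; the shear term is the lateral displacement $z\tan\theta$ of the
tilted profile observed through the lateral resolution envelope. The form
is a model, not a fit: its free constants are fixed by the three
properties above. `incoherent_sum_profile()` integrates $m$ over a
uniform-disc source (radial quadrature with annulus weights, 64 samples by
default; doubling the samples changes the contrast by <1%). Contrast
(max − min of the profile) decreases strictly with source diameter and
the axial FWHM shrinks — equivalently, the FWHM grows as the effective NA
shrinks. Profile sets are normalized by the affine map sending the
most-contrasted (reference) condition to [0, 1], the same normalization
used for measured axial stacks.

```{r}
contrast_sweep(c(0.3, 3, 15))
```

## Image-processing chain

The per-camera chain, in the published order, is: Bayer-mismatch
smoothing (3×3 Gaussian, σ = 0.8 px — kernel-limited; color camera only),
fixed-pattern removal by subtracting the per-pixel temporal mean of a
stack of moving frames (mono camera; the temporal *median* is reserved as
the test oracle for the residual static component), a large-kernel
high-pass (121×121 boxcar local-mean subtraction; a Gaussian variant is
available by flag), and optional frame averaging. All filters use reflect
padding, which avoids edge darkening in the background subtraction.
`select_pulse_frame()` implements the software rolling buffer (brightest
frame wins, earliest index on ties), and `two_phase_subtract()` the
two-camera tomographic difference: frames gain-matched by median ratio,
then subtracted, reinforcing structures that flip sign between the two
defocus planes. The two cameras' defocus offsets are a free parameter of
the phantom tests (±DOF/2 by default), since no canonical value exists.
Averaging assumes registered frames; the phantom tests provide
pre-registered stacks, and no registration beyond that is attempted.

## Quantification

* `detect_cells()` finds local extrema of one contrast sign at the
  expected cell scale (light smoothing at scale/8 — strong enough to kill
  pixel noise, weak enough not to merge neighboring cells), with a minimum
  separation of half the expected diameter and a threshold relative to the
  in-mask median so detection is invariant to global affine intensity
  changes. Restricting to one sign, over the region where that sign is
  observed, mirrors the counting rule used when bright and dark cells
  coexist near focus; cells are counted iff their center lies in the
  analysis region.
* `nerve_length_density()` measures polylines directly, or skeleton masks
  by counting 8-connected steps with the Kulpa coefficients (0.948
  orthogonal, 1.340 diagonal), which correct the systematic overestimation
  of digitized curve length; diagonal steps linked through a shared
  orthogonal neighbor are corner artifacts and are dropped.
  `trace_nerves()` smooths (σ = 1.5 px), thresholds at half the robust
  peak, despeckles, thins by Zhang–Suen iteration and prunes short spurs.
* `measure_cell_diameters()` measures the width of each detected body at
  70% of its peak and extrapolates to the FWHM assuming a Gaussian-like
  profile; measuring high on the profile keeps the estimate clear of
  neighbor overlap, and paths that rise before crossing are rejected. The
  Gaussian-shape assumption matches the phantom renderer and is an
  approximation for real cell bodies.
* `snr_db()` uses the amplitude convention, $20\log_{10}$ of mean signal
  over noise standard deviation (a `power` flag gives $10\log_{10}$); the
  convention is a documented choice, not prescribed.

## Synthetic phantoms: what they do and do not show

`gen_endothelial_mosaic()` draws a minimum-distance point process at the
target density (exact count), assigns each cell a defocus from a smooth
curvature-like field squashed by a tanh so that most of the field sits at
±$z_R$ (both contrasts coexist, with a narrow transition band where cells
are nearly invisible — exactly as at a focus crossing on a curved
cornea), and renders cell bodies as Gaussian blobs whose signed amplitude
comes from the same defocus law as the analytic model (one source of
truth). The bright/dark analysis masks exclude the transition band
(relative modulation below 0.3), matching the rule of counting within the
region where a sign is observed. `gen_nerve_layer()` draws bounded-
curvature random strokes until the total length hits the target exactly
(the last stroke is trimmed). `gen_scatterer_stack()` renders point
scatterers through `incoherent_sum_profile()` at each axial offset.
`add_camera_artifacts()` adds a seeded static fixed-pattern field (column
banding plus pixel offsets, shared across a stack), a period-2 Bayer
checkerboard, and per-frame Gaussian noise; shot-noise is not modeled
(the camera noise is not characterized), and the injected fields are
returned for oracle tests.

Phantoms emulate the *statistical structure the pipeline assumes* — cell
mosaics, curvilinear nerves, signed defocus contrast, sensor artifacts.
They do not emulate tear-film debris, eye motion within a frame,
specular residue, stromal texture, or pathology beyond signed blobs, so
passing recovery tests demonstrates correctness of the operators, not
clinical performance. The recovery battery (20 seeds, 0.5–1 mm fields at
1 µm/px) recovers 3200 cells/mm² and 22 mm/mm² within 10% per seed and
within ~2–5% in the ensemble mean. The published in vivo values (35 dB
SNR, measured cell diameters, patient densities) have no deposited raw
data, so the corresponding operators are validated on these phantoms at
the same scales instead.

## Known limitations

* The wave simulation is 2D scalar and ~80 wavelengths long; it
  demonstrates the contrast phenomenology qualitatively and is never
  pixel-exact. Polarization (the cross-polarized specular rejection) and
  the true 23 mm eye are out of scope.
* The mean-NA resolution formula is an approximation; Mie-regime
  corrections are discussed qualitatively in the field but have no closed
  form to implement.
* The corneal pulse-limit power law and the dB convention are documented
  reconstructions/choices, as noted above.
* The safety model implements exactly the checks of the instrument's
  budget, not the full ISO 15004-2 dual-limit system across wavelengths.
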