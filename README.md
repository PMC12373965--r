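# timeye

Computational toolkit for **transmission interference microscopy of the
anterior human eye** — an imaging geometry in which the illumination is
focused to a small spot on the sclera and the diffusely back-scattered light
re-illuminates the cornea and crystalline lens from behind. The scleral spot
acts as the condenser aperture of a classical transmission microscope: the
smaller the spot, the lower the illumination numerical aperture, the higher
the spatial coherence, and the stronger the interference contrast between
the wave transmitted past a transparent cell and the wave it diffracts —
at the price of a longer depth of field.

The package is aimed at instrument builders and image analysts working on
this modality. It provides:

* **Closed-form optics** (`optics_chain()` and friends): scleral spot
  projection, diffusion broadening `D = 2*sqrt(sigma0^2 + 2 z l*)`,
  illumination NA `NA_i = n*sin(arctan(r/L))`, effective NA
  `(min(NA_i, NA_d) + NA_d)/2`, lateral resolution `0.61*lambda/NA_eff` and
  depth of field `n*lambda/NA_eff^2`.
* **Ocular light-safety budget** (`assess_mode()`): ISO 15004-2 style
  retinal and corneal irradiance/exposure checks for pulsed illumination,
  adult and child geometries, with margins and a sweep over exposure times.
* **2D scalar-wave simulator** (`four_f_system()`,
  `simulate_camera_image()`, `axial_contrast_scan()`,
  `source_size_sweep()`): a time-domain wave-equation model of the 4F
  imaging geometry reproducing the Gouy-phase bright/dark contrast flip
  across focus, the transmitted/diffracted wave separation in the back
  focal plane, and the contrast-vs-source-size trade-off.
* **Analytic defocus-contrast model** (`single_angle_profile()`,
  `incoherent_sum_profile()`, `contrast_sweep()`): a fast Gouy-phase model
  of the axial bright/dark profile under extended incoherent sources.
* **Raw-frame processing** (`bayer_smooth()`, `remove_fixed_pattern()`,
  `highpass()`, `average_frames()`, `select_pulse_frame()`,
  `two_phase_subtract()`, `process_stack()`): the per-camera processing
  chain, pulse-synchronized frame selection, and two-camera tomographic
  subtraction.
* **Quantification** (`detect_cells()`, `cell_density()`,
  `trace_nerves()`, `nerve_length_density()`, `measure_cell_diameters()`,
  `snr_db()`): endothelial/epithelial cell density, sub-basal nerve length
  density (mm/mm²), cell diameters and SNR in dB.
* **Synthetic phantoms** (`gen_endothelial_mosaic()`, `gen_nerve_layer()`,
  `gen_scatterer_stack()`, `add_camera_artifacts()`): seeded generators
  with exact ground truth for end-to-end validation.

## Worked example

The clinical configuration uses a 0.3 NA objective (18 mm focal length)
with the 1.8 mm LED relayed 1:1, so a 1.7 mm spot lands on the sclera of a
23 mm adult eye:

```r
library(timeye)

optics_chain(1.7, detection_config(0.3))
#> Transmission-microscope resolution report
#>   incident spot        : 1.7 mm
#>   diffused source      : 2.4 mm
#>   illumination NA      : 0.072
#>   effective NA         : 0.186
#>   lateral resolution   : 2.8 um
#>   depth of field       : 34 um
```

Reading: the 1.7 mm incident spot diffuses to a 2.4 mm secondary source in
the sclera, which subtends an illumination NA of 0.07 from the cornea;
averaged with the 0.3 detection NA this gives a 2.8 µm lateral resolution
and a 34 µm depth of field — cells defocus gently over tens of microns, so
both bright and dark cell contrasts are visible near focus.

The safety budget for the standard pulsed mode (10 ms light / 90 ms dark,
100 mW at the eye):

```r
assess_mode("standard")
#> Ocular light-safety assessment (standard mode, 1.7 mm retinal spot)
#>                                          name  value   units  limit margin pass
#>    retinal irradiance, time-averaged weighted 218.00 mW/cm^2 706.00   3.24 TRUE
#>  retinal irradiance, time-averaged unweighted 346.00 mW/cm^2 706.00   2.04 TRUE
#>    retinal radiant exposure, short time scale   4.36  J/cm^2  14.80   3.39 TRUE
#>             corneal irradiance, time-averaged  50.00 mW/cm^2 100.00   2.00 TRUE
#>    corneal radiant exposure, short time scale   1.00  J/cm^2   3.81   3.81 TRUE
#> time sweep (0, 20] s: all times compliant
```

Every check passes with a margin of at least 2x, at all exposure times up
to 20 s.

End-to-end phantom validation — generate an endothelial mosaic at a
healthy 3200 cells/mm², add sensor artifacts, run the processing chain and
recover the density:

```r
spec <- phantom_spec(fov_mm = 0.5, density = 3200, modulation = 20,
                     bayer_amplitude = 4, noise_sd = 2, seed = 1)
ph  <- gen_endothelial_mosaic(spec)
img <- highpass(bayer_smooth(add_camera_artifacts(ph$image, spec)$image), 121)
det <- detect_cells(img, 1, "bright", scale_um = ph$truth$cell_spacing_um,
                    mask = ph$truth$mask_bright)
cell_density(det)
#> [1] 3164.179
```

A command-line wrapper is installed under `inst/cli/timeye` with
subcommands `optics`, `safety`, `contrast-sweep`, `simulate`, `process`,
`quantify` and `phantom`.

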