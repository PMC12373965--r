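# Fast analytic model of defocus interference contrast under extended
# incoherent sources, plus the experimental contrast metric and profile
# normalization.
#
# Model: a small scatterer near focus modulates the on-axis camera intensity
# by the sine of the Gouy-type phase accumulated across focus,
#   m(z, 0) = A * sin(atan(z / zR)) * exp(-z^2 / (4 zR^2)),
# an antisymmetric dark/bright profile whose extrema sit exactly at
# z = +/- zR, i.e. one depth of field apart (zR = DOF/2). Each illumination
# angle theta shears the profile laterally by z * tan(theta); observed on
# axis through the lateral point-spread envelope this multiplies the
# modulation by exp(-(z tan(theta))^2 / (2 w0^2)) with w0 the lateral
# resolution scale. Summing over the angles of an extended incoherent source
# reduces the peak-to-trough contrast and shortens the axial extent.

#' Defocus-contrast model parameters
#'
#' @param na_detection Detection numerical aperture.
#' @param wavelength Wavelength in um.
#' @param amplitude Base modulation amplitude of the scatterer (arbitrary
#'   intensity-offset units).
#' @param n_medium Refractive index of the imaging medium.
#' @return An object of class `defocus_params` with derived fields `dof_um`
#'   (`n * lambda / NA_d^2`), `z_rayleigh_um` (`DOF/2`) and `w0_um`
#'   (`0.61 lambda / NA_d`, lateral resolution scale).
#' @export
defocus_params <- function(na_detection = 0.3, wavelength = 0.85,
                           amplitude = 1, n_medium = 1.4) {
  stop_if_not_positive(na_detection, "na_detection")
  stop_if_not_positive(wavelength, "wavelength")
  stop_if_not_positive(amplitude, "amplitude")
  stop_if_not_positive(n_medium, "n_medium")
  dof <- n_medium * wavelength / na_detection^2
  structure(
    list(na_detection = na_detection, wavelength = wavelength,
         amplitude = amplitude, n_medium = n_medium,
         dof_um = dof, z_rayleigh_um = dof / 2,
         w0_um = 0.61 * wavelength / na_detection),
    class = "defocus_params"
  )
}

#' Single-angle defocus modulation profile
#'
#' Intensity offset produced by a point scatterer at defocus `z` when
#' illuminated by a single plane wave tilted by `theta` (radians, inside the
#' medium). Antisymmetric in `z`, zero at focus, extrema one DOF apart at
#' `theta = 0`.
#'
#' @param z Defocus in um (vectorized).
#' @param theta Illumination tilt angle in radians.
#' @param params A [defocus_params()].
#' @return Intensity offsets (same length as `z`).
#' @export
single_angle_profile <- function(z, theta = 0, params = defocus_params()) {
  stopifnot(inherits(params, "defocus_params"))
  zr <- params$z_rayleigh_um
  gouy <- sin(atan(z / zr))
  envelope <- exp(-z^2 / (4 * zr^2))
  shear <- z * tan(theta)
  lateral <- exp(-shear^2 / (2 * params$w0_um^2))
  params$amplitude * gouy * envelope * lateral
}

#' Extended incoherent source as an angular distribution
#'
#' Discretizes a uniform-disc source of given diameter at the sclera into
#' radial tilt angles inside the medium, with annulus weights (weight
#' proportional to the radius, the area element of the uniform disc; the
#' modulation model depends only on the tilt magnitude). The maximum tilt
#' is `atan((d/2) / eye_length)`, i.e. `asin(NA_i / n)`.
#'
#' @param diameter_mm Equivalent source diameter at the sclera in mm; 0 gives
#'   a single on-axis angle (point source).
#' @param eye An [eye_geometry()].
#' @param n_angles Number of angular samples (>= 64 recommended for smooth
#'   sums; convergence is checked in the test suite by doubling).
#' @return An object of class `source_distribution` with fields `theta`
#'   (radians) and `weight` (summing to 1).
#' @export
source_distribution <- function(diameter_mm, eye = eye_geometry(),
                                n_angles = 64) {
  stop_if_negative(diameter_mm, "diameter_mm")
  stopifnot(inherits(eye, "eye_geometry"))
  if (diameter_mm == 0 || n_angles == 1) {
    return(structure(list(diameter_mm = diameter_mm, theta = 0, weight = 1),
                     class = "source_distribution"))
  }
  theta_max <- atan((diameter_mm / 2) / eye$eye_length)
  u <- (seq_len(n_angles) - 0.5) / n_angles   # radial fraction of the disc
  structure(
    list(diameter_mm = diameter_mm, theta = u * theta_max, weight = u / sum(u)),
    class = "source_distribution"
  )
}

#' Incoherent sum of single-angle profiles
#'
#' Weighted sum of [single_angle_profile()] over the angular samples of an
#' extended incoherent source. Peak-to-trough contrast decreases and the
#' axial extent shrinks as the source diameter grows.
#'
#' @param z Defocus grid in um.
#' @param source A [source_distribution()].
#' @param params A [defocus_params()].
#' @return An `axial_profile`: `data.frame` with columns `z` and `value`.
#' @export
incoherent_sum_profile <- function(z, source, params = defocus_params()) {
  stopifnot(inherits(source, "source_distribution"))
  if (length(source$theta) < 1) stop("source has no angular samples",
                                     call. = FALSE)
  v <- rowSums(vapply(
    seq_along(source$theta),
    function(j) source$weight[j] * single_angle_profile(z, source$theta[j],
                                                        params),
    numeric(length(z))
  ))
  axial_profile(z, v)
}

#' Axial profile container
#'
#' @param z Axial offsets (um).
#' @param value On-axis intensity (or intensity offset) per offset.
#' @return A `data.frame` of class `axial_profile`.
#' @export
axial_profile <- function(z, value) {
  stopifnot(length(z) == length(value))
  structure(data.frame(z = z, value = value),
            class = c("axial_profile", "data.frame"))
}

#' Peak-to-trough axial contrast
#'
#' The experimental contrast metric: difference between the maximal and
#' minimal values of an axial profile.
#'
#' @param profile An [axial_profile()] (or any numeric vector).
#' @return `max - min` of the profile values.
#' @export
axial_contrast <- function(profile) {
  v <- if (inherits(profile, "axial_profile")) profile$value else profile
  if (length(v) < 1) stop("empty profile", call. = FALSE)
  max(v) - min(v)
}

#' Normalize a set of axial profiles to a reference condition
#'
#' Applies the affine map that sends the reference profile's minimum to 0 and
#' maximum to 1 to every profile (the most-contrasted condition is the usual
#' reference, so other conditions stay within [0, 1]).
#'
#' @param profiles Named list of [axial_profile()] objects (or numeric
#'   vectors).
#' @param reference Name of the reference condition.
#' @return The same list with values affinely rescaled.
#' @export
normalize_profiles <- function(profiles, reference) {
  if (!reference %in% names(profiles)) {
    stop(sprintf("reference condition '%s' not found", reference),
         call. = FALSE)
  }
  ref <- profiles[[reference]]
  rv <- if (inherits(ref, "axial_profile")) ref$value else ref
  lo <- min(rv); hi <- max(rv)
  if (hi == lo) stop("degenerate reference profile (max == min)",
                     call. = FALSE)
  lapply(profiles, function(p) {
    if (inherits(p, "axial_profile")) {
      axial_profile(p$z, (p$value - lo) / (hi - lo))
    } else {
      (p - lo) / (hi - lo)
    }
  })
}

#' Full width at half maximum of |profile - background|
#'
#' Axial extent metric: FWHM of the absolute deviation of the profile from a
#' background level, measured with linear interpolation between samples.
#'
#' @param profile An [axial_profile()].
#' @param background Background level (default 0 for offset profiles).
#' @return FWHM in the units of `profile$z`.
#' @export
axial_fwhm <- function(profile, background = 0) {
  stopifnot(inherits(profile, "axial_profile"))
  a <- abs(profile$value - background)
  half <- max(a) / 2
  above <- which(a >= half)
  if (length(above) < 1) return(0)
  # linear interpolation at the outermost half-crossings
  zi <- profile$z
  lo <- above[1]; hi <- above[length(above)]
  z_lo <- if (lo > 1) {
    zi[lo - 1] + (half - a[lo - 1]) / (a[lo] - a[lo - 1]) * (zi[lo] - zi[lo - 1])
  } else zi[1]
  z_hi <- if (hi < length(zi)) {
    zi[hi] + (a[hi] - half) / (a[hi] - a[hi + 1]) * (zi[hi + 1] - zi[hi])
  } else zi[length(zi)]
  z_hi - z_lo
}

#' Contrast and axial extent versus source diameter
#'
#' Sweeps the analytic incoherent-sum model over equivalent source diameters
#' and reports peak-to-trough contrast and axial FWHM for each, mirroring the
#' experimental spot-size sweep.
#'
#' @param diameters_mm Source diameters at the sclera in mm.
#' @param params A [defocus_params()].
#' @param eye An [eye_geometry()].
#' @param z Defocus grid in um (default spans +/- 4 DOF).
#' @param n_angles Angular samples per source.
#' @return `data.frame` with columns `diameter_mm`, `contrast`,
#'   `axial_fwhm_um`.
#' @export
contrast_sweep <- function(diameters_mm, params = defocus_params(),
                           eye = eye_geometry(),
                           z = seq(-4, 4, length.out = 201) * params$dof_um,
                           n_angles = 64) {
  rows <- lapply(diameters_mm, function(d) {
    src <- source_distribution(d, eye, n_angles)
    prof <- incoherent_sum_profile(z, src, params)
    data.frame(diameter_mm = d, contrast = axial_contrast(prof),
               axial_fwhm_um = axial_fwhm(prof))
  })
  do.call(rbind, rows)
}
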