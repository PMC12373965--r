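# Closed-form model of the secondary illumination source at the sclera and the
# resulting resolution / depth of field of the transmission microscope.
#
# Unit conventions (used throughout the package): lengths in mm, wavelengths
# in um. Resolution and DOF are reported in um.

#' Eye geometry for secondary-source calculations
#'
#' Describes the optical geometry of the eye as seen by the transmission
#' microscope: the secondary illumination source sits at the sclera, one eye
#' length behind the anterior structures being imaged.
#'
#' @param eye_length Axial eye length in mm (source-to-image distance for the
#'   secondary illumination). Adult default 23 mm.
#' @param eye_focal_length Effective focal length of the eye's optics in mm
#'   (adult 17, young child about 15, artificial model eye 25).
#' @param n_cornea_lens Refractive index of the cornea/crystalline-lens medium
#'   (approximated as 1.4).
#' @param sclera_thickness Scleral thickness traversed by the diffusing light,
#'   in mm.
#' @param reduced_scattering Reduced scattering coefficient of the sclera in
#'   cm^-1 (default 30, giving a transport mean free path of 1/3 mm).
#' @return An object of class `eye_geometry`.
#' @seealso [eye_preset()] for the named presets.
#' @export
eye_geometry <- function(eye_length = 23, eye_focal_length = 17,
                         n_cornea_lens = 1.4, sclera_thickness = 1,
                         reduced_scattering = 30) {
  stop_if_not_positive(eye_length, "eye_length")
  stop_if_not_positive(eye_focal_length, "eye_focal_length")
  stop_if_not_positive(n_cornea_lens, "n_cornea_lens")
  if (n_cornea_lens < 1) stop("`n_cornea_lens` must be >= 1", call. = FALSE)
  stop_if_negative(sclera_thickness, "sclera_thickness")
  stop_if_not_positive(reduced_scattering, "reduced_scattering")
  structure(
    list(eye_length = eye_length, eye_focal_length = eye_focal_length,
         n_cornea_lens = n_cornea_lens, sclera_thickness = sclera_thickness,
         reduced_scattering = reduced_scattering),
    class = "eye_geometry"
  )
}

#' Named eye-geometry presets
#'
#' `"adult"` is the standard 23 mm / 17 mm eye, `"child"` a young child's eye
#' with a roughly 15 mm focal length and proportionally shorter axial length,
#' and `"artificial_model"` the model eye with a flatter cornea (25 mm focal
#' length).
#'
#' @param name One of `"adult"`, `"child"`, `"artificial_model"`.
#' @return An `eye_geometry` object.
#' @export
eye_preset <- function(name = c("adult", "child", "artificial_model")) {
  name <- match.arg(name)
  switch(name,
    adult = eye_geometry(),
    # axial length scaled with the focal length (15/17 of the adult eye)
    child = eye_geometry(eye_length = 23 * 15 / 17, eye_focal_length = 15),
    artificial_model = eye_geometry(eye_length = 25, eye_focal_length = 25)
  )
}

#' Illumination relay train
#'
#' The LED source is relayed by a lens pair (`relay_f1`, `relay_f2`) onto the
#' back focal plane of the microscope objective, which projects it through the
#' eye's own optics onto the sclera. An optional physical aperture in front of
#' the LED replaces the LED's visible emitting size.
#'
#' @param led_visible_size Visible LED emitter size in mm (1.8 mm for a 1 mm
#'   chip under its aspheric dome).
#' @param relay_f1,relay_f2 Focal lengths of the relay lens pair in mm.
#' @param objective_focal_length Objective focal length in mm.
#' @param aperture_diameter Optional aperture diameter in mm; when set it
#'   defines the effective source size instead of the LED.
#' @return An object of class `illumination_train`.
#' @export
illumination_train <- function(led_visible_size = 1.8, relay_f1, relay_f2,
                               objective_focal_length,
                               aperture_diameter = NULL) {
  stop_if_not_positive(led_visible_size, "led_visible_size")
  stop_if_not_positive(relay_f1, "relay_f1")
  stop_if_not_positive(relay_f2, "relay_f2")
  stop_if_not_positive(objective_focal_length, "objective_focal_length")
  if (!is.null(aperture_diameter)) {
    stop_if_not_positive(aperture_diameter, "aperture_diameter")
  }
  structure(
    list(led_visible_size = led_visible_size, relay_f1 = relay_f1,
         relay_f2 = relay_f2,
         objective_focal_length = objective_focal_length,
         aperture_diameter = aperture_diameter),
    class = "illumination_train"
  )
}

#' Detection configuration
#'
#' @param na_detection Numerical aperture of the microscope objective.
#' @param wavelength Center wavelength in um (850 nm NIR LED by default).
#' @param eye Optional [eye_geometry()] used only to validate that the
#'   detection NA does not exceed the index of the imaging medium.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(na_detection, wavelength = 0.85,
                             eye = eye_geometry()) {
  stop_if_not_positive(na_detection, "na_detection")
  stop_if_not_positive(wavelength, "wavelength")
  if (na_detection >= eye$n_cornea_lens) {
    stop("`na_detection` must be smaller than the cornea/lens refractive index",
         call. = FALSE)
  }
  structure(list(na_detection = na_detection, wavelength = wavelength),
            class = "detection_config")
}

#' Project the source onto the sclera
#'
#' Ideal thin-lens projection of the LED (or of an aperture in front of it)
#' through the relay pair and the objective/eye telescope:
#' `size x (relay_f2/relay_f1) x (eye_focal_length/objective_focal_length)`.
#'
#' @param train An [illumination_train()].
#' @param eye An [eye_geometry()].
#' @return Illumination spot diameter at the sclera in mm.
#' @examples
#' project_source_to_sclera(
#'   illumination_train(1.8, 40, 40, 18), eye_geometry()
#' ) # 1.7 mm
#' @export
project_source_to_sclera <- function(train, eye) {
  stopifnot(inherits(train, "illumination_train"),
            inherits(eye, "eye_geometry"))
  src <- train$aperture_diameter %||% train$led_visible_size
  src * (train$relay_f2 / train$relay_f1) *
    (eye$eye_focal_length / train$objective_focal_length)
}

#' Broadening of the illumination spot by scleral diffusion
#'
#' Diffuse light transport through the sclera enlarges the incident spot.
#' With transport mean free path `l* = 1/mu_s'` and forward plus backward
#' passage through a sclera of thickness `z`, the re-emitted source diameter
#' is `D = 2 * sqrt(sigma0^2 + 2 * z * l*)`, where `sigma0` is the incident
#' spot radius.
#'
#' @param incident_diameter Incident spot diameter at the sclera in mm.
#' @param eye An [eye_geometry()] providing `sclera_thickness` (mm) and
#'   `reduced_scattering` (cm^-1).
#' @return Diffused source diameter in mm.
#' @examples
#' scleral_broadening(1.7, eye_geometry()) # about 2.4 mm
#' @export
scleral_broadening <- function(incident_diameter, eye) {
  stopifnot(inherits(eye, "eye_geometry"))
  stop_if_negative(incident_diameter, "incident_diameter")
  l_star_mm <- 10 / eye$reduced_scattering  # cm^-1 -> mm
  sigma0 <- incident_diameter / 2
  2 * sqrt(sigma0^2 + 2 * eye$sclera_thickness * l_star_mm)
}

#' Numerical aperture of the secondary scleral source
#'
#' The source at the sclera sits one eye length behind the anterior-eye image
#' plane, so the illumination NA seen by a scatterer in the cornea/lens is
#' `NA_i = n * sin(arctan(source_radius / eye_length))`.
#'
#' @param source_diameter Diffused source diameter at the sclera in mm.
#' @param eye An [eye_geometry()].
#' @return Dimensionless illumination NA (bounded by `n_cornea_lens`).
#' @examples
#' illumination_na(0.3, eye_geometry()) # about 0.01
#' illumination_na(15, eye_geometry())  # about 0.43
#' @export
illumination_na <- function(source_diameter, eye) {
  stopifnot(inherits(eye, "eye_geometry"))
  stop_if_negative(source_diameter, "source_diameter")
  eye$n_cornea_lens * sin(atan((source_diameter / 2) / eye$eye_length))
}

#' Effective numerical aperture
#'
#' Mean of illumination and detection NA. Illumination beyond the acceptance
#' cone of the objective is not collected, so `NA_i` is clamped at
#' `NA_d` before averaging.
#'
#' @param na_i Illumination NA (from [illumination_na()]).
#' @param det A [detection_config()].
#' @return `(min(na_i, na_d) + na_d) / 2`.
#' @export
effective_na <- function(na_i, det) {
  stopifnot(inherits(det, "detection_config"))
  stop_if_negative(na_i, "na_i")
  (min(na_i, det$na_detection) + det$na_detection) / 2
}

#' Lateral resolution and depth of field
#'
#' `dx = 0.61 * lambda / NA_eff` and `DOF = n * lambda / NA_eff^2`, both in um.
#'
#' @param na_eff Effective NA (from [effective_na()]).
#' @param det A [detection_config()] providing the wavelength.
#' @param eye An [eye_geometry()] providing the medium index.
#' @return A one-row `data.frame` of class `resolution_report` with columns
#'   `na_effective`, `lateral_resolution_um`, `depth_of_field_um`.
#' @export
resolution_dof <- function(na_eff, det, eye) {
  stopifnot(inherits(det, "detection_config"), inherits(eye, "eye_geometry"))
  stop_if_not_positive(na_eff, "na_eff")
  out <- data.frame(
    na_effective = na_eff,
    lateral_resolution_um = 0.61 * det$wavelength / na_eff,
    depth_of_field_um = eye$n_cornea_lens * det$wavelength / na_eff^2
  )
  class(out) <- c("resolution_report", class(out))
  out
}

#' Full secondary-source chain
#'
#' Convenience chain from incident spot to the resolution report: scleral
#' broadening, illumination NA, effective NA, then resolution and DOF.
#'
#' @param incident_spot_mm Incident spot diameter at the sclera in mm (e.g.
#'   from [project_source_to_sclera()]).
#' @param det A [detection_config()].
#' @param eye An [eye_geometry()].
#' @return A one-row `data.frame` of class `resolution_report` with the
#'   intermediate quantities (`incident_spot_mm`, `diffused_spot_mm`,
#'   `na_illumination`) prepended.
#' @examples
#' # clinical 0.3 NA configuration: 1.7 mm spot -> 2.8 um / 34 um
#' optics_chain(1.7, detection_config(0.3))
#' @export
optics_chain <- function(incident_spot_mm, det, eye = eye_geometry()) {
  d_diff <- scleral_broadening(incident_spot_mm, eye)
  na_i <- illumination_na(d_diff, eye)
  na_eff <- effective_na(na_i, det)
  rep <- resolution_dof(na_eff, det, eye)
  out <- cbind(
    data.frame(incident_spot_mm = incident_spot_mm,
               diffused_spot_mm = d_diff,
               na_illumination = na_i),
    rep
  )
  class(out) <- c("resolution_report", "data.frame")
  out
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("Transmission-microscope resolution report\n")
  if (!is.null(x$incident_spot_mm)) {
    cat(sprintf("  incident spot        : %.1f mm\n", x$incident_spot_mm))
    cat(sprintf("  diffused source      : %.1f mm\n", x$diffused_spot_mm))
    cat(sprintf("  illumination NA      : %.3f\n", x$na_illumination))
  }
  cat(sprintf("  effective NA         : %.3f\n", x$na_effective))
  cat(sprintf("  lateral resolution   : %.1f um\n", x$lateral_resolution_um))
  cat(sprintf("  depth of field       : %.0f um\n", x$depth_of_field_um))
  invisible(x)
}

#' Etendue of an illumination stage (informative diagnostic)
#'
#' Approximate etendue `A * Omega = pi (d/2)^2 * pi NA^2` of a source of
#' diameter `d` radiating into numerical aperture `NA`. Conservation of
#' etendue sets a lower bound on the achievable spot size for an extended LED
#' source; this diagnostic is informative only and enters no imaging
#' calculation.
#'
#' @param diameter_mm Source diameter in mm.
#' @param na Numerical aperture of the emission cone.
#' @return Etendue in mm^2 sr, with attribute `informative_only = TRUE`.
#' @export
illumination_etendue <- function(diameter_mm, na) {
  stop_if_not_positive(diameter_mm, "diameter_mm")
  stop_if_negative(na, "na")
  structure(pi * (diameter_mm / 2)^2 * pi * na^2, informative_only = TRUE)
}
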