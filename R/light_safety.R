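# Pulsed-illumination ocular light-safety budget (ISO 15004-2 style checks
# for the retina and cornea, adult and child geometries).
#
# Arithmetic conventions follow the instrument's published budget: the
# "effective area" of the retinal spot is entered as (diameter in cm)^2, not
# as the circular area; a circular-area variant is available but off by
# default.

#' Pulse schedule
#'
#' @param pulse_duration Light-pulse duration in seconds.
#' @param off_interval Dark interval between pulses in seconds.
#' @param assessment_time Assessment window in seconds (default 20 s).
#' @return An object of class `pulse_schedule` with derived fields `duty`
#'   (pulse fraction of the period) and `n_pulses` (pulses completed within
#'   the assessment window, at least 1).
#' @examples
#' pulse_schedule(0.01, 0.09)  # standard mode: 10 ms on, 90 ms off
#' pulse_schedule(1, 19)       # alternative mode: 1 s on, 19 s off
#' @export
pulse_schedule <- function(pulse_duration, off_interval,
                           assessment_time = 20) {
  stop_if_not_positive(pulse_duration, "pulse_duration")
  stop_if_negative(off_interval, "off_interval")
  stop_if_not_positive(assessment_time, "assessment_time")
  period <- pulse_duration + off_interval
  n <- max(1L, as.integer(floor(assessment_time / period)))
  structure(
    list(pulse_duration = pulse_duration, off_interval = off_interval,
         assessment_time = assessment_time, period = period,
         duty = pulse_duration / period, n_pulses = n),
    class = "pulse_schedule"
  )
}

#' Beam description at the retinal or corneal plane
#'
#' @param power_mW Total incident power per pulse in mW (retina mode).
#' @param spot_diameter_mm Illumination spot diameter at the retina in mm.
#' @param irradiance_mW_mm2 Measured irradiance at the corneal plane in
#'   mW/mm^2 (cornea mode).
#' @return An object of class `beam_at_plane` with `plane` `"retina"` or
#'   `"cornea"`.
#' @name beam_at_plane
NULL

#' @rdname beam_at_plane
#' @export
retinal_beam <- function(power_mW, spot_diameter_mm) {
  stop_if_negative(power_mW, "power_mW")
  stop_if_not_positive(spot_diameter_mm, "spot_diameter_mm")
  structure(list(plane = "retina", power_mW = power_mW,
                 spot_diameter_mm = spot_diameter_mm),
            class = "beam_at_plane")
}

#' @rdname beam_at_plane
#' @export
corneal_beam <- function(irradiance_mW_mm2) {
  stop_if_negative(irradiance_mW_mm2, "irradiance_mW_mm2")
  structure(list(plane = "cornea", irradiance_mW_mm2 = irradiance_mW_mm2),
            class = "beam_at_plane")
}

#' Spectral weighting coefficient
#'
#' Retinal-hazard spectral weighting coefficient R from the ISO 15004-2
#' tables; 0.63 is the tabulated value for 800 nm, applied to the 850 nm LED.
#'
#' @param r_coefficient Weighting coefficient in (0, 1].
#' @return An object of class `spectral_weighting`.
#' @export
spectral_weighting <- function(r_coefficient = 0.63) {
  if (!is.numeric(r_coefficient) || r_coefficient <= 0 || r_coefficient > 1) {
    stop("`r_coefficient` must be in (0, 1]", call. = FALSE)
  }
  structure(list(r_coefficient = r_coefficient), class = "spectral_weighting")
}

#' Effective retinal spot area
#'
#' Budget convention: the spot area is entered as the square of the spot
#' diameter, `(d in cm)^2`, not as the circular area `pi (d/2)^2`. The
#' circular variant is provided for comparison via `circular = TRUE`.
#'
#' @param spot_diameter_mm Spot diameter in mm.
#' @param circular Use the true circular area instead of the
#'   diameter-squared convention (off by default; the published budget
#'   numbers use the default).
#' @return Area in cm^2.
#' @export
effective_area <- function(spot_diameter_mm, circular = FALSE) {
  stop_if_not_positive(spot_diameter_mm, "spot_diameter_mm")
  d_cm <- spot_diameter_mm / 10
  if (circular) pi * (d_cm / 2)^2 else d_cm^2
}

check_plane <- function(beam, plane) {
  stopifnot(inherits(beam, "beam_at_plane"))
  if (beam$plane != plane) {
    stop(sprintf("beam is specified at the %s, expected %s plane",
                 beam$plane, plane), call. = FALSE)
  }
}

#' Time-averaged retinal irradiance
#'
#' `power * duty / area`, optionally multiplied by the spectral weighting R.
#'
#' @param beam A [retinal_beam()].
#' @param sched A [pulse_schedule()].
#' @param w A [spectral_weighting()].
#' @param weighted Apply the spectral weighting coefficient.
#' @param circular Area convention, see [effective_area()].
#' @return Irradiance in mW/cm^2.
#' @examples
#' # standard mode: about 220 mW/cm^2 weighted
#' retinal_irradiance_time_avg(retinal_beam(100, 1.7), pulse_schedule(0.01, 0.09))
#' @export
retinal_irradiance_time_avg <- function(beam, sched, w = spectral_weighting(),
                                        weighted = TRUE, circular = FALSE) {
  check_plane(beam, "retina")
  stopifnot(inherits(sched, "pulse_schedule"), inherits(w, "spectral_weighting"))
  val <- beam$power_mW * sched$duty /
    effective_area(beam$spot_diameter_mm, circular)
  if (weighted) val <- val * w$r_coefficient
  val
}

#' Weighted retinal radiant exposure
#'
#' `(power / area) * t * duty * R`, converted to J/cm^2.
#'
#' @inheritParams retinal_irradiance_time_avg
#' @param t Exposure time in seconds.
#' @param duty Duty factor over the exposure window; defaults to the
#'   schedule's duty. For a single continuous pulse window use `duty = 1`.
#' @return Radiant exposure in J/cm^2.
#' @examples
#' # standard mode over 20 s: about 4.4 J/cm^2
#' retinal_radiant_exposure(retinal_beam(100, 1.7), pulse_schedule(0.01, 0.09), t = 20)
#' @export
retinal_radiant_exposure <- function(beam, sched, w = spectral_weighting(),
                                     t, duty = sched$duty, circular = FALSE) {
  check_plane(beam, "retina")
  stopifnot(inherits(w, "spectral_weighting"))
  stop_if_not_positive(t, "t")
  beam$power_mW / effective_area(beam$spot_diameter_mm, circular) *
    t * duty * w$r_coefficient / 1000
}

#' Pulsed retinal exposure limit
#'
#' `(10 / d_mm) * t^(3/4) * N^(-1/4)` J/cm^2 for a train of `n_pulses` pulses
#' within `t` seconds, with the spot-size normalization used in the
#' instrument's budget.
#'
#' @param spot_diameter_mm Retinal spot diameter in mm.
#' @param t Assessment time in seconds.
#' @param n_pulses Number of pulses within `t` (>= 1).
#' @return Limit in J/cm^2.
#' @examples
#' retinal_exposure_limit_pulsed(1.7, 20, 200)  # about 14.7 J/cm^2
#' retinal_exposure_limit_pulsed(1.7, 1, 1)     # about 5.8 J/cm^2
#' @export
retinal_exposure_limit_pulsed <- function(spot_diameter_mm, t, n_pulses) {
  stop_if_not_positive(spot_diameter_mm, "spot_diameter_mm")
  stop_if_not_positive(t, "t")
  if (!is.numeric(n_pulses) || n_pulses < 1) {
    stop("`n_pulses` must be >= 1", call. = FALSE)
  }
  (10 / spot_diameter_mm) * t^(3 / 4) * n_pulses^(-1 / 4)
}

#' Continuous-wave retinal irradiance limit
#'
#' `1.2 / d_mm` W/cm^2, returned in mW/cm^2 (700 mW/cm^2 for the 1.7 mm spot).
#'
#' @param spot_diameter_mm Retinal spot diameter in mm.
#' @return Limit in mW/cm^2.
#' @export
retinal_irradiance_limit_cw <- function(spot_diameter_mm) {
  stop_if_not_positive(spot_diameter_mm, "spot_diameter_mm")
  1.2 / spot_diameter_mm * 1000
}

#' Time-averaged corneal irradiance
#'
#' Measured corneal irradiance in mW/mm^2 converted to mW/cm^2 (factor 100)
#' and scaled by the duty factor. The applicable limit is the fixed
#' 100 mW/cm^2 corneal irradiance limit, attached as attribute `limit`.
#'
#' @param beam A [corneal_beam()].
#' @param sched A [pulse_schedule()].
#' @return Irradiance in mW/cm^2 with attribute `limit` (100 mW/cm^2).
#' @export
corneal_irradiance_time_avg <- function(beam, sched) {
  check_plane(beam, "cornea")
  stopifnot(inherits(sched, "pulse_schedule"))
  structure(beam$irradiance_mW_mm2 * 100 * sched$duty, limit = 100)
}

#' Corneal radiant exposure and its limit
#'
#' Exposure `irradiance * 100 * t * duty / 1000` J/cm^2. The corneal pulse
#' limit is modeled as `1.8 * t^(1/4)` J/cm^2, the unique power law through
#' the tabulated 1.8 J/cm^2 (1 s) and 3.8 J/cm^2 (20 s) values (reconstructed
#' functional form, not a quoted ISO formula).
#'
#' @param beam A [corneal_beam()].
#' @param t Exposure time in seconds.
#' @param duty Duty factor over the window.
#' @return Exposure in J/cm^2.
#' @name corneal_exposure
NULL

#' @rdname corneal_exposure
#' @export
corneal_radiant_exposure <- function(beam, t, duty) {
  check_plane(beam, "cornea")
  stop_if_not_positive(t, "t")
  stop_if_negative(duty, "duty")
  beam$irradiance_mW_mm2 * 100 * t * duty / 1000
}

#' @rdname corneal_exposure
#' @export
corneal_exposure_limit <- function(t) {
  stop_if_not_positive(t, "t")
  1.8 * t^(1 / 4)
}

# Light-on time accumulated by time t of a pulse train starting at t = 0.
pulse_on_time <- function(t, sched) {
  n_full <- floor(t / sched$period)
  n_full * sched$pulse_duration + pmin(t %% sched$period, sched$pulse_duration)
}

#' Full safety assessment of an illumination mode
#'
#' Evaluates the complete safety budget for one of the instrument's modes:
#' `"standard"` (10 ms pulse / 90 ms dark) or `"alternative"` (1 s pulse /
#' 19 s dark). The retinal spot diameter is obtained by projecting the LED
#' through the illumination train and the given eye, every retinal and
#' corneal check is computed together with its limit and margin
#' (`limit / value`), and a sweep over exposure times in (0, 20] s verifies
#' compliance at all intermediate times.
#'
#' @param mode `"standard"` or `"alternative"`.
#' @param eye An [eye_geometry()]; use `eye_preset("child")` for the
#'   pediatric geometry.
#' @param train An [illumination_train()]; the default is the clinical
#'   prototype (1.8 mm LED, 40/40 relay, 18 mm objective).
#' @param power_mW Total incident power per pulse in mW.
#' @param corneal_irradiance_mW_mm2 Measured corneal-plane irradiance in
#'   mW/mm^2.
#' @param w A [spectral_weighting()].
#' @param sweep_times Times (s) at which the time sweep is evaluated.
#' @return An object of class `safety_assessment`: a `data.frame` with one
#'   row per check (`name`, `value`, `units`, `limit`, `margin`, `pass`) and
#'   attributes `mode`, `spot_diameter_mm` and `sweep` (the sweep table).
#' @examples
#' assess_mode("standard")
#' assess_mode("alternative", eye = eye_preset("child"))
#' @export
assess_mode <- function(mode = c("standard", "alternative"),
                        eye = eye_preset("adult"),
                        train = illumination_train(1.8, 40, 40, 18),
                        power_mW = 100, corneal_irradiance_mW_mm2 = 5,
                        w = spectral_weighting(),
                        sweep_times = seq(0.1, 20, by = 0.1)) {
  mode <- match.arg(mode)
  stopifnot(inherits(eye, "eye_geometry"), inherits(train, "illumination_train"))
  sched <- switch(mode,
    standard = pulse_schedule(0.01, 0.09, assessment_time = 20),
    alternative = pulse_schedule(1, 19, assessment_time = 20)
  )
  spot <- project_source_to_sclera(train, eye)
  rbeam <- retinal_beam(power_mW, spot)
  cbeam <- corneal_beam(corneal_irradiance_mW_mm2)

  # short-time-scale window: the full 20 s train for the standard mode, the
  # single continuous 1 s pulse (duty 1, one pulse) for the alternative mode
  if (mode == "standard") {
    t_short <- 20; duty_short <- sched$duty; n_short <- sched$n_pulses
  } else {
    t_short <- 1; duty_short <- 1; n_short <- 1
  }

  checks <- list(
    list(name = "retinal irradiance, time-averaged weighted",
         value = retinal_irradiance_time_avg(rbeam, sched, w, weighted = TRUE),
         units = "mW/cm^2",
         limit = retinal_irradiance_limit_cw(spot)),
    list(name = "retinal irradiance, time-averaged unweighted",
         value = retinal_irradiance_time_avg(rbeam, sched, w, weighted = FALSE),
         units = "mW/cm^2",
         limit = retinal_irradiance_limit_cw(spot)),
    list(name = "retinal radiant exposure, short time scale",
         value = retinal_radiant_exposure(rbeam, sched, w, t = t_short,
                                          duty = duty_short),
         units = "J/cm^2",
         limit = retinal_exposure_limit_pulsed(spot, t_short, n_short)),
    list(name = "corneal irradiance, time-averaged",
         value = as.numeric(corneal_irradiance_time_avg(cbeam, sched)),
         units = "mW/cm^2",
         limit = 100),
    list(name = "corneal radiant exposure, short time scale",
         value = corneal_radiant_exposure(cbeam, t = t_short,
                                          duty = duty_short),
         units = "J/cm^2",
         limit = corneal_exposure_limit(t_short))
  )

  out <- do.call(rbind, lapply(checks, function(ck) {
    data.frame(name = ck$name, value = ck$value, units = ck$units,
               limit = ck$limit, margin = ck$limit / ck$value,
               pass = ck$value <= ck$limit)
  }))

  # sweep: verify value <= limit at all times in (0, 20] for both planes
  sweep <- do.call(rbind, lapply(sweep_times, function(t) {
    on_t <- pulse_on_time(t, sched)
    n_t <- max(1, ceiling(t / sched$period))
    re <- power_mW / effective_area(spot) * on_t * w$r_coefficient / 1000
    rl <- retinal_exposure_limit_pulsed(spot, t, n_t)
    ce <- corneal_irradiance_mW_mm2 * 100 * on_t / 1000
    cl <- corneal_exposure_limit(t)
    data.frame(t = t, retinal_exposure = re, retinal_limit = rl,
               corneal_exposure = ce, corneal_limit = cl,
               pass = re <= rl && ce <= cl)
  }))

  structure(out, class = c("safety_assessment", "data.frame"),
            mode = mode, spot_diameter_mm = spot, sweep = sweep,
            sweep_pass = all(sweep$pass))
}

#' @export
print.safety_assessment <- function(x, ...) {
  cat(sprintf("Ocular light-safety assessment (%s mode, %.1f mm retinal spot)\n",
              attr(x, "mode"), attr(x, "spot_diameter_mm")))
  df <- as.data.frame(x)
  df$value <- signif(df$value, 3)
  df$limit <- signif(df$limit, 3)
  df$margin <- signif(df$margin, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("time sweep (0, 20] s: %s\n",
              if (isTRUE(attr(x, "sweep_pass"))) "all times compliant"
              else "VIOLATION at some time"))
  invisible(x)
}
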