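# 2D scalar-wave simulation of the 4F transmission imaging geometry:
# quasi-incoherent illumination of a wavelength-scale scatterer, relay
# through two lenses, and the bright/dark Gouy-phase defocus contrast at the
# camera plane.
#
# Internal units: lengths in wavelengths (lambda = 1), c0 = 1, so one optical
# period is one time unit. The propagation axis z runs along matrix rows,
# the transverse axis x along columns.

#' Simulation grid
#'
#' @param nz_lambda,nx_lambda Domain extent along the propagation and
#'   transverse axes, in wavelengths.
#' @param spatial_step Grid step as a fraction of the wavelength (default
#'   1/20; 1/10 is adequate for the qualitative 4F experiments and four
#'   times faster).
#' @param courant Courant number `c0 dt / dx`; stability of the explicit 2D
#'   update requires `courant <= 1/sqrt(2)`.
#' @param sponge_lambda Thickness of the absorbing (exponential-damping)
#'   boundary layer on every edge, in wavelengths. Must be at least 10 cells.
#' @return An object of class `wave_grid`.
#' @export
wave_grid <- function(nz_lambda, nx_lambda, spatial_step = 1 / 20,
                      courant = 0.7, sponge_lambda = 4) {
  stop_if_not_positive(nz_lambda, "nz_lambda")
  stop_if_not_positive(nx_lambda, "nx_lambda")
  stop_if_not_positive(spatial_step, "spatial_step")
  if (courant <= 0 || courant > 1 / sqrt(2) + 1e-12) {
    stop("unstable step: `courant` must satisfy 0 < courant <= 1/sqrt(2)",
         call. = FALSE)
  }
  sponge_cells <- round(sponge_lambda / spatial_step)
  if (sponge_cells < 10) {
    stop("absorbing layer must be at least 10 cells thick", call. = FALSE)
  }
  nz <- round(nz_lambda / spatial_step)
  nx <- round(nx_lambda / spatial_step)
  structure(
    list(nz = nz, nx = nx, dx = spatial_step, dt = courant * spatial_step,
         courant = courant, sponge_cells = sponge_cells,
         nz_lambda = nz_lambda, nx_lambda = nx_lambda),
    class = "wave_grid"
  )
}

# transverse coordinates (lambda units, centered) and axial coordinates
grid_x <- function(grid) (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$dx
grid_z <- function(grid) (seq_len(grid$nz) - 0.5) * grid$dx

#' Refractive-index map builders
#'
#' `refractive_map()` creates a homogeneous background (n = 1) on a grid.
#' `add_lens()` inserts a thin biconvex lens as a refractive thickness
#' profile of glass (n = 1.5) whose paraxial optical-path difference equals
#' `-x^2 / (2 f)`, giving geometric focal length `f`. `add_scatterer()`
#' inserts a high-index disc (n = 2.5, diameter about one wavelength).
#' `add_diffuser()` inserts a random assembly of quarter-wavelength glass
#' particles (deterministic per seed) that scrambles the wavefront phase.
#'
#' @param grid A [wave_grid()].
#' @param map An index map created by `refractive_map()`.
#' @param z_lambda Axial position of the element, in wavelengths.
#' @param x_lambda Transverse position (0 = on axis).
#' @param focal_lambda Lens focal length in wavelengths.
#' @param half_aperture_lambda Lens half-aperture in wavelengths.
#' @param diameter_lambda Scatterer/particle diameter in wavelengths.
#' @param n Refractive index of the element.
#' @param thickness_lambda Axial thickness of the diffuser slab.
#' @param width_lambda Transverse width of the diffuser slab.
#' @param n_particles Number of particles in the diffuser assembly.
#' @param seed Seed for the particle positions.
#' @return The updated index matrix (`nz x nx`, values >= 1).
#' @name refractive_map
NULL

#' @rdname refractive_map
#' @export
refractive_map <- function(grid) {
  stopifnot(inherits(grid, "wave_grid"))
  matrix(1, grid$nz, grid$nx)
}

#' @rdname refractive_map
#' @export
add_lens <- function(map, grid, z_lambda, focal_lambda,
                     half_aperture_lambda, n = 1.5) {
  stopifnot(inherits(grid, "wave_grid"))
  x <- grid_x(grid)
  z <- grid_z(grid)
  a <- half_aperture_lambda
  f <- focal_lambda
  # aspheric thickness profile: equal optical path from a plane wave to the
  # focal point, (n - 1) * t(x) = const - (sqrt(f^2 + x^2) - f), which is
  # aberration-free at the collimated-to-point conjugates used in a 4F relay
  sag <- function(xx) (sqrt(f^2 + xx^2) - f) / (n - 1)
  thick <- pmax(0, sag(a) - sag(pmin(abs(x), a)))
  thick[abs(x) > a] <- 0
  for (j in seq_along(x)) {
    if (thick[j] > 0) {
      rows <- which(abs(z - z_lambda) <= thick[j] / 2)
      map[rows, j] <- n
    }
  }
  map
}

#' @rdname refractive_map
#' @export
add_scatterer <- function(map, grid, z_lambda, x_lambda = 0,
                          diameter_lambda = 1, n = 2.5) {
  stopifnot(inherits(grid, "wave_grid"))
  x <- grid_x(grid)
  z <- grid_z(grid)
  r <- diameter_lambda / 2
  cols <- which(abs(x - x_lambda) <= r)
  for (j in cols) {
    dz <- sqrt(max(0, r^2 - (x[j] - x_lambda)^2))
    rows <- which(abs(z - z_lambda) <= dz)
    map[rows, j] <- n
  }
  map
}

#' @rdname refractive_map
#' @export
add_diffuser <- function(map, grid, z_lambda, thickness_lambda = 1,
                         width_lambda, n_particles = 200,
                         diameter_lambda = 0.25, n = 1.5, seed = 1) {
  stopifnot(inherits(grid, "wave_grid"))
  with_seed(seed, {
    zs <- z_lambda + runif(n_particles, -thickness_lambda / 2,
                           thickness_lambda / 2)
    xs <- runif(n_particles, -width_lambda / 2, width_lambda / 2)
  })
  for (p in seq_len(n_particles)) {
    map <- add_scatterer(map, grid, zs[p], xs[p], diameter_lambda, n)
  }
  map
}

# sponge factor per cell: exp(-a s^2) with s the normalized depth into the
# absorbing layer; calibrated so a one-way passage attenuates by ~exp(-3.5)
sponge_mask <- function(grid, strength = 3.5) {
  w <- grid$sponge_cells
  a <- strength * 3 * grid$courant / w
  depth_profile <- function(n) {
    d <- pmax(0, pmax(w - (seq_len(n) - 1), (seq_len(n) - (n - w))))
    (d / w)^2
  }
  sz <- depth_profile(grid$nz)
  sx <- depth_profile(grid$nx)
  s2 <- outer(sz, sx, pmax)
  exp(-a * s2)
}

#' Propagate a wave through a refractive map
#'
#' Runs the explicit time-domain scalar-wave solver with absorbing boundary
#' layers and a monochromatic soft line source.
#'
#' @param map Refractive-index matrix from the [refractive_map()] builders.
#' @param grid The matching [wave_grid()].
#' @param src_row Grid row of the line source.
#' @param src_amp Source amplitude envelope along x (length `nx`).
#' @param src_phase Source phase along x in radians (length `nx`); a linear
#'   phase `2*pi*sin(theta)*x` launches a plane wave tilted by `theta`.
#' @param duration Total simulated time in optical periods.
#' @param avg_periods Number of final periods over which the time-averaged
#'   intensity `<u^2>` is accumulated.
#' @param snapshot_every Store a field snapshot every this many steps
#'   (0 = none).
#' @param source_off_period Optical period after which the source is
#'   switched off (0 = always on).
#' @param screen Optional per-cell absorbing-screen factor (<= 1, e.g.
#'   aperture stops), multiplied into the boundary damping mask.
#' @param frequency Source frequency as a multiple of the nominal frequency
#'   (1 = exactly one wavelength per length unit); small per-realization
#'   jitter models the finite coherence length of an LED.
#' @param energy_trace Record the total field energy (kinetic plus gradient)
#'   at every step in the returned `trace` vector.
#' @return List with `intensity` (time-averaged `<u^2>` matrix), `field`
#'   (final field), `snapshots` (list of matrices) and `grid`.
#' @export
propagate <- function(map, grid, src_row, src_amp, src_phase = NULL,
                      duration, avg_periods = 4, snapshot_every = 0,
                      source_off_period = 0, screen = NULL, frequency = 1,
                      energy_trace = FALSE) {
  stopifnot(inherits(grid, "wave_grid"))
  if (any(map < 1)) stop("refractive map must have n >= 1 everywhere",
                         call. = FALSE)
  src_phase <- src_phase %||% numeric(grid$nx)
  n_steps <- ceiling(duration / grid$dt)
  avg_start <- max(1L, n_steps - ceiling(avg_periods / grid$dt) + 1L)
  src_stop <- if (source_off_period > 0) {
    ceiling(source_off_period / grid$dt)
  } else 0L
  damp <- sponge_mask(grid)
  if (!is.null(screen)) damp <- damp * screen
  res <- fdtd_run_cpp(1 / map^2, damp, grid$courant,
                      as.integer(n_steps), as.integer(src_row),
                      src_amp, src_phase, 2 * pi * frequency * grid$dt,
                      as.integer(avg_start), as.integer(snapshot_every),
                      as.integer(src_stop), as.integer(ceiling(1 / grid$dt)),
                      as.integer(energy_trace))
  res$grid <- grid
  res
}

#' 4F imaging system description
#'
#' Two identical lenses in a 4F arrangement: the sample plane one focal
#' length before the first lens, the back focal plane between the lenses,
#' and the camera one focal length after the second lens (magnification -1).
#' A wavelength-scale scatterer can be placed near the sample plane with an
#' axial offset, and the quasi-incoherent illumination is realized as an
#' ensemble of randomly tilted, randomly phased plane waves whose maximum
#' tilt is the equivalent source half-angle.
#'
#' @param focal_lambda Lens focal length in wavelengths.
#' @param half_aperture_lambda Lens half-aperture in wavelengths.
#' @param spatial_step Grid step (fraction of the wavelength).
#' @param sponge_lambda Absorbing-layer thickness in wavelengths.
#' @param scatterer_diameter_lambda Scatterer diameter.
#' @param scatterer_n Scatterer refractive index.
#' @param source_half_angle Half-angle (radians) of the equivalent extended
#'   incoherent source.
#' @param source_bandwidth Relative frequency jitter of the source across
#'   realizations (models the LED's finite coherence length and suppresses
#'   etalon fringes between the lens surfaces).
#' @return An object of class `four_f_system` carrying the grid, the plane
#'   positions (`sample_z`, `bfp_z`, `camera_z`, `source_z`) and the
#'   geometry parameters, including the system estimates `na_detection`
#'   (lens acceptance), `na_effective` and `dof_lambda`
#'   (`lambda / NA_eff^2`).
#' @export
four_f_system <- function(focal_lambda = 13, half_aperture_lambda = 9,
                          spatial_step = 1 / 20, sponge_lambda = 3,
                          scatterer_diameter_lambda = 1, scatterer_n = 1.15,
                          source_half_angle = 0.03, source_bandwidth = 0.03,
                          sample_offset_lambda = 12) {
  f <- focal_lambda
  sample_z <- sponge_lambda + sample_offset_lambda  # room for axial scans
  camera_z <- sample_z + 4 * f
  nz <- camera_z + 4 + sponge_lambda
  nx <- 2 * (half_aperture_lambda + 4 + sponge_lambda)
  grid <- wave_grid(nz, nx, spatial_step = spatial_step,
                    sponge_lambda = sponge_lambda)
  na_d <- sin(atan(half_aperture_lambda / f))
  na_i <- sin(source_half_angle)
  na_eff <- (min(na_i, na_d) + na_d) / 2
  structure(
    list(grid = grid, focal_lambda = f,
         half_aperture_lambda = half_aperture_lambda,
         sample_z = sample_z, lens1_z = sample_z + f,
         bfp_z = sample_z + 2 * f, lens2_z = sample_z + 3 * f,
         camera_z = camera_z,
         source_z = sponge_lambda + 1.5,
         source_width_lambda = 2 * half_aperture_lambda - 2,
         source_taper_lambda = 5,
         scatterer_diameter_lambda = scatterer_diameter_lambda,
         scatterer_n = scatterer_n,
         source_half_angle = source_half_angle,
         source_bandwidth = source_bandwidth,
         na_detection = na_d, na_effective = na_eff,
         dof_lambda = 1 / na_eff^2),
    class = "four_f_system"
  )
}

row_of <- function(grid, z_lambda) {
  max(1L, min(grid$nz, round(z_lambda / grid$dx + 0.5)))
}

# refractive map plus absorbing aperture stops around both lenses
build_4f_map <- function(sys, scatterer = TRUE, scatterer_z_offset = 0) {
  grid <- sys$grid
  map <- refractive_map(grid)
  map <- add_lens(map, grid, sys$lens1_z, sys$focal_lambda,
                  sys$half_aperture_lambda)
  map <- add_lens(map, grid, sys$lens2_z, sys$focal_lambda,
                  sys$half_aperture_lambda)
  if (scatterer) {
    map <- add_scatterer(map, grid, sys$sample_z + scatterer_z_offset, 0,
                         sys$scatterer_diameter_lambda, sys$scatterer_n)
  }
  screen <- matrix(1, grid$nz, grid$nx)
  z <- grid_z(grid)
  x <- grid_x(grid)
  blocked <- abs(x) > sys$half_aperture_lambda
  for (zl in c(sys$lens1_z, sys$lens2_z)) {
    rows <- which(abs(z - zl) <= 1)
    screen[rows, blocked] <- 0.75
  }
  list(map = map, screen = screen)
}

# flat-top source envelope with raised-cosine edges; the wide taper keeps
# Fresnel ringing of the envelope edges out of the central analysis window
source_envelope <- function(grid, width_lambda, taper_lambda = 5) {
  x <- grid_x(grid)
  half <- width_lambda / 2
  amp <- numeric(grid$nx)
  core <- abs(x) <= half - taper_lambda
  edge <- abs(x) > half - taper_lambda & abs(x) <= half
  amp[core] <- 1
  amp[edge] <- 0.5 * (1 + cos(pi * (abs(x[edge]) - (half - taper_lambda)) /
                                taper_lambda))
  amp
}

run_4f_once <- function(sys, ms, theta, phase0, frequency = 1,
                        duration = NULL, avg_periods = 3) {
  grid <- sys$grid
  duration <- duration %||% (sys$camera_z + 18)
  amp <- source_envelope(grid, sys$source_width_lambda,
                         sys$source_taper_lambda %||% 5)
  phase <- 2 * pi * frequency * sin(theta) * grid_x(grid) + phase0
  propagate(ms$map, grid, row_of(grid, sys$source_z), amp, phase,
            duration = duration, avg_periods = avg_periods,
            screen = ms$screen, frequency = frequency)
}

#' Time-averaged camera image of the 4F system
#'
#' Averages the camera-plane intensity over independent realizations of the
#' quasi-incoherent source (random tilt within the source half-angle and
#' random phase per realization). Without the scatterer the camera sees a
#' uniform field; with it, a localized bright or dark interference feature
#' appears at the conjugate position depending on the axial offset.
#'
#' @param sys A [four_f_system()].
#' @param n_realizations Number of source realizations to average (>= 1).
#' @param seed Seed controlling all realizations (deterministic given
#'   `seed` and `n_realizations`).
#' @param scatterer Include the scatterer.
#' @param scatterer_z_offset Axial scatterer offset from the sample plane,
#'   in wavelengths (positive = towards the lens).
#' @return An object of class `sim_result`: list with `camera` (intensity
#'   along the camera row), `bfp` (back-focal-plane row), `intensity`
#'   (time-averaged 2D intensity of the last realization), `x` (transverse
#'   coordinates in wavelengths) and the call parameters.
#' @export
simulate_camera_image <- function(sys, n_realizations = 16, seed = 1,
                                  scatterer = TRUE, scatterer_z_offset = 0) {
  stopifnot(inherits(sys, "four_f_system"))
  if (n_realizations < 1) stop("`n_realizations` must be >= 1", call. = FALSE)
  grid <- sys$grid
  ms <- build_4f_map(sys, scatterer, scatterer_z_offset)
  # stratified quadrature over the incoherent ensemble: tilts equally spaced
  # across the source disc, frequencies stratified across the bandwidth and
  # paired with the tilts in a seeded random order
  draws <- with_seed(seed, {
    u <- if (n_realizations == 1) 0 else
      seq(-1, 1, length.out = n_realizations)
    fq <- 1 + sys$source_bandwidth *
      (if (n_realizations == 1) 0 else
         sample(seq(-1, 1, length.out = n_realizations)))
    data.frame(u = u, phi = runif(n_realizations, 0, 2 * pi), freq = fq)
  })
  cam_row <- row_of(grid, sys$camera_z)
  bfp_row <- row_of(grid, sys$bfp_z)
  cam <- numeric(grid$nx)
  bfp <- numeric(grid$nx)
  res <- NULL
  for (r in seq_len(n_realizations)) {
    theta <- draws$u[r] * sys$source_half_angle
    res <- run_4f_once(sys, ms, theta, draws$phi[r], draws$freq[r])
    cam <- cam + res$intensity[cam_row, ]
    bfp <- bfp + res$intensity[bfp_row, ]
  }
  structure(
    list(camera = cam / n_realizations, bfp = bfp / n_realizations,
         intensity = res$intensity, x = grid_x(grid), sys = sys,
         n_realizations = n_realizations, seed = seed,
         scatterer = scatterer, scatterer_z_offset = scatterer_z_offset),
    class = "sim_result"
  )
}

# analysis window: central part of the relayed field, away from the source
# envelope taper and aperture diffraction at the edges
analysis_cols <- function(sim, halfwidth_lambda = NULL) {
  hw <- halfwidth_lambda %||% min(3, 0.4 * sim$sys$half_aperture_lambda)
  which(abs(sim$x) <= hw)
}

#' Camera uniformity and feature contrast
#'
#' `camera_uniformity()` returns the relative standard deviation of the
#' camera intensity over the central analysis window (low without a
#' scatterer). `camera_contrast()` returns the interference contrast of the
#' scatterer feature, `(I_feature - I_background) / I_background`, with the
#' background taken as the median camera intensity over the analysis window.
#'
#' @param sim A `sim_result` from [simulate_camera_image()].
#' @param feature_halfwidth_lambda Half-width of the feature window around
#'   the conjugate (on-axis) position.
#' @param reference Optional matched no-scatterer `sim_result` (same system,
#'   realizations and seed); when given, the background at the feature is
#'   taken pixel-wise from the reference, which removes the residual
#'   structure of the finite incoherent ensemble.
#' @return A single number.
#' @name camera_metrics
NULL

#' @rdname camera_metrics
#' @export
camera_uniformity <- function(sim) {
  cols <- analysis_cols(sim)
  v <- sim$camera[cols]
  sd(v) / mean(v)
}

#' @rdname camera_metrics
#' @export
camera_contrast <- function(sim, feature_halfwidth_lambda = 1,
                            reference = NULL) {
  feat <- which(abs(sim$x) <= feature_halfwidth_lambda)
  if (!is.null(reference)) {
    mean(sim$camera[feat]) / mean(reference$camera[feat]) - 1
  } else {
    cols <- analysis_cols(sim)
    bg <- median(sim$camera[setdiff(cols, feat)])
    (mean(sim$camera[feat]) - bg) / bg
  }
}

#' Back-focal-plane wave separation
#'
#' In the back focal plane of the first lens the transmitted (undiffracted)
#' wave is focused into a diffraction-limited core while light scattered by
#' a wavelength-scale object is spread over the aperture. This diagnostic
#' runs a single unaveraged realization and reports the fraction of
#' back-focal-plane energy outside the focused core (a few diffraction-
#' limited spot radii).
#'
#' @param sys A [four_f_system()].
#' @param scatterer Include the scatterer.
#' @param scatterer_z_offset Axial offset of the scatterer (wavelengths).
#' @param core_spots Core radius in units of the diffraction-limited spot
#'   half-width `f * lambda / W` (`W` = source width).
#' @return List with `outside_fraction`, `core_radius_lambda` and the
#'   back-focal-plane intensity profile.
#' @details The diagnostic uses a fully apodized (raised-cosine) source beam
#'   so that the focused transmitted wave has negligible sidelobes in the
#'   back focal plane; the outside-core fraction then isolates the light
#'   scattered by the sample.
#' @export
back_focal_plane_analysis <- function(sys, scatterer = TRUE,
                                      scatterer_z_offset = 0,
                                      core_spots = 3) {
  stopifnot(inherits(sys, "four_f_system"))
  grid <- sys$grid
  # only the first lens matters for the back-focal-plane separation; leaving
  # the tube lens out keeps its Fresnel back-reflection from polluting the
  # measurement
  map <- refractive_map(grid)
  map <- add_lens(map, grid, sys$lens1_z, sys$focal_lambda,
                  sys$half_aperture_lambda)
  if (scatterer) {
    map <- add_scatterer(map, grid, sys$sample_z + scatterer_z_offset, 0,
                         sys$scatterer_diameter_lambda, sys$scatterer_n)
  }
  screen <- build_4f_map(sys, scatterer = FALSE)$screen
  w <- sys$source_width_lambda
  amp <- source_envelope(grid, w, taper_lambda = w / 2)  # Hann apodization
  res <- propagate(map, grid, row_of(grid, sys$source_z), amp,
                   duration = sys$camera_z + 18, avg_periods = 3,
                   screen = screen)
  bfp <- res$intensity[row_of(grid, sys$bfp_z), ]
  x <- grid_x(grid)
  # spot half-width of the apodized beam is ~ f * lambda / (w/2)
  core_r <- core_spots * sys$focal_lambda / (w / 2)
  window <- abs(x) <= sys$half_aperture_lambda
  core <- abs(x) <= core_r
  total <- sum(bfp[window])
  outside <- sum(bfp[window & !core])
  list(outside_fraction = outside / total, core_radius_lambda = core_r,
       x = x[window], bfp = bfp[window])
}

#' Axial contrast scan of the 4F system
#'
#' Moves the scatterer axially and records the normalized on-axis camera
#' intensity (feature over background) at each offset. The profile crosses
#' the background level near focus, with a bright extremum on one side and a
#' dark extremum on the other.
#'
#' @param sys A [four_f_system()].
#' @param z_offsets Axial offsets in wavelengths (at least 5, spanning
#'   about +/- 2 DOF).
#' @param n_realizations Source realizations per offset.
#' @param seed Seed; the same realization set is reused at every offset (and
#'   in the shared no-scatterer reference) so that offsets differ only by
#'   the scatterer position.
#' @return An [axial_profile()] with `z` in wavelengths and `value` the
#'   normalized intensity (background = 1), plus attribute `background`.
#' @export
axial_contrast_scan <- function(sys, z_offsets, n_realizations = 12,
                                seed = 1) {
  stopifnot(inherits(sys, "four_f_system"))
  if (length(z_offsets) < 2) stop("need at least 2 offsets", call. = FALSE)
  ref <- simulate_camera_image(sys, n_realizations, seed, scatterer = FALSE)
  vals <- vapply(z_offsets, function(z) {
    sim <- simulate_camera_image(sys, n_realizations, seed,
                                 scatterer = TRUE, scatterer_z_offset = z)
    1 + camera_contrast(sim, reference = ref)
  }, numeric(1))
  structure(axial_profile(z_offsets, vals), background = 1)
}

#' Contrast and defocus persistence versus source size (wave simulation)
#'
#' Repeats the axial contrast scan for several equivalent source sizes
#' (half-angles of the incoherent tilt ensemble) and reports, for each, the
#' peak-to-trough contrast, the axial FWHM of the profile, and the defocus
#' persistence: the fraction of the peak |contrast| that survives at the
#' largest scanned defocus. The same stratified ensemble is shared across
#' sizes so that the sweep isolates the source-size effect. Larger sources
#' give lower contrast and a faster fade with defocus (lower persistence,
#' i.e. a shorter axial visibility range / smaller DOF).
#'
#' @param sys A [four_f_system()] template; its own `source_half_angle` is
#'   overridden by the sweep values.
#' @param half_angles Source half-angles in radians (>= 1).
#' @param z_offsets Axial offsets for each scan (wavelengths).
#' @param n_realizations Realizations per offset.
#' @param seed Seed shared across sizes.
#' @return `data.frame` with columns `half_angle`, `contrast`,
#'   `axial_fwhm_lambda`, `persistence` (in (0, 1]).
#' @export
source_size_sweep <- function(sys, half_angles = c(0.03, 0.12, 0.35),
                              z_offsets = seq(-8, 8, by = 2),
                              n_realizations = 8, seed = 1) {
  stopifnot(inherits(sys, "four_f_system"))
  rows <- lapply(half_angles, function(ha) {
    s <- sys
    s$source_half_angle <- ha
    prof <- axial_contrast_scan(s, z_offsets, n_realizations, seed)
    dev <- abs(prof$value - 1)
    far <- which.max(prof$z)
    data.frame(half_angle = ha,
               contrast = axial_contrast(prof),
               axial_fwhm_lambda = axial_fwhm(prof, background = 1),
               persistence = dev[far] / max(dev))
  })
  do.call(rbind, rows)
}
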