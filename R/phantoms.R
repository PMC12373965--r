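# Seeded synthetic phantoms with ground truth: endothelial-like cell
# mosaics, curvilinear nerve layers, defocus scatterer stacks, and camera
# artifacts (fixed-pattern noise, Bayer mismatch, per-frame noise). The
# defocus contrast of every phantom is rendered through the analytic
# contrast model, so phantoms and theory share one defocus law.

#' Phantom specification
#'
#' @param fov_mm Field of view in mm, `c(width, height)` or a single number
#'   for a square field.
#' @param pixel_pitch_um Pixel pitch in um.
#' @param density Target density: cells/mm^2 for the mosaic, mm/mm^2 for the
#'   nerve layer.
#' @param background Background intensity level.
#' @param modulation Peak interference modulation amplitude (intensity
#'   units) of a fully contrasted structure.
#' @param params A [defocus_params()] describing the defocus law.
#' @param source_diameter_mm Equivalent source diameter used when rendering
#'   defocus stacks.
#' @param nerve_width_um Nerve stroke width in um.
#' @param fixed_pattern_rms RMS of the static fixed-pattern field.
#' @param bayer_amplitude Amplitude of the period-2 Bayer modulation.
#' @param noise_sd Standard deviation of per-frame white noise.
#' @param seed Seed; every generator is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm = 0.5, pixel_pitch_um = 1, density = 3200,
                         background = 100, modulation = 20,
                         params = defocus_params(), source_diameter_mm = 2.4,
                         nerve_width_um = 3, fixed_pattern_rms = 0,
                         bayer_amplitude = 0, noise_sd = 0, seed = 1) {
  if (length(fov_mm) == 1L) fov_mm <- c(fov_mm, fov_mm)
  stop_if_not_positive(fov_mm[1], "fov_mm[1]")
  stop_if_not_positive(fov_mm[2], "fov_mm[2]")
  stop_if_not_positive(pixel_pitch_um, "pixel_pitch_um")
  stop_if_negative(density, "density")
  stop_if_negative(fixed_pattern_rms, "fixed_pattern_rms")
  stop_if_negative(bayer_amplitude, "bayer_amplitude")
  stop_if_negative(noise_sd, "noise_sd")
  structure(
    list(fov_mm = fov_mm, pixel_pitch_um = pixel_pitch_um, density = density,
         background = background, modulation = modulation, params = params,
         source_diameter_mm = source_diameter_mm,
         nerve_width_um = nerve_width_um,
         fixed_pattern_rms = fixed_pattern_rms,
         bayer_amplitude = bayer_amplitude, noise_sd = noise_sd,
         seed = seed),
    class = "phantom_spec"
  )
}

spec_dims <- function(spec) {
  c(nr = round(spec$fov_mm[2] * 1000 / spec$pixel_pitch_um),
    nc = round(spec$fov_mm[1] * 1000 / spec$pixel_pitch_um))
}

# minimum-distance dart throwing with spatial hashing (bucket size such that
# each bucket holds at most one accepted point); returns n x 2 (row, col) px
poisson_disc_points <- function(n, nr, nc, min_dist) {
  g <- min_dist / sqrt(2)
  gr <- ceiling(nr / g); gc <- ceiling(nc / g)
  bucket <- matrix(0L, gr, gc)
  pts <- matrix(NA_real_, n, 2)
  k <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  while (k < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, 1, nr); c <- runif(1, 1, nc)
    bi <- ceiling(r / g); bj <- ceiling(c / g)
    ok <- TRUE
    for (di in -2:2) {
      ii <- bi + di
      if (ii < 1 || ii > gr) next
      for (dj in -2:2) {
        jj <- bj + dj
        if (jj < 1 || jj > gc) next
        p <- bucket[ii, jj]
        if (p > 0L &&
            (pts[p, 1] - r)^2 + (pts[p, 2] - c)^2 < min_dist^2) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      k <- k + 1L
      pts[k, ] <- c(r, c)
      bucket[bi, bj] <- k
    }
  }
  if (k < n) {
    # fill the remainder without the distance constraint
    extra <- n - k
    pts[k + seq_len(extra), ] <- cbind(runif(extra, 1, nr),
                                       runif(extra, 1, nc))
  }
  pts
}

# smooth signed curvature-like defocus field over the image, in um:
# a low-frequency oblique sinusoid squashed by tanh so that most of the
# field sits at +/- zR (full bright/dark contrast) with a narrow
# transition band
defocus_field <- function(nr, nc, z_rayleigh_um, steepness = 6, phase = 0.7) {
  xs <- seq_len(nc) / nc
  ys <- seq_len(nr) / nr
  g <- sin(2 * pi * (outer(ys, xs * 0, `+`) * 0.9 +
                       outer(ys * 0, xs, `+`) * 1.1) + phase)
  z_rayleigh_um * tanh(steepness * g) / tanh(steepness)
}

# relative modulation (in [-1, 1]) of a structure at defocus z
modulation_at <- function(z, params) {
  peak <- single_angle_profile(params$z_rayleigh_um, 0, params)
  single_angle_profile(z, 0, params) / peak
}

stamp_blob <- function(img, r0, c0, amp, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(3 * sigma)
  rs <- max(1, round(r0) - w):min(nr, round(r0) + w)
  cs <- max(1, round(c0) - w):min(nc, round(c0) + w)
  if (!length(rs) || !length(cs)) return(img)
  blob <- amp * exp(-(outer((rs - r0)^2, (cs - c0)^2, `+`)) / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + blob
  img
}

#' Endothelial-mosaic phantom
#'
#' Generates a seeded quasi-regular cell mosaic (minimum-distance point
#' process) in which each cell body is rendered as a blob whose signed
#' modulation follows a smooth curvature-like defocus field, so bright and
#' dark cells coexist in one image as they do across a curved cornea near
#' focus. Cells inside the transition band around the focus crossing carry
#' little contrast and are excluded from the bright/dark analysis masks
#' (matching the counting rule of restricting to the area where one sign is
#' observed).
#'
#' @param spec A [phantom_spec()] with `density` in cells/mm^2 (0, or 500
#'   to 6000).
#' @param cell_diameter_um Rendered cell-body diameter (FWHM) in um;
#'   defaults to 0.47 of the mean cell spacing.
#' @return List with `image`, `truth` (cell centers, per-cell defocus and
#'   modulation, bright/dark masks with their areas, generated density) and
#'   `spec`.
#' @export
gen_endothelial_mosaic <- function(spec, cell_diameter_um = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec_dims(spec)
  area <- prod(spec$fov_mm)
  if (spec$density == 0) {
    img <- matrix(spec$background, d["nr"], d["nc"])
    return(list(image = img,
                truth = list(centers = matrix(numeric(0), 0, 2),
                             density = 0, area_mm2 = area),
                spec = spec))
  }
  if (spec$density < 500 || spec$density > 6000) {
    stop("mosaic density must be 0 or within [500, 6000] cells/mm^2",
         call. = FALSE)
  }
  n <- round(spec$density * area)
  spacing_px <- 1000 / (sqrt(spec$density) * spec$pixel_pitch_um)
  with_seed(spec$seed, {
    pts <- poisson_disc_points(n, d["nr"], d["nc"], 0.6 * spacing_px)
    phase <- runif(1, 0, 2 * pi)
  })
  zr <- spec$params$z_rayleigh_um
  zf <- defocus_field(d["nr"], d["nc"], zr, phase = phase)
  z_cell <- zf[cbind(pmin(d["nr"], pmax(1, round(pts[, 1]))),
                     pmin(d["nc"], pmax(1, round(pts[, 2]))))]
  rel <- modulation_at(z_cell, spec$params)
  img <- matrix(spec$background, d["nr"], d["nc"])
  diameter_um <- cell_diameter_um %||% (0.47 * spacing_px * spec$pixel_pitch_um)
  sigma <- diameter_um / spec$pixel_pitch_um / 2.355   # FWHM -> sigma
  for (i in seq_len(n)) {
    img <- stamp_blob(img, pts[i, 1], pts[i, 2],
                      spec$modulation * rel[i], sigma)
  }
  rel_field <- modulation_at(zf, spec$params)
  mask_bright <- rel_field >= 0.3
  mask_dark <- rel_field <= -0.3
  px_area <- (spec$pixel_pitch_um / 1000)^2
  list(
    image = img,
    truth = list(
      centers = pts, z_um = z_cell, rel_modulation = rel,
      bright = rel >= 0.3, dark = rel <= -0.3,
      mask_bright = mask_bright, mask_dark = mask_dark,
      area_bright_mm2 = sum(mask_bright) * px_area,
      area_dark_mm2 = sum(mask_dark) * px_area,
      density = spec$density, area_mm2 = area,
      cell_spacing_um = spacing_px * spec$pixel_pitch_um,
      cell_diameter_um = diameter_um
    ),
    spec = spec
  )
}

# one smooth random stroke; returns an n x 2 (row, col) polyline
random_stroke <- function(nr, nc, step_px, max_len_px) {
  r <- runif(1, 1, nr); c <- runif(1, 1, nc)
  heading <- runif(1, 0, 2 * pi)
  n_steps <- ceiling(max_len_px / step_px)
  pts <- matrix(NA_real_, n_steps + 1L, 2)
  pts[1, ] <- c(r, c)
  k <- 1L
  for (i in seq_len(n_steps)) {
    heading <- heading + rnorm(1, 0, 0.15)
    r <- r + step_px * sin(heading)
    c <- c + step_px * cos(heading)
    if (r < 1 || r > nr || c < 1 || c > nc) break
    k <- k + 1L
    pts[k, ] <- c(r, c)
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Nerve-layer phantom
#'
#' Draws smooth random curvilinear strokes (bounded curvature, a few um
#' wide) until the total polyline length per area reaches the target length
#' density, trimming the final stroke so the generated total matches the
#' target. Strokes are rendered as bright ridges of the given modulation.
#'
#' @param spec A [phantom_spec()] with `density` in mm/mm^2.
#' @return List with `image`, `truth` (polylines, generated total length
#'   and density) and `spec`.
#' @export
gen_nerve_layer <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec_dims(spec)
  area <- prod(spec$fov_mm)
  img <- matrix(spec$background, d["nr"], d["nc"])
  if (spec$density == 0) {
    return(list(image = img,
                truth = list(polylines = list(), total_length_mm = 0,
                             density = 0, area_mm2 = area),
                spec = spec))
  }
  target_px <- spec$density * area * 1000 / spec$pixel_pitch_um
  step_px <- 2
  polylines <- list()
  total <- 0
  with_seed(spec$seed, {
    while (total < target_px) {
      stroke <- random_stroke(d["nr"], d["nc"], step_px,
                              max_len_px = runif(1, 0.15, 0.35) * 1000 /
                                spec$pixel_pitch_um)
      len <- polyline_length_px(stroke)
      if (len < 5 * step_px) next
      if (total + len > target_px) {
        # trim the last stroke to land exactly on the target
        need <- target_px - total
        cum <- c(0, cumsum(sqrt(rowSums(diff(stroke)^2))))
        keep <- which(cum <= need)
        if (length(keep) < 2L) break
        stroke <- stroke[keep, , drop = FALSE]
        # extend the final segment fractionally to hit the target length
        rem <- need - cum[length(keep)]
        if (rem > 0 && length(keep) < nrow(stroke) + 1L) {
          dirv <- stroke[length(keep), ] - stroke[length(keep) - 1L, ]
          dirv <- dirv / sqrt(sum(dirv^2))
          stroke <- rbind(stroke, stroke[length(keep), ] + rem * dirv)
        }
        len <- polyline_length_px(stroke)
      }
      polylines[[length(polylines) + 1L]] <- stroke
      total <- total + len
    }
  })
  # rasterize: mark pixels near the polylines, then smooth into ridges
  width_px <- spec$nerve_width_um / spec$pixel_pitch_um
  mask <- matrix(FALSE, d["nr"], d["nc"])
  for (p in polylines) {
    # resample densely so the stamped discs overlap
    seg <- sqrt(rowSums(diff(p)^2))
    tt <- c(0, cumsum(seg))
    s <- seq(0, tt[length(tt)], by = 0.5)
    rr <- approx(tt, p[, 1], xout = s)$y
    cc <- approx(tt, p[, 2], xout = s)$y
    w <- max(0L, floor((width_px - 1) / 2))
    for (dr in -w:w) for (dc in -w:w) {
      if (dr^2 + dc^2 <= (width_px / 2)^2) {
        ri <- round(rr) + dr; ci <- round(cc) + dc
        ok <- ri >= 1 & ri <= d["nr"] & ci >= 1 & ci <= d["nc"]
        mask[cbind(ri[ok], ci[ok])] <- TRUE
      }
    }
  }
  ridge <- gaussian_smooth(mask * 1, sigma = max(0.6, width_px / 3))
  if (max(ridge) > 0) ridge <- ridge / max(ridge)
  img <- img + spec$modulation * ridge
  total_mm <- total * spec$pixel_pitch_um / 1000
  list(
    image = img,
    truth = list(polylines = polylines, total_length_mm = total_mm,
                 density = total_mm / area, area_mm2 = area,
                 mask = mask),
    spec = spec
  )
}

#' Defocus scatterer stack phantom
#'
#' Renders point scatterers through the incoherent-sum defocus law at each
#' requested axial offset, reproducing the bright-to-invisible-to-dark
#' transition through focus. A smaller equivalent source keeps the
#' scatterers visible over a longer axial range.
#'
#' @param spec A [phantom_spec()]; `source_diameter_mm` selects the
#'   equivalent source.
#' @param z_offsets_um Axial offsets of the stack slices in um.
#' @param n_scatterers Number of scatterers.
#' @param eye An [eye_geometry()] used to convert the source diameter to
#'   illumination angles.
#' @return List with `stack` (an [image_stack()]), `truth` (scatterer
#'   positions, per-slice modulation) and `spec`.
#' @export
gen_scatterer_stack <- function(spec, z_offsets_um, n_scatterers = 25,
                                eye = eye_geometry()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec_dims(spec)
  src <- source_distribution(spec$source_diameter_mm, eye)
  prof <- incoherent_sum_profile(z_offsets_um, src, spec$params)
  peak <- single_angle_profile(spec$params$z_rayleigh_um, 0, spec$params)
  with_seed(spec$seed, {
    pts <- cbind(runif(n_scatterers, 1, d["nr"]),
                 runif(n_scatterers, 1, d["nc"]))
  })
  sigma <- max(1, spec$params$w0_um / spec$pixel_pitch_um)
  frames <- lapply(seq_along(z_offsets_um), function(k) {
    img <- matrix(spec$background, d["nr"], d["nc"])
    amp <- spec$modulation * prof$value[k] / peak
    for (i in seq_len(n_scatterers)) {
      img <- stamp_blob(img, pts[i, 1], pts[i, 2], amp, sigma)
    }
    img
  })
  list(
    stack = image_stack(frames, spec$pixel_pitch_um, "mono_global",
                        meta = list(z_offsets_um = z_offsets_um)),
    truth = list(centers = pts, z_offsets_um = z_offsets_um,
                 rel_modulation = prof$value / peak),
    spec = spec
  )
}

#' Add camera artifacts to a phantom
#'
#' Adds a seeded static fixed-pattern field (shared across the frames of a
#' stack), a period-2 Bayer modulation, and independent per-frame white
#' noise, according to the artifact parameters of the spec. The injected
#' artifact fields are returned for oracle tests.
#'
#' @param x A matrix or an [image_stack()].
#' @param spec A [phantom_spec()] carrying `fixed_pattern_rms`,
#'   `bayer_amplitude`, `noise_sd` and `seed`.
#' @return List with `image` (or `stack`) and `artifacts` (the injected
#'   `fixed_pattern` and `bayer` fields).
#' @export
add_camera_artifacts <- function(x, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  frames <- if (inherits(x, "image_stack")) x$frames else list(x)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  fp <- matrix(0, nr, nc)
  bay <- matrix(0, nr, nc)
  with_seed(spec$seed + 104729L, {
    if (spec$fixed_pattern_rms > 0) {
      # column banding plus per-pixel offsets, typical of a front-illuminated
      # mono sensor
      raw <- 0.7 * matrix(rnorm(nc), nr, nc, byrow = TRUE) +
        0.7 * matrix(rnorm(nr * nc), nr, nc)
      fp <- spec$fixed_pattern_rms * raw / sqrt(mean(raw^2))
    }
    if (spec$bayer_amplitude > 0) {
      checker <- outer(seq_len(nr), seq_len(nc),
                       function(r, c) (-1)^(r + c))
      bay <- spec$bayer_amplitude * checker
    }
    frames <- lapply(frames, function(f) {
      f <- f + fp + bay
      if (spec$noise_sd > 0) f <- f + matrix(rnorm(nr * nc, 0, spec$noise_sd),
                                             nr, nc)
      f
    })
  })
  artifacts <- list(fixed_pattern = fp, bayer = bay)
  if (inherits(x, "image_stack")) {
    x$frames <- frames
    list(stack = x, artifacts = artifacts)
  } else {
    list(image = frames[[1]], artifacts = artifacts)
  }
}
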