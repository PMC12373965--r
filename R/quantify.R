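# Morphometric quantification: cell detection and density, nerve length
# density, mean cell diameter, and SNR in dB.

#' Detect cell bodies of one contrast sign
#'
#' Local-extremum detection at the expected cell scale on a band-passed
#' image. The image is lightly smoothed relative to the cell size, local
#' maxima of the selected sign are found with a minimum separation of half
#' the expected diameter, and weak maxima below a fraction of the robust
#' peak amplitude are discarded. Counting one contrast sign mirrors the
#' disambiguation rule used for interference images, where the same cells
#' appear bright on one side of focus and dark on the other.
#'
#' @param image Band-passed numeric matrix (background near 0).
#' @param pixel_pitch_um Pixel pitch in um.
#' @param sign `"bright"` (positive peaks) or `"dark"` (negative peaks).
#' @param scale_um Expected cell diameter in um.
#' @param mask Optional logical matrix restricting the analysis region (the
#'   region where the selected sign dominates); its area defines the
#'   density denominator.
#' @param threshold Detection threshold as a fraction of the robust (99th
#'   percentile) peak amplitude within the analysis region.
#' @return An object of class `cell_detections`: `data.frame` with columns
#'   `row`, `col`, `value`, and attributes `area_mm2`, `sign`,
#'   `pixel_pitch_um`.
#' @export
detect_cells <- function(image, pixel_pitch_um, sign = c("bright", "dark"),
                         scale_um, mask = NULL, threshold = 0.35) {
  sign <- match.arg(sign)
  stop_if_not_positive(pixel_pitch_um, "pixel_pitch_um")
  stop_if_not_positive(scale_um, "scale_um")
  s <- if (sign == "bright") image else -image
  scale_px <- scale_um / pixel_pitch_um
  # light smoothing: strong enough to suppress pixel noise, weak enough not
  # to merge neighboring cell bodies
  s <- gaussian_smooth(s, sigma = max(0.6, scale_px / 8))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  min_sep <- 0.5 * scale_px
  r <- max(1L, floor(min_sep / 2))
  is_max <- s >= max_filter(s, r) & mask
  # threshold relative to the in-mask median so that detection is invariant
  # to global affine intensity changes
  med <- median(s[mask])
  thr <- threshold * (quantile(s[mask], 0.99, names = FALSE) - med)
  cand <- which(is_max & (s - med) > thr, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    # greedy minimum-separation enforcement, strongest peaks first
    v <- s[cand]
    o <- order(v, decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    keep <- logical(nrow(cand))
    acc_r <- numeric(0); acc_c <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (length(acc_r) == 0L ||
          all((acc_r - cand[i, 1])^2 + (acc_c - cand[i, 2])^2 >= min_sep^2)) {
        keep[i] <- TRUE
        acc_r <- c(acc_r, cand[i, 1]); acc_c <- c(acc_c, cand[i, 2])
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  area_mm2 <- sum(mask) * (pixel_pitch_um / 1000)^2
  out <- data.frame(row = cand[, 1], col = cand[, 2],
                    value = if (nrow(cand)) s[cand] else numeric(0))
  structure(out, class = c("cell_detections", "data.frame"),
            area_mm2 = area_mm2, sign = sign,
            pixel_pitch_um = pixel_pitch_um)
}

#' Cell density
#'
#' Number of detected cells divided by the analysis area.
#'
#' @param detections A [detect_cells()] result, or a count.
#' @param area_mm2 Analysis area in mm^2 (taken from the detections object
#'   if not given).
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(detections, area_mm2 = NULL) {
  n <- if (inherits(detections, "cell_detections")) nrow(detections)
       else as.numeric(detections)
  area_mm2 <- area_mm2 %||% attr(detections, "area_mm2")
  if (is.null(area_mm2) || area_mm2 <= 0) {
    stop("analysis area must be positive", call. = FALSE)
  }
  n / area_mm2
}

#' Nerve trace container
#'
#' Either explicit polylines (list of n x 2 matrices of pixel coordinates)
#' or a skeleton mask (logical matrix), with the pixel pitch and analysis
#' area needed to express length density in mm/mm^2.
#'
#' @param polylines List of n x 2 coordinate matrices (px), or `NULL`.
#' @param skeleton Logical matrix marking skeleton pixels, or `NULL`.
#' @param pixel_pitch_um Pixel pitch in um.
#' @param area_mm2 Analysis area in mm^2.
#' @return An object of class `nerve_trace`.
#' @export
nerve_trace <- function(polylines = NULL, skeleton = NULL, pixel_pitch_um,
                        area_mm2) {
  stop_if_not_positive(pixel_pitch_um, "pixel_pitch_um")
  stop_if_not_positive(area_mm2, "area_mm2")
  if (is.null(polylines) && is.null(skeleton)) {
    polylines <- list()
  }
  structure(list(polylines = polylines, skeleton = skeleton,
                 pixel_pitch_um = pixel_pitch_um, area_mm2 = area_mm2),
            class = "nerve_trace")
}

polyline_length_px <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# length of an 8-connected skeleton in px. Orthogonal and diagonal
# adjacencies are counted separately (diagonals linked through a shared
# orthogonal neighbor are corner artifacts and are dropped), then combined
# with the Kulpa coefficients (0.948, 1.340), which correct the systematic
# overestimation of digitized curve length by the naive (1, sqrt(2)) weights
skeleton_length_px <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  right <- sk[, -nc, drop = FALSE] & sk[, -1, drop = FALSE]
  down <- sk[-nr, , drop = FALSE] & sk[-1, , drop = FALSE]
  dr <- sk[-nr, -nc, drop = FALSE] & sk[-1, -1, drop = FALSE]
  dl <- sk[-nr, -1, drop = FALSE] & sk[-1, -nc, drop = FALSE]
  n_orth <- sum(right) + sum(down)
  n_diag <- sum(dr & !(down[, -nc, drop = FALSE] | right[-nr, , drop = FALSE])) +
    sum(dl & !(down[, -1, drop = FALSE] | right[-1, , drop = FALSE]))
  0.948 * n_orth + 1.340 * n_diag
}

#' Nerve length density
#'
#' Total traced nerve length divided by the analysis area, in mm/mm^2.
#' Polylines are summed directly; a skeleton mask is measured by counting
#' 8-connected steps (orthogonal steps 1 px, diagonal steps sqrt(2) px).
#'
#' @param trace A [nerve_trace()].
#' @return Length density in mm/mm^2.
#' @export
nerve_length_density <- function(trace) {
  stopifnot(inherits(trace, "nerve_trace"))
  len_px <- 0
  if (!is.null(trace$polylines) && length(trace$polylines)) {
    len_px <- sum(vapply(trace$polylines, polyline_length_px, numeric(1)))
  } else if (!is.null(trace$skeleton)) {
    len_px <- skeleton_length_px(trace$skeleton)
  }
  (len_px * trace$pixel_pitch_um / 1000) / trace$area_mm2
}

#' Mean cell diameter
#'
#' @param diameters_um Non-empty vector of measured diameters in um.
#' @return Arithmetic mean in um.
#' @export
mean_cell_diameter <- function(diameters_um) {
  if (length(diameters_um) < 1L) stop("no diameters supplied", call. = FALSE)
  mean(diameters_um)
}

#' Measure cell diameters at detected centers
#'
#' For each detection, measures the width of the cell body at 70% of its
#' peak amplitude along the two image axes (walking outward with subpixel
#' interpolation) and extrapolates to the full width at half maximum
#' assuming a Gaussian-like body profile. Measuring high on the profile
#' keeps the estimate clear of overlap with neighboring cells; paths whose
#' intensity rises again before the crossing (contamination by a neighbor)
#' are discarded. The automated analogue of measuring diameters with a
#' ruler tool.
#'
#' @param image Band-passed numeric matrix (background near 0).
#' @param detections A [detect_cells()] result.
#' @param max_radius_um Search radius for the level crossing.
#' @param level Fraction of the peak at which the width is measured.
#' @return Vector of FWHM diameters in um (NaN where no clean crossing was
#'   found on any axis).
#' @export
measure_cell_diameters <- function(image, detections, max_radius_um = NULL,
                                   level = 0.7) {
  stopifnot(inherits(detections, "cell_detections"))
  pitch <- attr(detections, "pixel_pitch_um")
  sgn <- if (attr(detections, "sign") == "bright") 1 else -1
  img <- sgn * image
  rmax <- round((max_radius_um %||% (50 * pitch)) / pitch)
  # FWHM / (full width at `level`) for a Gaussian profile
  scale_fac <- 1.1774 / sqrt(2 * log(1 / level))
  half_width <- function(r0, c0, dr, dc) {
    peak <- img[r0, c0]
    prev <- peak
    for (k in seq_len(rmax)) {
      r <- r0 + k * dr; c <- c0 + k * dc
      if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) return(NA_real_)
      v <- img[r, c]
      if (v <= level * peak) {
        return((k - 1) + (prev - level * peak) / (prev - v))
      }
      if (v > prev && k > 1) return(NA_real_)  # rising again: neighbor overlap
      prev <- v
    }
    NA_real_
  }
  vapply(seq_len(nrow(detections)), function(i) {
    r0 <- detections$row[i]; c0 <- detections$col[i]
    w <- c(half_width(r0, c0, 1, 0) + half_width(r0, c0, -1, 0),
           half_width(r0, c0, 0, 1) + half_width(r0, c0, 0, -1))
    mean(w, na.rm = TRUE) * pitch * scale_fac
  }, numeric(1))
}

#' Signal-to-noise ratio in dB
#'
#' `20 * log10(mean(signal) / sd(noise))` between disjoint signal and noise
#' regions (the amplitude convention; `convention = "power"` uses
#' `10 * log10`).
#'
#' @param image Numeric matrix.
#' @param signal_roi,noise_roi Logical masks (or index vectors) selecting
#'   disjoint regions of `image`.
#' @param convention `"amplitude"` (20 log10, default) or `"power"`
#'   (10 log10).
#' @return SNR in dB.
#' @export
snr_db <- function(image, signal_roi, noise_roi,
                   convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (is.logical(signal_roi) && is.logical(noise_roi) &&
      any(signal_roi & noise_roi)) {
    stop("signal and noise ROIs must be disjoint", call. = FALSE)
  }
  s <- mean(image[signal_roi])
  n <- sd(image[noise_roi])
  if (!is.finite(n) || n <= 0) stop("noise ROI has zero variance",
                                    call. = FALSE)
  fac <- if (convention == "amplitude") 20 else 10
  fac * log10(s / n)
}

# --- skeletonization (Zhang-Suen thinning) --------------------------------

shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

zs_subiteration <- function(b, step) {
  # neighbors clockwise from north: p2 .. p9
  p2 <- shift_pad(b, 1, 0);  p3 <- shift_pad(b, 1, -1)
  p4 <- shift_pad(b, 0, -1); p5 <- shift_pad(b, -1, -1)
  p6 <- shift_pad(b, -1, 0); p7 <- shift_pad(b, -1, 1)
  p8 <- shift_pad(b, 0, 1);  p9 <- shift_pad(b, 1, 1)
  bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nrow(b), ncol(b))
  for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
  if (step == 1L) {
    c1 <- !(p2 & p4 & p6); c2 <- !(p4 & p6 & p8)
  } else {
    c1 <- !(p2 & p4 & p8); c2 <- !(p2 & p6 & p8)
  }
  del <- b & bsum >= 2 & bsum <= 6 & a == 1L & c1 & c2
  b & !del
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen morphological thinning, reducing connected foreground strokes
#' to 8-connected single-pixel-wide skeletons.
#'
#' @param mask Logical matrix.
#' @param max_iter Iteration cap.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask, max_iter = 100L) {
  b <- mask
  for (it in seq_len(max_iter)) {
    b1 <- zs_subiteration(b, 1L)
    b2 <- zs_subiteration(b1, 2L)
    if (identical(b2, b)) break
    b <- b2
  }
  b
}

neighbor_count <- function(mask) {
  shift_pad(mask, 1, 0) + shift_pad(mask, -1, 0) +
    shift_pad(mask, 0, 1) + shift_pad(mask, 0, -1) +
    shift_pad(mask, 1, 1) + shift_pad(mask, 1, -1) +
    shift_pad(mask, -1, 1) + shift_pad(mask, -1, -1)
}

#' Trace nerves in a processed image
#'
#' Lightly smooths the magnitude of a band-passed image, thresholds it at a
#' fraction of its robust peak amplitude, despeckles the mask (pixels with
#' fewer than two 8-neighbors are isolated noise, not strokes), thins it to
#' a skeleton and prunes short noise spurs. The length density of the
#' resulting trace is measured with [nerve_length_density()].
#'
#' @param image Band-passed numeric matrix.
#' @param pixel_pitch_um Pixel pitch in um.
#' @param threshold Fraction of the robust (99.5th percentile) magnitude.
#' @param smooth_sigma Pre-threshold Gaussian sigma in px (0 = none);
#'   suppresses boundary roughness that would otherwise wiggle the skeleton.
#' @param prune Number of spur-pruning passes (each removes skeleton
#'   endpoints with fewer than two neighbors).
#' @return A [nerve_trace()] with the skeleton mask; the analysis area is
#'   the full image area.
#' @export
trace_nerves <- function(image, pixel_pitch_um, threshold = 0.5,
                         smooth_sigma = 1.5, prune = 3) {
  a <- abs(image)
  if (smooth_sigma > 0) a <- gaussian_smooth(a, smooth_sigma)
  thr <- threshold * quantile(a, 0.995, names = FALSE)
  mask <- a > thr
  mask <- mask & neighbor_count(mask) >= 2   # despeckle
  sk <- skeletonize(mask)
  for (i in seq_len(prune)) sk <- sk & neighbor_count(sk) >= 2
  area <- nrow(image) * ncol(image) * (pixel_pitch_um / 1000)^2
  nerve_trace(skeleton = sk, pixel_pitch_um = pixel_pitch_um,
              area_mm2 = area)
}
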