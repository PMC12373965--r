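# Raw-frame processing chain: Bayer-mismatch smoothing (color camera),
# fixed-pattern-noise removal (mono camera), large-kernel high-pass to
# suppress the bright uniform background, frame averaging, pulse-frame
# selection from a rolling buffer, and two-phase tomographic subtraction.

#' Image stack container
#'
#' @param frames A list of numeric matrices of identical dimensions, or a
#'   3D array (row, col, frame).
#' @param pixel_pitch_um Pixel pitch at the sample, in um.
#' @param camera Camera tag: `"mono_global"` (global-shutter mono sensor,
#'   fixed-pattern noise) or `"color_rolling"` (rolling-shutter color
#'   sensor, Bayer mismatch).
#' @param meta Optional named list of acquisition metadata.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_pitch_um = 1,
                        camera = c("mono_global", "color_rolling"),
                        meta = list()) {
  camera <- match.arg(camera)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  stop_if_not_positive(pixel_pitch_um, "pixel_pitch_um")
  structure(list(frames = frames, pixel_pitch_um = pixel_pitch_um,
                 camera = camera, meta = meta),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px, %.2f um/px, %s camera\n",
              length(x$frames), d[1], d[2], x$pixel_pitch_um, x$camera))
  invisible(x)
}

#' Bayer-mismatch smoothing
#'
#' Minimal 3x3 Gaussian blur (sigma 0.8 px) that uniformizes the
#' illumination mismatch between the segments of the Bayer filter of the
#' color camera. Mono frames are returned unchanged with a warning.
#'
#' @param frame Numeric matrix.
#' @param camera Camera tag; smoothing applies only to `"color_rolling"`.
#' @param sigma Gaussian sigma in px.
#' @return The smoothed frame.
#' @export
bayer_smooth <- function(frame, camera = "color_rolling", sigma = 0.8) {
  if (!identical(camera, "color_rolling")) {
    warning("bayer_smooth is a no-op for mono frames")
    return(frame)
  }
  gaussian_smooth(frame, sigma = sigma, r = 1L)
}

#' Fixed-pattern-noise removal
#'
#' Subtracts the per-pixel temporal mean from every frame of a stack of
#' moving images. The static sensor pattern averages into the temporal mean
#' and is removed; moving content is preserved up to a DC shift.
#'
#' @param stack An [image_stack()] with at least 2 frames (10 or more moving
#'   frames recommended for good attenuation).
#' @return The stack with the temporal mean subtracted from every frame.
#' @export
remove_fixed_pattern <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L) {
    stop("fixed-pattern removal needs a stack of several moving frames",
         call. = FALSE)
  }
  avg <- Reduce(`+`, stack$frames) / length(stack$frames)
  stack$frames <- lapply(stack$frames, function(f) f - avg)
  stack
}

#' Large-kernel high-pass filter
#'
#' Subtracts the local mean computed over a large kernel (121 x 121 px by
#' default), suppressing the bright uniform illumination background while
#' preserving cellular-scale structure. The local mean is a boxcar by
#' default; a Gaussian variant (sigma = kernel/6) is available.
#'
#' @param frame Numeric matrix.
#' @param kernel_size Odd kernel size in px (>= 3).
#' @param method `"box"` (default) or `"gaussian"`.
#' @return The high-passed frame (mean approximately 0 in the interior).
#' @export
highpass <- function(frame, kernel_size = 121, method = c("box", "gaussian")) {
  method <- match.arg(method)
  if (kernel_size %% 2 != 1 || kernel_size < 3) {
    stop("`kernel_size` must be odd and >= 3", call. = FALSE)
  }
  lowpass <- switch(method,
    box = box_mean(frame, kernel_size),
    gaussian = gaussian_smooth(frame, sigma = kernel_size / 6,
                               r = (kernel_size - 1L) / 2L)
  )
  frame - lowpass
}

#' Average the first n frames of a stack
#'
#' Pixel-wise mean of the first `n` (registered) frames; additive white
#' noise is reduced by about `sqrt(n)`.
#'
#' @param stack An [image_stack()].
#' @param n Number of frames to average (defaults to all).
#' @return A single averaged frame (matrix).
#' @export
average_frames <- function(stack, n = length(stack$frames)) {
  stopifnot(inherits(stack, "image_stack"))
  if (n < 1 || n > length(stack$frames)) {
    stop("`n` must be between 1 and the stack length", call. = FALSE)
  }
  Reduce(`+`, stack$frames[seq_len(n)]) / n
}

#' Select the pulse-synchronized frame from a rolling buffer
#'
#' Returns the frame with the highest mean intensity, i.e. the frame whose
#' exposure coincided with the LED pulse. Ties are broken by the earliest
#' acquisition index.
#'
#' @param buffer An [image_stack()] (the rolling buffer).
#' @return The selected frame (matrix) with attribute `index`.
#' @export
select_pulse_frame <- function(buffer) {
  stopifnot(inherits(buffer, "image_stack"))
  if (length(buffer$frames) < 1L) stop("empty buffer", call. = FALSE)
  means <- vapply(buffer$frames, mean, numeric(1))
  i <- which.max(means)   # which.max returns the earliest maximum
  structure(buffer$frames[[i]], index = i)
}

#' Two-phase tomographic subtraction
#'
#' Difference of two co-registered frames captured at opposite defocus
#' phases (two cameras at different defocus levels). In-focus interference
#' structures flip sign between the two planes and are reinforced by the
#' subtraction, while the defocus-symmetric background cancels. The second
#' frame is gain-matched to the first by the median ratio before
#' subtraction.
#'
#' @param frame_a,frame_b Co-registered numeric matrices of equal shape.
#' @param gain_match Match the gain of `frame_b` to `frame_a` by the median
#'   ratio of the two frames.
#' @return The difference image `frame_a - frame_b`.
#' @export
two_phase_subtract <- function(frame_a, frame_b, gain_match = TRUE) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  if (gain_match) {
    ok <- abs(frame_b) > .Machine$double.eps
    if (any(ok)) {
      g <- median(frame_a[ok] / frame_b[ok])
      if (is.finite(g) && g > 0) frame_b <- frame_b * g
    }
  }
  frame_a - frame_b
}

#' Camera-specific processing chain
#'
#' Applies the published per-camera processing order: Bayer smoothing (color
#' camera only), fixed-pattern removal (mono camera only, from the temporal
#' mean of the stack), the large-kernel high-pass, and optional frame
#' averaging.
#'
#' @param stack An [image_stack()] carrying the camera tag.
#' @param highpass_kernel High-pass kernel size in px.
#' @param average Number of frames to average after filtering (0 = return
#'   the full filtered stack).
#' @return If `average > 0` a single processed frame, otherwise the
#'   processed [image_stack()].
#' @export
process_stack <- function(stack, highpass_kernel = 121, average = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$camera == "color_rolling") {
    stack$frames <- lapply(stack$frames, bayer_smooth,
                           camera = "color_rolling")
  }
  if (stack$camera == "mono_global" && length(stack$frames) >= 2L) {
    stack <- remove_fixed_pattern(stack)
  }
  stack$frames <- lapply(stack$frames, highpass,
                         kernel_size = highpass_kernel)
  if (average > 0) {
    average_frames(stack, min(average, length(stack$frames)))
  } else {
    stack
  }
}
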