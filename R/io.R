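# Image-stack readers and writers: single/multi-page TIFF and numbered PNG,
# with a YAML sidecar carrying pixel pitch, camera tag and value scaling.

sidecar_path <- function(path) paste0(path, ".yml")

#' Write an image stack
#'
#' Writes a multi-page TIFF (or numbered PNG files) plus a YAML sidecar with
#' the pixel pitch, camera tag and value scaling. Integer-valued data up to
#' 16 bits round-trips losslessly; floating-point data is stored as scaled
#' 32-bit samples with the affine scale recorded in the sidecar.
#'
#' @param stack An [image_stack()].
#' @param path Output file (`.tif`/`.tiff`) or directory (numbered PNG).
#' @param format `"tiff"` or `"png"`; guessed from `path` by default.
#' @param seed Optional seed to record in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = NULL, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  format <- format %||% if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    "tiff" else "png"
  vals <- unlist(lapply(stack$frames, range))
  lo <- min(vals); hi <- max(vals)
  integerish <- all(vapply(stack$frames, function(f) {
    all(f >= 0) && all(f == round(f)) && max(f) <= 65535
  }, logical(1)))
  if (integerish && format == "png" && hi <= 255) {
    # PNG frames are 8-bit; byte data round-trips losslessly
    scale <- list(kind = "integer8", lo = 0, hi = 255)
    norm <- lapply(stack$frames, function(f) f / 255)
    bits <- 8L
  } else if (integerish) {
    scale <- list(kind = "integer16", lo = 0, hi = 65535)
    norm <- lapply(stack$frames, function(f) f / 65535)
    bits <- 16L
  } else {
    span <- if (hi > lo) hi - lo else 1
    scale <- list(kind = "float", lo = lo, hi = lo + span)
    norm <- lapply(stack$frames, function(f) (f - lo) / span)
    bits <- 32L
  }
  meta <- list(pixel_pitch_um = stack$pixel_pitch_um, camera = stack$camera,
               n_frames = length(stack$frames), scale = scale,
               meta = stack$meta)
  if (!is.null(seed)) meta$seed <- seed
  if (format == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = bits)
    yaml::write_yaml(meta, sidecar_path(path))
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(norm)) {
      png::writePNG(norm[[k]], file.path(path, sprintf("frame_%04d.png", k)))
    }
    yaml::write_yaml(meta, file.path(path, "stack.yml"))
  }
  invisible(path)
}

#' Read an image stack
#'
#' Reads a multi-page TIFF (or a directory of numbered PNG frames) written
#' by [write_stack()], restoring the original values and metadata from the
#' YAML sidecar when present.
#'
#' @param path TIFF file or PNG directory.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path, call. = FALSE)
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
    side <- file.path(path, "stack.yml")
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
    side <- sidecar_path(path)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed frame sizes in ", path, call. = FALSE)
  }
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  sc <- meta$scale
  frames <- lapply(frames, function(f) {
    if (!is.null(sc) && sc$kind == "integer16") {
      round(f * 65535)
    } else if (!is.null(sc) && sc$kind == "integer8") {
      round(f * 255)
    } else if (!is.null(sc) && sc$kind == "float") {
      f * (sc$hi - sc$lo) + sc$lo
    } else f
  })
  image_stack(frames,
              pixel_pitch_um = meta$pixel_pitch_um %||% 1,
              camera = meta$camera %||% "mono_global",
              meta = meta$meta %||% list())
}
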