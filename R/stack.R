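#' Time-lapse fluorescence stack
#'
#' Container for a calcium-indicator recording: an `H x W x T` intensity array
#' on the 8-bit scale together with its temporal and spatial calibration.
#' All downstream detection and trace analysis operates on this object.
#'
#' @param data numeric `H x W x T` array of pixel intensities (8-bit scale,
#'   0-255; values are stored as floating point and only clamped when written
#'   to disk).
#' @param frame_interval time between frames in seconds.
#' @param calibration spatial calibration in micrometres per pixel.
#' @param bit_depth nominal bit depth of the source data, 8 or 16. 16-bit
#'   input is min-max rescaled to the 8-bit range on read, because the
#'   activity threshold band (160-200) is defined on that scale.
#'
#' @return An object of class `time_lapse_stack` with elements `data`,
#'   `frame_interval`, `calibration`, `bit_depth`.
#' @export
time_lapse_stack <- function(data, frame_interval = 0.5, calibration = 1,
                             bit_depth = 8L) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "data must be an H x W x T array")
  assert_that(dim(data)[3] >= 2L, "a time-lapse stack needs at least 2 frames")
  assert_that(is.numeric(frame_interval) && frame_interval > 0,
              "frame_interval must be positive (seconds)")
  assert_that(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  structure(list(data = data, frame_interval = frame_interval,
                 calibration = calibration, bit_depth = as.integer(bit_depth)),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "time_lapse_stack: %d x %d px, %d frames @ %.3g s (%.3g um/px, %d-bit)\n",
    d[1], d[2], d[3], x$frame_interval, x$calibration, x$bit_depth))
  invisible(x)
}

#' @export
dim.time_lapse_stack <- function(x) dim(x$data)

#' Read a multi-page TIFF as a time-lapse stack
#'
#' Frames are read as raw integer intensities. Data with values above 255 is
#' treated as 16-bit and min-max rescaled to the 0-255 range, the scale on
#' which the activity threshold is defined.
#'
#' @param path path to a multi-page TIFF file.
#' @inheritParams time_lapse_stack
#' @return A [time_lapse_stack].
#' @export
read_stack_tiff <- function(path, frame_interval = 0.5, calibration = 1) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]  # first channel of RGB input
    arr[, , t] <- f
  }
  bit_depth <- 8L
  if (max(arr) > 255) {
    bit_depth <- 16L
    rng <- range(arr)
    arr <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) * 255 else arr * 0
  }
  time_lapse_stack(arr, frame_interval = frame_interval,
                   calibration = calibration, bit_depth = bit_depth)
}

#' Write a time-lapse stack as an 8-bit multi-page TIFF
#'
#' Intensities are clamped to 0-255 and quantized to 8 bits.
#'
#' @param stack a [time_lapse_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  t <- dim(stack$data)[3]
  frames <- lapply(seq_len(t), function(i) {
    pmin(pmax(stack$data[, , i], 0), 255) / 255
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a single-frame image as an 8-bit TIFF
#'
#' @param image numeric matrix on the 8-bit scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 255) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a single-frame TIFF image
#'
#' @param path path to a TIFF file; the first page is read.
#' @return numeric matrix on the 8-bit scale.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (max(img) > 255) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) * 255 else img * 0
  }
  img
}
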