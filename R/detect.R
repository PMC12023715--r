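# Semiautomatic detection of active-cell ROIs from a time-lapse stack:
# max-min range projection -> lowpass -> intensity threshold -> circular
# median smoothing -> 8-connected components -> particle size gate.

#' Detection configuration
#'
#' Parameters of the active-cell detection chain. The activity threshold is
#' defined on the 8-bit intensity scale with a valid band of 160-200; the
#' default 180 is the midpoint of that band. The size gate of 50-200 square
#' pixels rejects particles that are not cells.
#'
#' @param activity_threshold intensity threshold applied to the lowpassed
#'   range projection (default 180).
#' @param median_radius radius in pixels of the circular median filter
#'   applied to the thresholded binary image (default 5, the ImageJ
#'   convention of a circular structuring element).
#' @param min_area,max_area particle size gate in px^2 (defaults 50 and 200).
#' @param lowpass lowpass filter specification: `list(type = "mean", size = 3)`
#'   (the ImageJ Smooth 3x3 mean, default) or `list(type = "gaussian",
#'   sigma = <px>)`.
#' @return A `detection_config` object.
#' @export
detection_config <- function(activity_threshold = 180, median_radius = 5,
                             min_area = 50, max_area = 200,
                             lowpass = list(type = "mean", size = 3)) {
  assert_that(min_area < max_area, "min_area must be below max_area")
  assert_that(activity_threshold > 0 && activity_threshold < 256,
              "activity_threshold must lie within the 8-bit range")
  structure(list(activity_threshold = activity_threshold,
                 median_radius = median_radius,
                 min_area = min_area, max_area = max_area, lowpass = lowpass),
            class = "detection_config")
}

#' Construct a region of interest
#'
#' @param label character identifier.
#' @param pixels integer matrix of 1-based `(row, col)` pixel coordinates.
#' @param kind `"active_cell"` or `"background"`.
#' @return A `roi` object; `area` is the raw pixel count (square pixels,
#'   no spatial calibration).
#' @export
roi <- function(label, pixels, kind = c("active_cell", "background")) {
  kind <- match.arg(kind)
  assert_that(is.matrix(pixels) && ncol(pixels) == 2L && nrow(pixels) > 0L,
              "pixels must be a nonempty (row, col) matrix")
  structure(list(label = label, pixels = pixels, area = nrow(pixels),
                 kind = kind),
            class = "roi")
}

#' Construct a set of ROIs
#'
#' @param rois list of [roi] objects; at most one of kind `"background"`.
#' @param shape `(H, W)` of the source image.
#' @return A `roi_set` object.
#' @export
roi_set <- function(rois, shape) {
  kinds <- vapply(rois, function(r) r$kind, character(1))
  assert_that(sum(kinds == "background") <= 1L,
              "a roi_set can hold at most one background ROI")
  structure(list(rois = rois, shape = as.integer(shape)), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  kinds <- vapply(x$rois, function(r) r$kind, character(1))
  cat(sprintf("roi_set: %d active cell ROI(s), %d background ROI(s) in %d x %d px\n",
              sum(kinds == "active_cell"), sum(kinds == "background"),
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' Max-min range projection of a time-lapse stack
#'
#' For every pixel, the maximum intensity across the time lapse minus the
#' minimum: active cells light up, static structures cancel out. The result
#' is invariant to adding a constant to all frames.
#'
#' @param stack a [time_lapse_stack].
#' @return numeric `H x W` matrix, nonnegative.
#' @export
range_projection <- function(stack) {
  assert_that(inherits(stack, "time_lapse_stack"), "stack required")
  d <- dim(stack$data)
  assert_that(d[3] >= 2L, "range projection needs at least 2 frames")
  mx <- stack$data[, , 1L]; mn <- mx
  for (t in 2:d[3]) {
    f <- stack$data[, , t]
    mx <- pmax(mx, f); mn <- pmin(mn, f)
  }
  mx - mn
}

#' Lowpass filter an image
#'
#' Default is a 3x3 uniform mean (the ImageJ Smooth filter); a Gaussian of
#' configurable sigma is available. Both are DC-preserving: a constant image
#' passes through unchanged.
#'
#' @param image numeric matrix.
#' @param config a [detection_config] (its `lowpass` element is used).
#' @return filtered matrix of the same size.
#' @export
lowpass <- function(image, config = detection_config()) {
  lp <- config$lowpass
  if (identical(lp$type, "mean")) {
    sz <- if (is.null(lp$size)) 3L else as.integer(lp$size)
    kernel <- matrix(1 / sz^2, sz, sz)
  } else if (identical(lp$type, "gaussian")) {
    sigma <- lp$sigma
    assert_that(is.numeric(sigma) && sigma > 0, "gaussian lowpass needs sigma > 0")
    r <- ceiling(3 * sigma)
    g <- exp(-(-r:r)^2 / (2 * sigma^2))
    kernel <- outer(g, g); kernel <- kernel / sum(kernel)
  } else stop("unknown lowpass type: ", lp$type, call. = FALSE)
  convolve2(image, kernel, boundary = "replicate")
}

# Majority (median) filter of a binary image with a circular element of the
# given pixel radius; exact for binary input via counting convolution.
#' @keywords internal
#' @noRd
median_smooth <- function(mask, radius = 5) {
  if (radius <= 0) return(mask)
  k <- circular_kernel(radius)
  cnt <- convolve2(mask * 1, k / sum(k), boundary = 0)
  cnt > 0.5
}

#' Detect active-cell ROIs in a time-lapse stack
#'
#' Runs the full semiautomatic chain: range projection, lowpass, binarization
#' at the activity threshold, circular median smoothing, 8-connected
#' component labelling, and the particle size gate. Returns only active-cell
#' ROIs; a background ROI is added separately with [add_background_roi()].
#'
#' @param stack a [time_lapse_stack].
#' @param config a [detection_config].
#' @return A [roi_set] of active-cell ROIs (possibly empty, with a warning).
#' @export
detect_active_rois <- function(stack, config = detection_config()) {
  proj <- range_projection(stack)
  smoothed <- lowpass(proj, config)
  binary <- smoothed > config$activity_threshold
  binary <- median_smooth(binary, config$median_radius)
  labels <- label_components(binary)
  n <- max(labels)
  rois <- list()
  for (id in seq_len(n)) {
    idx <- which(labels == id)
    if (length(idx) < config$min_area || length(idx) > config$max_area) next
    pix <- cbind(row = (idx - 1L) %% nrow(labels) + 1L,
                 col = (idx - 1L) %/% nrow(labels) + 1L)
    rois[[length(rois) + 1L]] <-
      roi(sprintf("cell_%02d", length(rois) + 1L), pix, kind = "active_cell")
  }
  if (length(rois) == 0L)
    warning("no active ROIs detected within the size gate")
  roi_set(rois, dim(stack$data)[1:2])
}

#' Add a background ROI to a set of active-cell ROIs
#'
#' The background ROI samples a location without biological fluorescence to
#' define the background intensity of the recording. When no location is
#' given, the square window minimizing (temporal variance + temporal mean),
#' among windows disjoint from all active ROIs, is chosen automatically.
#'
#' @param stack a [time_lapse_stack].
#' @param rois a [roi_set] of active-cell ROIs.
#' @param location optional `(row, col)` of the window's top-left corner; it
#'   must not intersect any active ROI.
#' @param size background window area in px^2 (rendered as a square).
#' @return A [roi_set] with one background ROI (label `"background"`) appended.
#' @export
add_background_roi <- function(stack, rois, location = NULL, size = 64) {
  h <- dim(stack$data)[1]; w <- dim(stack$data)[2]
  side <- max(2L, ceiling(sqrt(size)))
  occupied <- matrix(FALSE, h, w)
  for (r in rois$rois)
    occupied[r$pixels[, 1L] + (r$pixels[, 2L] - 1L) * h] <- TRUE
  window_pixels <- function(loc) {
    rows <- loc[1]:(loc[1] + side - 1L)
    cols <- loc[2]:(loc[2] + side - 1L)
    as.matrix(expand.grid(row = rows, col = cols))
  }
  if (!is.null(location)) {
    location <- as.integer(location)
    assert_that(location[1] >= 1 && location[2] >= 1 &&
                location[1] + side - 1L <= h && location[2] + side - 1L <= w,
                "background window falls outside the image")
    pix <- window_pixels(location)
    assert_that(!any(occupied[pix[, 1L] + (pix[, 2L] - 1L) * h]),
                "background location intersects an active ROI")
  } else {
    # per-pixel temporal mean and variance, then window scores on a grid
    tt <- dim(stack$data)[3]
    s1 <- rowSums(stack$data, dims = 2)
    s2 <- rowSums(stack$data^2, dims = 2)
    mu <- s1 / tt
    va <- pmax(0, s2 / tt - mu^2)
    score_px <- mu + va
    best <- NULL; best_score <- Inf
    for (i in seq(1L, h - side + 1L, by = side)) {
      for (j in seq(1L, w - side + 1L, by = side)) {
        occ <- occupied[i:(i + side - 1L), j:(j + side - 1L)]
        if (any(occ)) next
        sc <- mean(score_px[i:(i + side - 1L), j:(j + side - 1L)])
        if (sc < best_score) { best_score <- sc; best <- c(i, j) }
      }
    }
    assert_that(!is.null(best),
                "no admissible background location outside the active ROIs")
    pix <- window_pixels(best)
  }
  roi_set(c(rois$rois, list(roi("background", pix, kind = "background"))),
          rois$shape)
}

#' Extract mean-intensity traces for every ROI
#'
#' For each ROI and each frame, the mean intensity over the ROI's pixels.
#'
#' @param stack a [time_lapse_stack].
#' @param rois a [roi_set].
#' @return A `raw_traces` object: `values` is a `T x n_roi` matrix (one
#'   column per ROI, labelled), plus `frame_interval`, per-ROI `areas`,
#'   `kinds` and `background_label` (`NA` if absent).
#' @export
extract_traces <- function(stack, rois) {
  d <- dim(stack$data); h <- d[1]; w <- d[2]; tt <- d[3]
  assert_that(length(rois$rois) > 0L, "no ROIs to extract traces from")
  values <- matrix(0, tt, length(rois$rois))
  labels <- character(length(rois$rois))
  for (k in seq_along(rois$rois)) {
    r <- rois$rois[[k]]
    assert_that(all(r$pixels[, 1L] >= 1 & r$pixels[, 1L] <= h &
                    r$pixels[, 2L] >= 1 & r$pixels[, 2L] <= w),
                "ROI pixels outside stack bounds")
    idx <- pixel_frame_index(r$pixels, h, w, tt)
    values[, k] <- colMeans(matrix(stack$data[idx], nrow(r$pixels), tt))
    labels[k] <- r$label
  }
  colnames(values) <- labels
  kinds <- vapply(rois$rois, function(r) r$kind, character(1))
  bg <- labels[kinds == "background"]
  structure(list(values = values,
                 frame_interval = stack$frame_interval,
                 areas = vapply(rois$rois, function(r) r$area, numeric(1)),
                 kinds = kinds,
                 background_label = if (length(bg)) bg[1] else NA_character_),
            class = "raw_traces")
}

#' Write a ROI set as a JSON sidecar
#'
#' Stores label, kind, area, optional cell-class annotation, and the pixel
#' coordinates of every ROI.
#'
#' @param rois a [roi_set].
#' @param path output JSON path.
#' @param classes optional named character vector of cell classes per label.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path, classes = NULL) {
  out <- list(shape = rois$shape,
              rois = lapply(rois$rois, function(r) {
                x <- list(label = r$label, kind = r$kind, area = r$area,
                          rows = r$pixels[, 1L], cols = r$pixels[, 2L])
                if (!is.null(classes) && r$label %in% names(classes))
                  x$cell_class <- unname(classes[r$label])
                x
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write traces as CSV
#'
#' One row per frame; first column is time in seconds, then one column per
#' ROI with the ROI label as header.
#'
#' @param traces a `raw_traces` object from [extract_traces()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  tt <- nrow(traces$values)
  df <- data.frame(time_s = (seq_len(tt) - 1L) * traces$frame_interval)
  df <- cbind(df, as.data.frame(traces$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
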