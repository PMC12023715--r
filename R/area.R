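# Active neuronal area: percentage of the total stained cell area occupied
# by detected active ROIs.

#' Total stained cell area of an image
#'
#' Binarizes the image, labels 8-connected components, and sums the areas of
#' components of at least `min_size` square pixels (smaller blobs are
#' debris and are discarded).
#'
#' @param image numeric matrix (for a time-lapse region, typically its
#'   temporal mean).
#' @param threshold numeric intensity threshold, or `"otsu"` for Otsu's
#'   method (default). The manual-threshold step of interactive analysis is
#'   replaced by this configurable method for unattended use.
#' @param min_size minimum component area in px^2 (default 50).
#' @return total stained area in px^2 (0 with a warning if nothing is
#'   stained).
#' @export
total_stained_area <- function(image, threshold = "otsu", min_size = 50) {
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (rng[2] <= rng[1]) {
      warning("image is constant; total stained area is 0")
      return(0)
    }
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    threshold <- EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1]) + rng[1]
  }
  mask <- image > threshold
  if (!any(mask)) {
    warning("no stained pixels above threshold; total stained area is 0")
    return(0)
  }
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  sum(sizes[sizes >= min_size])
}

#' Percentage of active neuronal area
#'
#' `percent = 100 * A_active / A_total`, where `A_active` is the summed
#' pixel count of the detected active ROIs and `A_total` the total stained
#' cell area of the region.
#'
#' @param active_rois a [roi_set] of active-cell ROIs (background ROIs are
#'   ignored), or a single numeric `A_active` in px^2.
#' @param a_total total stained area in px^2 (> 0), from
#'   [total_stained_area()].
#' @return An `activity_area_result`: `a_active`, `a_total`, `percent`.
#' @export
active_area_percent <- function(active_rois, a_total) {
  assert_that(is.numeric(a_total) && a_total > 0,
              "a_total must be positive; percentage undefined otherwise")
  a_active <- if (inherits(active_rois, "roi_set")) {
    sum(vapply(active_rois$rois,
               function(r) if (r$kind == "active_cell") r$area else 0,
               numeric(1)))
  } else as.numeric(active_rois)
  assert_that(a_active >= 0, "a_active must be nonnegative")
  assert_that(a_active <= a_total,
              "a_active exceeds a_total: inconsistent inputs")
  structure(list(a_active = a_active, a_total = a_total,
                 percent = 100 * a_active / a_total),
            class = "activity_area_result")
}

#' @export
print.activity_area_result <- function(x, ...) {
  cat(sprintf("active area: %.0f / %.0f px^2 = %.1f%%\n",
              x$a_active, x$a_total, x$percent))
  invisible(x)
}
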