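# Spheroid invasion-rate and 2D coverage morphometrics.

#' Measure a spheroid's diameter and radius from a fluorescence image
#'
#' In `auto` mode the largest bright component is segmented (Otsu threshold)
#' and its diameter measured along three rays through the centroid at 0, 60
#' and 120 degrees, standardizing the manual practice of measuring each
#' spheroid from three different points; the three values are averaged. In
#' `manual` mode the three supplied diameters (micrometres) are averaged.
#' The radius is half the mean diameter.
#'
#' @param image numeric matrix (GFP fluorescence image), `auto` mode.
#' @param calibration micrometres per pixel.
#' @param mode `"auto"` or `"manual"`.
#' @param manual_diameters numeric length-3 vector of diameters in
#'   micrometres (manual mode).
#' @param day culture day annotation carried into the result.
#' @return A `spheroid_timepoint`: `day`, `diameters` (um), `mean_diameter`,
#'   `radius` (um).
#' @export
measure_spheroid <- function(image = NULL, calibration = 1,
                             mode = c("auto", "manual"),
                             manual_diameters = NULL, day = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    assert_that(length(manual_diameters) == 3 && all(manual_diameters > 0),
                "manual mode needs three positive diameters (um)")
    diameters <- as.numeric(manual_diameters)
  } else {
    assert_that(is.matrix(image), "auto mode needs an image")
    rng <- range(image)
    assert_that(rng[2] > rng[1], "no spheroid found: image is constant")
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(scaled))
    mask <- scaled > thr
    labels <- label_components(mask)
    assert_that(max(labels) > 0L, "no spheroid component found")
    sizes <- tabulate(labels)
    comp <- labels == which.max(sizes)
    idx <- which(comp)
    cy <- mean((idx - 1L) %% nrow(comp) + 1L)
    cx <- mean((idx - 1L) %/% nrow(comp) + 1L)
    diameters <- vapply(c(0, 60, 120) * pi / 180, function(theta) {
      dir <- c(sin(theta), cos(theta))   # (row, col) step
      reach <- function(s) {             # farthest in-mask sample along s*dir
        r <- 0; step <- 0.25
        repeat {
          p <- round(c(cy, cx) + (r + step) * s * dir)
          if (p[1] < 1 || p[1] > nrow(comp) || p[2] < 1 || p[2] > ncol(comp) ||
              !comp[p[1], p[2]]) break
          r <- r + step
        }
        r
      }
      (reach(1) + reach(-1)) * calibration
    }, numeric(1))
  }
  structure(list(day = day, diameters = diameters,
                 mean_diameter = mean(diameters),
                 radius = mean(diameters) / 2),
            class = "spheroid_timepoint")
}

#' Invasion rate between two spheroid timepoints
#'
#' The radius at the earlier time point subtracted from the radius at the
#' later one, divided by the days between them: an average invasion rate in
#' micrometres per day. A shrinking spheroid (drug response) gives a
#' negative rate.
#'
#' @param earlier,later `spheroid_timepoint`s with `later$day > earlier$day`.
#' @return An `invasion_result`: `rate` (um/day), `from_day`, `to_day`.
#' @export
invasion_rate <- function(earlier, later) {
  assert_that(inherits(earlier, "spheroid_timepoint") &&
              inherits(later, "spheroid_timepoint"),
              "spheroid_timepoint inputs required")
  assert_that(is.finite(earlier$day) && is.finite(later$day),
              "timepoints must carry culture days")
  assert_that(later$day > earlier$day,
              "later timepoint must come after the earlier one")
  structure(list(rate = (later$radius - earlier$radius) /
                        (later$day - earlier$day),
                 from_day = earlier$day, to_day = later$day),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("invasion rate: %.1f um/day (day %g -> %g)\n",
              x$rate, x$from_day, x$to_day))
  invisible(x)
}

#' 2D culture coverage from a fluorescence image
#'
#' Converts the image to the 8-bit range, applies a percentile-based
#' contrast stretch (default 0.35% saturated pixels, matching the common
#' auto-contrast convention), thresholds at the mean of all pixel values
#' (the "Mean" auto-threshold) and reports the covered fraction.
#'
#' @param image numeric matrix.
#' @param saturation total fraction of pixels saturated by the contrast
#'   stretch (default 0.0035; 0 disables stretching).
#' @return A `coverage_result`: `covered_area` (px^2), `field_area` (px^2),
#'   `fraction` (percent).
#' @export
coverage_2d <- function(image, saturation = 0.0035) {
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) * 255
         else image * 0
  if (saturation > 0 && rng[2] > rng[1]) {
    q <- stats::quantile(img, c(saturation / 2, 1 - saturation / 2),
                         names = FALSE)
    if (q[2] > q[1])
      img <- pmin(pmax((img - q[1]) / (q[2] - q[1]) * 255, 0), 255)
  }
  covered <- sum(img > mean(img))
  structure(list(covered_area = covered, field_area = length(img),
                 fraction = 100 * covered / length(img)),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage: %d / %d px^2 = %.1f%%\n",
              x$covered_area, x$field_area, x$fraction))
  invisible(x)
}
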