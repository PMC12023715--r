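# Synthetic-data generators: seeded, ground-truth-annotated fixtures that
# emulate every input class the pipeline consumes (calcium movies, GFP
# reference images, spheroid growth series, secretion spot-density tables).

#' Specify a synthetic cell for the calcium movie generator
#'
#' A cell is a soft-edged disc emitting calcium transients. The footprint is
#' the hard-disc support (`footprint_area` px^2); fluorescence additionally
#' decays smoothly outside the footprint over `halo_sigma` pixels (set on the
#' movie spec), emulating the out-of-focus halo of widefield recordings of 3D
#' hydrogel cultures. Neuron kinetics are fast and spike-like; glioblastoma
#' (gb) kinetics broad and slow. Each event follows the double-exponential
#' kernel `(1 - exp(-t/rise_tau)) * exp(-t/decay_tau)`, peak-normalized.
#'
#' @param centroid numeric `(row, col)` centre in pixels.
#' @param footprint_area target footprint in px^2.
#' @param cell_class `"neuron"` or `"gb"`.
#' @param event_times event onset times in seconds (within the recording).
#' @param event_amplitude event amplitude in dF/F0 units relative to the
#'   cell's baseline fluorescence.
#' @param rise_tau,decay_tau kernel time constants in seconds. Defaults depend
#'   on `cell_class`: neuron 0.3/1.5 s, gb 3/15 s, reproducing the fast
#'   spike-like vs. broad slow contrast between the two cell types.
#' @param baseline baseline fluorescence intensity of the cell above
#'   background (8-bit scale).
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(centroid, footprint_area, cell_class = c("neuron", "gb"),
                      event_times = numeric(0), event_amplitude = 5.5,
                      rise_tau = NULL, decay_tau = NULL, baseline = 38) {
  cell_class <- match.arg(cell_class)
  if (is.null(rise_tau)) rise_tau <- if (cell_class == "neuron") 0.3 else 3
  if (is.null(decay_tau)) decay_tau <- if (cell_class == "neuron") 1.5 else 15
  assert_that(footprint_area > 0, "footprint_area must be positive")
  assert_that(rise_tau > 0 && decay_tau > 0, "kernel taus must be positive")
  assert_that(event_amplitude >= 0, "event_amplitude must be nonnegative")
  assert_that(baseline > 0, "baseline must be positive")
  structure(list(centroid = as.numeric(centroid),
                 footprint_area = footprint_area, cell_class = cell_class,
                 event_times = as.numeric(event_times),
                 event_amplitude = event_amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 baseline = baseline),
            class = "cell_spec")
}

#' Specify a synthetic calcium movie
#'
#' Defaults emulate an approximately 2-minute widefield recording at 2 Hz on
#' the 8-bit intensity scale.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames (default 0.5 s = 2 Hz,
#'   a typical widefield calcium-imaging cadence).
#' @param cells list of [cell_spec] objects; footprints must be disjoint and
#'   inside the frame.
#' @param background_level constant background intensity.
#' @param noise_sd additive Gaussian pixel noise standard deviation
#'   (intensity units; 0 = noise-free).
#' @param bleach_slope linear photobleaching drift in intensity per frame
#'   (negative values darken over time).
#' @param halo_sigma Gaussian decay length (px) of cell fluorescence outside
#'   the footprint.
#' @param seed integer seed; identical spec + seed gives bit-identical movies.
#' @return A `movie_spec` object.
#' @export
movie_spec <- function(height = 128, width = 128, n_frames = 240,
                       frame_interval = 0.5, cells = list(),
                       background_level = 6, noise_sd = 0, bleach_slope = 0,
                       halo_sigma = 2, seed = 1L) {
  assert_that(n_frames >= 2, "n_frames must be >= 2")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(frame_interval > 0, "frame_interval must be positive")
  for (cl in cells) {
    assert_that(inherits(cl, "cell_spec"), "cells must be cell_spec objects")
    r <- sqrt(cl$footprint_area / pi)
    assert_that(cl$centroid[1] - r >= 1 && cl$centroid[1] + r <= height &&
                cl$centroid[2] - r >= 1 && cl$centroid[2] + r <= width,
                "cell footprint outside image bounds")
    dur <- (n_frames - 1) * frame_interval
    assert_that(all(cl$event_times >= 0 & cl$event_times <= dur),
                "event_times must lie within the recording")
  }
  structure(list(height = height, width = width, n_frames = n_frames,
                 frame_interval = frame_interval, cells = cells,
                 background_level = background_level, noise_sd = noise_sd,
                 bleach_slope = bleach_slope, halo_sigma = halo_sigma,
                 seed = seed),
            class = "movie_spec")
}

# Peak-normalized double-exponential transient kernel evaluated at times t (s).
#' @keywords internal
#' @noRd
event_kernel <- function(t, rise_tau, decay_tau) {
  k <- ifelse(t < 0, 0, (1 - exp(-t / rise_tau)) * exp(-t / decay_tau))
  t_peak <- rise_tau * log((rise_tau + decay_tau) / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  k / peak
}

#' Generate a synthetic calcium time-lapse movie with ground truth
#'
#' Renders each cell's pixels as `baseline * w * (1 + sum of events)` on top
#' of the background, where `w` is 1 on the footprint and decays as a
#' Gaussian of width `halo_sigma` outside it, then adds optional linear
#' bleaching and Gaussian noise. Intensities are kept as floating point;
#' clamping to 8 bits happens only in [write_stack_tiff()].
#'
#' @param spec a [movie_spec].
#' @return A list with elements `stack` (a [time_lapse_stack]) and `truth`,
#'   the ground-truth annotation: per-cell footprint pixel matrices
#'   (`cell_masks`), `classes`, `event_times`, `event_counts`, the tumor-cell
#'   pixel mask `gb_mask`, and per-cell noise-free footprint-mean traces
#'   (`traces`).
#' @export
generate_calcium_movie <- function(spec) {
  assert_that(inherits(spec, "movie_spec"), "spec must be a movie_spec")
  h <- spec$height; w <- spec$width; tt <- spec$n_frames
  cells <- spec$cells
  masks <- lapply(cells, function(cl)
    disc_pixels(cl$centroid[1], cl$centroid[2], cl$footprint_area, h, w))
  # disjoint footprints are required for well-posed ground truth
  if (length(masks) > 1L) {
    lin <- lapply(masks, function(m) m[, 1L] + (m[, 2L] - 1L) * h)
    all_pix <- unlist(lin)
    assert_that(!anyDuplicated(all_pix),
                "overlapping cell footprints: ground truth would be ill-posed")
  }
  times <- (seq_len(tt) - 1L) * spec$frame_interval

  data <- array(spec$background_level, dim = c(h, w, tt))
  if (spec$bleach_slope != 0) {
    drift <- spec$bleach_slope * (seq_len(tt) - 1L)
    data <- data + rep(drift, each = h * w)
  }
  truth_traces <- matrix(spec$background_level, tt, length(cells))
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    r0 <- sqrt(cl$footprint_area / pi)
    reach <- r0 + 3.5 * spec$halo_sigma
    rows <- max(1L, floor(cl$centroid[1] - reach)):min(h, ceiling(cl$centroid[1] + reach))
    cols <- max(1L, floor(cl$centroid[2] - reach)):min(w, ceiling(cl$centroid[2] + reach))
    grid <- expand.grid(row = rows, col = cols)
    d <- sqrt((grid$row - cl$centroid[1])^2 + (grid$col - cl$centroid[2])^2)
    keep <- d <= reach
    grid <- grid[keep, , drop = FALSE]; d <- d[keep]
    wgt <- ifelse(d <= r0, 1, exp(-(d - r0)^2 / (2 * spec$halo_sigma^2)))
    sig <- rep(1, tt)
    for (ei in seq_along(cl$event_times))
      sig <- sig + cl$event_amplitude *
        event_kernel(times - cl$event_times[ei], cl$rise_tau, cl$decay_tau)
    sig <- cl$baseline * sig
    idx <- outer(grid$row + (grid$col - 1L) * h, (seq_len(tt) - 1L) * h * w, "+")
    data[idx] <- data[idx] + outer(wgt, sig)
    truth_traces[, ci] <- truth_traces[, ci] + sig +
      if (spec$bleach_slope != 0) spec$bleach_slope * (seq_len(tt) - 1L) else 0
  }
  if (spec$noise_sd > 0) {
    data <- with_seed(spec$seed,
      data + array(stats::rnorm(length(data), 0, spec$noise_sd), dim = dim(data)))
  }
  classes <- vapply(cells, function(cl) cl$cell_class, character(1))
  gb_mask <- matrix(FALSE, h, w)
  for (ci in which(classes == "gb"))
    gb_mask[masks[[ci]][, 1L] + (masks[[ci]][, 2L] - 1L) * h] <- TRUE
  truth <- list(
    cell_masks = masks,
    classes = classes,
    event_times = lapply(cells, function(cl) cl$event_times),
    event_counts = vapply(cells, function(cl) length(cl$event_times), integer(1)),
    gb_mask = gb_mask,
    traces = truth_traces,
    frame_interval = spec$frame_interval
  )
  list(stack = time_lapse_stack(data, frame_interval = spec$frame_interval),
       truth = truth)
}

#' Generate a GFP reference image from movie ground truth
#'
#' Bright over tumor-cell (gb) pixels, dark elsewhere, as acquired to
#' distinguish GFP-tagged glioblastoma cells from neurons before mask-based
#' signal separation.
#'
#' @param truth ground truth from [generate_calcium_movie()] (or any list
#'   with a logical `gb_mask`).
#' @param bright,dark intensities for tumor and non-tumor pixels
#'   (`bright > dark`).
#' @param noise_sd optional additive Gaussian noise sd.
#' @param seed seed for the noise.
#' @return numeric matrix (8-bit scale).
#' @export
generate_gfp_reference <- function(truth, bright = 200, dark = 10,
                                   noise_sd = 0, seed = 1L) {
  assert_that(bright > dark, "bright must exceed dark")
  mask <- truth$gb_mask
  if (!any(mask))
    warning("gb_mask is empty: mask-based unmixing will be degenerate")
  img <- matrix(dark, nrow(mask), ncol(mask))
  img[mask] <- bright
  if (noise_sd > 0)
    img <- with_seed(seed, img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  img
}

#' Generate a spheroid growth image series with known radii
#'
#' Renders, for each culture day, a bright disc whose true radius grows
#' linearly: `r(d) = r0 + growth_rate * (d - days[1])`.
#'
#' @param r0 initial radius in micrometres (> 0).
#' @param growth_rate radial growth in micrometres per day (>= 0 for growth;
#'   negative values render a shrinking spheroid, as under drug treatment).
#' @param days culture days at which images are taken (increasing).
#' @param calibration micrometres per pixel.
#' @param bright,dark disc and background intensities.
#' @param margin_px background margin kept around the largest disc.
#' @return A list with `images` (named list of matrices, one per day) and
#'   `truth` (`days`, `radius_um`).
#' @export
generate_spheroid_series <- function(r0, growth_rate, days, calibration = 2,
                                     bright = 200, dark = 10, margin_px = 12) {
  assert_that(r0 > 0, "r0 must be positive")
  assert_that(length(days) >= 1 && !is.unsorted(days), "days must be increasing")
  radii_um <- r0 + growth_rate * (days - days[1])
  assert_that(all(radii_um > 0), "spheroid radius must stay positive")
  radii_px <- radii_um / calibration
  side <- 2L * ceiling(max(radii_px)) + 2L * margin_px + 1L
  assert_that(side >= 2 * max(radii_px),
              "disc exceeds frame")  # by construction; guards bad margins
  centre <- (side + 1) / 2
  idx <- seq_len(side)
  d2 <- outer((idx - centre)^2, (idx - centre)^2, "+")
  images <- lapply(radii_px, function(r) {
    img <- matrix(dark, side, side)
    img[d2 <= r^2] <- bright
    img
  })
  names(images) <- paste0("day", days)
  list(images = images,
       truth = list(days = days, radius_um = radii_um, calibration = calibration))
}

#' Generate a secretion spot-density table with known fold changes
#'
#' Emulates a cytokine-array pixel-density table: the control conditions sit
#' at `base_density` and the coculture condition at `base_density * ratio`
#' per analyte, so the true coculture-vs-control log2 fold change is
#' `log2(ratio)`.
#'
#' @param analytes character vector of analyte names.
#' @param true_ratios positive numeric vector, one per analyte.
#' @param base_density control pixel density.
#' @return A data.frame with columns `analyte`, `condition`
#'   (`coculture`, `neuron_control`, `gb_control`) and `density`.
#' @export
generate_secretion_table <- function(analytes, true_ratios, base_density = 1000) {
  assert_that(length(analytes) == length(true_ratios),
              "analytes and true_ratios must have equal length")
  assert_that(all(true_ratios > 0), "true_ratios must be positive")
  data.frame(
    analyte = rep(analytes, times = 3),
    condition = rep(c("coculture", "neuron_control", "gb_control"),
                    each = length(analytes)),
    density = c(base_density * true_ratios,
                rep(base_density, length(analytes)),
                rep(base_density, length(analytes))),
    stringsAsFactors = FALSE
  )
}
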