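# Trace processing: background subtraction, moving-average smoothing, dF/F0
# normalization, linear detrending, prominence-based peak detection, and the
# seven calcium peak parameters.

#' Subtract the background trace from every active trace
#'
#' Framewise subtraction of the background ROI's trace from each active
#' ROI's trace; the background column is removed from the result.
#'
#' @param traces a `raw_traces` object containing a background ROI.
#' @return A `raw_traces` object with background-subtracted active traces.
#' @export
subtract_background <- function(traces) {
  assert_that(inherits(traces, "raw_traces"), "raw_traces required")
  assert_that(!is.na(traces$background_label),
              "no background ROI present; add one with add_background_roi()")
  bg_col <- which(colnames(traces$values) == traces$background_label)
  bg <- traces$values[, bg_col]
  active <- traces$values[, -bg_col, drop = FALSE] - bg
  structure(list(values = active,
                 frame_interval = traces$frame_interval,
                 areas = traces$areas[-bg_col],
                 kinds = traces$kinds[-bg_col],
                 background_label = NA_character_),
            class = "raw_traces")
}

#' Moving-average smoothing of a trace
#'
#' Trailing (causal) moving average of the given window length, the
#' convention of MATLAB's `filter`; the leading edge uses partial windows
#' (mean of the samples available so far) rather than zero padding. A
#' centered window is available as an option.
#'
#' @param x numeric trace.
#' @param window number of points in the average (default 10).
#' @param align `"trailing"` (default) or `"centered"`.
#' @return smoothed numeric vector, same length as `x`.
#' @export
smooth_trace <- function(x, window = 10L, align = c("trailing", "centered")) {
  align <- match.arg(align)
  n <- length(x)
  window <- as.integer(window)
  assert_that(window >= 1L, "window must be >= 1")
  assert_that(window <= n, "window longer than the trace")
  cs <- cumsum(c(0, x))
  if (align == "trailing") {
    lo <- pmax(0L, seq_len(n) - window)
    (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
  } else {
    half_l <- (window - 1L) %/% 2L; half_r <- window - 1L - half_l
    lo <- pmax(0L, seq_len(n) - 1L - half_l)
    hi <- pmin(n, seq_len(n) + half_r)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
}

#' Compute dF/F0 normalization of a trace
#'
#' The baseline F0 is the mean of the lowest 20% of the samples
#' (`ceiling(0.2 * T)` smallest values, ties by sorted order) and
#' `dF/F0 = (x - F0) / F0`. The result is invariant to positive rescaling of
#' the raw trace.
#'
#' @param x numeric trace (background-subtracted, smoothed intensity).
#' @param frame_interval seconds between samples.
#' @return A `normalized_trace`: `dff`, `f0`, `frame_interval`, and `trend`
#'   (line coefficients, filled by [detrend_trace()]).
#' @export
compute_dff <- function(x, frame_interval = 0.5) {
  n <- length(x)
  assert_that(n > 0, "empty trace")
  k <- ceiling(0.2 * n)
  f0 <- mean(sort(x)[seq_len(k)])
  if (f0 <= 0)
    stop("F0 <= 0 after background subtraction; add a constant intensity ",
         "offset to the traces before normalization", call. = FALSE)
  structure(list(dff = (x - f0) / f0, f0 = f0,
                 frame_interval = frame_interval, trend = NULL),
            class = "normalized_trace")
}

#' Remove a linear trend from a dF/F0 trace
#'
#' Fits a least-squares line to dF/F0 against time and returns the residual,
#' storing the fitted coefficients. This removes slow drift (for example
#' residual photobleaching) before peak detection; the operation is a
#' projection, hence idempotent.
#'
#' @param nt a `normalized_trace`.
#' @return A `normalized_trace` with detrended `dff` and `trend` set to
#'   `c(intercept, slope_per_second)`.
#' @export
detrend_trace <- function(nt) {
  assert_that(inherits(nt, "normalized_trace"), "normalized_trace required")
  n <- length(nt$dff)
  assert_that(n >= 2, "detrending needs at least 2 samples")
  tm <- (seq_len(n) - 1) * nt$frame_interval
  fit <- stats::lm.fit(cbind(1, tm), nt$dff)
  nt$dff <- unname(fit$residuals)
  nt$trend <- unname(fit$coefficients)
  nt
}

#' Detect peaks by prominence
#'
#' Local maxima of the trace whose prominence reaches `prominence_min` and
#' whose absolute height exceeds the mean of the signal are retained.
#' Prominence follows the standard definition: the peak height minus the
#' higher of the two flanking minima, where each flank extends to the
#' nearest strictly higher sample or, failing that, to the end of the trace.
#' For plateau maxima the leftmost sample of the plateau is the peak index;
#' trace endpoints are not eligible.
#'
#' @param nt a `normalized_trace` (or numeric vector; then `frame_interval`
#'   is taken from the argument).
#' @param prominence_min minimum prominence in dF/F0 units (default 0.07).
#' @param height_min minimum height; default the mean of the trace.
#' @param frame_interval used only when `nt` is a bare numeric vector.
#' @return data.frame with one row per peak: `index` (1-based frame),
#'   `time` (s), `height`, `prominence`, `width` (s at half prominence),
#'   `left_base`, `right_base` (frames), `left_cross`, `right_cross`
#'   (fractional frames of the half-prominence crossings).
#' @export
detect_peaks <- function(nt, prominence_min = 0.07, height_min = NULL,
                         frame_interval = 0.5) {
  if (inherits(nt, "normalized_trace")) {
    x <- nt$dff; dt <- nt$frame_interval
  } else {
    x <- as.numeric(nt); dt <- frame_interval
  }
  n <- length(x)
  if (is.null(height_min)) height_min <- mean(x)
  empty <- data.frame(index = integer(0), time = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width = numeric(0), left_base = integer(0),
                      right_base = integer(0), left_cross = numeric(0),
                      right_cross = numeric(0))
  if (n < 3) return(empty)

  # candidate local maxima (plateaus -> leftmost sample; endpoints excluded)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(empty)

  rows <- lapply(cand, function(p) {
    h <- x[p]
    # left flank: to the nearest strictly higher sample (or trace start)
    lh <- p - 1L
    while (lh >= 1L && x[lh] <= h) lh <- lh - 1L
    lseg <- (lh + 1L):(p - 1L)
    lmin <- min(x[lseg]); lbase <- lseg[which.min(x[lseg])]
    rh <- p + 1L
    while (rh <= n && x[rh] <= h) rh <- rh + 1L
    rseg <- (p + 1L):(rh - 1L)
    rmin <- min(x[rseg]); rbase <- rseg[which.min(x[rseg])]
    prom <- h - max(lmin, rmin)
    if (prom < prominence_min || h <= height_min) return(NULL)
    # half-prominence width with linear interpolation, bounded by the bases;
    # both flanking minima lie below ref, so a crossing always exists
    ref <- h - prom / 2
    j <- p
    while (j > lbase && x[j - 1L] > ref) j <- j - 1L
    lcross <- if (j > lbase && x[j] != x[j - 1L])
      (j - 1L) + (ref - x[j - 1L]) / (x[j] - x[j - 1L]) else as.numeric(j - (j > lbase))
    j <- p
    while (j < rbase && x[j + 1L] > ref) j <- j + 1L
    rcross <- if (j < rbase && x[j] != x[j + 1L])
      j + (x[j] - ref) / (x[j] - x[j + 1L]) else as.numeric(j + (j < rbase))
    data.frame(index = p, time = (p - 1L) * dt, height = h, prominence = prom,
               width = (rcross - lcross) * dt, left_base = lbase,
               right_base = rbase, left_cross = lcross, right_cross = rcross)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize peak parameters of a trace
#'
#' Computes the seven calcium activity parameters: number of peaks, mean
#' amplitude (peak height in dF/F0), mean prominence, mean duration (width
#' at half prominence, s), mean peak-to-peak distance (s; `NA` when fewer
#' than two peaks), mean rising and descending slope angles (degrees, from
#' the half-prominence crossing to the peak, with time in seconds), and
#' frequency (peaks per second of recording).
#'
#' @param nt the `normalized_trace` the peaks were detected on.
#' @param peaks data.frame from [detect_peaks()].
#' @return one-row data.frame with columns `n_peaks`, `amplitude`,
#'   `prominence`, `width_s`, `p2p_s`, `rise_deg`, `fall_deg`, `freq_hz`.
#' @export
peak_features <- function(nt, peaks) {
  assert_that(inherits(nt, "normalized_trace"), "normalized_trace required")
  dt <- nt$frame_interval
  duration <- length(nt$dff) * dt
  np <- nrow(peaks)
  if (np == 0L)
    return(data.frame(n_peaks = 0L, amplitude = NA_real_,
                      prominence = NA_real_, width_s = NA_real_,
                      p2p_s = NA_real_, rise_deg = NA_real_,
                      fall_deg = NA_real_, freq_hz = 0))
  half <- peaks$prominence / 2
  rise <- atan(half / pmax((peaks$index - peaks$left_cross) * dt, .Machine$double.eps))
  fall <- atan(half / pmax((peaks$right_cross - peaks$index) * dt, .Machine$double.eps))
  data.frame(
    n_peaks = np,
    amplitude = mean(peaks$height),
    prominence = mean(peaks$prominence),
    width_s = mean(peaks$width),
    p2p_s = if (np >= 2L) mean(diff(peaks$time)) else NA_real_,
    rise_deg = mean(rise) * 180 / pi,
    fall_deg = mean(fall) * 180 / pi,
    freq_hz = np / duration
  )
}

#' Run the full trace-analysis chain on extracted traces
#'
#' Applies, per active ROI: background subtraction (if a background ROI is
#' present), moving-average smoothing, dF/F0 normalization, linear
#' detrending, peak detection, and peak parameterization.
#'
#' @param traces a `raw_traces` object.
#' @param smooth_window moving-average window (points).
#' @param prominence_min peak prominence threshold in dF/F0 units.
#' @param classes optional character vector (or named vector by ROI label)
#'   of cell classes to annotate the feature table with.
#' @return A list: `features` (one row per ROI: `roi`, `cell_class`, the
#'   seven parameters), `normalized` (list of `normalized_trace`), `peaks`
#'   (list of peak tables).
#' @export
analyze_traces <- function(traces, smooth_window = 10L, prominence_min = 0.07,
                           classes = NULL) {
  assert_that(inherits(traces, "raw_traces"), "raw_traces required")
  if (!is.na(traces$background_label)) traces <- subtract_background(traces)
  labels <- colnames(traces$values)
  if (!is.null(classes) && !is.null(names(classes)))
    classes <- unname(classes[labels])
  normalized <- list(); peak_tabs <- list(); feats <- list()
  for (k in seq_along(labels)) {
    sm <- smooth_trace(traces$values[, k], window = smooth_window)
    nt <- compute_dff(sm, frame_interval = traces$frame_interval)
    nt <- detrend_trace(nt)
    pk <- detect_peaks(nt, prominence_min = prominence_min)
    ft <- peak_features(nt, pk)
    ft <- cbind(data.frame(roi = labels[k],
                           cell_class = if (is.null(classes)) NA_character_
                                        else classes[k],
                           stringsAsFactors = FALSE), ft)
    normalized[[labels[k]]] <- nt
    peak_tabs[[labels[k]]] <- pk
    feats[[k]] <- ft
  }
  list(features = do.call(rbind, feats), normalized = normalized,
       peaks = peak_tabs)
}
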