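# Independent oracles and fixture helpers for the test suite.

# Brute-force peak finder: enumerates local maxima by direct scanning and
# computes prominence from its definition (height above the higher of the
# two flanking minima, each flank bounded by the nearest strictly higher
# sample or the trace end). Deliberately naive and independent of the
# package's detector; plateau maxima resolve to their leftmost sample.
oracle_peak_indices <- function(x, prominence_min = 0.07,
                                height_min = mean(x)) {
  n <- length(x)
  out <- integer(0)
  if (n < 3) return(out)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next           # must rise into i (plateau-leftmost)
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j == n || x[j + 1] > x[i]) next  # must fall after the plateau
    left <- x[1:(i - 1)]
    higher_l <- which(left > x[i])
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1):(i - 1)])
            else min(left)
    right <- x[(i + 1):n]
    higher_r <- which(right > x[i])
    rmin <- if (length(higher_r)) min(right[1:(min(higher_r) - 1)])
            else min(right)
    prom <- x[i] - max(lmin, rmin)
    if (prom >= prominence_min && x[i] > height_min) out <- c(out, i)
  }
  out
}

# Random test traces: rounded random walks (ties and plateaus) and
# event-bearing noisy traces, under a fixed seed per index.
random_trace <- function(seed, n = 240) {
  set.seed(seed)
  if (seed %% 2 == 0) {
    round(cumsum(rnorm(n, 0, 0.05)), 2)
  } else {
    tm <- (seq_len(n) - 1) * 0.5
    x <- rnorm(n, 0, 0.03)
    for (t0 in sort(runif(sample(2:5, 1), 5, max(tm) - 15)))
      x <- x + runif(1, 0.2, 1.5) *
        ifelse(tm < t0, 0, (1 - exp(-(tm - t0) / 0.4)) * exp(-(tm - t0) / 2))
    x
  }
}

# Match detected ROIs to ground-truth cell masks by majority pixel overlap.
# Returns a data.frame with one row per detected ROI: the index of the best
# truth cell, the overlap fraction of detected pixels, and the ROI label.
match_rois_to_truth <- function(rois, truth, h) {
  truth_lin <- lapply(truth$cell_masks, function(m) m[, 1] + (m[, 2] - 1) * h)
  rows <- lapply(rois$rois, function(r) {
    if (r$kind != "active_cell") return(NULL)
    det <- r$pixels[, 1] + (r$pixels[, 2] - 1) * h
    ov <- vapply(truth_lin,
                 function(tl) length(intersect(det, tl)) / length(det),
                 numeric(1))
    data.frame(roi = r$label, cell = which.max(ov), overlap = max(ov),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A movie spec holding one cell with fully specified events, for per-trace
# recovery tests.
single_cell_spec <- function(seed, cell_class = "neuron", noise_sd = 0,
                             n_events = 3, n_frames = 240,
                             frame_interval = 0.5) {
  duration <- (n_frames - 1) * frame_interval
  set.seed(seed)
  end_margin <- 12 + 4 * (if (cell_class == "neuron") 0.3 else 3)
  base <- seq(8, duration - end_margin, length.out = n_events)
  times <- sort(base + runif(n_events, -2, 2))
  movie_spec(height = 48, width = 48, n_frames = n_frames,
             frame_interval = frame_interval,
             cells = list(cell_spec(c(24, 24), 120, cell_class,
                                    event_times = times)),
             noise_sd = noise_sd, seed = seed)
}
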