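# Trace pipeline: background subtraction, smoothing, dF/F0, detrending,
# peak detection against the brute-force oracle, and peak parameters.

test_that("background subtraction removes the background trace framewise", {
  v <- cbind(a = rep(100, 5), b = c(30, 40, 50, 40, 30),
             background = rep(20, 5))
  tr <- structure(list(values = v, frame_interval = 0.5,
                       areas = c(10, 10, 9), kinds = c("active_cell",
                       "active_cell", "background"),
                       background_label = "background"),
                  class = "raw_traces")
  out <- subtract_background(tr)
  expect_equal(ncol(out$values), 2L)
  expect_equal(unname(out$values[, "a"]), rep(80, 5))
  expect_equal(unname(out$values[, "b"]), c(10, 20, 30, 20, 10))
  # a trace equal to the background becomes all-zero
  v2 <- cbind(a = rep(20, 5), background = rep(20, 5))
  tr2 <- tr; tr2$values <- v2; tr2$areas <- c(10, 9)
  tr2$kinds <- c("active_cell", "background")
  expect_true(all(subtract_background(tr2)$values == 0))
  tr$background_label <- NA_character_
  expect_error(subtract_background(tr), "background")
})

test_that("trailing moving average has the expected FIR response", {
  x <- rep(4, 30)
  expect_equal(smooth_trace(x, 10), x)
  x <- rep(0, 50); x[20] <- 1
  s <- smooth_trace(x, 10)
  expect_equal(s[20:29], rep(0.1, 10))
  expect_true(all(s[-(20:29)] == 0))
  # interior sums are preserved by the unit-gain FIR
  expect_equal(sum(s), 1)
  expect_error(smooth_trace(1:5, 10), "window")
})

test_that("dF/F0 uses the mean of the lowest 20% and scales out", {
  x <- c(rep(50, 80), rep(100, 20))
  nt <- compute_dff(x)
  expect_identical(nt$f0, 50)
  expect_identical(max(nt$dff), 1)
  # constant trace
  ntc <- compute_dff(rep(7, 40))
  expect_identical(ntc$f0, 7)
  expect_true(all(ntc$dff == 0))
  # invariance under positive rescaling
  nt2 <- compute_dff(3.7 * x)
  expect_equal(nt2$dff, nt$dff, tolerance = 1e-12)
  expect_error(compute_dff(c(-5, -4, rep(1, 8))), "F0")
})

test_that("linear detrending removes a line exactly and is idempotent", {
  tm <- (0:99) * 0.5
  line <- 0.3 + 0.01 * tm
  nt <- compute_dff(100 + 10 * line)  # arbitrary positive trace
  nt$dff <- line                      # force a pure line
  out <- detrend_trace(nt)
  expect_true(all(abs(out$dff) < 1e-12))
  # peaks + slope: residual refit has zero slope
  set.seed(1)
  nt$dff <- 0.002 * seq_along(tm) + rnorm(100, 0, 0.05)
  out <- detrend_trace(nt)
  refit <- stats::lm.fit(cbind(1, tm), out$dff)$coefficients
  expect_lt(abs(refit[2]), 1e-9)
  expect_equal(detrend_trace(out)$dff, out$dff, tolerance = 1e-12)
})

test_that("peaks below the prominence threshold or the mean are excluded", {
  expect_identical(nrow(detect_peaks(rep(0, 50))), 0L)
  # a single bump of prominence 0.05 is not a peak at the 0.07 threshold
  x <- rep(0, 50); x[25] <- 0.05
  expect_identical(nrow(detect_peaks(x, height_min = -1)), 0L)
  x[25] <- 0.08
  pk <- detect_peaks(x, height_min = -1)
  expect_identical(pk$index, 25L)
  expect_equal(pk$prominence, 0.08)
})

test_that("peak detection matches the brute-force oracle on random traces", {
  for (seed in 1:50) {
    x <- random_trace(seed)
    got <- detect_peaks(x, frame_interval = 0.5)$index
    want <- oracle_peak_indices(x)
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("peak parameters follow their definitions on a constructed trace", {
  # symmetric triangular peaks at t = 10 s and 40 s in a 120 s trace
  n <- 240; dt <- 0.5
  x <- rep(0, n)
  tri <- c(seq(0, 1, by = 0.1), seq(0.9, 0, by = -0.1))  # 21 samples, apex 11th
  x[15:35] <- tri; x[75:95] <- tri
  nt <- structure(list(dff = x, f0 = 1, frame_interval = dt, trend = NULL),
                  class = "normalized_trace")
  pk <- detect_peaks(nt, height_min = -1)
  expect_identical(pk$index, c(25L, 85L))
  expect_equal(pk$time, c(12, 42))
  ft <- peak_features(nt, pk)
  expect_identical(ft$n_peaks, 2L)
  expect_equal(ft$p2p_s, 30)
  expect_equal(ft$freq_hz, 2 / 120)
  expect_equal(ft$rise_deg, ft$fall_deg, tolerance = 1e-9)  # symmetry
  # fewer than two peaks: peak-to-peak missing, not zero
  x1 <- rep(0, n); x1[100:120] <- tri
  nt1 <- structure(list(dff = x1, f0 = 1, frame_interval = dt, trend = NULL),
                   class = "normalized_trace")
  ft1 <- peak_features(nt1, detect_peaks(nt1, height_min = -1))
  expect_identical(ft1$n_peaks, 1L)
  expect_true(is.na(ft1$p2p_s))
})

test_that("event counts are recovered from noise-free single-cell traces", {
  for (seed in 1:5) {
    for (class in c("neuron", "gb")) {
      sp <- single_cell_spec(seed, class, n_events = 3)
      sim <- generate_calcium_movie(sp)
      rs <- roi_set(list(roi("c", sim$truth$cell_masks[[1]], "active_cell")),
                    c(48, 48))
      tr <- extract_traces(sim$stack, rs)
      tr$values <- tr$values - sp$background_level  # background known exactly
      an <- analyze_traces(tr)
      expect_identical(an$features$n_peaks, 3L,
                       info = paste(class, "seed", seed))
    }
  }
})

test_that("adding the same constant to trace and background leaves peaks unchanged", {
  sp <- single_cell_spec(2, "neuron", n_events = 4)
  sim <- generate_calcium_movie(sp)
  mk <- function(offset) {
    v <- cbind(cell = sim$truth$traces[, 1] + offset,
               background = rep(sp$background_level + offset,
                                nrow(sim$truth$traces)))
    structure(list(values = v, frame_interval = 0.5, areas = c(120, 64),
                   kinds = c("active_cell", "background"),
                   background_label = "background"),
              class = "raw_traces")
  }
  a <- analyze_traces(mk(0)); b <- analyze_traces(mk(37))
  expect_identical(a$peaks$cell$index, b$peaks$cell$index)
  expect_equal(a$features$amplitude, b$features$amplitude, tolerance = 1e-10)
})
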