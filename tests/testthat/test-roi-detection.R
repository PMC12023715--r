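# Detection chain: projection, lowpass, thresholding + median smoothing +
# size gate, background ROI placement, trace extraction.

test_that("range projection is max minus min per pixel", {
  arr <- array(5, dim = c(4, 4, 3))
  stack <- time_lapse_stack(arr)
  expect_true(all(range_projection(stack) == 0))
  arr[2, 3, ] <- c(10, 50, 30)
  expect_equal(range_projection(time_lapse_stack(arr))[2, 3], 40)
  # shift invariance
  shifted <- time_lapse_stack(arr + 17)
  expect_equal(range_projection(shifted), range_projection(time_lapse_stack(arr)))
})

test_that("lowpass preserves constants and spreads an impulse as expected", {
  img <- matrix(7, 9, 9)
  expect_equal(lowpass(img), img)
  img <- matrix(0, 9, 9); img[5, 5] <- 9
  out <- lowpass(img)
  expect_equal(out[4:6, 4:6], matrix(1, 3, 3))
  expect_lt(max(abs(out[-(4:6), ])), 1e-10)  # FFT-convolution residue only
  expect_lte(max(out), max(img))
})

test_that("size gate keeps only blobs in range and a constant stack yields none", {
  # flashing blobs of ~120 (kept), ~30 and ~300 px^2 (rejected)
  cells <- list(cell_spec(c(40, 40), 120, "neuron", event_times = 20),
                cell_spec(c(40, 110), 30, "neuron", event_times = 20),
                cell_spec(c(110, 75), 300, "neuron", event_times = 20))
  sp <- movie_spec(height = 150, width = 150, n_frames = 120, cells = cells)
  sim <- generate_calcium_movie(sp)
  rois <- detect_active_rois(sim$stack)
  expect_length(rois$rois, 1L)
  m <- match_rois_to_truth(rois, sim$truth, 150)
  expect_identical(m$cell, 1L)
  expect_gt(m$overlap, 0.9)
  # every returned ROI satisfies the gate
  cfg <- detection_config()
  for (r in rois$rois)
    expect_true(r$area >= cfg$min_area && r$area <= cfg$max_area)

  flat <- time_lapse_stack(array(5, dim = c(32, 32, 4)))
  expect_warning(none <- detect_active_rois(flat), "no active ROIs")
  expect_length(none$rois, 0L)
})

test_that("detection is invariant to a constant intensity offset", {
  sp <- coculture_movie_spec(n_neurons = 3, n_gb = 1, height = 128,
                             width = 128, n_frames = 120, seed = 5)
  sim <- generate_calcium_movie(sp)
  rois1 <- detect_active_rois(sim$stack)
  shifted <- sim$stack; shifted$data <- shifted$data + 23
  rois2 <- detect_active_rois(shifted)
  expect_identical(lapply(rois1$rois, `[[`, "pixels"),
                   lapply(rois2$rois, `[[`, "pixels"))
})

test_that("background ROI placement avoids cells and honors explicit locations", {
  sp <- coculture_movie_spec(n_neurons = 3, n_gb = 1, height = 128,
                             width = 128, n_frames = 120, seed = 5)
  sim <- generate_calcium_movie(sp)
  rois <- detect_active_rois(sim$stack)
  # auto placement lands outside all ground-truth cell pixels
  auto <- add_background_roi(sim$stack, rois)
  bg <- auto$rois[[length(auto$rois)]]
  expect_identical(bg$kind, "background")
  truth_pix <- do.call(rbind, sim$truth$cell_masks)
  truth_lin <- truth_pix[, 1] + (truth_pix[, 2] - 1) * 128
  expect_length(intersect(bg$pixels[, 1] + (bg$pixels[, 2] - 1) * 128,
                          truth_lin), 0L)
  # explicit placement in an empty corner
  manual <- add_background_roi(sim$stack, rois, location = c(1, 1), size = 64)
  expect_identical(manual$rois[[length(manual$rois)]]$pixels[1, ],
                   c(row = 1L, col = 1L))
  # overlapping an active ROI is an error
  cell_px <- rois$rois[[1]]$pixels[1, ]
  expect_error(add_background_roi(sim$stack, rois, location = cell_px),
               "intersects")
})

test_that("extracted traces are ROI pixel means", {
  arr <- array(3, dim = c(8, 8, 4))
  arr[2, 2, ] <- c(10, 20, 30, 40)
  arr[2, 3, ] <- c(20, 10, 40, 20)
  stack <- time_lapse_stack(arr)
  rs <- roi_set(list(roi("a", cbind(2L, 2:3), "active_cell"),
                     roi("b", cbind(5L, 5L), "active_cell")),
                c(8, 8))
  tr <- extract_traces(stack, rs)
  expect_equal(tr$values[, "a"], c(15, 15, 35, 30))
  expect_equal(tr$values[, "b"], rep(3, 4))  # uniform region -> constant
})

test_that("traces of detected cells match ground-truth footprint means", {
  sp <- movie_spec(height = 48, width = 48, n_frames = 120,
                   cells = list(cell_spec(c(24, 24), 120, "neuron",
                                          event_times = c(15, 45))))
  sim <- generate_calcium_movie(sp)
  rs <- roi_set(list(roi("truth", sim$truth$cell_masks[[1]], "active_cell")),
                c(48, 48))
  tr <- extract_traces(sim$stack, rs)
  expect_equal(unname(tr$values[, 1]), unname(sim$truth$traces[, 1]),
               tolerance = 1e-10)
})
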