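# GFP mask binarization, stack splitting, and per-ROI cell-type labels.

test_that("binarization at the mean recovers the bright half exactly", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  mask <- binarize_gfp(img)
  expect_equal(mask$threshold_used, 100)
  expect_identical(mask$gb_mask, img > 100)
  expect_warning(empty <- binarize_gfp(matrix(5, 4, 4)), "empty")
  expect_false(any(empty$gb_mask))
})

test_that("split stacks reconstruct the input and have zero leakage", {
  sp <- coculture_movie_spec(n_neurons = 2, n_gb = 2, height = 96, width = 96,
                             n_frames = 60, seed = 9)
  sim <- generate_calcium_movie(sp)
  mask <- binarize_gfp(generate_gfp_reference(sim$truth))
  expect_identical(mask$gb_mask, sim$truth$gb_mask)  # exact mask fixture
  sides <- split_stack(sim$stack, mask)
  expect_identical(sides$gb$data + sides$neuron$data, sim$stack$data)
  # neuron-side traces over gb footprints are identically zero (and vice versa)
  gb_cells <- which(sim$truth$classes == "gb")
  rs <- roi_set(lapply(gb_cells, function(i)
    roi(paste0("gb", i), sim$truth$cell_masks[[i]], "active_cell")), c(96, 96))
  expect_true(all(extract_traces(sides$neuron, rs)$values == 0))
  nrn_cells <- which(sim$truth$classes == "neuron")
  rs2 <- roi_set(lapply(nrn_cells, function(i)
    roi(paste0("n", i), sim$truth$cell_masks[[i]], "active_cell")), c(96, 96))
  expect_true(all(extract_traces(sides$gb, rs2)$values == 0))
})

test_that("degenerate masks send every signal to one side", {
  arr <- array(runif(4 * 4 * 3, 0, 10), dim = c(4, 4, 3))
  stack <- time_lapse_stack(arr)
  all_on <- structure(list(gb_mask = matrix(TRUE, 4, 4), threshold_used = 0),
                      class = "celltype_mask")
  sides <- split_stack(stack, all_on)
  expect_identical(sides$gb$data, arr)
  expect_true(all(sides$neuron$data == 0))
})

test_that("ROI classes follow the majority of mask pixels", {
  mask <- structure(list(gb_mask = cbind(matrix(TRUE, 8, 4),
                                         matrix(FALSE, 8, 4)),
                         threshold_used = 1), class = "celltype_mask")
  rs <- roi_set(list(roi("in", as.matrix(expand.grid(2:4, 2:3)), "active_cell"),
                     roi("out", as.matrix(expand.grid(2:4, 6:7)), "active_cell")),
                c(8, 8))
  cls <- classify_rois(rs, mask)
  expect_identical(cls$cell_class, c("gb", "neuron"))
  expect_equal(cls$gb_fraction, c(1, 0))
})

test_that("labels match generator classes for every cell with exact masks", {
  sp <- coculture_movie_spec(n_neurons = 5, n_gb = 3, height = 160,
                             width = 160, n_frames = 120, seed = 4)
  sim <- generate_calcium_movie(sp)
  rois <- detect_active_rois(sim$stack)
  cls <- classify_rois(rois, binarize_gfp(generate_gfp_reference(sim$truth)))
  m <- match_rois_to_truth(rois, sim$truth, 160)
  expect_identical(nrow(m), 8L)
  expect_identical(cls$cell_class[match(m$roi, cls$roi)],
                   sim$truth$classes[m$cell])
})
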