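# Synthetic-data generators: determinism, ground-truth consistency, and the
# stated arithmetic of each fixture class.

test_that("an empty noise-free movie is constant at the background level", {
  sp <- movie_spec(height = 32, width = 32, n_frames = 10, cells = list(),
                   background_level = 6, noise_sd = 0)
  sim <- generate_calcium_movie(sp)
  expect_true(all(sim$stack$data == 6))
})

test_that("identical spec and seed give bit-identical movies", {
  sp <- coculture_movie_spec(n_neurons = 2, n_gb = 1, height = 96, width = 96,
                             n_frames = 40, noise_sd = 8, seed = 11)
  a <- generate_calcium_movie(sp)
  b <- generate_calcium_movie(sp)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$cell_masks, b$truth$cell_masks)
})

test_that("a noise-free single neuron shows exactly its events as maxima", {
  sp <- movie_spec(height = 48, width = 48, n_frames = 240,
                   cells = list(cell_spec(c(24, 24), 120, "neuron",
                                          event_times = c(20, 60, 100))),
                   noise_sd = 0)
  sim <- generate_calcium_movie(sp)
  tr <- sim$truth$traces[, 1]
  interior <- 2:(length(tr) - 1)
  n_maxima <- sum(tr[interior] > tr[interior - 1] &
                  tr[interior] >= tr[interior + 1] &
                  tr[interior] > tr[1] + 1e-9)
  expect_identical(n_maxima, 3L)
})

test_that("overlapping footprints are rejected", {
  cells <- list(cell_spec(c(24, 24), 120, "neuron"),
                cell_spec(c(26, 24), 120, "gb"))
  expect_error(generate_calcium_movie(
    movie_spec(height = 48, width = 48, n_frames = 10, cells = cells)),
    "overlapping")
})

test_that("footprint masks match the requested area up to a discretization ring", {
  for (area in c(60, 100, 150)) {
    sp <- movie_spec(height = 64, width = 64, n_frames = 5,
                     cells = list(cell_spec(c(32, 32), area, "neuron")))
    sim <- generate_calcium_movie(sp)
    got <- nrow(sim$truth$cell_masks[[1]])
    ring <- 2 * pi * sqrt(area / pi)  # one-pixel boundary ring
    expect_lt(abs(got - area), ring)
  }
})

test_that("neuron events are strictly narrower than gb events at default kinetics", {
  tm <- seq(0, 120, by = 0.1)
  fwhm <- function(class) {
    cl <- cell_spec(c(1, 1), 10, class)
    k <- (1 - exp(-tm / cl$rise_tau)) * exp(-tm / cl$decay_tau)
    k <- k / max(k)
    diff(range(tm[k >= 0.5]))
  }
  expect_lt(fwhm("neuron"), fwhm("gb"))
})

test_that("GFP reference is bright exactly over gb pixels", {
  sp <- coculture_movie_spec(n_neurons = 2, n_gb = 2, height = 96, width = 96,
                             n_frames = 20, seed = 3)
  sim <- generate_calcium_movie(sp)
  img <- generate_gfp_reference(sim$truth, bright = 200, dark = 0)
  expect_equal(mean(img), 200 * mean(sim$truth$gb_mask))
  # neuron pixels are never bright
  for (ci in which(sim$truth$classes == "neuron")) {
    m <- sim$truth$cell_masks[[ci]]
    expect_true(all(img[m[, 1] + (m[, 2] - 1) * 96] == 0))
  }
  # no gb cells -> uniform dark image, with a warning about degeneracy
  sp2 <- coculture_movie_spec(n_neurons = 2, n_gb = 0, height = 96, width = 96,
                              n_frames = 20, seed = 3)
  sim2 <- generate_calcium_movie(sp2)
  expect_warning(img2 <- generate_gfp_reference(sim2$truth, 200, 0), "empty")
  expect_true(all(img2 == 0))
})

test_that("spheroid series renders the programmed linear growth", {
  out <- generate_spheroid_series(r0 = 100, growth_rate = 100,
                                  days = c(8, 21), calibration = 1)
  expect_equal(out$truth$radius_um, c(100, 1400))
  # equivalent radius of the rendered disc within 1 px of truth
  for (i in seq_along(out$images)) {
    a <- sum(out$images[[i]] > 100)
    expect_lt(abs(sqrt(a / pi) - out$truth$radius_um[i]), 1)
  }
  zero <- generate_spheroid_series(100, 0, days = c(8, 14, 21))
  expect_identical(zero$images[[1]], zero$images[[3]])
  expect_error(generate_spheroid_series(100, -20, days = c(8, 21)), "positive")
})

test_that("secretion tables encode the requested fold changes", {
  tab <- generate_secretion_table(c("A", "B", "C"), c(1, 4, 0.25))
  fc <- log2_fold_change(tab, pseudocount = 0)
  expect_equal(fc$log2fc, c(0, 2, -2))
})
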