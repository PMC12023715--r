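# End-to-end orchestration: synthesize or ingest a recording, detect ROIs,
# unmix cell types, extract and parameterize traces, compute the active-area
# statistic, compare classes, and write a reproducibility manifest.

#' Lay out a synthetic coculture movie specification
#'
#' Places non-overlapping neuron and tumor (gb) cells on a jittered grid and
#' assigns each cell seeded spontaneous events: neurons fire more, faster
#' events; gb cells fewer, broader ones. This is the standard fixture
#' builder used by the demo pipeline and the package's own validation.
#'
#' @param n_neurons,n_gb number of cells of each class.
#' @param height,width,n_frames,frame_interval,noise_sd,bleach_slope passed
#'   to [movie_spec()].
#' @param area_range footprint-area range (px^2) cells are drawn from.
#' @param n_events_neuron,n_events_gb events per cell (single value or
#'   range to sample from).
#' @param seed integer seed controlling layout and event times.
#' @return A [movie_spec].
#' @export
coculture_movie_spec <- function(n_neurons = 6, n_gb = 4, height = 160,
                                 width = 160, n_frames = 240,
                                 frame_interval = 0.5, noise_sd = 0,
                                 bleach_slope = 0, area_range = c(80, 150),
                                 n_events_neuron = c(4, 6),
                                 n_events_gb = c(2, 2), seed = 1L) {
  n_cells <- n_neurons + n_gb
  spacing <- 32L; margin <- 16L
  rows <- seq(margin, height - margin, by = spacing)
  cols <- seq(margin, width - margin, by = spacing)
  slots <- expand.grid(row = rows, col = cols)
  assert_that(nrow(slots) >= n_cells,
              "frame too small for the requested number of cells")
  duration <- (n_frames - 1) * frame_interval
  with_seed(seed, {
    slots <- slots[sample.int(nrow(slots), n_cells), ]
    classes <- sample(rep(c("neuron", "gb"), c(n_neurons, n_gb)))
    cells <- lapply(seq_len(n_cells), function(i) {
      k_range <- if (classes[i] == "neuron") n_events_neuron else n_events_gb
      k <- if (length(k_range) == 2L && k_range[1] < k_range[2])
        sample(seq(k_range[1], k_range[2]), 1) else k_range[1]
      # events on a jittered regular grid: well separated by construction,
      # with an end margin so the transient peaks (kernel lag plus the
      # trailing smoothing lag) stay inside the recording
      end_margin <- 12 + 4 * (if (classes[i] == "neuron") 0.3 else 3)
      base <- seq(8, duration - end_margin, length.out = max(k, 1))
      times <- sort(base + stats::runif(k, -2, 2))
      cell_spec(centroid = c(slots$row[i], slots$col[i]) + stats::runif(2, -3, 3),
                footprint_area = stats::runif(1, area_range[1], area_range[2]),
                cell_class = classes[i],
                event_times = pmin(pmax(times, 0), duration))
    })
    movie_spec(height = height, width = width, n_frames = n_frames,
               frame_interval = frame_interval, cells = cells,
               noise_sd = noise_sd, bleach_slope = bleach_slope, seed = seed)
  })
}

#' Default pipeline configuration
#'
#' @return named list of configuration sections understood by
#'   [run_calcium_pipeline()]: `seed`, `out_dir`, `frame_interval`,
#'   `calibration`, `inputs` (paths to a movie TIFF and GFP TIFF, or `NULL`
#'   to synthesize), `synthesize`, `detection`, `trace`, `area`, `stats`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = file.path(tempdir(), "calcimetry_run"),
    frame_interval = 0.5,
    calibration = 1,
    inputs = NULL,
    synthesize = list(n_neurons = 6, n_gb = 4, height = 160, width = 160,
                      n_frames = 240, noise_sd = 0),
    detection = list(activity_threshold = 180, median_radius = 5,
                     min_area = 50, max_area = 200),
    trace = list(smooth_window = 10, prominence_min = 0.07),
    area = list(threshold = "otsu", min_size = 50),
    stats = list(enabled = TRUE, features = c("width_s", "freq_hz"))
  )
}

# Merge user config over defaults, rejecting unknown top-level keys.
#' @keywords internal
#' @noRd
normalize_config <- function(config) {
  defaults <- default_run_config()
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0L,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, config)
}

#' @keywords internal
#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the calcium-imaging pipeline end to end
#'
#' Stages: synthesize (or read) the recording and GFP reference, detect
#' active ROIs, add a background ROI, binarize the GFP image and classify
#' ROIs by cell type, extract traces, compute dF/F0 peak features per ROI,
#' compute the active neuronal area on the neuron side, compare feature
#' distributions between classes, and write all outputs with a manifest
#' that makes the run reproducible.
#'
#' @param config a configuration list (see [default_run_config()]) or the
#'   path to a YAML file with the same structure. Unknown keys are rejected.
#' @return (invisibly) a list: `features`, `rois`, `classes`, `area`,
#'   `stats`, `manifest`, `out_dir`.
#' @export
run_calcium_pipeline <- function(config = default_run_config()) {
  cfg <- normalize_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("calcimetry pipeline -> ", cfg$out_dir)

  if (!is.null(cfg$inputs)) {
    stack <- stage("ingest", read_stack_tiff(cfg$inputs$movie_tiff,
                                             frame_interval = cfg$frame_interval,
                                             calibration = cfg$calibration))
    gfp <- stage("ingest", read_image_tiff(cfg$inputs$gfp_tiff))
    truth <- NULL
  } else {
    sim <- stage("synthesize", {
      sp <- do.call(coculture_movie_spec,
                    c(cfg$synthesize, list(frame_interval = cfg$frame_interval,
                                           seed = cfg$seed)))
      generate_calcium_movie(sp)
    })
    stack <- sim$stack; truth <- sim$truth
    gfp <- generate_gfp_reference(truth)
  }

  det_cfg <- do.call(detection_config, cfg$detection)
  rois <- stage("detect", detect_active_rois(stack, det_cfg))
  rois <- stage("background", add_background_roi(stack, rois))
  mask <- stage("unmix", binarize_gfp(gfp))
  classes <- stage("classify", classify_rois(rois, mask))
  traces <- stage("traces", extract_traces(stack, rois))
  stage("traces", write_traces_csv(traces, file.path(cfg$out_dir, "traces.csv")))
  class_by_label <- stats::setNames(classes$cell_class, classes$roi)
  analysis <- stage("features",
                    analyze_traces(traces,
                                   smooth_window = cfg$trace$smooth_window,
                                   prominence_min = cfg$trace$prominence_min,
                                   classes = class_by_label))
  utils::write.csv(analysis$features,
                   file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
  stage("rois", write_rois_json(rois, file.path(cfg$out_dir, "rois.json"),
                                classes = class_by_label))
  stage("mask", write_image_tiff(mask$gb_mask * 255,
                                 file.path(cfg$out_dir, "gb_mask.tif")))

  # active neuronal area on the neuron side of the recording
  area_res <- stage("area", {
    sides <- split_stack(stack, mask)
    mean_img <- rowSums(sides$neuron$data, dims = 2) / dim(stack$data)[3]
    a_total <- total_stained_area(mean_img, threshold = cfg$area$threshold,
                                  min_size = cfg$area$min_size)
    neuron_labels <- classes$roi[!is.na(classes$cell_class) &
                                 classes$cell_class == "neuron"]
    a_active <- sum(vapply(rois$rois, function(r)
      if (r$label %in% neuron_labels) r$area else 0, numeric(1)))
    if (a_total > 0 && a_active <= a_total)
      active_area_percent(a_active, a_total)
    else {
      warning("active neuronal area undefined for this field")
      NULL
    }
  })
  if (!is.null(area_res))
    utils::write.csv(data.frame(a_active = area_res$a_active,
                                a_total = area_res$a_total,
                                percent = area_res$percent),
                     file.path(cfg$out_dir, "activity_area.csv"),
                     row.names = FALSE)

  stats_res <- NULL
  if (isTRUE(cfg$stats$enabled)) {
    stats_res <- stage("stats", {
      ft <- analysis$features
      out <- list()
      for (feat in cfg$stats$features) {
        a <- ft[[feat]][ft$cell_class %in% "neuron"]
        b <- ft[[feat]][ft$cell_class %in% "gb"]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) >= 2 && length(b) >= 2)
          out[[feat]] <- compare_two(a, b, group_names = c("neuron", "gb"))
      }
      out
    })
    if (length(stats_res)) {
      sr <- lapply(stats_res, function(s)
        list(test = s$test, statistic = s$statistic, p_value = s$p_value,
             stars = s$stars))
      jsonlite::write_json(sr, file.path(cfg$out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("calcimetry")),
    r_version = R.version.string,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(features = analysis$features, rois = rois,
                 classes = classes, area = area_res, stats = stats_res,
                 truth = truth, manifest = manifest, out_dir = cfg$out_dir))
}
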