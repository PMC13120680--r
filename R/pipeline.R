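# End-to-end pipeline driver: one YAML config in, reproducible CSV/TIFF
# outputs and a JSON run manifest out.

parse_quant_config <- function(q) {
  q <- q %||% list()
  quant_config(
    n_directions = q$n_directions %||% 6L,
    ray_length = q$ray_length %||% 25,
    top_fraction = q$top_fraction %||% 0.2,
    ray_origin = q$ray_origin %||% "centroid",
    sample_step = q$sample_step %||% 1,
    normalize_to_dapi = q$normalize_to_dapi %||% TRUE,
    min_area = q$min_area %||% 0L
  )
}

parse_channel_specs <- function(channels) {
  specs <- lapply(channels, function(ch) {
    channel_spec(ch$role,
                 population_model(weights = unlist(ch$weights %||% 1),
                                  means = unlist(ch$means),
                                  sds = unlist(ch$sds %||%
                                                 rep(0, length(unlist(ch$means))))))
  })
  names(specs) <- names(channels)
  specs
}

parse_field_spec <- function(synth, seed) {
  field_spec(
    image_shape = unlist(synth$image_shape %||% c(192L, 192L)),
    n_cells = synth$n_cells %||% 40L,
    nucleus_radius_range = unlist(synth$nucleus_radius_range %||% c(6, 9)),
    membrane_ring_radius = synth$membrane_ring_radius %||% 14,
    membrane_ring_width = synth$membrane_ring_width %||% 3,
    background_level = synth$background_level %||% 0,
    noise_sd = synth$noise_sd %||% 0,
    channel_specs = parse_channel_specs(synth$channels),
    cytoplasm_level = synth$cytoplasm_level %||% 0,
    min_spacing = synth$min_spacing %||% NULL,
    shared_population_channels = unlist(synth$shared_population_channels),
    seed = seed
  )
}

parse_gates <- function(gates) {
  lapply(gates, function(g) {
    gate_spec(g$channel_x, g$channel_y, g$threshold_x, g$threshold_y,
              source = g$source %||% "manual")
  })
}

# run one stage; on error leave a <stage>.partial marker and abort with the
# stage name
run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    file.create(file.path(out_dir, paste0(stage, ".partial")))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(verbose, ...) if (verbose) message("[streakquant] ", ...)

#' Run the full pipeline from a single configuration
#'
#' Orchestrates generation (synth modes) or loading (file modes),
#' segmentation, per-cell quantification, gating and statistics, writing all
#' stage outputs plus a JSON manifest to the configured output directory.
#' Reruns with the same configuration and inputs reproduce identical CSVs.
#'
#' Modes: `synth-fixed` (generate fields, quantify, gate),
#' `synth-live` (generate a time lapse, compute ratio time series),
#' `fixed` (quantify images + masks/probability maps from disk),
#' `live` (ratio time series from a stack + masks on disk).
#'
#' @param config path to a YAML file or an equivalent named list. See the
#'   example configuration shipped at
#'   `system.file("extdata", "example_synth_fixed.yaml", package = "streakquant")`.
#' @param output_dir overrides the configured output directory.
#' @param seed overrides the configured seed.
#' @param verbose emit one log line per stage.
#' @return the manifest, invisibly (list of inputs, outputs, counts, seed and
#'   package version; also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% stop("config must declare a 'mode'")
  out_dir <- output_dir %||% config$output_dir %||%
    stop("config must declare 'output_dir'")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = mode, seed = seed,
                   package_version = as.character(utils::packageVersion("streakquant")),
                   config = config, outputs = list(), counts = list())

  if (mode %in% c("synth-fixed", "fixed")) {
    qc <- parse_quant_config(config$quant)
    records <- run_stage("quantify", out_dir, {
      if (mode == "synth-fixed") {
        quantify_synth_fixed(config, qc, seed, out_dir, verbose)
      } else {
        quantify_fixed_files(config, qc, out_dir, verbose)
      }
    })
    cells_path <- file.path(out_dir, "cells_all.csv")
    utils::write.csv(records, cells_path, row.names = FALSE)
    manifest$outputs$cells <- cells_path
    manifest$counts$n_cells <- nrow(records)
    manifest$counts$n_images <- length(unique(records$image_id))
    log_stage(verbose, "quantified ", nrow(records), " cells from ",
              manifest$counts$n_images, " image(s)")
    gates <- parse_gates(config$gates %||% list())
    if (length(gates)) {
      paths <- run_stage("gating", out_dir, {
        g <- gates[[1L]]
        channels <- unique(c(g$channel_x, g$channel_y))
        cmp <- lapply(config$comparisons %||% NULL, unlist)
        if (!length(cmp)) cmp <- NULL
        export_gating_tables(
          records, g, channels, out_dir, comparisons = cmp,
          n_comparisons = config$n_comparisons %||% NULL
        )
      })
      manifest$outputs <- c(manifest$outputs, as.list(paths))
      log_stage(verbose, "gating tables written")
    }
  } else if (mode %in% c("synth-live", "live")) {
    ratios <- run_stage("live_ratios", out_dir, {
      if (mode == "synth-live") {
        live_from_synth(config, seed, out_dir, verbose)
      } else {
        live_from_files(config, verbose)
      }
    })
    rpath <- file.path(out_dir, "live_ratios.csv")
    utils::write.csv(ratios, rpath, row.names = FALSE)
    manifest$outputs$live_ratios <- rpath
    manifest$counts$n_timepoints <- length(unique(ratios$timepoint))
    manifest$counts$n_positions <- length(unique(ratios$image_id))
    # per-position values plus a mean +/- SEM aggregate across positions
    if (manifest$counts$n_positions >= 2L) {
      agg <- do.call(rbind, lapply(
        split(ratios, list(ratios$timepoint, ratios$channel)),
        function(r) data.frame(timepoint = r$timepoint[1L],
                               channel = r$channel[1L],
                               mean_ratio = mean(r$ratio),
                               sem_ratio = sem(r$ratio),
                               n_positions = nrow(r))))
      apath <- file.path(out_dir, "live_ratios_aggregate.csv")
      utils::write.csv(agg[order(agg$channel, agg$timepoint), ], apath,
                       row.names = FALSE)
      manifest$outputs$live_ratios_aggregate <- apath
    }
    log_stage(verbose, "live ratios written for ",
              manifest$counts$n_positions, " position(s)")
  } else {
    stop("unknown mode '", mode, "'")
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest$outputs$manifest <- manifest_path
  invisible(manifest)
}

# synth-fixed: generate n_images per condition, write images + truth, segment
# (truth mask or fallback), quantify, tag condition
quantify_synth_fixed <- function(config, qc, seed, out_dir, verbose) {
  synth <- config$synth %||% stop("synth-fixed mode needs a 'synth' block")
  n_images <- synth$n_images %||% 1L
  conditions <- config$conditions %||% list(default = list())
  seg <- config$segmentation %||% list()
  use <- seg$use %||% "truth"
  img_dir <- file.path(out_dir, "images")
  all <- list()
  k <- 0L
  for (cond in names(conditions)) {
    synth_c <- utils::modifyList(synth, conditions[[cond]] %||% list())
    for (i in seq_len(n_images)) {
      k <- k + 1L
      fs <- parse_field_spec(synth_c, seed = seed + k)
      field <- generate_fixed_field(fs)
      image_id <- sprintf("%s_img%02d", cond, i)
      write_fixed_field(field, img_dir, prefix = image_id)
      mask <- if (use == "fallback") {
        dapi <- channels_by_role(field$image, "dapi")[1L]
        fallback_segment_nuclei(get_channel(field$image, dapi),
                                threshold_mode = seg$threshold_mode %||% "otsu",
                                threshold = seg$threshold %||% NULL,
                                min_area = seg$min_area %||% 50L)
      } else field$mask
      rec <- quantify_cells(field$image, mask, qc, image_id = image_id)
      rec$condition <- cond
      all[[image_id]] <- rec
      log_stage(verbose, image_id, ": ", nrow(rec), " cells")
    }
  }
  do.call(rbind, all)
}

# fixed: quantify images listed in the config, each with a mask or probmap
quantify_fixed_files <- function(config, qc, out_dir, verbose) {
  images <- config$images %||% stop("fixed mode needs an 'images' list")
  roles <- unlist(config$channels) %||%
    stop("fixed mode needs a 'channels' role map")
  seg <- config$segmentation %||% list()
  all <- list()
  for (im in images) {
    if (is.null(im$path) || !file.exists(im$path)) {
      stop("image file not found: ", im$path %||% "<missing path>")
    }
    image <- read_image_tiff(im$path, roles, n_z = im$n_z %||% 1L)
    mask <- if (!is.null(im$mask)) {
      if (!file.exists(im$mask)) stop("mask file not found: ", im$mask)
      read_labels_tiff(im$mask)
    } else if (!is.null(im$probmap)) {
      if (!file.exists(im$probmap)) stop("probability map not found: ", im$probmap)
      probmap_to_labels(read_probmap_tiff(im$probmap),
                        threshold = seg$threshold %||% 0.5,
                        min_area = seg$min_area %||% 50L)
    } else {
      dapi <- channels_by_role(image, "dapi")[1L]
      fallback_segment_nuclei(get_channel(image, dapi),
                              min_area = seg$min_area %||% 50L)
    }
    rec <- quantify_cells(image, mask, qc, image_id = im$id %||% basename(im$path))
    if (!is.null(im$condition)) rec$condition <- im$condition
    all[[length(all) + 1L]] <- rec
    log_stage(verbose, rec$image_id[1L], ": ", nrow(rec), " cells")
  }
  do.call(rbind, all)
}

# synth-live: generate positions and compute ratio time series
live_from_synth <- function(config, seed, out_dir, verbose) {
  synth <- config$synth %||% stop("synth-live mode needs a 'synth' block")
  live <- config$live %||% stop("synth-live mode needs a 'live' block")
  n_positions <- live$n_positions %||% 1L
  n_t <- live$n_timepoints %||% stop("live block needs 'n_timepoints'")
  traj_cfg <- live$trajectory %||% stop("live block needs 'trajectory' values")
  shifts <- lapply(live$shifts %||% stop("live block needs 'shifts'"), unlist)
  trajectory <- lapply(traj_cfg, function(v) {
    v <- unlist(v)
    if (length(v) != n_t) stop("trajectory length must equal n_timepoints")
    function(t) v[t]
  })
  out <- list()
  for (p in seq_len(n_positions)) {
    fs <- parse_field_spec(synth, seed = seed + p)
    gen <- generate_live_stack(fs, n_t, trajectory, shifts)
    out[[p]] <- ratio_timeseries(gen$stack, gen$membrane_mask, gen$cell_mask,
                                 max_shift = live$max_shift %||% 10L,
                                 image_id = sprintf("pos%02d", p))
    log_stage(verbose, "position ", p, " quantified")
  }
  do.call(rbind, out)
}

# live: stacks and masks from disk
live_from_files <- function(config, verbose) {
  images <- config$images %||% stop("live mode needs an 'images' list")
  roles <- unlist(config$channels) %||%
    stop("live mode needs a 'channels' role map")
  out <- list()
  for (im in images) {
    for (f in c(im$path, im$membrane_mask, im$cell_mask)) {
      if (is.null(f) || !file.exists(f)) {
        stop("live input file not found: ", f %||% "<missing path>")
      }
    }
    stack <- read_timeseries_tiff(im$path, roles, im$n_timepoints)
    out[[length(out) + 1L]] <- ratio_timeseries(
      stack,
      read_labels_tiff(im$membrane_mask, kind = "membrane"),
      read_labels_tiff(im$cell_mask, kind = "cell_nonmembrane"),
      max_shift = config$max_shift %||% 10L,
      image_id = im$id %||% basename(im$path)
    )
    log_stage(verbose, im$id %||% im$path, " quantified")
  }
  do.call(rbind, out)
}
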