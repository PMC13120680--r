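# Fixed-cell per-cell quantification: nuclear means, DAPI normalization and
# directional membrane-intensity profiling.

#' Quantification parameters
#'
#' Houses the tunables of the per-cell measurements. Defaults are the
#' standard directional-profiling settings: intensities sampled along six
#' equally spaced rays from the nuclear centroid, the top 20% of samples
#' within 25 pixels averaged per ray, and the per-cell signal taken as the
#' mean over rays.
#'
#' @param n_directions number of equally spaced rays (>= 1).
#' @param ray_length sampling extent along each ray, pixels (>= 1).
#' @param top_fraction fraction of retained samples averaged per ray,
#'   in (0, 1]; the count is `ceiling(top_fraction * m)` for `m` retained
#'   samples.
#' @param ray_origin `"centroid"` (rays measured from the nuclear centroid,
#'   the default) or `"edge"` (sampling starts just outside the nuclear
#'   boundary along each ray).
#' @param sample_step spacing of samples along a ray, pixels.
#' @param normalize_to_dapi if `TRUE`, nuclear marker means are also reported
#'   relative to the same cell's DAPI mean.
#' @param min_area cells with nuclei smaller than this are dropped before
#'   quantification.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(n_directions = 6L, ray_length = 25, top_fraction = 0.2,
                         ray_origin = c("centroid", "edge"), sample_step = 1,
                         normalize_to_dapi = TRUE, min_area = 0L) {
  ray_origin <- match.arg(ray_origin)
  if (n_directions < 1L) stop("n_directions must be >= 1")
  if (ray_length < 1) stop("ray_length must be >= 1")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  if (sample_step <= 0) stop("sample_step must be positive")
  structure(list(n_directions = as.integer(n_directions),
                 ray_length = ray_length, top_fraction = top_fraction,
                 ray_origin = ray_origin, sample_step = sample_step,
                 normalize_to_dapi = isTRUE(normalize_to_dapi),
                 min_area = as.integer(min_area)),
            class = "quant_config")
}

#' Mean nuclear intensity per cell
#'
#' Arithmetic mean of one channel over each label's pixels.
#'
#' @param channel numeric intensity matrix.
#' @param mask a nuclear [label_mask] aligned to the channel.
#' @return named numeric vector, one mean per label (names = labels); empty
#'   for an empty mask.
#' @export
nuclear_mean_intensity <- function(channel, mask) {
  stopifnot(is.matrix(channel), inherits(mask, "label_mask"))
  if (!identical(dim(channel), dim(mask$labels))) {
    stop("channel and mask shapes differ")
  }
  idx <- mask$labels > 0L
  if (!any(idx)) return(stats::setNames(numeric(), character()))
  m <- tapply(channel[idx], mask$labels[idx], mean)
  stats::setNames(as.numeric(m), names(m))
}

#' DAPI-relative normalization of nuclear marker means
#'
#' Divides each nuclear marker's per-cell mean by the same cell's DAPI mean,
#' correcting for staining and illumination variation. Cells with a
#' nonpositive DAPI mean cannot be normalized: their ratios are set to `NA`,
#' they are flagged in `qc_zero_dapi`, and a warning reports the count.
#'
#' @param records per-cell data.frame containing `<channel>_nuclear_mean`
#'   columns and a `<dapi_channel>_nuclear_mean` column.
#' @param channels nuclear marker channel names to normalize.
#' @param dapi_channel name of the DAPI channel.
#' @return `records` with `<channel>_dapi_norm` columns and a logical
#'   `qc_zero_dapi` column added.
#' @export
dapi_normalize <- function(records, channels, dapi_channel = "dapi") {
  dapi_col <- paste0(dapi_channel, "_nuclear_mean")
  if (!dapi_col %in% names(records)) {
    stop("records lack the DAPI mean column '", dapi_col, "'")
  }
  dapi <- records[[dapi_col]]
  bad <- !is.finite(dapi) | dapi <= 0
  for (ch in channels) {
    col <- paste0(ch, "_nuclear_mean")
    if (!col %in% names(records)) stop("records lack column '", col, "'")
    records[[paste0(ch, "_dapi_norm")]] <-
      ifelse(bad, NA_real_, records[[col]] / dapi)
  }
  records$qc_zero_dapi <- bad
  if (any(bad)) {
    warning(sum(bad), " cell(s) with nonpositive DAPI mean excluded from ",
            "normalization")
  }
  records
}

# sample positions for all (cell, direction, step) triples; angle 0 points
# along +col and angles increase towards +row (downwards on screen)
ray_sample_positions <- function(centroids, config, mask = NULL) {
  n_dir <- config$n_directions
  steps <- seq(config$sample_step, config$ray_length, by = config$sample_step)
  angles <- 2 * pi * (seq_len(n_dir) - 1L) / n_dir
  grid <- expand.grid(step = seq_along(steps), dir = seq_len(n_dir),
                      cell = seq_len(nrow(centroids)))
  d <- steps[grid$step]
  offset <- 0
  if (!is.null(mask) && config$ray_origin == "edge") {
    # per (cell, dir): first integer distance whose nearest pixel leaves the
    # cell's own nucleus label
    offset <- mapply(function(cell, dir) {
      r0 <- centroids$centroid_row[cell]; c0 <- centroids$centroid_col[cell]
      id <- centroids$cell_id[cell]
      th <- angles[dir]
      for (dd in seq_len(ceiling(config$ray_length))) {
        rr <- round(r0 + dd * sin(th)); cc <- round(c0 + dd * cos(th))
        if (rr < 1 || rr > nrow(mask$labels) || cc < 1 ||
            cc > ncol(mask$labels) || mask$labels[rr, cc] != id) {
          return(dd - 1)
        }
      }
      ceiling(config$ray_length)
    }, grid$cell, grid$dir)
  }
  data.frame(
    cell = grid$cell, dir = grid$dir,
    r = centroids$centroid_row[grid$cell] + (d + offset) * sin(angles[grid$dir]),
    c = centroids$centroid_col[grid$cell] + (d + offset) * cos(angles[grid$dir])
  )
}

#' Directional membrane-intensity profiling
#'
#' For each cell, fluorescence intensities are sampled along `n_directions`
#' equally spaced rays from the nuclear centroid (bilinear interpolation at
#' unit steps up to `ray_length` pixels; samples falling outside the image are
#' discarded). Per ray, the top `ceiling(top_fraction * m)` of the `m`
#' retained samples are averaged, and the cell's membrane signal is the mean
#' of the per-ray values over rays with at least one retained sample. Cells
#' whose rays all fall outside the image are flagged with `NA` and reported
#' in a warning.
#'
#' @param channel numeric membrane-channel matrix.
#' @param mask nuclear [label_mask] aligned to the channel (supplies the
#'   centroids).
#' @param config a [quant_config].
#' @return data.frame with `cell_id`, `membrane_signal` and per-direction
#'   columns `dir_1..dir_n` (NA for directions with no retained sample).
#' @export
directional_membrane_intensity <- function(channel, mask,
                                           config = quant_config()) {
  stopifnot(is.matrix(channel), inherits(mask, "label_mask"),
            inherits(config, "quant_config"))
  if (!identical(dim(channel), dim(mask$labels))) {
    stop("channel and mask shapes differ")
  }
  cen <- mask_centroids(mask)
  n_dir <- config$n_directions
  dir_cols <- paste0("dir_", seq_len(n_dir))
  if (!nrow(cen)) {
    out <- data.frame(cell_id = integer(), membrane_signal = numeric())
    out[dir_cols] <- numeric()
    return(out)
  }
  pos <- ray_sample_positions(cen, config,
                              mask = if (config$ray_origin == "edge") mask)
  pos$value <- bilinear_sample(channel, pos$r, pos$c)
  dirmat <- matrix(NA_real_, nrow(cen), n_dir)
  sp <- split(pos$value, list(dir = pos$dir, cell = pos$cell))
  for (cell in seq_len(nrow(cen))) {
    for (dir in seq_len(n_dir)) {
      v <- sp[[paste(dir, cell, sep = ".")]]
      v <- v[!is.na(v)]
      m <- length(v)
      if (m == 0L) next
      k <- top_k_count(config$top_fraction, m)
      dirmat[cell, dir] <- mean(sort(v, decreasing = TRUE)[seq_len(k)])
    }
  }
  signal <- rowMeans(dirmat, na.rm = TRUE)
  all_na <- !is.finite(signal)
  signal[all_na] <- NA_real_
  if (any(all_na)) {
    warning(sum(all_na), " cell(s) with all rays out of bounds excluded")
  }
  out <- data.frame(cell_id = cen$cell_id, membrane_signal = signal)
  out[dir_cols] <- as.data.frame(dirmat)
  out
}

#' Quantify every cell in one image
#'
#' Runs the fixed-cell measurements for a segmented field: maximum-intensity
#' projection if a z axis is present, per-cell nuclear means for the DAPI and
#' nuclear-marker channels, DAPI-relative normalization (optional), and
#' directional membrane profiling for each membrane-marker channel.
#'
#' @param image a [multichannel_image].
#' @param mask nuclear [label_mask] aligned to the image.
#' @param config a [quant_config].
#' @param image_id identifier recorded in every row.
#' @return data.frame, one row per cell: `image_id`, `cell_id`,
#'   `centroid_row`, `centroid_col`, `nucleus_area`,
#'   `<channel>_nuclear_mean` for DAPI/nuclear channels,
#'   `<channel>_dapi_norm` (if normalizing), `<channel>_membrane` and
#'   `<channel>_dir_1..n` for membrane channels.
#' @export
quantify_cells <- function(image, mask, config = quant_config(),
                           image_id = "image_1") {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(mask, "label_mask"))
  if (has_z(image)) image <- max_intensity_projection(image)
  cen <- mask_centroids(mask)
  if (config$min_area > 0L) cen <- cen[cen$area >= config$min_area, ]
  rec <- data.frame(image_id = rep(image_id, nrow(cen)),
                    cell_id = cen$cell_id,
                    centroid_row = cen$centroid_row,
                    centroid_col = cen$centroid_col,
                    nucleus_area = cen$area)
  nuclear <- c(channels_by_role(image, "dapi"),
               channels_by_role(image, "nuclear_marker"))
  for (ch in nuclear) {
    m <- nuclear_mean_intensity(get_channel(image, ch), mask)
    rec[[paste0(ch, "_nuclear_mean")]] <-
      as.numeric(m[as.character(rec$cell_id)])
  }
  dapi <- channels_by_role(image, "dapi")
  markers <- channels_by_role(image, "nuclear_marker")
  if (config$normalize_to_dapi && length(dapi) == 1L && length(markers)) {
    rec <- dapi_normalize(rec, markers, dapi_channel = dapi)
  }
  for (ch in channels_by_role(image, "membrane_marker")) {
    dmi <- directional_membrane_intensity(get_channel(image, ch), mask, config)
    dmi <- dmi[match(rec$cell_id, dmi$cell_id), ]
    rec[[paste0(ch, "_membrane")]] <- dmi$membrane_signal
    dcols <- grep("^dir_", names(dmi), value = TRUE)
    rec[paste0(ch, "_", dcols)] <- dmi[dcols]
  }
  rec
}
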