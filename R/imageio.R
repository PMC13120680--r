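# TIFF input/output and mask construction.
#
# Intensity images are serialized as multipage 16-bit TIFF at one grey level
# per intensity unit (values rounded to integers in [0, 65535]); probability
# maps as single-page 32-bit float TIFF in [0, 1]; label masks as uint16.

#' Write a multichannel image as multipage 16-bit TIFF
#'
#' One page per channel; for z-stacks the channel index varies fastest
#' (page = (z - 1) * n_channels + channel). Intensities are rounded to the
#' nearest integer grey level; values must lie in [0, 65535].
#'
#' @param image a [multichannel_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  d <- dim(image$pixels)
  if (max(image$pixels) > 65535) {
    stop("intensities exceed the 16-bit range [0, 65535]")
  }
  nz <- if (length(d) == 4L) d[4L] else 1L
  pages <- vector("list", d[3L] * nz)
  i <- 0L
  for (z in seq_len(nz)) {
    for (ch in seq_len(d[3L])) {
      i <- i + 1L
      pg <- if (length(d) == 4L) image$pixels[, , ch, z] else image$pixels[, , ch]
      pages[[i]] <- round(pg) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multipage 16-bit TIFF as a multichannel image
#'
#' @param path file written by [write_image_tiff()] (or any multipage TIFF
#'   with the same page order).
#' @param channel_roles named role vector, as in [multichannel_image()].
#' @param n_z number of z slices (pages must equal `length(channel_roles) * n_z`).
#' @return a [multichannel_image].
#' @export
read_image_tiff <- function(path, channel_roles, n_z = 1L) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channel_roles)
  if (length(pages) != nc * n_z) {
    stop("expected ", nc * n_z, " pages in ", path, ", found ", length(pages))
  }
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  px <- if (n_z > 1L) array(0, c(H, W, nc, n_z)) else array(0, c(H, W, nc))
  i <- 0L
  for (z in seq_len(n_z)) {
    for (ch in seq_len(nc)) {
      i <- i + 1L
      pg <- round(pages[[i]] * 65535)
      if (n_z > 1L) px[, , ch, z] <- pg else px[, , ch] <- pg
    }
  }
  multichannel_image(px, channel_roles, source_path = path)
}

#' Write / read a label mask as uint16 TIFF
#'
#' @param mask a [label_mask] (labels must be < 65536).
#' @param path file path.
#' @return `path` invisibly, or the [label_mask] read back.
#' @export
write_labels_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("labels exceed uint16 range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @param kind mask kind, as in [label_mask()].
#' @export
read_labels_tiff <- function(path, kind = "nuclear") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- tiff::readTIFF(path)
  label_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)), kind)
}

#' Write / read a pixel-probability map as float32 TIFF
#'
#' Probability maps (e.g. exported from a pixel classifier such as ilastik)
#' hold per-pixel foreground probabilities in [0, 1].
#'
#' @param prob numeric matrix in [0, 1].
#' @param path file path.
#' @export
write_probmap_tiff <- function(prob, path) {
  stopifnot(is.matrix(prob))
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  tiff::writeTIFF(prob, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_probmap_tiff
#' @export
read_probmap_tiff <- function(path) {
  if (!file.exists(path)) stop("probability map not found: ", path)
  m <- tiff::readTIFF(path)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Write / read a live time series as multipage 16-bit TIFF
#'
#' Pages are ordered frame-major with the channel index varying fastest
#' (page = (t - 1) * n_channels + channel).
#'
#' @param stack an [mc_timeseries].
#' @param path file path.
#' @export
write_timeseries_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "mc_timeseries"))
  pages <- list()
  for (fr in stack$frames) {
    d <- dim(fr$pixels)
    if (max(fr$pixels) > 65535) stop("intensities exceed the 16-bit range")
    for (ch in seq_len(d[3L])) {
      pages[[length(pages) + 1L]] <- round(fr$pixels[, , ch]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_timeseries_tiff
#' @param channel_roles named role vector, as in [multichannel_image()].
#' @param n_timepoints number of frames stored in the file.
#' @export
read_timeseries_tiff <- function(path, channel_roles, n_timepoints) {
  if (!file.exists(path)) stop("time series file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channel_roles)
  if (length(pages) != nc * n_timepoints) {
    stop("expected ", nc * n_timepoints, " pages in ", path,
         ", found ", length(pages))
  }
  frames <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) {
    px <- array(0, c(nrow(pages[[1L]]), ncol(pages[[1L]]), nc))
    for (ch in seq_len(nc)) {
      px[, , ch] <- round(pages[[(t - 1L) * nc + ch]] * 65535)
    }
    frames[[t]] <- multichannel_image(px, channel_roles, source_path = path)
  }
  mc_timeseries(frames)
}

# 8-connected component labelling by iterative minimum-label propagation:
# each foreground pixel starts with its row-major linear index and repeatedly
# takes the minimum over its 8-neighbourhood until a fixed point. Components
# end up labelled by their first pixel in row-major order, then renumbered
# densely 1..K in that order.
label_components8 <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  if (!any(fg)) return(matrix(0L, H, W))
  lab <- matrix(Inf, H, W)
  lab[fg] <- ((row(fg) - 1) * W + col(fg))[fg]
  shift_inf <- function(m, dy, dx) {
    out <- matrix(Inf, H, W)
    rd <- seq_len(H)[seq_len(H) - dy >= 1 & seq_len(H) - dy <= H]
    cd <- seq_len(W)[seq_len(W) - dx >= 1 & seq_len(W) - dx <= W]
    if (length(rd) && length(cd)) out[rd, cd] <- m[rd - dy, cd - dx]
    out
  }
  repeat {
    new <- lab
    for (dy in -1:1) {
      for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        new <- pmin(new, shift_inf(lab, dy, dx))
      }
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  firsts <- sort(unique(lab[fg]))
  out <- matrix(0L, H, W)
  out[fg] <- match(lab[fg], firsts)
  out
}

# drop components below min_area and renumber densely, preserving the
# row-major order of first pixels
filter_relabel <- function(labels, min_area) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(labels)
  sizes <- tabulate(labels[idx])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[idx] <- match(labels[idx], keep, nomatch = 0L)
  out
}

#' Convert a foreground-probability map to a nuclear label mask
#'
#' Thresholds the map, labels 8-connected foreground components 1..K in
#' row-major order of each component's first pixel, and removes components
#' smaller than `min_area` (remaining labels renumbered densely).
#'
#' @param prob numeric matrix of foreground probabilities in [0, 1].
#' @param threshold probability cutoff; pixels >= threshold are foreground.
#' @param min_area minimum component area in pixels.
#' @return a [label_mask] of kind `"nuclear"`.
#' @export
probmap_to_labels <- function(prob, threshold = 0.5, min_area = 50L) {
  stopifnot(is.matrix(prob))
  if (min(prob) < 0 || max(prob) > 1) {
    stop("probability values must lie in [0, 1]")
  }
  lab <- label_components8(prob >= threshold)
  label_mask(filter_relabel(lab, min_area), "nuclear")
}

#' Intensity-based nuclear segmentation fallback
#'
#' A simple DAPI segmenter for running the pipeline without an external pixel
#' classifier: global threshold (Otsu or fixed), distance-transform watershed
#' to split touching nuclei, 8-connected relabelling in row-major order and
#' small-object removal. It is a convenience, not a reimplementation of
#' trained pixel classification.
#'
#' @param dapi numeric intensity matrix (DAPI channel).
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param threshold intensity cutoff when `threshold_mode = "fixed"`.
#' @param min_area minimum nucleus area in pixels.
#' @param watershed_tolerance minimum object-height separation for the
#'   watershed split (in distance-transform units).
#' @return a [label_mask] of kind `"nuclear"`.
#' @export
fallback_segment_nuclei <- function(dapi, threshold_mode = c("otsu", "fixed"),
                                    threshold = NULL, min_area = 50L,
                                    watershed_tolerance = 1) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.matrix(dapi))
  rng <- range(dapi)
  if (threshold_mode == "otsu") {
    if (rng[2] <= rng[1]) {
      return(label_mask(matrix(0L, nrow(dapi), ncol(dapi)), "nuclear"))
    }
    norm <- (dapi - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1] + thr01 * (rng[2] - rng[1])
  } else if (is.null(threshold)) {
    stop("'threshold' is required when threshold_mode = 'fixed'")
  }
  fg <- dapi >= threshold
  if (!any(fg)) {
    return(label_mask(matrix(0L, nrow(dapi), ncol(dapi)), "nuclear"))
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))
  # renumber watershed objects in row-major first-pixel order
  idx <- which(ws > 0)
  ord <- order(((row(ws) - 1) * ncol(ws) + col(ws))[idx])
  firsts <- unique(ws[idx][ord])
  out <- matrix(0L, nrow(ws), ncol(ws))
  out[idx] <- match(ws[idx], firsts)
  label_mask(filter_relabel(out, min_area), "nuclear")
}
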