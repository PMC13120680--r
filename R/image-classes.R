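# Containers for multichannel images and label masks.
#
# Coordinate convention used throughout the package: (row, col), 1-based,
# origin at the top-left pixel, rows increasing downwards. All centroids,
# shifts and ray angles are expressed in this frame.

CHANNEL_ROLES <- c("dapi", "nuclear_marker", "membrane_marker", "caax")

#' Multichannel fluorescence image
#'
#' A named stack of co-registered intensity channels, optionally with a z
#' axis. Pixels are nonnegative intensities in arbitrary units.
#'
#' @param pixels numeric array, `(row, col, channel)` or
#'   `(row, col, channel, z)`, all values >= 0.
#' @param channel_roles named character vector mapping channel name to role,
#'   one of `"dapi"`, `"nuclear_marker"`, `"membrane_marker"`, `"caax"`.
#'   Order matches the channel axis of `pixels`.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param source_path provenance string (file the image came from, if any).
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(pixels, channel_roles, pixel_size = NULL,
                               source_path = "") {
  if (!is.array(pixels) || !(length(dim(pixels)) %in% c(3L, 4L))) {
    stop("'pixels' must be a (row, col, channel[, z]) array")
  }
  if (min(pixels) < 0) stop("pixel intensities must be nonnegative")
  nms <- names(channel_roles)
  if (is.null(nms) || anyDuplicated(nms)) {
    stop("'channel_roles' must be a named vector with unique channel names")
  }
  if (!all(channel_roles %in% CHANNEL_ROLES)) {
    stop("channel roles must be one of: ", paste(CHANNEL_ROLES, collapse = ", "))
  }
  if (dim(pixels)[3L] != length(channel_roles)) {
    stop("channel axis length (", dim(pixels)[3L],
         ") does not match channel_roles (", length(channel_roles), ")")
  }
  dimnames(pixels)[[3L]] <- nms
  structure(
    list(pixels = pixels, channel_roles = channel_roles,
         pixel_size = pixel_size, source_path = source_path),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<multichannel_image> ", d[1L], "x", d[2L], " px, ",
      d[3L], " channel(s)", if (length(d) == 4L) paste0(", ", d[4L], " z-slice(s)"),
      "\n", sep = "")
  cat("  channels:", paste0(names(x$channel_roles), " (", x$channel_roles, ")",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel as a 2D matrix (or 3D array for z-stacks)
#'
#' @param image a [multichannel_image].
#' @param name channel name.
#' @return numeric matrix `(row, col)`, or `(row, col, z)` array.
#' @export
get_channel <- function(image, name) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!name %in% names(image$channel_roles)) {
    stop("no channel named '", name, "'")
  }
  if (has_z(image)) image$pixels[, , name, ] else image$pixels[, , name]
}

#' @rdname get_channel
#' @param role a channel role; returns the names of all channels with it.
#' @export
channels_by_role <- function(image, role) {
  names(image$channel_roles)[image$channel_roles == role]
}

has_z <- function(image) length(dim(image$pixels)) == 4L

#' Maximum-intensity projection of a z-stack
#'
#' Collapses the z axis by taking, per channel, the elementwise maximum over
#' slices — the standard reduction applied to confocal stacks before per-cell
#' quantification. Projecting an image without a z axis is an error; a
#' single-slice stack projects to that slice.
#'
#' @param image a [multichannel_image] with a z axis.
#' @return a [multichannel_image] without a z axis; channel roles preserved.
#' @export
max_intensity_projection <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!has_z(image)) stop("image has no z axis to project")
  d <- dim(image$pixels)
  out <- array(0, d[1:3])
  for (ch in seq_len(d[3L])) {
    acc <- image$pixels[, , ch, 1L]
    if (d[4L] > 1L) {
      for (z in 2:d[4L]) acc <- pmax(acc, image$pixels[, , ch, z])
    }
    out[, , ch] <- acc
  }
  multichannel_image(out, image$channel_roles, image$pixel_size,
                     image$source_path)
}

#' Integer label mask
#'
#' An integer matrix aligned to an image: 0 is background, positive integers
#' label objects (nuclei, membrane regions, or non-membrane cell regions).
#'
#' @param labels integer matrix with values >= 0.
#' @param kind one of `"nuclear"`, `"membrane"`, `"cell_nonmembrane"`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, kind = c("nuclear", "membrane",
                                        "cell_nonmembrane")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  k <- setdiff(unique(as.vector(x$labels)), 0L)
  cat("<label_mask> ", nrow(x$labels), "x", ncol(x$labels), " px, ",
      length(k), " object(s), kind = ", x$kind, "\n", sep = "")
  invisible(x)
}

#' Per-label centroids and areas
#'
#' @param mask a [label_mask].
#' @return data.frame with `cell_id`, `centroid_row`, `centroid_col`,
#'   `area` (pixels), one row per label, ordered by label.
#' @export
mask_centroids <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(cell_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area = integer()))
  }
  ids <- lab[idx]
  rr <- row(lab)[idx]
  cc <- col(lab)[idx]
  area <- as.integer(tapply(ids, ids, length))
  data.frame(
    cell_id = as.integer(names(tapply(ids, ids, length))),
    centroid_row = as.numeric(tapply(rr, ids, mean)),
    centroid_col = as.numeric(tapply(cc, ids, mean)),
    area = area,
    row.names = NULL
  )
}

#' Multichannel time series
#'
#' An ordered sequence of co-registered [multichannel_image] frames from
#' live imaging.
#'
#' @param frames list of [multichannel_image], identical shapes and channels.
#' @param times numeric vector of acquisition times (defaults to 1..T).
#' @return an object of class `mc_timeseries`.
#' @export
mc_timeseries <- function(frames, times = seq_along(frames)) {
  stopifnot(length(frames) >= 1L, length(times) == length(frames),
            !is.unsorted(times))
  ok <- vapply(frames, inherits, logical(1), "multichannel_image")
  if (!all(ok)) stop("all frames must be multichannel_image objects")
  structure(list(frames = frames, times = times), class = "mc_timeseries")
}

#' @export
print.mc_timeseries <- function(x, ...) {
  cat("<mc_timeseries> ", length(x$frames), " timepoint(s)\n", sep = "")
  print(x$frames[[1L]])
  invisible(x)
}
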