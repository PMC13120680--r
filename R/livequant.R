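# Live-imaging branch: integer-pixel channel registration, background
# subtraction and per-image membrane/non-membrane intensity ratios over time.

#' Estimate the integer pixel shift between two channels
#'
#' Exhaustively scores every integer shift `(dy, dx)` with
#' `|dy|, |dx| <= max_shift` by the Pearson correlation of the two channels
#' over their overlap region, and returns the maximizer. Registration is at
#' integer-pixel resolution only; ties are broken by smallest `|dy| + |dx|`,
#' then row-major order (dy, then dx, ascending).
#'
#' @param reference,moving numeric matrices of identical shape. The returned
#'   shift is the translation that takes `reference` content onto `moving`
#'   (i.e. `moving[r + dy, c + dx]` matches `reference[r, c]`).
#' @param max_shift search radius in pixels.
#' @return object of class `alignment_shift`: list with `dy`, `dx`, `score`.
#' @export
estimate_channel_shift <- function(reference, moving, max_shift = 10L) {
  stopifnot(is.matrix(reference), is.matrix(moving), max_shift >= 0L)
  if (!identical(dim(reference), dim(moving))) {
    stop("reference and moving must have the same shape")
  }
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    stop("cannot correlate constant (zero-variance) input")
  }
  H <- nrow(reference); W <- ncol(reference)
  cand <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx), ]
  best <- list(dy = 0L, dx = 0L, score = -Inf)
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    rr <- max(1L, 1L - dy):min(H, H - dy)
    cc <- max(1L, 1L - dx):min(W, W - dx)
    if (!length(rr) || !length(cc)) next
    a <- as.vector(reference[rr, cc])
    b <- as.vector(moving[rr + dy, cc + dx])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    s <- stats::cor(a, b)
    if (s > best$score) best <- list(dy = dy, dx = dx, score = s)
  }
  if (!is.finite(best$score)) stop("no valid overlap found within max_shift")
  structure(list(dy = as.integer(best$dy), dx = as.integer(best$dx),
                 score = best$score), class = "alignment_shift")
}

#' @export
print.alignment_shift <- function(x, ...) {
  cat("<alignment_shift> dy =", x$dy, ", dx =", x$dx,
      ", correlation =", signif(x$score, 4), "\n")
  invisible(x)
}

#' Subtract the background level of a channel
#'
#' The background region is the complement of all supplied masks; its median
#' is subtracted from every pixel and the result is clipped at zero (the
#' median is robust to bright outliers in the background region).
#'
#' @param channel numeric intensity matrix.
#' @param masks a [label_mask] or list of them; pixels labelled in any mask
#'   are excluded from the background region.
#' @return background-subtracted matrix (attribute `background_estimate`
#'   holds the subtracted median).
#' @export
subtract_background <- function(channel, masks) {
  stopifnot(is.matrix(channel))
  if (inherits(masks, "label_mask")) masks <- list(masks)
  fg <- Reduce(`|`, lapply(masks, function(m) {
    if (!identical(dim(m$labels), dim(channel))) {
      stop("mask and channel shapes differ")
    }
    m$labels > 0L
  }))
  bg <- !fg
  if (!any(bg)) stop("background region is empty")
  med <- stats::median(channel[bg])
  out <- channel - med
  out[out < 0] <- 0
  attr(out, "background_estimate") <- med
  out
}

#' Membrane to non-membrane intensity ratio of one image
#'
#' The per-image live readout: mean intensity over the membrane mask divided
#' by mean intensity over the non-membrane cell mask, both computed after
#' background subtraction (the caller subtracts).
#'
#' @param channel numeric intensity matrix (background-subtracted).
#' @param membrane_mask,nonmembrane_mask disjoint nonempty [label_mask]s
#'   aligned to the channel.
#' @param image_id,timepoint,channel_name identifiers recorded in the result.
#' @return one-row data.frame: `image_id`, `timepoint`, `channel`, `ratio`,
#'   `mean_membrane_intensity`, `mean_nonmembrane_intensity`,
#'   `n_membrane_px`, `n_cell_px`. A nonpositive denominator yields an `NA`
#'   ratio with a warning.
#' @export
membrane_ratio <- function(channel, membrane_mask, nonmembrane_mask,
                           image_id = "image_1", timepoint = 1L,
                           channel_name = "channel") {
  stopifnot(is.matrix(channel), inherits(membrane_mask, "label_mask"),
            inherits(nonmembrane_mask, "label_mask"))
  if (!identical(dim(channel), dim(membrane_mask$labels)) ||
      !identical(dim(channel), dim(nonmembrane_mask$labels))) {
    stop("masks and channel shapes differ")
  }
  mm <- membrane_mask$labels > 0L
  nm <- nonmembrane_mask$labels > 0L
  if (!any(mm) || !any(nm)) stop("membrane and non-membrane masks must be nonempty")
  if (any(mm & nm)) stop("membrane and non-membrane masks must be disjoint")
  mean_m <- mean(channel[mm])
  mean_n <- mean(channel[nm])
  ratio <- if (mean_n > 0) mean_m / mean_n else {
    warning("nonpositive non-membrane mean; ratio flagged NA")
    NA_real_
  }
  data.frame(image_id = image_id, timepoint = timepoint,
             channel = channel_name, ratio = ratio,
             mean_membrane_intensity = mean_m,
             mean_nonmembrane_intensity = mean_n,
             n_membrane_px = sum(mm), n_cell_px = sum(nm))
}

#' Membrane-ratio time series for a live stack
#'
#' Orchestrates the live branch for one imaging position: inter-channel
#' shifts are estimated once at the first timepoint against the reference
#' (CAAX) channel and applied to all frames, background is subtracted from
#' each membrane-protein channel per frame (background = complement of the
#' two cell masks), and the membrane/non-membrane ratio is computed per
#' timepoint and channel.
#'
#' @param stack an [mc_timeseries].
#' @param membrane_mask,nonmembrane_mask [label_mask]s in the reference frame.
#' @param reference_channel name of the reference channel (default: the caax
#'   channel).
#' @param channels membrane channels to quantify (default: all
#'   `membrane_marker` channels).
#' @param max_shift registration search radius, pixels.
#' @param image_id identifier recorded in every row.
#' @return tidy data.frame, one row per timepoint per channel, with the
#'   [membrane_ratio()] columns plus `shift_dy` and `shift_dx`.
#' @export
ratio_timeseries <- function(stack, membrane_mask, nonmembrane_mask,
                             reference_channel = NULL, channels = NULL,
                             max_shift = 10L, image_id = "image_1") {
  stopifnot(inherits(stack, "mc_timeseries"))
  first <- stack$frames[[1L]]
  reference_channel <- reference_channel %||%
    channels_by_role(first, "caax")[1L]
  if (is.na(reference_channel) || is.null(reference_channel)) {
    stop("no reference (caax) channel found")
  }
  channels <- channels %||% channels_by_role(first, "membrane_marker")
  if (!length(channels)) stop("no membrane channels to quantify")
  ref_img <- get_channel(first, reference_channel)
  shifts <- lapply(channels, function(ch) {
    estimate_channel_shift(ref_img, get_channel(first, ch), max_shift)
  })
  names(shifts) <- channels
  masks <- list(membrane_mask, nonmembrane_mask)
  out <- vector("list", length(stack$frames) * length(channels))
  i <- 0L
  for (t in seq_along(stack$frames)) {
    for (ch in channels) {
      i <- i + 1L
      s <- shifts[[ch]]
      img <- get_channel(stack$frames[[t]], ch)
      # undo the estimated shift to bring the channel into the reference frame
      aligned <- apply_pixel_shift(img, -s$dy, -s$dx)
      corrected <- subtract_background(aligned, masks)
      row <- membrane_ratio(corrected, membrane_mask, nonmembrane_mask,
                            image_id = image_id, timepoint = stack$times[t],
                            channel_name = ch)
      row$shift_dy <- s$dy
      row$shift_dx <- s$dx
      out[[i]] <- row
    }
  }
  do.call(rbind, out)
}
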