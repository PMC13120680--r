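# Synthetic microscopy fields with per-cell ground truth.
#
# The generator emulates the fields this pipeline is built to quantify:
# DAPI-like nuclear disks, nuclear fate-marker channels with mixture
# populations, ring-like membrane signal for cadherin channels, a CAAX-like
# membrane channel for live mode, additive background and zero-truncated
# Gaussian noise, and (live mode) known integer inter-channel pixel shifts.
# Every draw is recorded so each downstream stage has an exact oracle.

#' Mixture population model for one channel
#'
#' Per-cell true intensity (nuclear channels) or membrane amplitude (membrane
#' channels) is drawn from a Gaussian mixture over cell populations, emulating
#' the mixed-fate cultures the quadrant gates are applied to.
#'
#' @param weights component probabilities, summing to 1.
#' @param means component mean intensities (>= 0).
#' @param sds component standard deviations (>= 0).
#' @return an object of class `population_model`.
#' @export
population_model <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights < 0) || any(means < 0) || any(sds < 0)) {
    stop("weights, means and sds must be nonnegative")
  }
  structure(list(weights = weights, means = means, sds = sds),
            class = "population_model")
}

#' One channel of a synthetic field
#'
#' @param role channel role: `"dapi"`, `"nuclear_marker"`,
#'   `"membrane_marker"` or `"caax"`.
#' @param model a [population_model] for the per-cell intensity or amplitude.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(role = c("dapi", "nuclear_marker", "membrane_marker",
                                  "caax"),
                         model) {
  role <- match.arg(role)
  stopifnot(inherits(model, "population_model"))
  structure(list(role = role, model = model), class = "channel_spec")
}

#' Specification of a synthetic field of cells
#'
#' @param image_shape `(height, width)` in pixels.
#' @param n_cells number of cells to place (>= 1).
#' @param nucleus_radius_range `(min, max)` nuclear radius, pixels.
#' @param membrane_ring_radius distance from the nucleus centroid to the cell
#'   boundary ring, pixels; must exceed the maximum nucleus radius.
#' @param membrane_ring_width width of the membrane ring, pixels.
#' @param background_level additive background intensity.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (truncated at zero after addition).
#' @param channel_specs named list of [channel_spec]; names become channel
#'   names.
#' @param cytoplasm_level intensity of membrane-marker channels inside the
#'   cell (between nucleus and ring); used mainly in live mode where the
#'   membrane/non-membrane ratio needs a nonzero interior signal.
#' @param min_spacing optional minimum centroid-to-centroid distance in
#'   pixels. The default (`NULL`) only prevents nuclear overlap, as in a
#'   confluent culture; set it to at least `ray_length +
#'   membrane_ring_radius` when a field with well-isolated membranes is
#'   needed (directional profiling does not mask out neighbouring cells, so
#'   at confluent densities a ray can sample a neighbour's membrane).
#' @param shared_population_channels character vector of channel names that
#'   share a single latent population label per cell (their models must have
#'   identical component weights), so correlated co-expression — e.g. a joint
#'   quadrant design — is expressible.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(image_shape = c(256L, 256L), n_cells = 50L,
                       nucleus_radius_range = c(6, 9),
                       membrane_ring_radius = 15, membrane_ring_width = 3,
                       background_level = 0, noise_sd = 0,
                       channel_specs, cytoplasm_level = 0,
                       min_spacing = NULL,
                       shared_population_channels = NULL, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L))
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (any(nucleus_radius_range <= 0) || membrane_ring_radius <= 0 ||
      membrane_ring_width <= 0) {
    stop("radii and widths must be positive")
  }
  if (nucleus_radius_range[1] > nucleus_radius_range[2]) {
    stop("nucleus_radius_range must be (min, max)")
  }
  if (membrane_ring_radius <= nucleus_radius_range[2]) {
    stop("membrane_ring_radius must exceed the maximum nucleus radius")
  }
  if (noise_sd < 0 || background_level < 0 || cytoplasm_level < 0) {
    stop("background_level, noise_sd and cytoplasm_level must be >= 0")
  }
  if (missing(channel_specs) || !length(channel_specs) ||
      is.null(names(channel_specs))) {
    stop("'channel_specs' must be a named list of channel_spec objects")
  }
  ok <- vapply(channel_specs, inherits, logical(1), "channel_spec")
  if (!all(ok)) stop("all channel_specs entries must be channel_spec objects")
  shared_population_channels <- shared_population_channels %||% character()
  if (length(shared_population_channels)) {
    miss <- setdiff(shared_population_channels, names(channel_specs))
    if (length(miss)) stop("unknown shared channels: ", paste(miss, collapse = ", "))
    w <- lapply(channel_specs[shared_population_channels],
                function(cs) cs$model$weights)
    if (length(unique(vapply(w, length, integer(1)))) != 1L ||
        max(vapply(w, function(x) max(abs(x - w[[1L]])), numeric(1))) > 1e-9) {
      stop("shared-population channels must have identical component weights")
    }
  }
  structure(list(
    image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
    nucleus_radius_range = nucleus_radius_range,
    membrane_ring_radius = membrane_ring_radius,
    membrane_ring_width = membrane_ring_width,
    background_level = background_level, noise_sd = noise_sd,
    channel_specs = channel_specs, cytoplasm_level = cytoplasm_level,
    min_spacing = min_spacing,
    shared_population_channels = shared_population_channels,
    seed = as.integer(seed)
  ), class = "field_spec")
}

# rejection-sample non-overlapping nucleus centres; error after max_attempts
# per cell, naming the density that failed
place_cells <- function(spec, max_attempts = 10000L) {
  H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
  margin <- spec$membrane_ring_radius + spec$membrane_ring_width / 2 + 1
  if (H - 2 * margin <= 0 || W - 2 * margin <= 0) {
    stop("image too small for the requested cell geometry")
  }
  radii <- runif(spec$n_cells, spec$nucleus_radius_range[1],
                 spec$nucleus_radius_range[2])
  rows <- numeric(spec$n_cells); cols <- numeric(spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- runif(1, margin, H - margin)
      c <- runif(1, margin, W - margin)
      min_d <- radii[seq_len(i - 1L)] + radii[i] + 1
      if (!is.null(spec$min_spacing)) min_d <- pmax(min_d, spec$min_spacing)
      if (i == 1L ||
          all(sqrt((rows[seq_len(i - 1L)] - r)^2 +
                   (cols[seq_len(i - 1L)] - c)^2) > min_d)) {
        rows[i] <- r; cols[i] <- c; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place cell ", i, " of ", spec$n_cells, " after ",
           max_attempts, " attempts: density ",
           signif(spec$n_cells / (H * W), 3), " cells/px^2 too high for ",
           H, "x", W, " image")
    }
  }
  data.frame(cell_id = seq_len(spec$n_cells), centroid_row = rows,
             centroid_col = cols, nucleus_radius = radii)
}

# pixel index sets for one cell: nucleus disk, membrane annulus, interior
cell_regions <- function(cells, H, W, ring_radius, ring_width) {
  lapply(seq_len(nrow(cells)), function(i) {
    r0 <- cells$centroid_row[i]; c0 <- cells$centroid_col[i]
    rad <- cells$nucleus_radius[i]
    outer_r <- ring_radius + ring_width / 2
    rr <- max(1L, floor(r0 - outer_r)):min(H, ceiling(r0 + outer_r))
    cc <- max(1L, floor(c0 - outer_r)):min(W, ceiling(c0 + outer_r))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    lin <- outer(rr, (cc - 1L) * H, `+`)  # column-major linear indices
    list(
      nucleus = lin[d <= rad],
      annulus = lin[abs(d - ring_radius) <= ring_width / 2],
      interior = lin[d < ring_radius - ring_width / 2]
    )
  })
}

# draw latent population labels and per-cell values for every channel
draw_populations <- function(spec) {
  n <- spec$n_cells
  shared <- spec$shared_population_channels
  shared_lab <- NULL
  if (length(shared)) {
    w <- spec$channel_specs[[shared[1L]]]$model$weights
    shared_lab <- sample.int(length(w), n, replace = TRUE, prob = w)
  }
  out <- list()
  for (nm in names(spec$channel_specs)) {
    m <- spec$channel_specs[[nm]]$model
    lab <- if (nm %in% shared) shared_lab else {
      sample.int(length(m$weights), n, replace = TRUE, prob = m$weights)
    }
    val <- pmax(0, rnorm(n, m$means[lab], m$sds[lab]))
    out[[nm]] <- list(label = lab, value = val)
  }
  out
}

render_field <- function(spec, cells, pops, amplitude_override = NULL) {
  H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
  regions <- cell_regions(cells, H, W, spec$membrane_ring_radius,
                          spec$membrane_ring_width)
  nms <- names(spec$channel_specs)
  px <- array(0, c(H, W, length(nms)))
  for (k in seq_along(nms)) {
    role <- spec$channel_specs[[k]]$role
    ch <- matrix(spec$background_level, H, W)
    if (role %in% c("dapi", "nuclear_marker")) {
      for (i in seq_len(nrow(cells))) {
        ch[regions[[i]]$nucleus] <- ch[regions[[i]]$nucleus] +
          pops[[nms[k]]]$value[i]
      }
    } else {  # membrane_marker or caax: ring signal, optional interior level
      amp <- matrix(0, H, W)
      cyt <- matrix(0, H, W)
      a <- if (!is.null(amplitude_override) && nms[k] %in% names(amplitude_override)) {
        rep(amplitude_override[[nms[k]]], nrow(cells))
      } else pops[[nms[k]]]$value
      for (i in seq_len(nrow(cells))) {
        an <- regions[[i]]$annulus
        amp[an] <- pmax(amp[an], a[i])
        if (spec$cytoplasm_level > 0 && role == "membrane_marker") {
          inr <- regions[[i]]$interior
          cyt[inr] <- pmax(cyt[inr], spec$cytoplasm_level)
        }
      }
      ch <- ch + amp + cyt
    }
    if (spec$noise_sd > 0) {
      ch <- ch + rnorm(H * W, 0, spec$noise_sd)
      ch[ch < 0] <- 0
    }
    px[, , k] <- ch
  }
  roles <- vapply(spec$channel_specs, `[[`, character(1), "role")
  names(roles) <- nms
  list(image = multichannel_image(px, roles, source_path = "synthetic"),
       regions = regions)
}

build_truth <- function(spec, cells, pops) {
  truth <- cells
  for (nm in names(spec$channel_specs)) {
    role <- spec$channel_specs[[nm]]$role
    truth[[paste0(nm, "_population")]] <- pops[[nm]]$label
    col <- if (role %in% c("dapi", "nuclear_marker")) "_true_intensity" else "_true_amplitude"
    truth[[paste0(nm, col)]] <- pops[[nm]]$value
  }
  truth
}

#' Generate a fixed-cell synthetic field
#'
#' Places non-overlapping circular nuclei by rejection sampling, draws
#' per-cell true intensities/amplitudes from each channel's population model,
#' renders the channels (nuclear disks; membrane annuli of the stated radius
#' and width; background everywhere; zero-truncated Gaussian noise), and
#' returns the image together with the matching nuclear label mask and the
#' full ground truth.
#'
#' @param spec a [field_spec].
#' @return list with elements `image` ([multichannel_image]), `mask`
#'   (nuclear [label_mask] with labels 1..n_cells), and `truth` (list with
#'   per-cell data.frame `cells` and image-level list `image`).
#' @export
generate_fixed_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, {
    cells <- place_cells(spec)
    pops <- draw_populations(spec)
    rendered <- render_field(spec, cells, pops)
    H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
    lab <- matrix(0L, H, W)
    for (i in seq_len(nrow(cells))) {
      lab[rendered$regions[[i]]$nucleus] <- i
    }
    list(
      image = rendered$image,
      mask = label_mask(lab, "nuclear"),
      truth = list(cells = build_truth(spec, cells, pops),
                   image = list(background_level = spec$background_level,
                                noise_sd = spec$noise_sd,
                                seed = spec$seed))
    )
  })
}

#' Generate a live-imaging synthetic time-lapse
#'
#' Renders the same field geometry at every timepoint with the membrane
#' amplitude of each membrane-marker channel following a supplied trajectory
#' of time, fresh noise per frame, and each non-reference channel translated
#' by a known integer pixel shift (zero-filled), emulating the chromatic
#' offsets the live pipeline must register away. Membrane and non-membrane
#' cell masks are emitted in the reference frame.
#'
#' @param spec a [field_spec]; must contain exactly one `"caax"` channel
#'   (the reference) and at least one `"membrane_marker"` channel, and a
#'   positive `cytoplasm_level`.
#' @param n_timepoints number of frames.
#' @param trajectory named list (per membrane-marker channel) of functions
#'   `t -> amplitude` giving the ring amplitude applied to all cells at
#'   frame `t` (t = 1..n_timepoints).
#' @param shifts named list (per channel) of integer `(dy, dx)`; the caax
#'   reference must have shift `(0, 0)`; `|shift| <= image_shape / 4`.
#' @return list with `stack` ([mc_timeseries]), `membrane_mask`,
#'   `cell_mask` (non-membrane interiors, both [label_mask] in the reference
#'   frame), and `truth` (per-cell data.frame, per-channel shifts, the
#'   trajectory values actually applied, background and cytoplasm levels).
#' @export
generate_live_stack <- function(spec, n_timepoints, trajectory, shifts) {
  stopifnot(inherits(spec, "field_spec"), n_timepoints >= 1L)
  roles <- vapply(spec$channel_specs, `[[`, character(1), "role")
  caax <- names(roles)[roles == "caax"]
  memb <- names(roles)[roles == "membrane_marker"]
  if (length(caax) != 1L) stop("live mode needs exactly one caax channel")
  if (!length(memb)) stop("live mode needs at least one membrane_marker channel")
  if (spec$cytoplasm_level <= 0) {
    stop("live mode needs a positive cytoplasm_level")
  }
  if (!all(memb %in% names(trajectory))) {
    stop("trajectory must be supplied for every membrane_marker channel")
  }
  if (!all(names(spec$channel_specs) %in% names(shifts))) {
    stop("shifts must be supplied for every channel")
  }
  for (nm in names(shifts)) {
    s <- shifts[[nm]]
    if (length(s) != 2L || any(s != round(s))) {
      stop("shift for '", nm, "' must be an integer (dy, dx) pair")
    }
    if (any(abs(s) > spec$image_shape / 4)) {
      stop("shift for '", nm, "' exceeds image_shape / 4")
    }
  }
  if (any(shifts[[caax]] != 0)) stop("reference (caax) shift must be (0, 0)")

  with_seed(spec$seed, {
    cells <- place_cells(spec)
    pops <- draw_populations(spec)
    H <- spec$image_shape[1L]; W <- spec$image_shape[2L]
    regions <- cell_regions(cells, H, W, spec$membrane_ring_radius,
                            spec$membrane_ring_width)
    mm <- matrix(0L, H, W); cm <- matrix(0L, H, W)
    for (i in seq_len(nrow(cells))) {
      mm[regions[[i]]$annulus] <- i
      cm[regions[[i]]$interior] <- i
    }
    # where a neighbour's membrane crosses another cell's interior, the pixel
    # is membrane; the two masks must partition the cell area disjointly
    cm[mm > 0L] <- 0L
    traj_values <- sapply(memb, function(nm) {
      vapply(seq_len(n_timepoints), function(t) trajectory[[nm]](t), numeric(1))
    })
    traj_values <- matrix(traj_values, nrow = n_timepoints,
                          dimnames = list(NULL, memb))
    frames <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      override <- as.list(traj_values[t, , drop = TRUE])
      names(override) <- memb
      fr <- render_field(spec, cells, pops, amplitude_override = override)$image
      for (nm in names(spec$channel_specs)) {
        s <- shifts[[nm]]
        if (any(s != 0)) {
          fr$pixels[, , nm] <- apply_pixel_shift(fr$pixels[, , nm], s[1L], s[2L])
        }
      }
      frames[[t]] <- fr
    }
    list(
      stack = mc_timeseries(frames),
      membrane_mask = label_mask(mm, "membrane"),
      cell_mask = label_mask(cm, "cell_nonmembrane"),
      truth = list(
        cells = build_truth(spec, cells, pops),
        shifts = shifts,
        trajectory = traj_values,
        image = list(background_level = spec$background_level,
                     cytoplasm_level = spec$cytoplasm_level,
                     noise_sd = spec$noise_sd, seed = spec$seed)
      )
    )
  })
}

#' Write a generated field to disk
#'
#' Emits the multipage image TIFF, the uint16 label-mask TIFF, the per-cell
#' ground truth as CSV and the image-level truth as a JSON sidecar.
#'
#' @param field result of [generate_fixed_field()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named character vector of the paths written, invisibly.
#' @export
write_fixed_field <- function(field, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.tif")),
    mask = file.path(dir, paste0(prefix, "_mask.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    sidecar = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_image_tiff(field$image, paths[["image"]])
  write_labels_tiff(field$mask, paths[["mask"]])
  utils::write.csv(field$truth$cells, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(field$truth$image, paths[["sidecar"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
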