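# Population-level analysis of per-cell tables: quadrant gating, positivity
# fractions, per-image summarization, and Welch tests with Bonferroni
# adjustment on per-image summary values.

#' Two-channel gate specification
#'
#' Manually defined intensity (or DAPI-normalized) thresholds separating a
#' co-expression scatter into four quadrants. A value exactly at a threshold
#' counts as positive.
#'
#' @param channel_x,channel_y column names in the per-cell records.
#' @param threshold_x,threshold_y finite positive thresholds.
#' @param source `"manual"` (thresholds supplied, the standard use) or
#'   `"otsu"` (thresholds from [suggest_threshold_otsu()], a convenience not
#'   part of the reference procedure).
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(channel_x, channel_y, threshold_x, threshold_y,
                      source = c("manual", "otsu")) {
  source <- match.arg(source)
  if (!is.finite(threshold_x) || !is.finite(threshold_y) ||
      threshold_x <= 0 || threshold_y <= 0) {
    stop("thresholds must be finite and > 0")
  }
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 threshold_x = threshold_x, threshold_y = threshold_y,
                 source = source),
            class = "gate_spec")
}

QUADRANT_LEVELS <- c("x-y-", "x+y-", "x-y+", "x+y+")

#' Assign each cell to a quadrant
#'
#' @param records per-cell data.frame.
#' @param gate a [gate_spec].
#' @return factor of quadrant labels (`x-y-`, `x+y-`, `x-y+`, `x+y+`), one
#'   per record; positivity is `value >= threshold`.
#' @export
assign_quadrants <- function(records, gate) {
  for (col in c(gate$channel_x, gate$channel_y)) {
    if (!col %in% names(records)) stop("records lack channel column '", col, "'")
  }
  xp <- records[[gate$channel_x]] >= gate$threshold_x
  yp <- records[[gate$channel_y]] >= gate$threshold_y
  factor(QUADRANT_LEVELS[1L + xp + 2L * yp], levels = QUADRANT_LEVELS)
}

#' Quadrant gating of a co-expression scatter
#'
#' Partitions cells by the two gate thresholds and reports counts and
#' percentages per quadrant (double-negative, single-positives,
#' double-positive), as annotated on co-expression scatter plots.
#'
#' @param records per-cell data.frame (nonempty).
#' @param gate a [gate_spec].
#' @return object of class `quadrant_result`: data.frame with `quadrant`,
#'   `count`, `percentage`, and attribute `n_total`.
#' @export
quadrant_classify <- function(records, gate) {
  if (!nrow(records)) stop("no cells to gate")
  q <- assign_quadrants(records, gate)
  counts <- as.integer(table(q))
  out <- data.frame(quadrant = QUADRANT_LEVELS, count = counts,
                    percentage = 100 * counts / nrow(records))
  attr(out, "n_total") <- nrow(records)
  class(out) <- c("quadrant_result", class(out))
  out
}

#' Fraction of cells positive for one channel
#'
#' @param values numeric per-cell values (or supply `records` + `channel`).
#' @param threshold positivity cutoff; boundary counts positive.
#' @param records,channel alternative interface: take `records[[channel]]`.
#' @return proportion in [0, 1].
#' @export
positive_fraction <- function(values = NULL, threshold, records = NULL,
                              channel = NULL) {
  if (is.null(values)) {
    if (is.null(records) || is.null(channel)) {
      stop("supply either 'values' or 'records' and 'channel'")
    }
    values <- records[[channel]]
  }
  if (!length(values)) stop("no cells")
  mean(values >= threshold, na.rm = TRUE)
}

#' Per-image summary of per-cell values
#'
#' Collapses single-cell measurements to one representative value per image —
#' the median by default, so that images (not cells) are the statistical
#' units downstream — or the mean (as drawn as per-image bars on plots). The
#' median of an even count is the midpoint of the two central order
#' statistics.
#'
#' @param records per-cell data.frame with an `image_id` column.
#' @param channels measurement columns to summarize.
#' @param statistic `"median"` or `"mean"`.
#' @return data.frame with `image_id`, `channel`, `value`, `n_cells`.
#' @export
summarize_per_image <- function(records, channels,
                                statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!"image_id" %in% names(records)) stop("records lack 'image_id'")
  fun <- if (statistic == "median") stats::median else mean
  out <- list()
  for (ch in channels) {
    if (!ch %in% names(records)) stop("records lack column '", ch, "'")
    v <- tapply(records[[ch]], records$image_id, fun, na.rm = TRUE)
    n <- tapply(records[[ch]], records$image_id, function(x) sum(!is.na(x)))
    out[[ch]] <- data.frame(image_id = names(v), channel = ch,
                            value = as.numeric(v), n_cells = as.integer(n),
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`; the
#' error-bar statistic.
#'
#' @param values numeric vector with at least two values.
#' @return the SEM.
#' @export
sem <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("sem needs at least two values")
  stats::sd(values) / sqrt(length(values))
}

#' Significance stars at the conventional thresholds
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001; empty
#' string otherwise.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else
      if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Welch two-sample t-tests with Bonferroni adjustment
#'
#' Group comparisons on per-image summary values: Welch's unequal-variance
#' t statistic, Welch–Satterthwaite degrees of freedom, a two-sided p-value,
#' and Bonferroni adjustment `p_adjusted = min(1, p * n_comparisons)`.
#' `n_comparisons` is the number of comparisons declared for the panel, not
#' inferred from the data.
#'
#' @param groups named list of numeric vectors (per-image values per
#'   condition), each with >= 2 values.
#' @param comparisons list of `c(group_a, group_b)` pairs; default: all pairs.
#' @param n_comparisons Bonferroni multiplier; default: number of comparisons.
#' @return data.frame, one row per comparison: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `t_statistic`, `df`, `p_value`, `p_adjusted`,
#'   `stars`.
#' @export
welch_bonferroni <- function(groups, comparisons = NULL, n_comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(comparisons)) {
    nms <- names(groups)
    comparisons <- list()
    if (length(nms) >= 2L) {
      for (i in seq_len(length(nms) - 1L)) {
        for (j in (i + 1L):length(nms)) {
          comparisons[[length(comparisons) + 1L]] <- c(nms[i], nms[j])
        }
      }
    }
  }
  if (!length(comparisons)) stop("no comparisons to perform")
  n_comparisons <- n_comparisons %||% length(comparisons)
  if (n_comparisons < length(comparisons)) {
    stop("n_comparisons must be >= the number of comparisons")
  }
  rows <- lapply(comparisons, function(cmp) {
    a_name <- cmp[1L]; b_name <- cmp[2L]
    for (g in c(a_name, b_name)) {
      if (!g %in% names(groups)) stop("unknown group '", g, "'")
      if (sum(!is.na(groups[[g]])) < 2L) {
        stop("group '", g, "' has fewer than 2 values")
      }
    }
    a <- groups[[a_name]][!is.na(groups[[a_name]])]
    b <- groups[[b_name]][!is.na(groups[[b_name]])]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stop("groups '", a_name, "' and '", b_name,
           "' both have zero variance; Welch test undefined")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(group_a = a_name, group_b = b_name,
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * n_comparisons)
  out$stars <- significance_stars(out$p_adjusted)
  out
}

#' Suggest a gate threshold by Otsu's method
#'
#' A labelled convenience for picking a starting threshold from the data;
#' the reference gating procedure uses manually defined thresholds.
#'
#' @param values numeric per-cell values.
#' @return suggested threshold on the scale of `values`.
#' @export
suggest_threshold_otsu <- function(values) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (rng[2] <= rng[1]) stop("values are constant; no threshold exists")
  norm <- (values - rng[1]) / (rng[2] - rng[1])
  side <- ceiling(sqrt(length(norm)))
  img <- matrix(c(norm, rep(norm[1L], side^2 - length(norm))), side, side)
  thr01 <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  rng[1] + thr01 * (rng[2] - rng[1])
}

#' Export tidy gating and statistics tables
#'
#' Writes the CSV bundle that feeds scatter/violin-style figures: a per-cell
#' scatter table with quadrant assignment, quadrant percentages per condition,
#' a per-image summary table, and (when groups are compared) a comparison
#' table with significance stars.
#'
#' @param records per-cell data.frame with `image_id` and, if conditions are
#'   compared, a `condition` column.
#' @param gate a [gate_spec].
#' @param channels measurement columns for the per-image summary.
#' @param out_dir output directory (created if needed).
#' @param comparisons,n_comparisons passed to [welch_bonferroni()] on the
#'   per-image medians of the gate's x channel when a `condition` column is
#'   present; `NULL` skips testing.
#' @param statistic per-image statistic for the summary table.
#' @return named character vector of paths written, invisibly.
#' @export
export_gating_tables <- function(records, gate, channels, out_dir,
                                 comparisons = NULL, n_comparisons = NULL,
                                 statistic = "median") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scatter = file.path(out_dir, "scatter.csv"),
             quadrants = file.path(out_dir, "quadrants.csv"),
             summary = file.path(out_dir, "per_image_summary.csv"))
  scatter <- data.frame(
    image_id = records$image_id, cell_id = records$cell_id,
    x = records[[gate$channel_x]], y = records[[gate$channel_y]],
    quadrant = assign_quadrants(records, gate)
  )
  utils::write.csv(scatter, paths[["scatter"]], row.names = FALSE)
  if ("condition" %in% names(records)) {
    qr <- do.call(rbind, lapply(split(records, records$condition), function(r) {
      q <- quadrant_classify(r, gate)
      data.frame(condition = r$condition[1L], q, n_total = attr(q, "n_total"))
    }))
  } else {
    q <- quadrant_classify(records, gate)
    qr <- data.frame(q, n_total = attr(q, "n_total"))
  }
  utils::write.csv(qr, paths[["quadrants"]], row.names = FALSE)
  summ <- summarize_per_image(records, channels, statistic = statistic)
  utils::write.csv(summ, paths[["summary"]], row.names = FALSE)
  if ("condition" %in% names(records) &&
      length(unique(records$condition)) >= 2L) {
    med <- summarize_per_image(records, gate$channel_x, statistic = "median")
    cond_of <- tapply(as.character(records$condition), records$image_id,
                      function(x) x[1L])
    groups <- split(med$value, as.character(cond_of[med$image_id]))
    cmp <- welch_bonferroni(groups, comparisons, n_comparisons)
    paths <- c(paths, comparisons = file.path(out_dir, "comparisons.csv"))
    utils::write.csv(cmp, paths[["comparisons"]], row.names = FALSE)
  }
  invisible(paths)
}
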