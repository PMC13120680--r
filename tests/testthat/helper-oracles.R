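# Independent straight-loop oracles. These deliberately avoid the package's
# vectorized code paths: scalar bilinear interpolation by nested linear
# interpolation, explicit per-ray loops with an explicit sort, and the Welch
# formulas written out by hand.

oracle_bilinear <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  if (r < 1 || r > H || c < 1 || c > W) return(NA_real_)
  r0 <- floor(r); c0 <- floor(c)
  if (r0 == H) r0 <- H - 1
  if (c0 == W) c0 <- W - 1
  fr <- r - r0; fc <- c - c0
  top <- img[r0, c0] + fc * (img[r0, c0 + 1] - img[r0, c0])
  bot <- img[r0 + 1, c0] + fc * (img[r0 + 1, c0 + 1] - img[r0 + 1, c0])
  top + fr * (bot - top)
}

# directional profiling for one cell: enumerate every sample point, sort,
# average the top ceiling(top_fraction * m), mean over rays
oracle_directional_one <- function(channel, r0, c0, n_directions = 6,
                                   ray_length = 25, top_fraction = 0.2) {
  dir_vals <- rep(NA_real_, n_directions)
  for (k in seq_len(n_directions)) {
    theta <- 2 * pi * (k - 1) / n_directions
    vals <- numeric(0)
    for (d in seq_len(ray_length)) {
      v <- oracle_bilinear(channel, r0 + d * sin(theta), c0 + d * cos(theta))
      if (!is.na(v)) vals <- c(vals, v)
    }
    m <- length(vals)
    if (m == 0) next
    k_top <- max(1L, as.integer(ceiling(top_fraction * m - 1e-12)))
    sorted <- sort(vals, decreasing = TRUE)
    dir_vals[k] <- mean(sorted[seq_len(k_top)])
  }
  list(signal = mean(dir_vals[!is.na(dir_vals)]), directions = dir_vals)
}

# Welch statistic, Welch-Satterthwaite df and two-sided p, by hand
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# rotate an image about a point by `angle` (radians) with bilinear resampling
# of the source; used for the rotation-robustness property
oracle_rotate_about <- function(img, r0, c0, angle, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      dr <- r - r0; dc <- c - c0
      sr <- r0 + cos(angle) * dr - sin(angle) * dc
      sc <- c0 + sin(angle) * dr + cos(angle) * dc
      v <- oracle_bilinear(img, sr, sc)
      if (!is.na(v)) out[r, c] <- v
    }
  }
  out
}
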