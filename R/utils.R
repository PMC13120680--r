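# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG state
#' afterwards so generators are deterministic without clobbering the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Bilinear interpolation at continuous (row, col) positions
#'
#' Samples a 2D intensity array at fractional 1-based coordinates. Positions
#' outside `[1, nrow] x [1, ncol]` return `NA` (the caller discards them);
#' positions exactly on the far border are clamped into the last pixel pair.
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of row/col positions (same length).
#' @return numeric vector of interpolated values, `NA` where out of bounds.
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  H <- nrow(img)
  W <- ncol(img)
  stopifnot(H >= 2L, W >= 2L, length(r) == length(c))
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), H - 1)
  c0 <- pmin(floor(c), W - 1)
  fr <- r - r0
  fc <- c - c0
  v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
    fr * (1 - fc) * img[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * img[cbind(r0, c0 + 1)] +
    fr * fc * img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v
  out
}

#' Translate an image by an integer pixel shift
#'
#' `out[r, c] = img[r - dy, c - dx]`: positive `dy` moves content down,
#' positive `dx` moves it right. Exposed pixels are zero-filled.
#'
#' @param img numeric matrix.
#' @param dy,dx integer shifts in pixels.
#' @return shifted matrix of the same dimensions.
#' @export
apply_pixel_shift <- function(img, dy, dx) {
  stopifnot(is.matrix(img), dy == round(dy), dx == round(dx))
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  r_dest <- seq_len(H)[seq_len(H) - dy >= 1 & seq_len(H) - dy <= H]
  c_dest <- seq_len(W)[seq_len(W) - dx >= 1 & seq_len(W) - dx <= W]
  if (length(r_dest) && length(c_dest)) {
    out[r_dest, c_dest] <- img[r_dest - dy, c_dest - dx]
  }
  out
}

# top-k count: ceiling(fraction * m) with a tiny guard against floating-point
# excess (e.g. fractions stored inexactly in binary); at least 1 when m >= 1.
top_k_count <- function(fraction, m) {
  if (m < 1L) return(0L)
  max(1L, as.integer(ceiling(fraction * m - 1e-12)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
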