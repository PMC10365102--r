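# Pixel-center coordinate mapping for resampling: output pixel i (1-based)
# has center (i - 0.5) * n_in / n_out + 0.5 in input pixel coordinates.
.resampleCoords <- function(nIn, nOut) {
  (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
}

#' Bilinear image resize
#'
#' Resamples a matrix to \code{side x side} (or \code{c(rows, cols)}) with
#' bilinear interpolation under the pixel-center convention; coordinates
#' outside the input are clamped to the border. Output values are convex
#' combinations of input values, hence stay within the input's range.
#' Non-square inputs are resized anisotropically (no padding).
#'
#' @param pixels numeric matrix.
#' @param side integer target side, or length-2 \code{c(rows, cols)}.
#' @return resized matrix.
#' @export
resizeBilinear <- function(pixels, side) {
  side <- as.integer(side)
  if (any(side < 1L)) stop("'side' must be >= 1")
  ho <- side[1]; wo <- if (length(side) > 1L) side[2] else side[1]
  h <- nrow(pixels); w <- ncol(pixels)
  if (h == ho && w == wo) return(pixels)
  u <- pmin(pmax(.resampleCoords(h, ho), 1), h)
  v <- pmin(pmax(.resampleCoords(w, wo), 1), w)
  # rows first, then columns
  if (h == 1L) {
    rows <- pixels[rep(1L, ho), , drop = FALSE]
  } else {
    r0 <- pmax(pmin(floor(u), h - 1L), 1L); fr <- u - r0
    top <- pixels[r0, , drop = FALSE]; bot <- pixels[r0 + 1L, , drop = FALSE]
    rows <- top * (1 - fr) + bot * fr                   # ho x w
  }
  if (w == 1L) return(rows[, rep(1L, wo), drop = FALSE])
  c0 <- pmax(pmin(floor(v), w - 1L), 1L); fc <- v - c0
  left <- rows[, c0, drop = FALSE]; right <- rows[, c0 + 1L, drop = FALSE]
  sweep(left, 2, (1 - fc), "*") + sweep(right, 2, fc, "*")
}

#' Nearest-neighbor resize (for masks)
#'
#' Same pixel-center mapping as \code{\link{resizeBilinear}} but picks the
#' nearest input pixel, so binary masks stay binary.
#'
#' @inheritParams resizeBilinear
#' @return resized matrix containing only values present in the input.
#' @export
resizeNearest <- function(pixels, side) {
  side <- as.integer(side)
  if (any(side < 1L)) stop("'side' must be >= 1")
  ho <- side[1]; wo <- if (length(side) > 1L) side[2] else side[1]
  h <- nrow(pixels); w <- ncol(pixels)
  if (h == ho && w == wo) return(pixels)
  ri <- pmin(pmax(round(.resampleCoords(h, ho)), 1L), h)
  ci <- pmin(pmax(round(.resampleCoords(w, wo)), 1L), w)
  pixels[ri, ci, drop = FALSE]
}
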