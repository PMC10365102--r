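#' Central quarter region of an image
#'
#' Index ranges of the central quarter-area window used to derive the
#' truncation bounds: rows \code{[x/4, 3x/4)} by columns \code{[y/4, 3y/4)}
#' (half-open, floor for odd dimensions), i.e. the half-height by half-width
#' window centered in the image.
#'
#' @param pixels numeric matrix of image intensities (rows x, cols y).
#' @return list with integer vectors \code{rows} and \code{cols} (1-based).
#' @examples
#' centralRegion(matrix(0, 8, 8))   # rows 3:6, cols 3:6
#' @export
centralRegion <- function(pixels) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  x <- nrow(pixels); y <- ncol(pixels)
  if (x < 4L || y < 4L)
    stop(sprintf("image too small for central-quarter windowing (%dx%d; need >= 4x4)",
                 x, y))
  if (!all(is.finite(pixels))) stop("image contains non-finite intensities")
  list(rows = (x %/% 4L + 1L):((3L * x) %/% 4L),
       cols = (y %/% 4L + 1L):((3L * y) %/% 4L))
}

#' Truncation bounds from the central quarter
#'
#' The minimum and maximum intensity attained inside the central-quarter
#' region; all pixels of the full image are subsequently clipped to this
#' window. Windowing to the central range suppresses machine-dependent
#' extreme values near the image border (collimation, markers, burnt-out
#' background) so that images from different acquisition settings become
#' comparable.
#'
#' @inheritParams centralRegion
#' @return list with numeric \code{vmin}, \code{vmax} and the \code{region}
#'   index ranges.
#' @examples
#' img <- matrix(0, 4, 4); img[2:3, 2:3] <- c(5, 6, 6, 7); img[1, 1] <- 10
#' truncationBounds(img)  # vmin 5, vmax 7
#' @export
truncationBounds <- function(pixels) {
  reg <- centralRegion(pixels)
  centre <- pixels[reg$rows, reg$cols]
  list(vmin = min(centre), vmax = max(centre), region = reg)
}

#' Clip an image to truncation bounds
#'
#' Per-pixel windowing: values at or below \code{vmin} become \code{vmin},
#' values at or above \code{vmax} become \code{vmax}, values strictly
#' between are unchanged.
#'
#' @inheritParams centralRegion
#' @param bounds list with \code{vmin} and \code{vmax}
#'   (from \code{\link{truncationBounds}}).
#' @return matrix with all values in \code{[vmin, vmax]}.
#' @export
applyTruncation <- function(pixels, bounds) {
  if (bounds$vmin > bounds$vmax) stop("vmin must be <= vmax")
  pmin(pmax(pixels, bounds$vmin), bounds$vmax)
}

#' Min-max normalize a truncated image to [0,1]
#'
#' Affine map \code{v -> (v - vmin) / (vmax - vmin)}. The degenerate case
#' \code{vmax == vmin} (constant central region) returns an all-zero image
#' rather than failing, so batch pipelines survive blank frames.
#'
#' @inheritParams applyTruncation
#' @return matrix with values in [0, 1].
#' @export
normalizeUnit <- function(pixels, bounds) {
  d <- bounds$vmax - bounds$vmin
  if (d <= 0) return(matrix(0, nrow(pixels), ncol(pixels)))
  (pixels - bounds$vmin) / d
}

#' Full radiograph preprocessing
#'
#' Composition of the harmonization pipeline: optional photometric
#' inversion (for inverted-grayscale sources, where bone is dark),
#' central-quarter truncation bound extraction, clipping, min-max
#' normalization to [0,1], and resizing to \code{side x side} (bilinear).
#' The result is invariant to any positive affine rescaling of the input
#' intensities, which is the point: radiographs from machines with
#' different gain/offset map to the same normalized image.
#'
#' @inheritParams centralRegion
#' @param side output image side (default 512).
#' @param photometric \code{"standard"} (higher value = brighter) or
#'   \code{"inverted"}; inverted inputs are flipped \code{v -> max(v) - v}
#'   before windowing.
#' @return \code{side x side} matrix in [0,1].
#' @examples
#' ph <- generatePhantom(PhantomConfig(side = 64), 1)
#' norm <- preprocessImage(ph$image, side = 64)
#' range(norm)
#' @export
preprocessImage <- function(pixels, side = 512,
                            photometric = c("standard", "inverted")) {
  photometric <- match.arg(photometric)
  if (photometric == "inverted") pixels <- max(pixels) - pixels
  b <- truncationBounds(pixels)
  out <- normalizeUnit(applyTruncation(pixels, b), b)
  resizeBilinear(out, side)
}
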