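#' Read a grayscale image (PNG or TIFF)
#'
#' Returns the raw intensity matrix. Multi-channel files are reduced to a
#' single channel by averaging. PNG values arrive scaled to [0,1] by the
#' reader; TIFF values are returned as stored.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix.
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG/TIFF supported)", ext)))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Read a binary mask PNG
#'
#' @param path PNG path; any pixel above half intensity is foreground.
#' @return binary 0/1 matrix.
#' @export
readMaskPNG <- function(path) {
  m <- readImageGray(path)
  (m > 0.5) * 1
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask binary 0/1 matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  assertBinaryMask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Write an intensity image as 16-bit TIFF
#'
#' Intensities are min-max rescaled to the file's [0,1] range (the scale is
#' arbitrary anyway once per-machine affine transforms are in play); a
#' constant image is written as zeros.
#'
#' @param pixels numeric matrix.
#' @param path output path (.tif).
#' @export
writeImage16 <- function(pixels, path) {
  rng <- range(pixels)
  x <- if (diff(rng) > 0) (pixels - rng[1]) / diff(rng)
       else matrix(0, nrow(pixels), ncol(pixels))
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}
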