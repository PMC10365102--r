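#' Threshold a probability map into a binary mask
#'
#' @param prob numeric matrix of lung probabilities in [0,1].
#' @param threshold numeric in (0,1); pixels with probability
#'   \code{>= threshold} become 1.
#' @return binary 0/1 matrix.
#' @export
binarizeMask <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0,1)")
  (prob >= threshold) * 1
}

#' Label connected components of a binary mask
#'
#' Connected-component ("connected domain") labeling with selectable 4- or
#' 8-connectivity, built on an adjacency graph of foreground pixels.
#'
#' @param mask binary 0/1 matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  assertBinaryMask(mask)
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  vid <- integer(h * w)            # pixel linear index -> vertex id
  vid[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  addPairs <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= h & cc + dc >= 1L & cc + dc <= w
    nb <- (cc[ok] + dc - 1L) * h + (r[ok] + dr)
    on <- mask[nb] == 1
    rbind(vid[fg[ok]][on], vid[nb][on])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  epairs <- do.call(cbind, lapply(offs, function(o) addPairs(o[1], o[2])))
  g <- igraph::make_graph(edges = as.vector(epairs), n = length(fg),
                          directed = FALSE)
  lab[fg] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Remove spurious connected components
#'
#' Keeps at most \code{maxComponents} largest components, and among those
#' only components whose area is at least \code{minAreaFraction} of the
#' largest one; everything else (small specks misidentified as lung) is
#' zeroed. The default keep rule of two encodes the two-lung prior while
#' the area fraction tolerates a merged single lung field.
#'
#' @param mask binary 0/1 matrix.
#' @param config a \code{\link{PostprocConfig}}.
#' @return binary matrix; never adds foreground pixels.
#' @export
removeSpurious <- function(mask, config = PostprocConfig()) {
  lab <- labelComponents(mask, config@connectivity)
  n <- max(lab)
  if (n <= 1L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- order(areas, decreasing = TRUE)[seq_len(min(config@maxComponents, n))]
  keep <- keep[areas[keep] >= config@minAreaFraction * max(areas)]
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1
}

#' Fill enclosed holes and smooth mask boundaries
#'
#' Repairs the second failure mode of raw network masks — small regions
#' inside the lung field left unrecognized — by filling background
#' components that do not touch the image border (holes are labeled with
#' the connectivity dual to the foreground's), then applies a morphological
#' opening with a disc of radius \code{openingRadius} to smooth ragged
#' boundaries. Either stage can be disabled (\code{fillHoles = FALSE},
#' \code{openingRadius = 0}).
#'
#' @inheritParams removeSpurious
#' @return binary matrix.
#' @export
completeRegions <- function(mask, config = PostprocConfig()) {
  assertBinaryMask(mask)
  out <- mask
  if (config@fillHoles) {
    bgConn <- if (config@connectivity == 8) 4 else 8
    bg <- labelComponents(1 - out, connectivity = bgConn)
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    hole <- bg > 0L & !(bg %in% border)
    out[hole] <- 1
  }
  r <- config@openingRadius
  if (r > 0L) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    out <- (EBImage::opening(out, brush) > 0) * 1
  }
  out
}

#' Full mask post-processing
#'
#' Binarize the network's probability map, drop spurious components, fill
#' holes and smooth: \code{\link{binarizeMask}} then
#' \code{\link{removeSpurious}} then \code{\link{completeRegions}}.
#'
#' @param prob probability matrix in [0,1] (a binary mask also works).
#' @param config a \code{\link{PostprocConfig}}.
#' @return binary 0/1 matrix with at most \code{maxComponents} components
#'   entering the smoothing stage.
#' @examples
#' ph <- generatePhantom(PhantomConfig(side = 64), 1)
#' bad <- corruptMask(ph$mask, seed = 2)
#' fixed <- postprocessMask(bad, PostprocConfig(openingRadius = 1))
#' diceCoef(fixed, ph$mask) > diceCoef(bad, ph$mask)
#' @export
postprocessMask <- function(prob, config = PostprocConfig()) {
  m <- binarizeMask(prob, config@threshold)
  m <- removeSpurious(m, config)
  completeRegions(m, config)
}
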