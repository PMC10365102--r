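# Pixel-center coordinate grids (fractions of side), cached per side.
.gridCache <- new.env(parent = emptyenv())
.phantomGrid <- function(side) {
  key <- as.character(side)
  g <- .gridCache[[key]]
  if (is.null(g)) {
    u <- (seq_len(side) - 0.5) / side
    g <- list(Y = matrix(u, side, side),                 # row coordinate
              X = matrix(u, side, side, byrow = TRUE))   # column coordinate
    .gridCache[[key]] <- g
  }
  g
}

# Inside-ellipse indicator on the unit-square grid.
.insideEllipse <- function(g, cx, cy, a, b, rotDeg = 0) {
  th <- rotDeg * pi / 180
  dx <- g$X - cx; dy <- g$Y - cy
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  (xr / b)^2 + (yr / a)^2 <= 1
}

#' Generate one synthetic chest phantom
#'
#' Renders a thorax ellipse containing two darker lung ellipses (their
#' union is the noise-free ground-truth mask), a brighter mediastinal band
#' between the lungs, slanted bright rib stripes crossing the lung fields,
#' and — with configured probability — a distractor blob outside the lungs
#' whose intensity falls in the lung band (the classic false-positive
#' trap). Gaussian noise is added on the nominal [0,1] scale and the image
#' is then mapped through a per-image affine transform \code{a*I + b}
#' emulating machine-dependent intensity ranges. Fully deterministic given
#' \code{(config@seed, index)}.
#'
#' @param config a \code{\link{PhantomConfig}}.
#' @param index positive integer identifying the phantom within the seeded
#'   series.
#' @return list with \code{image} (numeric matrix, machine scale),
#'   \code{mask} (binary matrix), and \code{params} (the drawn geometry,
#'   affine gain/offset, etc.).
#' @examples
#' ph <- generatePhantom(PhantomConfig(side = 64), 1)
#' dim(ph$image); mean(ph$mask)
#' @export
generatePhantom <- function(config = PhantomConfig(), index = 1) {
  stopifnot(index >= 1)
  withSeed(deriveSeed(config@seed, index), {
    s <- config@side
    g <- .phantomGrid(s)
    iv <- config@intensities
    img <- matrix(iv[["background"]], s, s)

    # thorax
    thorax <- .insideEllipse(g, 0.5, 0.52, 0.44, 0.42)
    img[thorax] <- iv[["thorax"]]

    # lungs
    jit <- config@lungCenterJitter
    ax <- config@lungAxes
    lungPar <- lapply(c(-1, 1), function(sgn) list(
      cx = 0.5 + sgn * (0.19 + runif(1, -jit, jit)),
      cy = 0.50 + runif(1, -jit, jit),
      a = runif(1, ax[1], ax[2]),
      b = runif(1, ax[3], ax[4]),
      rot = sgn * runif(1, 0, config@lungRotationMax)))
    lungs <- .insideEllipse(g, lungPar[[1]]$cx, lungPar[[1]]$cy,
                            lungPar[[1]]$a, lungPar[[1]]$b, lungPar[[1]]$rot) |
             .insideEllipse(g, lungPar[[2]]$cx, lungPar[[2]]$cy,
                            lungPar[[2]]$a, lungPar[[2]]$b, lungPar[[2]]$rot)
    if (!any(lungs[2:(s - 1), 2:(s - 1)]) || any(lungs[c(1, s), ]) ||
        any(lungs[, c(1, s)]))
      stop("lung geometry ranges place lungs off-canvas")

    # mediastinal band between the lungs (brighter: heart/thymus/spine)
    medi <- thorax & !lungs & abs(g$X - 0.5) < 0.07 & g$Y > 0.18 & g$Y < 0.85
    img[medi] <- iv[["mediastinum"]]
    img[lungs] <- iv[["lung"]]

    # rib stripes: slanted bright bands across the thorax, crossing lungs
    nr <- sample(config@ribCount[1]:config@ribCount[2], 1)
    ribRows <- seq(0.25, 0.75, length.out = nr) + runif(nr, -0.02, 0.02)
    slope <- runif(nr, -0.08, 0.08)
    ribs <- matrix(FALSE, s, s)
    for (k in seq_len(nr)) {
      d <- abs(g$Y - (ribRows[k] + slope[k] * (g$X - 0.5)))
      ribs <- ribs | (d < config@ribWidth)
    }
    ribs <- ribs & thorax
    img[ribs] <- iv[["rib"]]

    # distractor blob outside the lungs, lung-band intensity
    hasDistractor <- runif(1) < config@distractorProb
    if (hasDistractor) {
      repeat {
        dc <- c(runif(1, 0.12, 0.88), runif(1, 0.12, 0.88))
        dr <- runif(1, config@distractorRadius[1], config@distractorRadius[2])
        blob <- .insideEllipse(g, dc[1], dc[2], dr, dr)
        if (!any(blob & lungs)) break
      }
      img[blob] <- iv[["distractor"]]
    }

    if (config@noiseSd > 0)
      img <- img + matrix(rnorm(s * s, sd = config@noiseSd), s, s)

    gain <- runif(1, config@gainRange[1], config@gainRange[2])
    offset <- runif(1, config@offsetRange[1], config@offsetRange[2])
    list(image = gain * img + offset,
         mask = lungs * 1,
         params = list(index = index, lungs = lungPar, n_ribs = nr,
                       distractor = hasDistractor, gain = gain,
                       offset = offset))
  })
}

#' Generate a phantom dataset
#'
#' \code{n} seeded phantoms; optionally written to disk as
#' \code{images/*.tif} (16-bit, machine-scale intensities rescaled to the
#' file range), \code{masks/*.png} and a \code{manifest.json} recording the
#' per-image draw parameters, seed and config hash.
#'
#' @param n number of phantoms.
#' @param config a \code{\link{PhantomConfig}}.
#' @param dir optional output directory.
#' @return invisibly, list with \code{images}, \code{masks}, \code{manifest}.
#' @export
generateDataset <- function(n, config = PhantomConfig(), dir = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  phs <- lapply(seq_len(n), function(i) generatePhantom(config, i))
  images <- lapply(phs, `[[`, "image")
  masks <- lapply(phs, `[[`, "mask")
  manifest <- lapply(phs, `[[`, "params")
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      id <- sprintf("phantom_%04d", i)
      writeImage16(images[[i]], file.path(dir, "images", paste0(id, ".tif")))
      writeMaskPNG(masks[[i]], file.path(dir, "masks", paste0(id, ".png")))
    }
    writeManifest(dir, configToList(config), config@seed,
                  list(n = n, entries = manifest))
  }
  invisible(list(images = images, masks = masks, manifest = manifest))
}

#' Corrupt a mask with the two failure modes of raw network output
#'
#' Adds a small foreground speck outside the mask (a non-lung area
#' misidentified as lung) and punches a small fully-enclosed hole inside it
#' (a lung section left unrecognized), each with its configured
#' probability. Used to exercise the post-processing stage.
#'
#' @param mask binary 0/1 matrix.
#' @param speckProb,holeProb probabilities of each corruption.
#' @param speckRadius,holeRadius radii in pixels.
#' @param seed integer seed.
#' @return corrupted binary matrix.
#' @export
corruptMask <- function(mask, speckProb = 1, holeProb = 1,
                        speckRadius = 2, holeRadius = 3, seed = 1) {
  assertBinaryMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  withSeed(deriveSeed(seed, 977), {
    out <- mask
    disc <- function(r0, c0, rad) {
      rr <- pmax(1, r0 - rad):pmin(h, r0 + rad)
      cc <- pmax(1, c0 - rad):pmin(w, c0 + rad)
      sel <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2 <= rad^2)
      list(rows = rr, cols = cc, sel = sel)
    }
    if (runif(1) < speckProb) {
      # background pixel whose speck disc stays clear of the mask
      for (try in 1:200) {
        r0 <- sample(seq(speckRadius + 2, h - speckRadius - 1), 1)
        c0 <- sample(seq(speckRadius + 2, w - speckRadius - 1), 1)
        d <- disc(r0, c0, speckRadius + 2)
        if (!any(out[d$rows, d$cols] == 1)) {
          d <- disc(r0, c0, speckRadius)
          patch <- out[d$rows, d$cols]; patch[d$sel] <- 1
          out[d$rows, d$cols] <- patch
          break
        }
      }
    }
    if (runif(1) < holeProb) {
      # interior pixel whose hole disc is fully enclosed by the mask
      eroded <- EBImage::erode(mask, EBImage::makeBrush(2 * (holeRadius + 2) + 1,
                                                        shape = "disc"))
      inside <- which(eroded > 0)
      if (length(inside)) {
        p <- inside[sample(length(inside), 1)]
        d <- disc(((p - 1) %% h) + 1, ((p - 1) %/% h) + 1, holeRadius)
        patch <- out[d$rows, d$cols]; patch[d$sel] <- 0
        out[d$rows, d$cols] <- patch
      }
    }
    out
  })
}

# Serialize an S4 config to a plain list (for manifests / JSON).
configToList <- function(config) {
  sn <- methods::slotNames(class(config))
  stats::setNames(lapply(sn, function(s) methods::slot(config, s)), sn)
}
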