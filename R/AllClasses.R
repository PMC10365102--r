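#' Network architecture configuration
#'
#' Describes one TransResUNet instance: the input side, the channel widths
#' of the three encoder levels, and the transformer bottleneck geometry.
#' The defaults correspond to the full-scale configuration (512x512 input,
#' 12 transformer layers, embedding size 768, 12 attention heads, ViT-style
#' MLP width of 4x the embedding size). A much smaller instance (e.g.
#' \code{side = 64}, \code{channels = c(8, 16, 32)}, \code{layers = 2},
#' \code{embedDim = 64}, \code{heads = 4}) trains in minutes on one CPU.
#'
#' @slot side integer, input image side S; the model consumes S x S images.
#' @slot channels integer(3), channel widths of encoder features F1, F2, F3
#'   (at resolutions S/2, S/4, S/8).
#' @slot layers integer, number of transformer layers L in the bottleneck.
#' @slot embedDim integer, token embedding size K.
#' @slot heads integer, attention heads h; K must be divisible by h.
#' @slot mlpDim integer, hidden width of the per-token MLP.
#' @slot patchStride integer p: patches are p x p blocks of F3, so the token
#'   grid has side S/(8p). p = 1 tokenizes every F3 cell.
#' @slot dropout numeric, dropout rate applied during training.
#' @slot numClasses integer, number of output classes (2: background, lung).
#' @name ModelConfig-class
#' @rdname ModelConfig
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  side = "integer", channels = "integer", layers = "integer",
  embedDim = "integer", heads = "integer", mlpDim = "integer",
  patchStride = "integer", dropout = "numeric", numClasses = "integer"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@channels) != 3L || any(object@channels < 1L))
    msg <- c(msg, "'channels' must be three positive integers")
  if (object@side < 8L || object@side %% (8L * object@patchStride) != 0L)
    msg <- c(msg, "'side' must be divisible by 8 * patchStride")
  if (object@embedDim %% object@heads != 0L)
    msg <- c(msg, "'embedDim' must be divisible by 'heads'")
  if (object@layers < 0L) msg <- c(msg, "'layers' must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "'dropout' must be in [0, 1)")
  if (object@numClasses != 2L) msg <- c(msg, "'numClasses' is fixed at 2")
  if (length(msg)) msg else TRUE
})

#' @param side,channels,layers,embedDim,heads,mlpDim,patchStride,dropout
#'   see slots.
#' @return a \code{ModelConfig} object.
#' @examples
#' cfg <- ModelConfig(side = 64, channels = c(8, 16, 32), layers = 2,
#'                    embedDim = 64, heads = 4)
#' countParams(cfg)
#' @rdname ModelConfig
#' @export
ModelConfig <- function(side = 512, channels = c(64, 128, 256), layers = 12,
                        embedDim = 768, heads = 12, mlpDim = 4 * embedDim,
                        patchStride = 1, dropout = 0.1) {
  new("ModelConfig", side = as.integer(side),
      channels = as.integer(channels), layers = as.integer(layers),
      embedDim = as.integer(embedDim), heads = as.integer(heads),
      mlpDim = as.integer(mlpDim), patchStride = as.integer(patchStride),
      dropout = as.numeric(dropout), numClasses = 2L)
}

#' Training configuration
#'
#' Training protocol: RMSprop with learning rate 0.001, batch size 2,
#' 20 epochs, and a 70:10:20 train/validation/test split. The loss is
#' per-pixel two-class cross-entropy by default; soft-Dice and a combined
#' loss are selectable. Model selection keeps the epoch with the best
#' validation Dice (\code{selection = "best"}) or the final epoch.
#'
#' @slot learningRate numeric, RMSprop initial learning rate.
#' @slot batchSize integer.
#' @slot epochs integer.
#' @slot splitRatios numeric(3) summing to 100.
#' @slot seed integer, seeds shuffling, initialization and dropout.
#' @slot loss one of "cross_entropy", "dice", "combined".
#' @slot selection one of "best", "last".
#' @name TrainConfig-class
#' @rdname TrainConfig
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  learningRate = "numeric", batchSize = "integer", epochs = "integer",
  splitRatios = "numeric", seed = "integer", loss = "character",
  selection = "character"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (length(object@splitRatios) != 3L || any(object@splitRatios <= 0) ||
      abs(sum(object@splitRatios) - 100) > 1e-8)
    msg <- c(msg, "'splitRatios' must be three positive numbers summing to 100")
  if (!object@loss %in% c("cross_entropy", "dice", "combined"))
    msg <- c(msg, "unknown 'loss'")
  if (!object@selection %in% c("best", "last"))
    msg <- c(msg, "'selection' must be \"best\" or \"last\"")
  if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "'epochs' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param learningRate,batchSize,epochs,splitRatios,seed,loss,selection
#'   see slots.
#' @return a \code{TrainConfig} object.
#' @rdname TrainConfig
#' @export
TrainConfig <- function(learningRate = 0.001, batchSize = 2, epochs = 20,
                        splitRatios = c(70, 10, 20), seed = 1,
                        loss = c("cross_entropy", "dice", "combined"),
                        selection = c("best", "last")) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      splitRatios = as.numeric(splitRatios), seed = as.integer(seed),
      loss = match.arg(loss), selection = match.arg(selection))
}

#' Mask post-processing configuration
#'
#' Parameters of the mask clean-up stage: probability threshold for
#' binarization, pixel connectivity for component labeling, the keep rule
#' (at most \code{maxComponents} components, each at least
#' \code{minAreaFraction} of the largest component's area — the two-lung
#' prior), and the disc radius of the morphological opening that smooths
#' boundaries after hole filling.
#'
#' @slot threshold numeric in (0,1).
#' @slot connectivity integer, 4 or 8.
#' @slot maxComponents integer >= 1.
#' @slot minAreaFraction numeric in [0,1].
#' @slot openingRadius integer >= 0 (pixels; 0 disables opening).
#' @slot fillHoles logical, fill enclosed background regions before opening.
#' @name PostprocConfig-class
#' @rdname PostprocConfig
#' @exportClass PostprocConfig
setClass("PostprocConfig", representation(
  threshold = "numeric", connectivity = "integer", maxComponents = "integer",
  minAreaFraction = "numeric", openingRadius = "integer", fillHoles = "logical"
))

setValidity("PostprocConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "'threshold' must be in (0,1)")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (object@maxComponents < 1L) msg <- c(msg, "'maxComponents' must be >= 1")
  if (object@minAreaFraction < 0 || object@minAreaFraction > 1)
    msg <- c(msg, "'minAreaFraction' must be in [0,1]")
  if (object@openingRadius < 0L) msg <- c(msg, "'openingRadius' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param threshold,connectivity,maxComponents,minAreaFraction,openingRadius,fillHoles
#'   see slots.
#' @return a \code{PostprocConfig} object.
#' @rdname PostprocConfig
#' @export
PostprocConfig <- function(threshold = 0.5, connectivity = 8,
                           maxComponents = 2, minAreaFraction = 0.10,
                           openingRadius = 3, fillHoles = TRUE) {
  new("PostprocConfig", threshold = as.numeric(threshold),
      connectivity = as.integer(connectivity),
      maxComponents = as.integer(maxComponents),
      minAreaFraction = as.numeric(minAreaFraction),
      openingRadius = as.integer(openingRadius),
      fillHoles = as.logical(fillHoles))
}

#' Synthetic chest-phantom configuration
#'
#' Parameters of the seeded phantom generator. Each phantom is a thorax
#' ellipse on a dark background containing two darker lung ellipses (whose
#' union is the ground-truth mask), a brighter mediastinal band between
#' them, bright rib-like stripes crossing the lung fields, and occasional
#' distractor blobs outside the lungs whose intensity sits in the lung
#' band. Nominal intensities live on a [0,1] scale; each image is then
#' pushed through a per-image affine "machine" transform a*I + b with gain
#' and offset drawn from wide ranges, emulating radiographs from machines
#' with inconsistent pixel-value ranges.
#'
#' @slot side integer, rendered image side in pixels.
#' @slot intensities named numeric: background, lung, thorax, mediastinum,
#'   rib, distractor (nominal scale; must satisfy lung < thorax < rib).
#' @slot lungAxes numeric(4): min/max vertical and min/max horizontal lung
#'   semi-axes as fractions of side.
#' @slot lungCenterJitter numeric, max center displacement (fraction of side).
#' @slot lungRotationMax numeric, max lung rotation (degrees).
#' @slot ribCount integer(2), min/max number of rib stripes.
#' @slot ribWidth numeric, rib stripe half-width as fraction of side.
#' @slot distractorProb numeric, probability of a distractor blob.
#' @slot distractorRadius numeric(2), blob radius range (fraction of side).
#' @slot noiseSd numeric, additive Gaussian noise sd on the nominal scale.
#' @slot gainRange numeric(2), per-image affine gain range.
#' @slot offsetRange numeric(2), per-image affine offset range.
#' @slot seed integer, base seed; phantom \code{index} derives a sub-seed.
#' @name PhantomConfig-class
#' @rdname PhantomConfig
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  side = "integer", intensities = "numeric", lungAxes = "numeric",
  lungCenterJitter = "numeric", lungRotationMax = "numeric",
  ribCount = "integer", ribWidth = "numeric", distractorProb = "numeric",
  distractorRadius = "numeric", noiseSd = "numeric", gainRange = "numeric",
  offsetRange = "numeric", seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  need <- c("background", "lung", "thorax", "mediastinum", "rib", "distractor")
  if (!all(need %in% names(object@intensities)))
    msg <- c(msg, paste("'intensities' must name:", paste(need, collapse = ", ")))
  else {
    iv <- object@intensities
    if (!(iv["lung"] < iv["thorax"] && iv["thorax"] < iv["rib"]))
      msg <- c(msg, "contrast ordering lung < thorax < rib violated")
  }
  if (object@side < 16L) msg <- c(msg, "'side' must be >= 16")
  if (length(object@lungAxes) != 4L || any(object@lungAxes <= 0))
    msg <- c(msg, "'lungAxes' must be 4 positive fractions")
  if (length(msg)) msg else TRUE
})

#' @param side,intensities,lungAxes,lungCenterJitter,lungRotationMax,ribCount
#'   see slots.
#' @param ribWidth,distractorProb,distractorRadius,noiseSd,gainRange,offsetRange,seed
#'   see slots.
#' @return a \code{PhantomConfig} object.
#' @rdname PhantomConfig
#' @export
PhantomConfig <- function(side = 128,
                          intensities = c(background = 0.10, lung = 0.20,
                                          thorax = 0.55, mediastinum = 0.75,
                                          rib = 0.85, distractor = 0.22),
                          lungAxes = c(0.24, 0.30, 0.11, 0.15),
                          lungCenterJitter = 0.02, lungRotationMax = 8,
                          ribCount = c(4, 6), ribWidth = 0.012,
                          distractorProb = 0.3,
                          distractorRadius = c(0.03, 0.06),
                          noiseSd = 0.03, gainRange = c(0.5, 4000),
                          offsetRange = c(0, 2000), seed = 1) {
  new("PhantomConfig", side = as.integer(side),
      intensities = intensities, lungAxes = as.numeric(lungAxes),
      lungCenterJitter = as.numeric(lungCenterJitter),
      lungRotationMax = as.numeric(lungRotationMax),
      ribCount = as.integer(ribCount), ribWidth = as.numeric(ribWidth),
      distractorProb = as.numeric(distractorProb),
      distractorRadius = as.numeric(distractorRadius),
      noiseSd = as.numeric(noiseSd), gainRange = as.numeric(gainRange),
      offsetRange = as.numeric(offsetRange), seed = as.integer(seed))
}

#' TransResUNet segmentation model
#'
#' Container for a TransResUNet instance: its \code{\linkS4class{ModelConfig}},
#' the flat list of trainable parameter arrays, batch-norm running
#' statistics, and (after training) the fitting history. Create with
#' \code{\link{TransResUNet}}, train with \code{\link{trainModel}}, predict
#' with \code{\link{predictMask}}.
#'
#' @slot config a \code{ModelConfig}.
#' @slot params named list of numeric arrays (trainable parameters).
#' @slot bnState named list of batch-norm running means/variances.
#' @slot trained logical.
#' @slot history data.frame with one row per epoch (train loss, val Dice).
#' @name TransResUNet-class
#' @rdname TransResUNet-class
#' @exportClass TransResUNet
setClass("TransResUNet", representation(
  config = "ModelConfig", params = "list", bnState = "list",
  trained = "logical", history = "data.frame"
))

#' @describeIn TransResUNet-class Pretty-print architecture and size.
#' @param object a \code{TransResUNet}.
#' @export
setMethod("show", "TransResUNet", function(object) {
  cfg <- object@config
  cat("TransResUNet segmentation model\n")
  cat(sprintf("  input: %d x %d grayscale\n", cfg@side, cfg@side))
  cat(sprintf("  encoder channels: %s (F1@%d, F2@%d, F3@%d)\n",
              paste(cfg@channels, collapse = "/"),
              cfg@side / 2, cfg@side / 4, cfg@side / 8))
  nt <- (cfg@side / (8L * cfg@patchStride))^2
  cat(sprintf("  transformer: %d layers, %d tokens, K=%d, %d heads\n",
              cfg@layers, nt, cfg@embedDim, cfg@heads))
  cat(sprintf("  parameters: %s\n", format(countParams(cfg), big.mark = ",")))
  cat(sprintf("  trained: %s\n", if (object@trained)
    sprintf("yes (%d epochs)", nrow(object@history)) else "no"))
})

#' @describeIn ModelConfig Pretty-print a model configuration.
#' @param object a \code{ModelConfig}.
#' @export
setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: S=%d, channels=%s, L=%d, K=%d, h=%d, mlp=%d, p=%d\n",
    object@side, paste(object@channels, collapse = "/"), object@layers,
    object@embedDim, object@heads, object@mlpDim, object@patchStride))
})

#' Accessor for a model's configuration
#' @param model a \code{TransResUNet}.
#' @return the embedded \code{ModelConfig}.
#' @export
modelConfig <- function(model) model@config

#' Accessor for a model's training history
#' @param model a \code{TransResUNet}.
#' @return data.frame of per-epoch train loss and validation Dice.
#' @export
trainHistory <- function(model) model@history
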