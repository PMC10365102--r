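#' Deterministic train/validation/test split
#'
#' Shuffles the ids with a seeded generator and cuts them by the ratio
#' rule: \code{n_train = floor(r_train * n)},
#' \code{n_val = floor(r_val * n + 0.5)} (round half up), and the test set
#' takes the remainder. At \code{n = 1158} with ratios 70:10:20 this gives
#' 810/116/232. Same seed, same split; different seeds permute membership
#' but never the sizes.
#'
#' @param ids vector of identifiers (length >= 3).
#' @param ratios numeric(3) of positive percentages summing to 100.
#' @param seed integer.
#' @return list with \code{train}, \code{val}, \code{test} — disjoint,
#'   jointly exhaustive subsets of \code{ids}.
#' @examples
#' sizes <- lengths(splitDataset(1:1158, c(70, 10, 20), seed = 1))
#' stopifnot(identical(unname(sizes), c(810L, 116L, 232L)))
#' @export
splitDataset <- function(ids, ratios = c(70, 10, 20), seed = 1) {
  n <- length(ids)
  if (n == 0L) stop("empty id list")
  if (n < 3L) stop("need at least 3 ids to split")
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 100) > 1e-8)
    stop("'ratios' must be three positive percentages summing to 100")
  nTrain <- floor(ratios[1] * n / 100)
  nVal <- floor(ratios[2] * n / 100 + 0.5)
  nTest <- n - nTrain - nVal
  perm <- withSeed(deriveSeed(seed, 17L), sample.int(n))
  shuffled <- ids[perm]
  list(train = shuffled[seq_len(nTrain)],
       val = shuffled[nTrain + seq_len(nVal)],
       test = shuffled[nTrain + nVal + seq_len(nTest)])
}

# ---- losses ----------------------------------------------------------------

# logits: n x 2, y: 0/1 vector. Returns loss, gradient and lung probability.
.lossCE <- function(logits, y) {
  P <- .softmax2(logits)
  py <- ifelse(y == 1, P[, 2], P[, 1])
  n <- length(y)
  list(loss = -mean(log(pmax(py, 1e-300))),
       dlogits = (P - unname(cbind(1 - y, y))) / n,
       prob = P[, 2])
}

.lossDice <- function(logits, y, smooth = 1) {
  P <- .softmax2(logits)
  p <- P[, 2]
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  # d(1 - num/den)/dp_i, then through the two-class softmax
  dp <- -(2 * y * den - num) / den^2
  dl2 <- dp * p * (1 - p)
  list(loss = 1 - num / den, dlogits = unname(cbind(-dl2, dl2)),
       prob = p)
}

.lossFun <- function(logits, y, kind) {
  switch(kind,
    cross_entropy = .lossCE(logits, y),
    dice = .lossDice(logits, y),
    combined = {
      a <- .lossCE(logits, y)
      b <- .lossDice(logits, y)
      list(loss = a$loss + b$loss, dlogits = a$dlogits + b$dlogits,
           prob = a$prob)
    })
}

# ---- RMSprop ---------------------------------------------------------------

# Standard RMSprop (squared-gradient smoothing alpha = 0.99, eps = 1e-8,
# no momentum), matching common framework defaults.
.rmspropStep <- function(params, grads, state, lr, alpha = 0.99,
                         eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    s <- state[[nm]]
    s <- alpha * s + (1 - alpha) * gr * gr
    state[[nm]] <- s
    params[[nm]] <- params[[nm]] - lr * gr / (sqrt(s) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ---------------------------------------------------------

#' Train a TransResUNet on preprocessed images
#'
#' Standard protocol: per epoch, shuffle the training ids, iterate batches,
#' compute the two-class per-pixel loss against the mask, take an RMSprop
#' step; then score the validation set by mean Dice of the 0.5-binarized
#' prediction. The returned model carries the parameters of the best
#' validation epoch (\code{selection = "best"}) or of the last epoch, plus
#' the per-epoch history.
#'
#' @param model an untrained (or pre-trained) \code{TransResUNet}.
#' @param images list of \code{side x side} matrices in [0,1].
#' @param masks list of matching binary matrices.
#' @param split list with \code{train} and \code{val} integer indices into
#'   \code{images} (see \code{\link{splitDataset}}); if \code{NULL}, one is
#'   drawn from \code{config@splitRatios} and \code{config@seed}.
#' @param config a \code{\link{TrainConfig}}.
#' @param verbose print a one-line summary per epoch.
#' @return the trained \code{TransResUNet}; inspect
#'   \code{\link{trainHistory}}.
#' @export
trainModel <- function(model, images, masks, split = NULL,
                       config = TrainConfig(), verbose = FALSE) {
  stopifnot(length(images) == length(masks))
  if (is.null(split))
    split <- splitDataset(seq_along(images), config@splitRatios, config@seed)
  if (length(split$train) == 0L) stop("empty training set")
  cfg <- model@config
  S <- cfg@side
  for (i in c(split$train, split$val)) {
    if (!all(dim(images[[i]]) == S))
      stop(sprintf("image %d is not %d x %d; preprocess first", i, S, S))
  }

  params <- model@params
  bnEnv <- list2env(model@bnState)
  optState <- lapply(params, function(p) p * 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric())
  best <- list(dice = -Inf, params = params, bn = as.list(bnEnv))

  valDice <- function(ps, bn) {
    if (length(split$val) == 0L) return(NA_real_)
    env <- list2env(bn)
    mean(vapply(split$val, function(i) {
      fw <- networkForward(ps, env, matrix(as.vector(images[[i]]), ncol = 1),
                           1L, cfg, train = FALSE)
      pred <- (matrix(.softmax2(fw$logits)[, 2], S, S) >= 0.5) * 1
      diceCoef(pred, masks[[i]])
    }, 1))
  }

  withSeed(deriveSeed(config@seed, 555L), {
    for (ep in seq_len(config@epochs)) {
      ord <- split$train[sample.int(length(split$train))]
      batches <- base::split(ord, ceiling(seq_along(ord) / config@batchSize))
      epLoss <- 0
      for (bt in batches) {
        B <- length(bt)
        X <- matrix(unlist(lapply(bt, function(i) as.vector(images[[i]]))),
                    ncol = 1)
        y <- unlist(lapply(bt, function(i) as.vector(masks[[i]])))
        fw <- networkForward(params, bnEnv, X, B, cfg, train = TRUE)
        ls <- .lossFun(fw$logits, y, config@loss)
        if (!is.finite(ls$loss))
          stop(sprintf(
            "non-finite loss (%g) at epoch %d, batch of ids [%s]; aborting",
            ls$loss, ep, paste(bt, collapse = ", ")))
        grads <- networkBackward(params, fw$caches, ls$dlogits, B, cfg)
        up <- .rmspropStep(params, grads, optState, config@learningRate)
        params <- up$params
        optState <- up$state
        epLoss <- epLoss + ls$loss * B
      }
      vd <- valDice(params, as.list(bnEnv))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = epLoss / length(ord), val_dice = vd))
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  val Dice %.4f", ep,
                        epLoss / length(ord), vd))
      if (!is.na(vd) && vd > best$dice)
        best <- list(dice = vd, params = params, bn = as.list(bnEnv))
    }
  })

  if (config@selection == "best" && best$dice > -Inf) {
    model@params <- best$params
    model@bnState <- best$bn
  } else {
    model@params <- params
    model@bnState <- as.list(bnEnv)
  }
  model@trained <- config@epochs > 0L
  model@history <- history
  model
}

#' Evaluate a model on a set of images
#'
#' Forward pass, post-processing, and the four segmentation scores per
#' image, plus the raw (binarize-only) Dice for comparison. The aggregate
#' is the unweighted mean over images, excluding undefined (NA) scores.
#'
#' @param model a trained \code{TransResUNet}.
#' @param images,masks lists as in \code{\link{trainModel}}.
#' @param ids indices of the images to evaluate.
#' @param postprocConfig a \code{\link{PostprocConfig}}.
#' @return list with \code{per_image} (data.frame: id, AC, SE, SP, DI,
#'   DI_raw) and \code{aggregate} (named means).
#' @export
evaluateSplit <- function(model, images, masks, ids = seq_along(images),
                          postprocConfig = PostprocConfig()) {
  rows <- lapply(ids, function(i) {
    prob <- predictMask(model, images[[i]])
    raw <- binarizeMask(prob, postprocConfig@threshold)
    post <- postprocessMask(prob, postprocConfig)
    m <- metricsReport(post, masks[[i]])
    data.frame(id = i, AC = m[["AC"]], SE = m[["SE"]], SP = m[["SP"]],
               DI = m[["DI"]], DI_raw = diceCoef(raw, masks[[i]]))
  })
  per <- do.call(rbind, rows)
  agg <- colMeans(per[, c("AC", "SE", "SP", "DI", "DI_raw")], na.rm = TRUE)
  list(per_image = per, aggregate = agg)
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding parameters, batch-norm state,
#' history and the configuration; a JSON sidecar (\code{<path>.json}) makes
#' the checkpoint self-describing.
#'
#' @param model a \code{TransResUNet}.
#' @param path checkpoint path (e.g. \code{model.rds}).
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the
#'   reconstructed \code{TransResUNet}.
#' @export
saveModel <- function(model, path) {
  cfgList <- configToList(model@config)
  saveRDS(list(config = cfgList, params = model@params,
               bnState = model@bnState, trained = model@trained,
               history = model@history), path)
  jsonlite::write_json(
    list(class = "TransResUNet", config = cfgList,
         params = countParams(model),
         package_version = as.character(packageVersion("lungfields"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  cfg <- ModelConfig(side = x$config$side, channels = x$config$channels,
                     layers = x$config$layers, embedDim = x$config$embedDim,
                     heads = x$config$heads, mlpDim = x$config$mlpDim,
                     patchStride = x$config$patchStride,
                     dropout = x$config$dropout)
  new("TransResUNet", config = cfg, params = x$params, bnState = x$bnState,
      trained = x$trained, history = x$history)
}
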