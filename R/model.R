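# TransResUNet: residual CNN encoder -> patch/position embedding ->
# transformer bottleneck -> skip-connected residual decoder -> per-pixel
# two-class head. Forward and backward passes are written out explicitly
# over the primitives in nn-core.R; parameters live in a flat named list.

# ---- parameter bookkeeping -------------------------------------------------

.resblockShapes <- function(prefix, cin, cout) {
  s <- list()
  s[[paste0(prefix, ".conv1.W")]] <- c(9L * cin, cout)
  s[[paste0(prefix, ".conv1.b")]] <- cout
  s[[paste0(prefix, ".bn1.g")]] <- cout
  s[[paste0(prefix, ".bn1.b")]] <- cout
  s[[paste0(prefix, ".conv2.W")]] <- c(9L * cout, cout)
  s[[paste0(prefix, ".conv2.b")]] <- cout
  s[[paste0(prefix, ".bn2.g")]] <- cout
  s[[paste0(prefix, ".bn2.b")]] <- cout
  if (cin != cout) {
    s[[paste0(prefix, ".sc.W")]] <- c(cin, cout)
    s[[paste0(prefix, ".sc.b")]] <- cout
  }
  s
}

#' Parameter shapes of a TransResUNet configuration
#'
#' Enumerates every trainable array of the architecture and its dimensions,
#' without allocating any parameter memory. \code{\link{countParams}} sums
#' these; initialization allocates from them.
#'
#' @param config a \code{\link{ModelConfig}}.
#' @return named list; each element is the dim vector of one parameter.
#' @export
paramShapes <- function(config) {
  ch <- config@channels; K <- config@embedDim; p <- config@patchStride
  gs <- config@side %/% (8L * p)
  N <- gs * gs
  s <- c(.resblockShapes("enc1", 1L, ch[1]),
         .resblockShapes("enc2", ch[1], ch[2]),
         .resblockShapes("enc3", ch[2], ch[3]))
  s[["embed.W"]] <- c(p * p * ch[3], K)
  s[["embed.b"]] <- K
  s[["embed.pos"]] <- c(N, K)
  for (l in seq_len(config@layers)) {
    pre <- paste0("tr", l)
    s[[paste0(pre, ".ln1.g")]] <- K
    s[[paste0(pre, ".ln1.b")]] <- K
    for (nm in c("q", "k", "v", "o")) {
      s[[paste0(pre, ".", nm, ".W")]] <- c(K, K)
      s[[paste0(pre, ".", nm, ".b")]] <- K
    }
    s[[paste0(pre, ".ln2.g")]] <- K
    s[[paste0(pre, ".ln2.b")]] <- K
    s[[paste0(pre, ".mlp1.W")]] <- c(K, config@mlpDim)
    s[[paste0(pre, ".mlp1.b")]] <- config@mlpDim
    s[[paste0(pre, ".mlp2.W")]] <- c(config@mlpDim, K)
    s[[paste0(pre, ".mlp2.b")]] <- K
  }
  s <- c(s, .resblockShapes("dec3", K + ch[3], ch[3]),
         .resblockShapes("dec2", ch[3] + ch[2], ch[2]),
         .resblockShapes("dec1", ch[2] + ch[1], ch[1]))
  s[["head.W"]] <- c(ch[1], config@numClasses)
  s[["head.b"]] <- config@numClasses
  s
}

#' Number of trainable parameters
#'
#' @param x a \code{\link{ModelConfig}} or a \code{TransResUNet} model.
#' @return integer-valued numeric count.
#' @examples
#' countParams(ModelConfig(side = 64, channels = c(8, 16, 32), layers = 2,
#'                         embedDim = 64, heads = 4))
#' @export
countParams <- function(x) {
  if (is(x, "TransResUNet")) return(sum(vapply(x@params, length, 1)))
  sum(vapply(paramShapes(x), prod, 1))
}

# Truncated-normal init (values resampled into +-2 sd), ViT convention.
.truncNorm <- function(n, sd = 0.02) {
  x <- rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

.initParams <- function(shapes) {
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    n <- prod(d)
    vals <-
      if (grepl("\\.conv[12]\\.W$", nm)) rnorm(n, sd = sqrt(2 / d[1]))
      else if (grepl("\\.sc\\.W$", nm)) rnorm(n, sd = sqrt(2 / d[1]))
      else if (grepl("\\.bn2\\.g$", nm)) rep(0, n)     # residual branch opens at 0
      else if (grepl("\\.(bn1|ln1|ln2)\\.g$", nm)) rep(1, n)
      else if (grepl("\\.b$", nm)) rep(0, n)
      else .truncNorm(n)                               # projections, pos table
    out[[nm]] <- if (length(d) == 2L) matrix(vals, d[1], d[2]) else vals
  }
  out
}

.bnNames <- function(config) {
  pre <- c("enc1", "enc2", "enc3", "dec3", "dec2", "dec1")
  as.vector(outer(pre, c("bn1", "bn2"), paste, sep = "."))
}

.bnStateInit <- function(config) {
  ch <- config@channels
  width <- c(enc1 = ch[1], enc2 = ch[2], enc3 = ch[3],
             dec3 = ch[3], dec2 = ch[2], dec1 = ch[1])
  st <- list()
  for (nm in .bnNames(config)) {
    w <- width[[sub("\\.bn[12]$", "", nm)]]
    st[[paste0(nm, ".mean")]] <- rep(0, w)
    st[[paste0(nm, ".var")]] <- rep(1, w)
  }
  st
}

#' Create an untrained TransResUNet
#'
#' Initializes all parameters: He-normal for convolutions, truncated normal
#' (sd 0.02) for projections and position embeddings, unity/zero for
#' normalization scales — except the closing batch-norm scale of every
#' residual branch, which starts at zero so each residual block begins as
#' its shortcut (stable small-data training).
#'
#' @param config a \code{\link{ModelConfig}}.
#' @param seed integer seed for initialization.
#' @return a \code{\linkS4class{TransResUNet}}.
#' @examples
#' m <- TransResUNet(ModelConfig(side = 64, channels = c(8, 16, 32),
#'                               layers = 2, embedDim = 64, heads = 4))
#' m
#' @export
TransResUNet <- function(config = ModelConfig(), seed = 1) {
  params <- withSeed(deriveSeed(seed, 31L), .initParams(paramShapes(config)))
  new("TransResUNet", config = config, params = params,
      bnState = .bnStateInit(config), trained = FALSE,
      history = data.frame())
}

#' Access or replace a model's parameter arrays
#'
#' The flat named list of trainable arrays (e.g. \code{"tr1.q.W"},
#' \code{"dec2.conv1.W"}). Replacement validates names and shapes.
#'
#' @param model a \code{TransResUNet}.
#' @export
modelParams <- function(model) model@params

#' @param value named list matching \code{modelParams(model)} in names and
#'   shapes.
#' @rdname modelParams
#' @export
`modelParams<-` <- function(model, value) {
  stopifnot(identical(sort(names(value)), sort(names(model@params))))
  for (nm in names(value))
    stopifnot(length(value[[nm]]) == length(model@params[[nm]]))
  model@params <- value[names(model@params)]
  model
}

# ---- residual block --------------------------------------------------------

resblockForward <- function(params, bnEnv, prefix, X, H, W, B, train) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  c1 <- convForward(X, p("conv1.W"), p("conv1.b"), H, W, B)
  b1 <- bnForward(c1$Y, p("bn1.g"), p("bn1.b"), bnEnv,
                  paste0(prefix, ".bn1"), train)
  r1 <- reluForward(b1$Y)
  c2 <- convForward(r1$Y, p("conv2.W"), p("conv2.b"), H, W, B)
  b2 <- bnForward(c2$Y, p("bn2.g"), p("bn2.b"), bnEnv,
                  paste0(prefix, ".bn2"), train)
  r2 <- reluForward(b2$Y)
  if (is.null(p("sc.W"))) {
    sc <- NULL
    Y <- r2$Y + X
  } else {
    sc <- linForward(X, p("sc.W"), p("sc.b"))
    Y <- r2$Y + sc$Y
  }
  list(Y = Y, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2, sc = sc)
}

resblockBackward <- function(params, prefix, cache, dY, grads) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  g <- function(s, v) grads[[paste0(prefix, ".", s)]] <<- v
  # shortcut branch
  if (is.null(cache$sc)) {
    dXsc <- dY
  } else {
    lb <- linBackward(cache$sc, dY, p("sc.W"))
    g("sc.W", lb$dW); g("sc.b", lb$db)
    dXsc <- lb$dX
  }
  # transform branch
  d <- reluBackward(cache$r2, dY)
  bb <- bnBackward(cache$b2, d, p("bn2.g"))
  g("bn2.g", bb$dg); g("bn2.b", bb$db)
  cb <- convBackward(cache$c2, bb$dX, p("conv2.W"))
  g("conv2.W", cb$dW); g("conv2.b", cb$db)
  d <- reluBackward(cache$r1, cb$dX)
  bb <- bnBackward(cache$b1, d, p("bn1.g"))
  g("bn1.g", bb$dg); g("bn1.b", bb$db)
  cb <- convBackward(cache$c1, bb$dX, p("conv1.W"))
  g("conv1.W", cb$dW); g("conv1.b", cb$db)
  list(dX = cb$dX + dXsc, grads = grads)
}

# ---- patch / position embedding -------------------------------------------

# token order is row-major over the token grid; pixel rows are column-major
.patchIdx <- function(Hf, p, B) {
  .cached(sprintf("patch_%d_%d_%d", Hf, p, B), function() {
    gs <- Hf %/% p
    N <- gs * gs
    tok <- seq_len(N) - 1L
    R <- tok %/% gs + 1L
    Cc <- tok %% gs + 1L
    out <- vector("list", p * p)
    j <- 0L
    for (u in seq_len(p)) for (v in seq_len(p)) {
      j <- j + 1L
      pr <- p * (R - 1L) + u
      pc <- p * (Cc - 1L) + v
      out[[j]] <- .batchIdx((pc - 1L) * Hf + pr, B, Hf * Hf)
    }
    # row-major within patch: u outer, v inner -> (u-1)*p + v
    out2 <- vector("list", p * p)
    j <- 0L
    for (u in seq_len(p)) for (v in seq_len(p)) {
      j <- j + 1L
      out2[[(u - 1L) * p + v]] <- out[[j]]
    }
    out2
  })
}

patchifyForward <- function(params, F3, Hf, B, config, train) {
  idx <- .patchIdx(Hf, config@patchStride, B)
  cols <- do.call(cbind, lapply(idx, function(ix) F3[ix, , drop = FALSE]))
  tok <- cols %*% params[["embed.W"]]
  tok <- tok + rep(params[["embed.b"]], each = nrow(tok))
  N <- nrow(params[["embed.pos"]])
  posRows <- rep(seq_len(N), times = B)
  tok <- tok + params[["embed.pos"]][posRows, , drop = FALSE]
  dp <- dropForward(tok, config@dropout, train)
  list(Y = dp$Y, cols = cols, idx = idx, posRows = posRows, drop = dp,
       nIn = nrow(F3), Cin = ncol(F3))
}

patchifyBackward <- function(params, cache, dY, grads) {
  dtok <- dropBackward(cache$drop, dY)
  N <- nrow(params[["embed.pos"]])
  grads[["embed.pos"]] <- unname(rowsum(dtok, group = cache$posRows))
  grads[["embed.b"]] <- colSums(dtok)
  grads[["embed.W"]] <- crossprod(cache$cols, dtok)
  dcols <- dtok %*% t(params[["embed.W"]])
  Cin <- cache$Cin
  dF3 <- matrix(0, cache$nIn, Cin)
  for (j in seq_along(cache$idx)) {
    blk <- dcols[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
    dF3[cache$idx[[j]], ] <- blk    # each pixel belongs to exactly one patch
  }
  list(dF3 = dF3, grads = grads)
}

# tokens (row-major grid) -> feature map (column-major pixels), upsampled to
# the S/8 grid when patchStride > 1
detokenForward <- function(tok, B, config) {
  p <- config@patchStride
  Hf <- config@side %/% 8L
  gs <- Hf %/% p
  idx <- .patchIdx(gs, 1L, B)[[1]]       # token row -> grid pixel row
  map <- matrix(0, nrow(tok), ncol(tok))
  map[idx, ] <- tok
  cache <- list(idx = idx, up = NULL)
  if (p > 1L) {
    up <- upForward(map, gs, gs, B, p)
    cache$up <- up
    map <- up$Y
  }
  list(Y = map, cache = cache)
}

detokenBackward <- function(cache, dY) {
  if (!is.null(cache$up)) dY <- upBackward(cache$up, dY)
  dY[cache$idx, , drop = FALSE]
}

# ---- transformer -----------------------------------------------------------

msaForward <- function(params, prefix, X, B, config) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  K <- config@embedDim; h <- config@heads; dk <- K %/% h
  scale <- 1 / sqrt(dk)
  N <- nrow(X) %/% B
  Q <- linForward(X, p("q.W"), p("q.b"))
  Kp <- linForward(X, p("k.W"), p("k.b"))
  V <- linForward(X, p("v.W"), p("v.b"))
  O <- matrix(0, nrow(X), K)
  A <- vector("list", B * h)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (hh in seq_len(h)) {
      cls <- ((hh - 1L) * dk + 1L):(hh * dk)
      Ab <- softmaxRows(Q$Y[rows, cls, drop = FALSE] %*%
                          t(Kp$Y[rows, cls, drop = FALSE]) * scale)
      A[[(b - 1L) * h + hh]] <- Ab
      O[rows, cls] <- Ab %*% V$Y[rows, cls, drop = FALSE]
    }
  }
  out <- linForward(O, p("o.W"), p("o.b"))
  list(Y = out$Y, Q = Q, K = Kp, V = V, A = A, O = out, Bn = B, N = N)
}

msaBackward <- function(params, prefix, cache, dY, grads, config) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  g <- function(s, v) grads[[paste0(prefix, ".", s)]] <<- v
  K <- config@embedDim; h <- config@heads; dk <- K %/% h
  scale <- 1 / sqrt(dk)
  B <- cache$Bn; N <- cache$N
  ob <- linBackward(cache$O, dY, p("o.W"))
  g("o.W", ob$dW); g("o.b", ob$db)
  dO <- ob$dX
  dQ <- matrix(0, nrow(dY), K)
  dK <- matrix(0, nrow(dY), K)
  dV <- matrix(0, nrow(dY), K)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (hh in seq_len(h)) {
      cls <- ((hh - 1L) * dk + 1L):(hh * dk)
      Ab <- cache$A[[(b - 1L) * h + hh]]
      Qh <- cache$Q$Y[rows, cls, drop = FALSE]
      Kh <- cache$K$Y[rows, cls, drop = FALSE]
      Vh <- cache$V$Y[rows, cls, drop = FALSE]
      dOh <- dO[rows, cls, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[rows, cls] <- crossprod(Ab, dOh)
      dS <- Ab * (dA - rowSums(dA * Ab))
      dQ[rows, cls] <- dS %*% Kh * scale
      dK[rows, cls] <- crossprod(dS, Qh) * scale
    }
  }
  qb <- linBackward(cache$Q, dQ, p("q.W")); g("q.W", qb$dW); g("q.b", qb$db)
  kb <- linBackward(cache$K, dK, p("k.W")); g("k.W", kb$dW); g("k.b", kb$db)
  vb <- linBackward(cache$V, dV, p("v.W")); g("v.W", vb$dW); g("v.b", vb$db)
  list(dX = qb$dX + kb$dX + vb$dX, grads = grads)
}

# pre-normalization residual form: x + MSA(LN(x)), then x + MLP(LN(x))
transformerLayerForward <- function(params, prefix, X, B, config, train) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  l1 <- lnForward(X, p("ln1.g"), p("ln1.b"))
  at <- msaForward(params, prefix, l1$Y, B, config)
  d1 <- dropForward(at$Y, config@dropout, train)
  x1 <- X + d1$Y
  l2 <- lnForward(x1, p("ln2.g"), p("ln2.b"))
  m1 <- linForward(l2$Y, p("mlp1.W"), p("mlp1.b"))
  ge <- geluForward(m1$Y)
  m2 <- linForward(ge$Y, p("mlp2.W"), p("mlp2.b"))
  d2 <- dropForward(m2$Y, config@dropout, train)
  list(Y = x1 + d2$Y, l1 = l1, at = at, d1 = d1, l2 = l2, m1 = m1, ge = ge,
       m2 = m2, d2 = d2)
}

transformerLayerBackward <- function(params, prefix, cache, dY, grads,
                                     config) {
  p <- function(s) params[[paste0(prefix, ".", s)]]
  g <- function(s, v) grads[[paste0(prefix, ".", s)]] <<- v
  dm <- dropBackward(cache$d2, dY)
  m2 <- linBackward(cache$m2, dm, p("mlp2.W"))
  g("mlp2.W", m2$dW); g("mlp2.b", m2$db)
  dge <- geluBackward(cache$ge, m2$dX)
  m1 <- linBackward(cache$m1, dge, p("mlp1.W"))
  g("mlp1.W", m1$dW); g("mlp1.b", m1$db)
  l2 <- lnBackward(cache$l2, m1$dX, p("ln2.g"))
  g("ln2.g", l2$dg); g("ln2.b", l2$db)
  dx1 <- dY + l2$dX
  da <- dropBackward(cache$d1, dx1)
  ms <- msaBackward(params, prefix, cache$at, da, grads, config)
  grads <- ms$grads
  l1 <- lnBackward(cache$l1, ms$dX, p("ln1.g"))
  g("ln1.g", l1$dg); g("ln1.b", l1$db)
  list(dX = dx1 + l1$dX, grads = grads)
}

# ---- full network ----------------------------------------------------------

networkForward <- function(params, bnEnv, X, B, config, train = FALSE) {
  S <- config@side
  caches <- list()
  cur <- X; H <- S
  feats <- vector("list", 3L)
  for (i in 1:3) {
    rb <- resblockForward(params, bnEnv, paste0("enc", i), cur, H, H, B, train)
    caches[[paste0("enc", i)]] <- rb
    pl <- poolForward(rb$Y, H, H, B)
    caches[[paste0("pool", i)]] <- pl
    cur <- pl$Y
    H <- H %/% 2L
    feats[[i]] <- cur
  }
  pe <- patchifyForward(params, cur, H, B, config, train)
  caches$embed <- pe
  tok <- pe$Y
  for (l in seq_len(config@layers)) {
    tl <- transformerLayerForward(params, paste0("tr", l), tok, B, config,
                                  train)
    caches[[paste0("tr", l)]] <- tl
    tok <- tl$Y
  }
  dm <- detokenForward(tok, B, config)
  caches$detoken <- dm$cache
  cur <- dm$Y
  H <- S %/% 8L
  for (i in 3:1) {
    caches[[paste0("catdim", i)]] <- ncol(cur)
    rb <- resblockForward(params, bnEnv, paste0("dec", i),
                          cbind(cur, feats[[i]]), H, H, B, train)
    caches[[paste0("dec", i)]] <- rb
    up <- upForward(rb$Y, H, H, B, 2L)
    caches[[paste0("up", i)]] <- up
    cur <- up$Y
    H <- H * 2L
  }
  hd <- linForward(cur, params[["head.W"]], params[["head.b"]])
  caches$head <- hd
  list(logits = hd$Y, caches = caches, feats = feats, tokens = pe$Y,
       ft = tok)
}

networkBackward <- function(params, caches, dlogits, B, config) {
  grads <- list()
  hb <- linBackward(caches$head, dlogits, params[["head.W"]])
  grads[["head.W"]] <- hb$dW; grads[["head.b"]] <- hb$db
  dcur <- hb$dX
  dfeats <- vector("list", 3L)
  for (i in 1:3) {
    dcur <- upBackward(caches[[paste0("up", i)]], dcur)
    rb <- resblockBackward(params, paste0("dec", i),
                           caches[[paste0("dec", i)]], dcur, grads)
    grads <- rb$grads
    k <- caches[[paste0("catdim", i)]]
    dcur <- rb$dX[, seq_len(k), drop = FALSE]
    dfeats[[i]] <- rb$dX[, (k + 1L):ncol(rb$dX), drop = FALSE]
  }
  dtok <- detokenBackward(caches$detoken, dcur)
  for (l in rev(seq_len(config@layers))) {
    tb <- transformerLayerBackward(params, paste0("tr", l),
                                   caches[[paste0("tr", l)]], dtok, grads,
                                   config)
    grads <- tb$grads
    dtok <- tb$dX
  }
  pb <- patchifyBackward(params, caches$embed, dtok, grads)
  grads <- pb$grads
  dcur <- pb$dF3 + dfeats[[3]]
  for (i in 3:1) {
    if (i < 3L) dcur <- dcur + dfeats[[i]]
    dcur <- poolBackward(caches[[paste0("pool", i)]], dcur)
    rb <- resblockBackward(params, paste0("enc", i),
                           caches[[paste0("enc", i)]], dcur, grads)
    grads <- rb$grads
    dcur <- rb$dX
  }
  grads
}

# ---- prediction ------------------------------------------------------------

#' Predict a lung-probability map
#'
#' Runs the network in evaluation mode (batch-norm running statistics, no
#' dropout) on one preprocessed image and returns the per-pixel probability
#' of the lung class; the two class scores at each pixel sum to one.
#'
#' @param model a trained (or untrained) \code{TransResUNet}.
#' @param image numeric \code{side x side} matrix in [0,1]
#'   (see \code{\link{preprocessImage}}).
#' @param intermediates if \code{TRUE}, also return encoder features,
#'   embedded tokens and the transformer output.
#' @return probability matrix in [0,1]; or, with
#'   \code{intermediates = TRUE}, a list with \code{prob}, \code{F1},
#'   \code{F2}, \code{F3} (pixels x channels matrices), \code{tokens} and
#'   \code{ft}.
#' @export
predictMask <- function(model, image, intermediates = FALSE) {
  cfg <- model@config
  if (!all(dim(image) == cfg@side))
    stop(sprintf("image must be %d x %d; got %d x %d", cfg@side, cfg@side,
                 nrow(image), ncol(image)))
  bnEnv <- list2env(model@bnState)
  fw <- networkForward(model@params, bnEnv, matrix(as.vector(image), ncol = 1),
                       1L, cfg, train = FALSE)
  prob <- matrix(.softmax2(fw$logits)[, 2], cfg@side, cfg@side)
  if (!intermediates) return(prob)
  list(prob = prob, F1 = fw$feats[[1]], F2 = fw$feats[[2]],
       F3 = fw$feats[[3]], tokens = fw$tokens, ft = fw$ft)
}

.softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  unname(cbind(e1, e2) / (e1 + e2))
}
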