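# Neural-network primitives on BLAS-backed matrices.
#
# Feature maps are stored as (B*H*W) x C matrices: pixels in column-major
# order within each image, images stacked along rows. All layers come as a
# *Forward() returning list(Y = output, ...cache) and a matching
# *Backward() consuming the cache and the output gradient. Index vectors
# for convolution gather/scatter, pooling and upsampling are precomputed
# and cached per (layout, shape).

.nnCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  v <- .nnCache[[key]]
  if (is.null(v)) {
    v <- build()
    .nnCache[[key]] <- v
  }
  v
}

.batchIdx <- function(idx, B, nIn) {
  # replicate a single-image index vector across B stacked images;
  # zeros (padding) stay zero
  if (B == 1L) return(idx)
  as.vector(vapply(0:(B - 1L), function(b) {
    v <- idx
    v[v > 0L] <- v[v > 0L] + b * nIn
    v
  }, integer(length(idx))))
}

# --- 3x3 same-padding convolution (im2col + GEMM) ------------------------

.convIdx <- function(H, W, B) {
  .cached(sprintf("conv_%d_%d_%d", H, W, B), function() {
    r <- rep(seq_len(H), W)
    cc <- rep(seq_len(W), each = H)
    n <- H * W
    idx1 <- vector("list", 9L)
    k <- 0L
    for (dc in -1:1) for (dr in -1:1) {
      k <- k + 1L
      rp <- r + dr; cp <- cc + dc
      ok <- rp >= 1L & rp <= H & cp >= 1L & cp <= W
      v <- integer(n)
      v[ok] <- (cp[ok] - 1L) * H + rp[ok]
      idx1[[k]] <- v
    }
    lapply(idx1, .batchIdx, B = B, nIn = n)
  })
}

convForward <- function(X, W, b, H, Wd, B) {
  idx <- .convIdx(H, Wd, B)
  Xa <- rbind(0, X)                      # row 1 = zero padding target
  cols <- do.call(cbind, lapply(idx, function(ix) Xa[ix + 1L, , drop = FALSE]))
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, cols = cols, idx = idx, Cin = ncol(X), nIn = nrow(X))
}

convBackward <- function(cache, dY, W) {
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(W)
  Cin <- cache$Cin
  dX <- matrix(0, cache$nIn, Cin)
  # scatter-add for offset k == gather with the mirrored offset 10-k
  for (k in 1:9) {
    blkAug <- rbind(0, dcols[, ((k - 1L) * Cin + 1L):(k * Cin),
                             drop = FALSE])
    dX <- dX + blkAug[cache$idx[[10L - k]] + 1L, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# --- pointwise (1x1) linear layer -----------------------------------------

linForward <- function(X, W, b) {
  Y <- X %*% W
  list(Y = Y + rep(b, each = nrow(Y)), X = X)
}

linBackward <- function(cache, dY, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# --- batch normalization (per channel over all pixels in the batch) -------

bnForward <- function(X, g, b, bnEnv, name, train, momentum = 0.1,
                      eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = nrow(X))
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * rep(ivar, each = nrow(X))
    bnEnv[[paste0(name, ".mean")]] <-
      (1 - momentum) * bnEnv[[paste0(name, ".mean")]] + momentum * mu
    bnEnv[[paste0(name, ".var")]] <-
      (1 - momentum) * bnEnv[[paste0(name, ".var")]] + momentum * v
  } else {
    mu <- bnEnv[[paste0(name, ".mean")]]
    v <- bnEnv[[paste0(name, ".var")]]
    ivar <- 1 / sqrt(v + eps)
    xhat <- (X - rep(mu, each = nrow(X))) * rep(ivar, each = nrow(X))
  }
  Y <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(Y = Y, xhat = xhat, ivar = ivar)
}

bnBackward <- function(cache, dY, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
    rep(cache$ivar, each = n)
  list(dX = dX, dg = dg, db = db)
}

# --- rectifier -------------------------------------------------------------

reluForward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

reluBackward <- function(cache, dY) dY * cache$mask

# --- 2x2 max pooling, stride 2 --------------------------------------------

.poolIdx <- function(H, W, B) {
  .cached(sprintf("pool_%d_%d_%d", H, W, B), function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    ro <- rep(seq_len(Ho), Wo)
    co <- rep(seq_len(Wo), each = Ho)
    out <- vector("list", 4L)
    k <- 0L
    for (dc in 0:1) for (dr in 0:1) {
      k <- k + 1L
      out[[k]] <- .batchIdx((2L * co - 2L + dc) * H + (2L * ro - 1L + dr),
                            B, H * W)
    }
    out
  })
}

# argmax code of each input pixel's position within its 2x2 window
.poolKvec <- function(H, W, B) {
  .cached(sprintf("poolk_%d_%d_%d", H, W, B), function() {
    r <- rep(seq_len(H), W)
    cc <- rep(seq_len(W), each = H)
    rep(1L + (r - 1L) %% 2L + 2L * ((cc - 1L) %% 2L), times = B)
  })
}

poolForward <- function(X, H, W, B) {
  idx <- .poolIdx(H, W, B)
  A1 <- X[idx[[1]], , drop = FALSE]; A2 <- X[idx[[2]], , drop = FALSE]
  A3 <- X[idx[[3]], , drop = FALSE]; A4 <- X[idx[[4]], , drop = FALSE]
  M <- pmax(A1, A2, A3, A4)
  # first-max wins on ties: assign in reverse priority
  wh <- matrix(4L, nrow(M), ncol(M))
  wh[A3 == M] <- 3L
  wh[A2 == M] <- 2L
  wh[A1 == M] <- 1L
  list(Y = M, wh = wh, H = H, W = W, B = B, nIn = nrow(X))
}

poolBackward <- function(cache, dY) {
  # gather formulation: each input pixel looks up its window's output and
  # takes the gradient iff it was the (first) argmax
  up <- .upIdx(cache$H %/% 2L, cache$W %/% 2L, cache$B, 2L)
  kv <- .poolKvec(cache$H, cache$W, cache$B)
  dY[up, , drop = FALSE] * (cache$wh[up, , drop = FALSE] == kv)
}

# --- nearest-neighbor upsampling by integer factor -------------------------

.upIdx <- function(H, W, B, f) {
  .cached(sprintf("up_%d_%d_%d_%d", H, W, B, f), function() {
    Ho <- H * f; Wo <- W * f
    ro <- rep(seq_len(Ho), Wo)
    co <- rep(seq_len(Wo), each = Ho)
    .batchIdx(((co + f - 1L) %/% f - 1L) * H + (ro + f - 1L) %/% f, B, H * W)
  })
}

upForward <- function(X, H, W, B, f) {
  idx <- .upIdx(H, W, B, f)
  list(Y = X[idx, , drop = FALSE], idx = idx, nIn = nrow(X))
}

upBackward <- function(cache, dY) {
  # every input pixel receives f^2 output gradients; groups 1..nIn are all
  # present so rowsum returns them in natural order
  unname(rowsum(dY, group = cache$idx))
}

# --- layer normalization (per token row) -----------------------------------

lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * ivar
  Y <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(Y = Y, xhat = xhat, ivar = ivar)
}

lnBackward <- function(cache, dY, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$ivar
  list(dX = dX, dg = dg, db = db)
}

# --- GELU -------------------------------------------------------------------

geluForward <- function(X) list(Y = X * stats::pnorm(X), X = X)

geluBackward <- function(cache, dY) {
  x <- cache$X
  dY * (stats::pnorm(x) + x * stats::dnorm(x))
}

# --- row softmax ------------------------------------------------------------

softmaxRows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# --- inverted dropout -------------------------------------------------------

dropForward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

dropBackward <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}
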