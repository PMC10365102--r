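# Shared fixtures: tiny model configurations and phantom data small enough
# for fast unit tests.

tinyModelConfig <- function(side = 64, layers = 2)
  ModelConfig(side = side, channels = c(8, 16, 32), layers = layers,
              embedDim = 64, heads = 4)

microModelConfig <- function()
  ModelConfig(side = 32, channels = c(4, 8, 16), layers = 1, embedDim = 32,
              heads = 2, dropout = 0)

testPhantoms <- function(n, side = 64, modelSide = 64, seed = 7) {
  cfg <- PhantomConfig(side = side, seed = seed)
  imgs <- vector("list", n)
  msks <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(cfg, i)
    imgs[[i]] <- preprocessImage(ph$image, side = modelSide)
    msks[[i]] <- resizeNearest(ph$mask, modelSide)
  }
  list(images = imgs, masks = msks)
}

# independent flood-fill component labeling (queue-based BFS), used as the
# oracle for the graph-based labeler
bfsLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] == 1 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          r <- p[1] + o[1]; cc <- p[2] + o[2]
          if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
              mask[r, cc] == 1 && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue <- c(queue, list(c(r, cc)))
          }
        }
      }
    }
  }
  lab
}

# canonical component partition (order-independent): list of sorted pixel
# index sets, sorted by first element
componentSets <- function(lab) {
  s <- lapply(seq_len(max(lab, 1L)), function(k) sort(which(lab == k)))
  s <- Filter(length, s)
  s[order(vapply(s, `[`, 1L, 1))]
}
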