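ns <- asNamespace("lungfields")

test_that("parameter counts follow the layer shapes analytically", {
  tiny <- tinyModelConfig()
  # independent analytic count
  rb <- function(cin, cout)
    9 * cin * cout + cout + 9 * cout^2 + cout + 4 * cout +
      if (cin != cout) cin * cout + cout else 0
  K <- 64; mlp <- 256; N <- 64
  trl <- 4 * K + 4 * (K^2 + K) + K * mlp + mlp + mlp * K + K
  analytic <- rb(1, 8) + rb(8, 16) + rb(16, 32) +
    32 * K + K + N * K + 2 * trl +
    rb(K + 32, 32) + rb(32 + 16, 16) + rb(16 + 8, 8) + 8 * 2 + 2
  expect_equal(countParams(tiny), analytic)
  expect_lt(countParams(tiny), 2e6)
  # instantiated arrays agree with the shape enumeration
  m <- TransResUNet(tiny, seed = 1)
  expect_equal(countParams(m), countParams(tiny))
  # full-scale configuration sits in the tens of millions
  full <- countParams(ModelConfig())
  expect_gt(full, 2e7)
  expect_lt(full, 2e8)
})

test_that("config validity catches inconsistent geometry", {
  expect_error(ModelConfig(side = 60), "divisible")
  expect_error(ModelConfig(embedDim = 65, heads = 4), "divisible")
  expect_s4_class(tinyModelConfig(), "ModelConfig")
})

test_that("a zero-weight residual block is the identity map", {
  cfg <- tinyModelConfig()
  shapes <- ns$.resblockShapes("t", 8L, 8L)
  params <- lapply(shapes, function(d)
    if (length(d) == 2) matrix(0, d[1], d[2]) else rep(0, d))
  bnEnv <- new.env()
  bnEnv[["t.bn1.mean"]] <- rep(0, 8); bnEnv[["t.bn1.var"]] <- rep(1, 8)
  bnEnv[["t.bn2.mean"]] <- rep(0, 8); bnEnv[["t.bn2.var"]] <- rep(1, 8)
  set.seed(1)
  X <- matrix(rnorm(16 * 16 * 8), 16 * 16, 8)
  for (train in c(TRUE, FALSE)) {
    out <- ns$resblockForward(params, bnEnv, "t", X, 16L, 16L, 1L, train)
    expect_equal(out$Y, X)
  }
})

test_that("a projection-shortcut block maps channels and stays finite", {
  m <- TransResUNet(microModelConfig(), seed = 3)
  bnEnv <- list2env(m@bnState)
  set.seed(4)
  X2 <- matrix(rnorm(64 * 4), 64, 4)       # enc2 projects 4 -> 8 channels
  out <- ns$resblockForward(m@params, bnEnv, "enc2", X2, 8L, 8L, 1L, FALSE)
  expect_equal(dim(out$Y), c(64L, 8L))
  expect_true(all(is.finite(out$Y)))
})

test_that("transformer layers with zero MSA/MLP weights are identities and
           attention rows are stochastic", {
  cfg <- tinyModelConfig()
  m <- TransResUNet(cfg, seed = 5)
  params <- m@params
  for (nm in grep("^tr1\\.(q|k|v|o|mlp1|mlp2)\\.", names(params),
                  value = TRUE))
    params[[nm]] <- params[[nm]] * 0
  set.seed(6)
  tok <- matrix(rnorm(64 * 64), 64, 64)
  out <- ns$transformerLayerForward(params, "tr1", tok, 1L, cfg, FALSE)
  expect_equal(out$Y, tok)
  # attention rows sum to one (with live weights)
  at <- ns$msaForward(m@params, "tr2", tok, 1L, cfg)
  for (A in at$A) expect_equal(rowSums(A), rep(1, 64))
})

test_that("a single token passes attention as its value projection", {
  cfg <- tinyModelConfig()
  m <- TransResUNet(cfg, seed = 8)
  p <- m@params
  tok <- matrix(rnorm(64), 1, 64)
  at <- ns$msaForward(p, "tr1", tok, 1L, cfg)
  v <- tok %*% p[["tr1.v.W"]] + rep(p[["tr1.v.b"]], each = 1)
  expect_equal(at$Y, v %*% p[["tr1.o.W"]] + rep(p[["tr1.o.b"]], each = 1))
})

test_that("a zero-layer bottleneck passes tokens through unchanged", {
  cfg <- tinyModelConfig(layers = 0)
  m <- TransResUNet(cfg, seed = 2)
  img <- testPhantoms(1, side = 64)$images[[1]]
  out <- predictMask(m, img, intermediates = TRUE)
  expect_identical(out$tokens, out$ft)
  expect_equal(dim(out$prob), c(64, 64))
})

test_that("the transformer stack is token-permutation equivariant when
           position embeddings vanish", {
  cfg <- tinyModelConfig()
  m <- TransResUNet(cfg, seed = 9)
  params <- m@params
  set.seed(10)
  tok <- matrix(rnorm(64 * 64), 64, 64)
  perm <- sample(64)
  runStack <- function(x) {
    for (l in 1:2)
      x <- ns$transformerLayerForward(params, paste0("tr", l), x, 1L, cfg,
                                      FALSE)$Y
    x
  }
  expect_equal(runStack(tok)[perm, ], runStack(tok[perm, , drop = FALSE]))
})

test_that("shape and probability contracts hold across a randomized grid of
           valid configurations", {
  set.seed(123)
  grid <- list(
    ModelConfig(side = 32, channels = c(4, 8, 16), layers = 1,
                embedDim = 32, heads = 2),
    ModelConfig(side = 32, channels = c(6, 6, 12), layers = 2,
                embedDim = 24, heads = 3, mlpDim = 48),
    ModelConfig(side = 64, channels = c(4, 8, 8), layers = 1,
                embedDim = 16, heads = 4, patchStride = 2),
    ModelConfig(side = 48, channels = c(5, 7, 9), layers = 0,
                embedDim = 20, heads = 5, patchStride = 2))
  for (cfg in grid) {
    m <- TransResUNet(cfg, seed = 1)
    img <- matrix(runif(cfg@side^2), cfg@side, cfg@side)
    p <- predictMask(m, img)
    expect_equal(dim(p), c(cfg@side, cfg@side))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("evaluation-mode forward passes are bitwise reproducible", {
  m <- TransResUNet(tinyModelConfig(), seed = 13)
  img <- testPhantoms(1, side = 64)$images[[1]]
  expect_identical(predictMask(m, img), predictMask(m, img))
  expect_error(predictMask(m, matrix(0, 32, 32)), "must be 64 x 64")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- microModelConfig()
  m <- TransResUNet(cfg, seed = 21)
  params <- m@params
  set.seed(22)
  img <- matrix(runif(32 * 32), 32, 32)
  y <- as.vector((matrix(runif(32 * 32), 32, 32) > 0.7) * 1)
  X <- matrix(as.vector(img), ncol = 1)
  lossAt <- function(ps) {
    bn <- list2env(m@bnState)
    fw <- ns$networkForward(ps, bn, X, 1L, cfg, train = TRUE)
    ns$.lossFun(fw$logits, y, "cross_entropy")$loss
  }
  bn <- list2env(m@bnState)
  fw <- ns$networkForward(params, bn, X, 1L, cfg, train = TRUE)
  ls <- ns$.lossFun(fw$logits, y, "cross_entropy")
  grads <- ns$networkBackward(params, fw$caches, ls$dlogits, 1L, cfg)
  eps <- 1e-5
  for (nm in c("head.W", "enc1.conv1.W", "dec1.conv2.b", "tr1.q.W",
               "embed.pos", "tr1.mlp1.W", "enc2.bn1.g", "tr1.ln2.b")) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
    expect_lt(abs(grads[[nm]][i] - fd), 1e-5 + 1e-3 * abs(fd),
              label = sprintf("gradient mismatch for %s", nm))
  }
})

test_that("checkpoints round-trip exactly", {
  m <- TransResUNet(microModelConfig(), seed = 30)
  img <- matrix(runif(32 * 32), 32, 32)
  path <- file.path(tempdir(), "ckpt.rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(predictMask(m, img), predictMask(m2, img))
  expect_true(file.exists(paste0(path, ".json")))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$params, countParams(m))
})
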