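ns <- asNamespace("lungfields")

test_that("the 70:10:20 split rule reproduces the published sizes and is a
           deterministic partition", {
  sp <- splitDataset(1:1158, c(70, 10, 20), seed = 1)
  expect_equal(lengths(sp), c(train = 810L, val = 116L, test = 232L))
  expect_equal(lengths(splitDataset(1:10, c(70, 10, 20), seed = 4)),
               c(train = 7L, val = 1L, test = 2L))
  # partition: disjoint and exhaustive
  for (n in c(3, 17, 101, 1158)) {
    sp <- splitDataset(seq_len(n), seed = n)
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_ids), seq_len(n))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  # determinism and size stability across seeds
  expect_identical(splitDataset(1:50, seed = 9), splitDataset(1:50, seed = 9))
  a <- splitDataset(1:50, seed = 1); b <- splitDataset(1:50, seed = 2)
  expect_equal(lengths(a), lengths(b))
  expect_false(identical(a$train, b$train))
  expect_error(splitDataset(integer(0)), "empty")
  expect_error(splitDataset(1:2), "at least 3")
  expect_error(splitDataset(1:10, c(50, 50, 10)), "summing to 100")
})

test_that("loss functions behave at their limits", {
  y <- c(1, 0, 1, 1)
  perfect <- cbind(ifelse(y == 1, -20, 20), ifelse(y == 1, 20, -20))
  expect_lt(ns$.lossFun(perfect, y, "cross_entropy")$loss, 1e-8)
  expect_lt(ns$.lossFun(perfect, y, "dice")$loss, 0.2)  # smoothing floor
  wrong <- -perfect
  expect_gt(ns$.lossFun(wrong, y, "cross_entropy")$loss, 10)
  comb <- ns$.lossFun(perfect, y, "combined")
  expect_equal(comb$loss,
               ns$.lossFun(perfect, y, "cross_entropy")$loss +
                 ns$.lossFun(perfect, y, "dice")$loss)
})

test_that("training with zero learning rate leaves parameters untouched", {
  d <- testPhantoms(4, side = 64)
  m <- TransResUNet(tinyModelConfig(), seed = 1)
  m2 <- trainModel(m, d$images, d$masks,
                   split = list(train = 1:3, val = 4),
                   config = TrainConfig(learningRate = 0, epochs = 1,
                                        seed = 1, selection = "last"))
  expect_equal(m2@params, m@params)
  expect_equal(nrow(trainHistory(m2)), 1)
})

test_that("one small-step update on one example strictly decreases the
           loss", {
  cfg <- microModelConfig()
  m <- TransResUNet(cfg, seed = 2)
  d <- testPhantoms(1, side = 48, modelSide = 32)
  X <- matrix(as.vector(d$images[[1]]), ncol = 1)
  y <- as.vector(d$masks[[1]])
  bn <- list2env(m@bnState)
  fw <- ns$networkForward(m@params, bn, X, 1L, cfg, train = TRUE)
  l0 <- ns$.lossFun(fw$logits, y, "cross_entropy")
  grads <- ns$networkBackward(m@params, fw$caches, l0$dlogits, 1L, cfg)
  st <- lapply(m@params, function(p) p * 0)
  up <- ns$.rmspropStep(m@params, grads, st, lr = 1e-4)
  bn2 <- list2env(m@bnState)
  fw2 <- ns$networkForward(up$params, bn2, X, 1L, cfg, train = TRUE)
  l1 <- ns$.lossFun(fw2$logits, y, "cross_entropy")
  expect_lt(l1$loss, l0$loss)
})

test_that("training on phantoms improves validation Dice reproducibly", {
  d <- testPhantoms(14, side = 96, modelSide = 64, seed = 41)
  sp <- list(train = 1:10, val = 11:14)
  tc <- TrainConfig(epochs = 6, seed = 3)
  m <- TransResUNet(tinyModelConfig(), seed = 3)
  m1 <- trainModel(m, d$images, d$masks, split = sp, config = tc)
  h <- trainHistory(m1)
  expect_equal(nrow(h), 6)
  expect_gt(h$val_dice[6], h$val_dice[1])
  expect_lt(h$train_loss[6], h$train_loss[1])
  # bitwise reproducibility of the whole history
  m2 <- trainModel(m, d$images, d$masks, split = sp, config = tc)
  expect_identical(trainHistory(m2), h)
})

test_that("training aborts with a diagnostic on non-finite input", {
  d <- testPhantoms(3, side = 64)
  d$images[[1]][5, 5] <- NaN
  m <- TransResUNet(tinyModelConfig(), seed = 1)
  expect_error(
    trainModel(m, d$images, d$masks,
               split = list(train = 1:2, val = 3),
               config = TrainConfig(epochs = 1, seed = 1)),
    "non-finite loss")
  expect_error(
    trainModel(m, d$images, d$masks, split = list(train = integer(0)),
               config = TrainConfig(epochs = 1)),
    "empty training set")
})

test_that("evaluateSplit aggregates per-image metrics as unweighted means", {
  d <- testPhantoms(2, side = 64)
  m <- TransResUNet(tinyModelConfig(), seed = 1)
  pc <- PostprocConfig(openingRadius = 1)
  one <- evaluateSplit(m, d$images, d$masks, ids = 1, postprocConfig = pc)
  expect_equal(as.numeric(one$aggregate[c("AC", "SE", "SP", "DI")]),
               as.numeric(one$per_image[1, c("AC", "SE", "SP", "DI")]))
  # duplicating the id list leaves the aggregate unchanged
  dup <- evaluateSplit(m, d$images, d$masks, ids = c(1, 1), postprocConfig = pc)
  expect_equal(dup$aggregate, one$aggregate)
  # agreement with the metrics module on the post-processed mask
  prob <- predictMask(m, d$images[[1]])
  post <- postprocessMask(prob, pc)
  expect_equal(unname(one$per_image$DI[1]), diceCoef(post, d$masks[[1]]))
})
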