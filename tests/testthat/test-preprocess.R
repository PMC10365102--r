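test_that("central quarter region follows the floor-based half-open rule", {
  expect_equal(centralRegion(matrix(0, 8, 8)), list(rows = 3:6, cols = 3:6))
  r512 <- centralRegion(matrix(0, 512, 512))
  expect_equal(r512$rows, 129:384)
  expect_equal(r512$cols, 129:384)
  # odd dimensions: floor(x/4) .. floor(3x/4), half-open
  expect_equal(centralRegion(matrix(0, 5, 5)), list(rows = 2:3, cols = 2:3))
  r <- centralRegion(matrix(0, 7, 9))
  expect_equal(r$rows, 2:5)
  expect_equal(r$cols, 3:6)
  expect_error(centralRegion(matrix(0, 3, 8)), "too small")
  expect_error(centralRegion(matrix(c(NA, rep(1, 24)), 5, 5)), "finite")
})

test_that("truncation bounds are the min/max attained in the central area", {
  expect_equal(truncationBounds(matrix(7, 6, 6))[c("vmin", "vmax")],
               list(vmin = 7, vmax = 7))
  img <- matrix(0, 4, 4)
  img[2:3, 2:3] <- c(5, 6, 6, 7)
  img[1, 1] <- 0; img[4, 4] <- 10
  b <- truncationBounds(img)
  expect_equal(c(b$vmin, b$vmax), c(5, 7))
  # global extremes inside the central region -> bounds = global range
  img2 <- matrix(runif(64, 2, 3), 8, 8)
  img2[4, 4] <- -5; img2[5, 5] <- 42
  b2 <- truncationBounds(img2)
  expect_equal(c(b2$vmin, b2$vmax), range(img2))
})

test_that("grayscale truncation clips exactly like the three-branch rule", {
  b <- list(vmin = 5, vmax = 7)
  expect_equal(applyTruncation(matrix(c(0, 5, 6, 10), 2), b),
               matrix(c(5, 5, 6, 7), 2))
  img <- matrix(rnorm(36), 6, 6)
  expect_equal(applyTruncation(img, list(vmin = min(img), vmax = max(img))),
               img)
  expect_equal(applyTruncation(img, list(vmin = 3, vmax = 3)),
               matrix(3, 6, 6))
  # per-pixel branch oracle on random images
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(rnorm(256, sd = 10), 16, 16)
    bb <- truncationBounds(x)
    oracle <- x
    for (i in 1:16) for (j in 1:16) {
      v <- x[i, j]
      oracle[i, j] <- if (v <= bb$vmin) bb$vmin
                      else if (v >= bb$vmax) bb$vmax else v
    }
    clipped <- applyTruncation(x, bb)
    expect_identical(clipped, oracle)
    # idempotence
    expect_identical(applyTruncation(clipped, bb), clipped)
  }
})

test_that("unit normalization maps the truncation window onto [0,1]", {
  b <- list(vmin = 5, vmax = 7)
  expect_equal(normalizeUnit(matrix(c(5, 5, 6, 7), 2), b),
               matrix(c(0, 0, 0.5, 1), 2))
  expect_equal(normalizeUnit(matrix(4, 5, 5), list(vmin = 4, vmax = 4)),
               matrix(0, 5, 5))
  set.seed(3)
  x <- matrix(rnorm(64), 8, 8)
  b <- truncationBounds(x)
  y <- normalizeUnit(applyTruncation(x, b), b)
  expect_equal(range(y), c(0, 1))
})

test_that("bilinear resize matches a double-loop oracle and stays in range", {
  cst <- matrix(2.5, 7, 7)
  expect_equal(resizeBilinear(cst, 13), matrix(2.5, 13, 13))
  x <- matrix(runif(49), 7, 7)
  expect_identical(resizeBilinear(x, 7), x)
  # 4x4 checkerboard -> 2x2: each output is the mean of its 2x2 block
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(resizeBilinear(cb, 2), matrix(0.5, 2, 2))
  # independent pixel-center oracle
  set.seed(11)
  a <- matrix(runif(8 * 6), 8, 6)
  for (dims in list(c(4, 3), c(16, 12), c(5, 5))) {
    got <- resizeBilinear(a, dims)
    oracle <- matrix(0, dims[1], dims[2])
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      u <- min(max((i - 0.5) * 8 / dims[1] + 0.5, 1), 8)
      v <- min(max((j - 0.5) * 6 / dims[2] + 0.5, 1), 6)
      r0 <- max(min(floor(u), 7), 1); fr <- u - r0
      c0 <- max(min(floor(v), 5), 1); fc <- v - c0
      oracle[i, j] <- (1 - fr) * (1 - fc) * a[r0, c0] +
        fr * (1 - fc) * a[r0 + 1, c0] + (1 - fr) * fc * a[r0, c0 + 1] +
        fr * fc * a[r0 + 1, c0 + 1]
    }
    expect_equal(got, oracle)
    expect_true(min(got) >= min(a) - 1e-12 && max(got) <= max(a) + 1e-12)
  }
})

test_that("nearest-neighbor resize preserves binarity", {
  set.seed(5)
  m <- (matrix(runif(100), 10, 10) > 0.6) * 1
  for (s in c(4, 7, 23)) {
    r <- resizeNearest(m, s)
    expect_true(all(r %in% c(0, 1)))
    expect_equal(dim(r), c(s, s))
  }
  expect_identical(resizeNearest(m, 10), m)
})

test_that("preprocessing is invariant to positive affine intensity maps", {
  set.seed(21)
  for (k in 1:10) {
    x <- matrix(rnorm(30 * 26, mean = 100, sd = 40), 30, 26)
    a <- runif(1, 0.01, 3000)
    b <- runif(1, -500, 2000)
    expect_equal(preprocessImage(a * x + b, side = 32),
                 preprocessImage(x, side = 32), tolerance = 1e-9)
  }
})

test_that("preprocessing contract: [0,1] output, requested shape, idempotent", {
  set.seed(31)
  x <- matrix(rnorm(100 * 80, sd = 1000), 100, 80)
  y <- preprocessImage(x, side = 64)
  expect_equal(dim(y), c(64, 64))
  expect_true(min(y) >= 0 && max(y) <= 1)
  # constant image -> all zeros
  expect_equal(preprocessImage(matrix(9, 40, 40), side = 16),
               matrix(0, 16, 16))
  # idempotence at matched size: second-pass bounds are already [0,1]
  z <- matrix(runif(64 * 64), 64, 64)
  p1 <- preprocessImage(z, side = 64)
  expect_equal(preprocessImage(p1, side = 64), p1)
  # inverted photometric flips before windowing
  expect_equal(preprocessImage(x, side = 32, photometric = "inverted"),
               preprocessImage(max(x) - x, side = 32))
})
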