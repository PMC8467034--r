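test_that("shape propagation reproduces the published layer tables", {
  encShapes <- propagateShapes(caeEncoderSpec(), c(11, 2601, 1))
  expect_equal(encShapes[[1]], c(11L, 2000L, 2L))     # first conv: 2601 - 602 + 1
  expect_equal(do.call(rbind, encShapes),
               cbind(11L, c(2000L, 1000L, 800L, 400L, 200L, 100L, 50L, 25L, 11L),
                     c(2L, 4L, 4L, 8L, 16L, 16L, 32L, 60L, 60L)))
  decShapes <- propagateShapes(caeDecoderSpec(caeEncoderSpec()), c(11, 11, 60))
  expect_equal(do.call(rbind, decShapes),
               cbind(11L, c(25L, 50L, 100L, 200L, 400L, 800L, 1000L, 2000L, 2601L, 2601L),
                     c(60L, 60L, 32L, 32L, 16L, 8L, 8L, 4L, 2L, 1L)))
  cnnShapes <- propagateShapes(cnnSpec(), c(11, 60, 1))
  expect_equal(do.call(rbind, cnnShapes[1:6]),
               cbind(11L, c(30L, 15L, 15L, 7L, 7L, 6L), c(6L, 6L, 12L, 12L, 24L, 24L)))
  expect_equal(cnnShapes[[7]], c(1L, 1L, 1584L))
  expect_equal(cnnShapes[[8]], c(1L, 1L, 2601L))
  expect_equal(cnnShapes[[10]], c(1L, 1L, 2601L))
  # a kernel wider than its input is rejected with the layer named
  expect_error(propagateShapes(list(layerConv(50, 2)), c(4, 10, 1)),
               "layer 1 \\(conv\\)")
})

test_that("reduced-width specs keep the block pattern and close the loop", {
  enc <- caeEncoderSpec(n = 441, p = 12)
  sh <- propagateShapes(enc, c(11, 441, 1))
  expect_equal(sh[[9]], c(11L, 11L, 12L))
  dec <- caeDecoderSpec(enc, n = 441)
  shd <- propagateShapes(dec, c(11, 11, 12))
  expect_equal(shd[[length(shd)]], c(11L, 441L, 1L))
  cn <- propagateShapes(cnnSpec(p = 12, n = 441), c(11, 12, 1))
  expect_equal(cn[[length(cn)]], c(1L, 1L, 441L))
  cn1 <- propagateShapes(cnnSpec(p = 1, n = 441), c(11, 1, 1))
  expect_equal(cn1[[length(cn1)]], c(1L, 1L, 441L))
})

test_that("mae matches hand and loop oracles", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2), c(1, 1)), 1)
  set.seed(4)
  a <- array(rnorm(60), c(3, 4, 5))
  b <- array(rnorm(60), c(3, 4, 5))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(mae(a, b), acc / length(a))
  expect_error(mae(1:3, 1:4), "shape")
})

test_that("analytic gradients match numerical differentiation", {
  relTol <- 1e-4
  s1 <- list(layerConv(3, 2, "tanh"), layerMaxPool(2), layerConv(2, 3, "sigmoid"),
             layerFlatten(), layerDense(5, "tanh"))
  expect_lt(max(gradCheckErrors(s1, c(4, 10, 1))), relTol)
  s2 <- list(layerBilinear(7), layerDeconv(3, 2, stride = 2, padding = "same"),
             layerDeconv(4, 3, "sigmoid"), layerConv(1, 1, "tanh", padding = "same"))
  expect_lt(max(gradCheckErrors(s2, c(3, 5, 2))), relTol)
  s3 <- list(layerConv(3, 4, "tanh", bn = TRUE), layerMaxPool(2),
             layerConv(1, 3, "sigmoid", bn = TRUE), layerFlatten(), layerDense(6))
  expect_lt(max(gradCheckErrors(s3, c(3, 8, 1), N = 5)), relTol)
})

test_that("an identity-initialized one-channel autoencoder reproduces any input", {
  spec <- list(layerConv(1, 1, activation = "none", padding = "same"),
               layerConv(1, 1, activation = "none", padding = "same"))
  net <- buildNet(spec, c(4, 9, 1), seed = 1)
  net$params[[1]]$W[] <- 1
  net$params[[2]]$W[] <- 1
  set.seed(9)
  x <- array(rnorm(2 * 4 * 9), c(2, 4, 9, 1))
  out <- emflowtomo:::netForward(net, x, training = FALSE)$out
  expect_equal(mae(out, x), 0)
})

test_that("CAE training reduces the reconstruction loss and encodes deterministically", {
  set.seed(5)
  W <- matrix(rnorm(11 * 169), 11, 169)
  Wstd <- standardizeWeights(W)$W
  model <- trainCAE(Wstd, p = 4, iterations = 40, lr = 1e-3, seed = 2)
  h <- lossHistory(model)
  expect_length(h, 40L)
  expect_true(all(is.finite(h)) && all(h >= 0))
  expect_lt(tail(h, 1), h[1])
  Wp <- encodeWeights(model, Wstd)
  expect_equal(dim(Wp), c(11L, 11L, 4L))
  expect_true(all(is.finite(Wp)))
  expect_identical(Wp, encodeWeights(model, Wstd))
})

test_that("training is reproducible under a fixed seed and inference is deterministic", {
  set.seed(6)
  N <- 24
  X <- array(rnorm(N * 11 * 3), c(N, 11, 3))
  Y <- matrix(rnorm(N * 20), N, 20)
  m1 <- trainCNN(X, Y, iterations = 15, lr = 1e-3, batch = 8, seed = 3)
  m2 <- trainCNN(X, Y, iterations = 15, lr = 1e-3, batch = 8, seed = 3)
  expect_identical(m1@params, m2@params)
  expect_identical(lossHistory(m1), lossHistory(m2))
  m3 <- trainCNN(X, Y, iterations = 15, lr = 1e-3, batch = 8, seed = 4)
  expect_false(identical(lossHistory(m1), lossHistory(m3)))

  # dropout off at prediction: repeated calls agree bitwise, and batch
  # prediction equals per-sample prediction
  P1 <- predictVelocity(m1, X)
  expect_identical(P1, predictVelocity(m1, X))
  expect_equal(dim(P1), c(N, 20L))
  expect_equal(P1[3, ], as.numeric(predictVelocity(m1, X[3, , , drop = FALSE])),
               tolerance = 1e-12)
  expect_true(all(is.finite(P1)))
})

test_that("a zeroed network outputs exactly its readout bias", {
  set.seed(7)
  X <- array(rnorm(6 * 11 * 3), c(6, 11, 3))
  Y <- matrix(rnorm(6 * 9), 6, 9)
  m <- trainCNN(X, Y, iterations = 1, lr = 0, batch = 6, seed = 1)
  for (i in seq_along(m@params))
    if (!is.null(m@params[[i]]))
      m@params[[i]] <- lapply(m@params[[i]], function(a) a * 0)
  m@params[[length(m@spec)]]$b[] <- 0.25
  P <- predictVelocity(m, X)
  expect_true(all(P == 0.25))
})

test_that("the BP baseline trains, shrinks its loss, and outputs length n", {
  set.seed(8)
  U <- matrix(rnorm(30 * 11), 30, 11)
  Y <- matrix(rnorm(30 * 50), 30, 50)
  m <- trainBP(U, Y, hidden = 16, iterations = 40, lr = 3e-3, batch = 30, seed = 2)
  expect_lt(tail(lossHistory(m), 1), lossHistory(m)[1])
  expect_equal(dim(predictVelocity(m, U)), c(30L, 50L))
})

test_that("standardization and normalization are well-behaved", {
  set.seed(10)
  W <- matrix(rnorm(11 * 40, mean = 3, sd = 2), 11, 40)
  s <- standardizeWeights(W)
  expect_equal(mean(s$W), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(s$W)), 1, tolerance = 1e-12)
  # reapplying the stored statistics reproduces the same transform
  expect_equal(standardizeWeights(W, stats = s)$W, s$W)

  X <- array(rnorm(50 * 4 * 3), c(50, 4, 3))
  nz <- normalizeFeatures(X)
  Xm <- matrix(nz$X, 50, 12)
  expect_true(all(abs(colMeans(Xm)) < 1e-12))
  expect_true(all(abs(apply(Xm, 2, sd) - 1) < 1e-12))
  X2 <- normalizeFeatures(X, stats = nz[c("mean", "sd")])
  expect_equal(X2$X, nz$X)
  # constant feature maps to zero through the floored deviation
  Xc <- matrix(5, 20, 3)
  expect_true(all(normalizeFeatures(Xc)$X == 0))
})

test_that("checkpoints round-trip and reproduce predictions bitwise", {
  set.seed(15)
  N <- 12
  X <- array(rnorm(N * 11 * 3), c(N, 11, 3))
  Y <- matrix(rnorm(N * 10), N, 10)
  m <- trainCNN(X, Y, iterations = 10, lr = 1e-3, batch = N, seed = 6)
  dir <- withr::local_tempdir()
  saveModel(m, dir)
  m2 <- loadModel(dir)
  expect_identical(predictVelocity(m2, X), predictVelocity(m, X))
  expect_equal(lossHistory(m2), lossHistory(m))
  expect_error(suppressWarnings(loadModel(withr::local_tempdir())),
               "checkpoint|cannot")
})
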