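test_that("Tikhonov reconstruction matches identity and dense oracles", {
  # identity system: vhat = U at lam = 0
  U <- rnorm(6)
  vhat <- tikhonovReconstruct(U, diag(6), 0)
  expect_equal(as.numeric(vhat), U, tolerance = 1e-10)

  # dense normal-equations oracle on a well-posed small system
  set.seed(11)
  W <- matrix(rnorm(4 * 7), 4, 7)
  u <- rnorm(4)
  lam <- 0.3
  oracle <- solve(t(W) %*% W + lam * diag(7), t(W) %*% u)
  expect_equal(as.numeric(tikhonovReconstruct(u, W, lam)), as.numeric(oracle),
               tolerance = 1e-8)

  # shrinkage: the solution norm decreases monotonically in lam
  norms <- vapply(10^seq(-6, 8, by = 2), function(l)
    sqrt(sum(tikhonovReconstruct(u, W, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-4 * norms[1])

  # continuity in lam
  v1 <- tikhonovReconstruct(u, W, 0.3)
  v2 <- tikhonovReconstruct(u, W, 0.3 * (1 + 1e-8))
  expect_lt(max(abs(v1 - v2)), 1e-6)

  # rank-deficient W at lam = 0 falls back to the pseudo-inverse
  Wr <- rbind(W[1, ], W[1, ], W[2, ], W[3, ])
  vr <- tikhonovReconstruct(u, Wr, 0)
  expect_true(attr(vr, "fallback"))
  expect_equal(as.numeric(vr), as.numeric(MASS::ginv(Wr) %*% u), tolerance = 1e-6)
  expect_error(tikhonovReconstruct(u, W, -1), "nonnegative")
})

test_that("rmse and cc match loop oracles and affine closed forms", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  set.seed(12)
  v <- rnorm(40); vh <- rnorm(40)
  acc <- 0
  for (i in seq_along(v)) acc <- acc + (v[i] - vh[i])^2
  expect_equal(rmse(v, vh), sqrt(acc / 40))
  # translation covariance
  expect_equal(rmse(v + 2, vh + 2), rmse(v, vh))

  expect_equal(cc(v, 2 * v + 1), 1)
  expect_equal(cc(v, -v), -1)
  num <- sum((vh - mean(vh)) * (v - mean(v)))
  den <- sqrt(sum((vh - mean(vh))^2) * sum((v - mean(v))^2))
  expect_equal(cc(v, vh), num / den)
  # positive affine invariance in either argument
  expect_equal(cc(3 * v + 5, vh), cc(v, vh))
  expect_warning(out <- cc(rep(1, 5), 1:5), "constant")
  expect_true(is.nan(out))
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(cc(1:3, 1:4), "length")
})

test_that("evaluation reports perfect scores for the oracle method and is order-invariant", {
  ph <- tinyPhantom()
  ds <- generateDataset(ph, simulationConfig(BValues = 0.1, rates = c(0, 0.3),
                                             times = c(0.05, 0.15), seed = 9))
  idx <- testIndices(ds)
  oracleRec <- methodReconstructor("oracle",
    list(labels = velocityLabels(ds)[idx, , drop = FALSE]))
  rep1 <- evaluateMethod(oracleRec, ds, indices = idx)
  expect_equal(rep1$meanRmse, 0)
  expect_equal(rep1$meanCc, 1)

  tik <- methodReconstructor("tikhonov",
    list(W = unclass(weightMatrix(ds)), lam = 1e-12))
  r1 <- evaluateMethod(tik, ds, indices = idx)
  r2 <- evaluateMethod(tik, ds, indices = rev(idx))
  expect_equal(r1$meanRmse, r2$meanRmse, tolerance = 1e-12)
  expect_equal(r1$meanCc, r2$meanCc, tolerance = 1e-12)
  expect_true(all(r1$perSample$rmse >= 0))
  expect_true(all(abs(r1$perSample$cc) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("the lambda grid search picks the RMSE-minimizing weight", {
  ph <- tinyPhantom()
  ds <- generateDataset(ph, simulationConfig(BValues = 0.1,
                                             rates = c(0, 0.2, 0.6),
                                             times = c(0.05, 0.1, 0.2), seed = 10))
  sel <- chooseTikhonovLambda(ds, grid = 10^seq(-6, 2, by = 2), seed = 2)
  expect_true(sel$lam %in% sel$table$lam)
  expect_equal(sel$table$meanRmse[sel$table$lam == sel$lam], min(sel$table$meanRmse))
})

test_that("an infinite SNR sweep reproduces the noiseless report exactly", {
  ph <- tinyPhantom()
  ds <- generateDataset(ph, simulationConfig(BValues = 0.1, rates = c(0, 0.4),
                                             times = c(0.05, 0.2), seed = 13))
  tik <- methodReconstructor("tikhonov",
    list(W = unclass(weightMatrix(ds)), lam = 1e-10))
  base <- evaluateMethod(tik, ds, seed = 5)
  sw <- noiseSweep(list(tikhonov = tik), ds, snrDb = c(Inf, 20), seed = 5)
  expect_equal(sw$meanRmse[sw$snrDb == Inf], base$meanRmse)
  expect_equal(sw$meanCc[sw$snrDb == Inf], base$meanCc)
  expect_equal(nrow(sw), 2L)
  # the default sweep covers the five published noise levels
  sw5 <- noiseSweep(list(tikhonov = tik), ds, seed = 5)
  expect_setequal(sw5$snrDb, c(60, 50, 40, 30, 20))
})

test_that("velocity images round-trip through the CSV matrix and render as PNG", {
  set.seed(14)
  v <- rnorm(13 * 13)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "v.csv")
  pngf <- file.path(dir, "v.png")
  M <- renderVelocityImage(v, c(13, 13), pngFile = pngf, csvFile = csv)
  expect_equal(readVelocityMatrix(csv), v, tolerance = 1e-12)
  img <- png::readPNG(pngf)
  expect_equal(dim(img)[1:2], c(13L, 13L))
  # an all-zero vector renders without error
  expect_silent(renderVelocityImage(numeric(25), c(5, 5),
                                    pngFile = file.path(dir, "z.png"),
                                    csvFile = file.path(dir, "z.csv")))
})
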