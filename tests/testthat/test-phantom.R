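test_that("tissue conductivities are assigned from the reference table", {
  ph <- tinyPhantom()
  sig <- conductivity(ph)
  expect_equal(unique(sig[tissueMask(ph, "artery")]), 1.12)
  expect_equal(unique(sig[tissueMask(ph, "vein")]), 1.12)
  expect_equal(unique(sig[tissueMask(ph, "skin")]), 0.005)
  expect_equal(unique(sig[tissueMask(ph, "trachea")]), 0)
  expect_equal(unique(sig[tissueMask(ph, "muscle")]), 0.2)
  expect_equal(unique(sig[tissueMask(ph, "fat")]), 0.1)
})

test_that("every cell carries exactly one tissue label and overrides work", {
  ph <- tinyPhantom()
  labs <- tissueLabels(ph)
  expect_true(all(labs %in% 0:9))
  counts <- table(labs)
  expect_equal(sum(counts), ph@nx * ph@ny)
  ph2 <- buildPhantom(phantomConfig("tiny", tissues = list(muscle = 0.33)))
  expect_equal(unique(conductivity(ph2)[tissueMask(ph2, "muscle")]), 0.33)
})

test_that("a single-tissue phantom is uniformly conductive", {
  ph <- uniformPhantom(33L, sigma = 0.2)
  expect_true(all(conductivity(ph) == 0.2))
  expect_true(all(tissueLabels(ph) == 3L))  # muscle everywhere
})

test_that("phantom construction rejects bad configurations", {
  expect_error(buildPhantom(phantomConfig("tiny", nx = 16L)), "32 x 32")
  expect_error(buildPhantom(phantomConfig("tiny", arteryRadius = -1)), "positive")
  expect_error(
    buildPhantom(phantomConfig("tiny", veinCenter = c(0.61, 0.41))), "overlap")
  expect_error(phantomConfig("tiny", nonsense = 1), "unknown")
})

test_that("electrodes are 12 distinct boundary cells of the conducting domain", {
  ph <- tinyPhantom()
  e <- electrodeCells(ph)
  expect_length(e, 12L)
  expect_false(anyDuplicated(e) > 0)
  sig <- conductivity(ph)
  expect_true(all(sig[e] > 0))
  # every electrode cell touches the non-conducting exterior (domain boundary)
  nx <- ph@nx
  for (cell in e) {
    ix <- (cell - 1L) %% nx + 1L
    iy <- (cell - 1L) %/% nx + 1L
    nbr <- rbind(c(ix + 1L, iy), c(ix - 1L, iy), c(ix, iy + 1L), c(ix, iy - 1L))
    onEdge <- any(nbr[, 1] < 1 | nbr[, 1] > nx | nbr[, 2] < 1 | nbr[, 2] > ph@ny)
    if (!onEdge)
      onEdge <- any(sig[cbind(nbr[, 1], nbr[, 2])] == 0)
    expect_true(onEdge)
  }
})

test_that("stenosis masks accrete by half-plane sweep with deterministic ties", {
  ph <- smallPhantom()
  aIdx <- which(tissueMask(ph, "artery"))
  expect_true(length(aIdx) > 20)

  expect_equal(sum(stenosisMask(ph, 0, "+x")), 0)
  expect_equal(sum(stenosisMask(ph, 0, "-y")), 0)

  for (r in c(0.2, 0.5, 0.9)) for (d in c("+x", "-y")) {
    m <- stenosisMask(ph, r, d)
    expect_equal(sum(m), round(r * length(aIdx)))
    expect_true(all(which(m) %in% aIdx))
  }

  # brute-force oracle: order artery cells by the sweep coordinate, tie by
  # ascending linear index, and take the first round(r * count)
  nx <- ph@nx
  ix <- (aIdx - 1L) %% nx + 1L
  iy <- (aIdx - 1L) %/% nx + 1L
  oracle <- aIdx[order(ix, aIdx)][seq_len(round(0.5 * length(aIdx)))]
  expect_setequal(which(stenosisMask(ph, 0.5, "+x")), oracle)
  oracleY <- aIdx[order(-iy, aIdx)][seq_len(round(0.4 * length(aIdx)))]
  expect_setequal(which(stenosisMask(ph, 0.4, "-y")), oracleY)

  # nesting and monotone growth across the rate ladder
  for (d in c("+x", "-y")) {
    prev <- stenosisMask(ph, 0, d)
    for (r in seq(0.1, 0.9, by = 0.1)) {
      cur <- stenosisMask(ph, r, d)
      expect_true(all(prev[cur == FALSE] == FALSE))
      expect_true(all(which(prev) %in% which(cur)))
      expect_gte(sum(cur), sum(prev))
      prev <- cur
    }
  }
  expect_error(stenosisMask(ph, 0.55), "0.1")
})

test_that("pulsatile waveform is periodic, nonnegative, peaks in systole", {
  fl <- flowConfig()
  t <- seq(0, fl$period, by = 0.001)
  w <- pulsatileWaveform(t, fl)
  expect_true(all(w >= 0))
  expect_equal(pulsatileWaveform(t + fl$period, fl), w, tolerance = 1e-12)
  expect_equal(max(w), fl$waveform$vmax, tolerance = 1e-3)
  tpk <- t[which.max(w)] / fl$period
  expect_gt(tpk, 0.05)
  expect_lt(tpk, 0.25)
  # inclusive endpoint sampling of one period gives 86 instants
  expect_length(seq(0, fl$period, by = fl$dt), 86L)
})

test_that("stenosis speed-up follows flux continuity and accepts overrides", {
  expect_equal(stenosisVelocityCoefficient(0), 1)
  # conservation oracle on a two-segment 1D pipe: A1 v1 = A2 v2
  A1 <- 1; v1 <- 1; rate <- 0.5; A2 <- A1 * (1 - rate)
  expect_equal(stenosisVelocityCoefficient(0.5), (A1 * v1 / A2) / v1)
  cvals <- stenosisVelocityCoefficient(seq(0, 0.9, by = 0.1))
  expect_true(all(diff(cvals) > 0))
  expect_error(stenosisVelocityCoefficient(1), "occluded")
  tab <- data.frame(rate = c(0, 0.5, 0.9), coef = c(1, 3, 8))
  expect_equal(stenosisVelocityCoefficient(0.5, table = tab), 3)
  expect_equal(stenosisVelocityCoefficient(0.25, table = tab), 2)
})

test_that("velocity fields assign artery, vein, stenosis and background speeds", {
  ph <- smallPhantom()
  fl <- flowConfig()
  vf <- velocityField(ph, 0.3, "+x", t = 0.1, flow = fl)
  art <- tissueMask(ph, "artery")
  vein <- tissueMask(ph, "vein")
  expect_equal(unique(vf$vz[vein]), -0.08)
  expect_true(all(vf$vz[vf$stenosisMask] == 0))
  open <- art & !vf$stenosisMask
  expected <- pulsatileWaveform(0.1, fl) * stenosisVelocityCoefficient(0.3)
  expect_equal(unique(vf$vz[open]), expected)
  expect_true(all(vf$vz[!art & !vein] == 0))
  expect_true(all(vf$vz[open] > 0) && all(vf$vz[vein] < 0))

  # rate 0 is direction-independent
  expect_equal(velocityField(ph, 0, "+x", 0.2)$vz,
               velocityField(ph, 0, "-y", 0.2)$vz)

  # at the waveform peak with no stenosis, all artery cells carry the peak
  tg <- seq(0, fl$period, by = 1e-3)
  tpk <- tg[which.max(pulsatileWaveform(tg, fl))]
  vf0 <- velocityField(ph, 0, "+x", tpk, fl)
  expect_equal(unique(vf0$vz[art]), pulsatileWaveform(tpk, fl))
})
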