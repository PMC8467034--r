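test_that("zero velocity gives zero potential; solver rejects degenerate input", {
  ph <- tinyPhantom()
  s <- tinySolver()
  vf <- velocityField(ph, 0, "+x", t = 0)
  vf$vz[] <- 0
  u <- solveFlowPotential(ph, vf, B = 0.1, solver = s)
  expect_true(all(u == 0))
  expect_error(makeSolver(ph, sigma = matrix(0, ph@nx, ph@ny)), "unsolvable")
})

test_that("potentials are linear in B and in the velocity scale", {
  ph <- tinyPhantom()
  s <- tinySolver()
  vf <- velocityField(ph, 0.3, "-y", t = 0.12)
  u1 <- solveFlowPotential(ph, vf, B = 0.05, solver = s)
  u2 <- solveFlowPotential(ph, vf, B = 0.10, solver = s)
  expect_lt(max(abs(2 * u1 - u2)) / max(abs(u2)), 1e-6)
  vf2 <- vf
  vf2$vz <- 3 * vf$vz
  u3 <- solveFlowPotential(ph, vf2, B = 0.05, solver = s)
  expect_lt(max(abs(3 * u1 - u3)) / max(abs(u3)), 1e-6)
  # gauge: reference electrode potential is exactly 0
  expect_identical(u1[electrodeCells(ph)[1]], 0)
})

test_that("manufactured solution converges at second order", {
  # u*(x,y) = cos(pi x) cos(pi y) on the unit square satisfies the zero-flux
  # boundary; the matching impressed field is vB = -2 pi cos(pi x) sin(pi y).
  err <- vapply(c(33L, 65L, 129L), function(ng) {
    ph <- uniformPhantom(ng, sigma = 1)
    s <- makeSolver(ph)
    xc <- (seq_len(ng) - 0.5) / ng
    X <- matrix(xc, ng, ng)
    Y <- matrix(xc, ng, ng, byrow = TRUE)
    vf <- list(vz = -2 * pi * cos(pi * X) * sin(pi * Y), time = 0)
    u <- solveFlowPotential(ph, vf, B = 1, solver = s)
    ustar <- cos(pi * X) * cos(pi * Y)
    max(abs((u - mean(u)) - (ustar - mean(ustar))))
  }, numeric(1))
  rates <- log2(err[-3] / err[-1])
  expect_true(all(rates > 1.7))
  expect_true(all(rates < 2.3))
})

test_that("electrode voltages are 11 differences against the reference", {
  ph <- tinyPhantom()
  s <- tinySolver()
  vf <- velocityField(ph, 0.2, "+x", t = 0.1)
  u <- solveFlowPotential(ph, vf, B = 0.1, solver = s)
  U <- electrodeVoltages(u, ph)
  expect_length(U, 11L)
  expect_false(all(U == 0))
  # constant potential field measures zero everywhere
  expect_equal(electrodeVoltages(matrix(3.7, ph@nx, ph@ny), ph), rep(0, 11))
  # flipping the field sign negates every entry
  Uneg <- electrodeVoltages(solveFlowPotential(ph, vf, B = -0.1, solver = s), ph)
  expect_equal(Uneg, -U, tolerance = 1e-12)
})

test_that("reciprocal fields obey Kirchhoff current conservation", {
  ph <- tinyPhantom()
  s <- tinySolver()
  expect_error(reciprocalField(ph, 0), "reference")
  rf <- reciprocalField(ph, 5, s)
  expect_true(all(is.finite(rf$Jx)) && all(is.finite(rf$Jy)))

  nx <- ph@nx
  eCells <- electrodeCells(ph)
  ek <- eCells[6]
  ix <- (ek - 1L) %% nx + 1L
  iy <- (ek - 1L) %/% nx + 1L

  # unit current crosses any contour separating the driven electrode from e0
  for (pad in 1:3) {
    rect <- c(max(1, ix - pad), min(nx, ix + pad),
              max(1, iy - pad), min(ph@ny, iy + pad))
    expect_equal(netCurrentThrough(ph, rf$uA, rect, s), 1, tolerance = 1e-8)
  }

  # discrete divergence vanishes away from both injection cells
  act <- which(s$active)
  ax <- (act - 1L) %% nx + 1L
  ay <- (act - 1L) %/% nx + 1L
  ex <- (eCells - 1L) %% nx + 1L
  ey <- (eCells - 1L) %/% nx + 1L
  dmin <- apply(abs(outer(ax, ex, `-`)) + abs(outer(ay, ey, `-`)), 1, min)
  interior <- act[dmin > 2]
  probe <- interior[round(seq(1, length(interior), length.out = 25))]
  for (cell in probe) {
    cx <- (cell - 1L) %% nx + 1L
    cy <- (cell - 1L) %/% nx + 1L
    div <- netCurrentThrough(ph, rf$uA, c(cx, cx, cy, cy), s)
    expect_lt(abs(div), 1e-8)
  }
})

test_that("reciprocal field is mirror-symmetric on a symmetric phantom", {
  ph <- uniformPhantom(33L, sigma = 0.5)
  s <- makeSolver(ph)
  # e0 sits at -90 degrees, electrode 6 at +90: both on the centre column
  rf <- reciprocalField(ph, 6, s)
  mir <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  expect_equal(rf$Jy, mir(rf$Jy), tolerance = 1e-9)
  expect_equal(rf$Jx, -mir(rf$Jx), tolerance = 1e-9)
})

test_that("weight matrix has the right shape, scaling, and reproduces the PDE", {
  ph <- smallPhantom()
  s <- smallSolver()
  W <- assembleWeightMatrix(ph, weightB = 0.1, solver = s)
  expect_equal(dim(W), c(11L, prod(ph@roi[3:4])))
  expect_true(all(assembleWeightMatrix(ph, weightB = 0, solver = s) == 0))

  # reciprocity oracle: W v must match the full PDE voltages for
  # ROI-supported velocity fields on the matched stenosis-free phantom
  for (tt in c(0.05, 0.30)) {
    vf <- velocityField(ph, 0, "+x", t = tt)
    U <- electrodeVoltages(solveFlowPotential(ph, vf, B = 0.1, solver = s), ph)
    v <- vf$vz[roiCells(ph)]
    relerr <- sqrt(sum((as.numeric(unclass(W) %*% v) - U)^2)) / sqrt(sum(U^2))
    expect_lt(relerr, 0.05)
  }
})

test_that("measurement noise matches the prescribed SNR and is reproducible", {
  U <- rnorm(11)
  U <- U / sqrt(mean(U^2))  # RMS 1
  n1 <- addNoise(U, 20, seed = 4)
  n2 <- addNoise(U, 20, seed = 4)
  n3 <- addNoise(U, 20, seed = 5)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_false(identical(as.numeric(n1), as.numeric(n3)))
  expect_identical(addNoise(U, Inf), U)
  expect_error(addNoise(rep(0, 11), 20), "RMS")
  # empirical noise sd over many draws approaches rms(U) * 10^(-snr/20) = 0.1
  devs <- vapply(1:400, function(s) addNoise(U, 20, seed = s) - U,
                 numeric(11))
  expect_equal(sd(as.numeric(devs)), 0.1, tolerance = 0.02)
})
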