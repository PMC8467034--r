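#' Tikhonov-regularized reconstruction
#'
#' Minimum-norm regularized solution `vhat = (W'W + lam I)^-1 W' U`,
#' computed through the equivalent m x m system
#' `vhat = W'(WW' + lam I)^-1 U` (push-through identity), which is both
#' stable and cheap for the strongly underdetermined m << n case. With
#' `lam = 0` and a rank-deficient W the SVD pseudo-inverse is used and the
#' result carries attribute `fallback = TRUE`.
#'
#' @param U measurement vector (length m) or matrix of samples (N x m).
#' @param W weight matrix (m x n), e.g. a [WeightMatrix-class].
#' @param lam nonnegative regularization weight.
#' @return n-vector (or N x n matrix) of reconstructed velocities.
#' @export
tikhonovReconstruct <- function(U, W, lam) {
  if (lam < 0) stopf("lam must be nonnegative")
  W <- unclass(W)
  m <- nrow(W)
  vec <- is.null(dim(U))
  Um <- if (vec) matrix(U, nrow = 1) else U
  if (ncol(Um) != m) stopf("measurement length does not match weight-matrix rows")
  G <- W %*% t(W) + lam * diag(m)
  fallback <- FALSE
  Z <- tryCatch({
    if (lam == 0 && rcond(G) < 1e-12) stop("rank deficient")
    t(solve(G, t(Um)))
  }, error = function(e) {
    fallback <<- TRUE
    Um %*% t(pseudoInverse(W %*% t(W)))
  })
  V <- Z %*% W
  out <- if (vec) as.numeric(V) else V
  attr(out, "fallback") <- fallback
  out
}

#' Select the Tikhonov weight on a held-out training slice
#'
#' Evaluates a logarithmic grid of regularization weights (scaled to the
#' magnitude of WW') on a seeded validation quarter of the training
#' samples and returns the weight minimizing the mean RMSE.
#'
#' @param dataset a [FlowDataset-class].
#' @param grid relative grid; absolute weights are `grid * mean(diag(WW'))`.
#' @param seed seed of the validation split.
#' @return list with `lam`, `table` (grid vs mean RMSE).
#' @export
chooseTikhonovLambda <- function(dataset, grid = 10^seq(-8, 2, by = 1), seed = 1L) {
  W <- unclass(dataset@W)
  tr <- dataset@trainIdx
  nval <- max(1L, length(tr) %/% 4L)
  val <- withSeed(subSeed(seed, "tikval"), sample(tr, nval))
  Um <- dataset@U[val, , drop = FALSE]
  Vm <- dataset@V[val, , drop = FALSE]
  scale <- mean(diag(W %*% t(W)))
  lams <- grid * scale
  score <- vapply(lams, function(l) {
    Vh <- tikhonovReconstruct(Um, W, l)
    mean(sqrt(rowMeans((Vh - Vm)^2)))
  }, numeric(1))
  list(lam = lams[which.min(score)],
       table = data.frame(lam = lams, meanRmse = score))
}

#' Root-mean-square error between a velocity vector and its estimate
#'
#' @param v,vhat equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
rmse <- function(v, vhat) {
  if (length(v) != length(vhat)) stopf("rmse: length mismatch")
  sqrt(mean((v - vhat)^2))
}

#' Pearson correlation coefficient between a velocity vector and its estimate
#'
#' Standard Pearson correlation. A constant input vector has no defined
#' correlation; the function warns and returns NaN in that case.
#'
#' @param v,vhat equal-length numeric vectors.
#' @return correlation in [-1, 1], or NaN for constant input.
#' @export
cc <- function(v, vhat) {
  if (length(v) != length(vhat)) stopf("cc: length mismatch")
  if (stats::sd(v) == 0 || stats::sd(vhat) == 0) {
    warning("constant input vector: correlation undefined")
    return(NaN)
  }
  stats::cor(v, vhat)
}

#' Evaluate a reconstruction method on a dataset subset
#'
#' Runs the method's full chain on every selected sample, computes
#' per-sample RMSE and CC against the labels, and averages them. The
#' evaluation subset is drawn with a recorded seed when `subsetSize` is
#' smaller than the candidate index set.
#'
#' @param reconstructor function mapping an N x m voltage matrix to an
#'   N x n velocity matrix (see [methodReconstructor()]).
#' @param dataset a [FlowDataset-class].
#' @param indices candidate sample indices (default: the test split).
#' @param subsetSize optional number of samples to draw from `indices`.
#' @param seed seed of the subset draw.
#' @param U optional replacement voltage matrix (same row order as the
#'   dataset) — used by [noiseSweep()] to evaluate noisy measurements.
#' @return list of class `evalReport`: `method`, `meanRmse`, `meanCc`,
#'   `perSample` (data.frame), `subset` (indices), `seed`.
#' @export
evaluateMethod <- function(reconstructor, dataset, indices = NULL,
                           subsetSize = NULL, seed = 1L, U = NULL) {
  indices <- indices %||% dataset@testIdx
  if (!is.null(subsetSize) && subsetSize < length(indices))
    indices <- withSeed(subSeed(seed, "evalsubset"), sample(indices, subsetSize))
  Um <- (U %||% dataset@U)[indices, , drop = FALSE]
  Vm <- dataset@V[indices, , drop = FALSE]
  Vh <- reconstructor(Um)
  if (!all(dim(Vh) == dim(Vm))) stopf("reconstructor returned wrong shape")
  per <- data.frame(
    index = indices,
    rmse = sqrt(rowMeans((Vm - Vh)^2)),
    cc = vapply(seq_len(nrow(Vm)), function(i)
      suppressWarnings(cc(Vm[i, ], Vh[i, ])), numeric(1))
  )
  structure(list(method = attr(reconstructor, "method") %||% "custom",
                 meanRmse = mean(per$rmse), meanCc = mean(per$cc, na.rm = TRUE),
                 perSample = per, subset = indices, seed = as.integer(seed)),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("evalReport [%s]: %d samples, mean RMSE %.4f, mean CC %.4f\n",
              x$method, nrow(x$perSample), x$meanRmse, x$meanCc))
  invisible(x)
}

#' Build a reconstructor closure for a named method
#'
#' Packages the per-method reconstruction chain behind a common
#' `U-matrix -> V-matrix` interface: `tikhonov` applies
#' [tikhonovReconstruct()]; `bp`/`cnn` standardize the voltages with the
#' training statistics and run the network; `cae_cnn` applies the data
#' domain transformation with the trained encoder's inverted sub-features,
#' normalizes, and runs the CNN.
#'
#' @param method one of "tikhonov", "bp", "cnn", "cae_cnn", "oracle".
#' @param context list of what the chain needs: `W`, `lam` (tikhonov);
#'   `model`, `uStats` (bp, cnn); `model`, `inv`, `vpStats` (cae_cnn);
#'   `labels` (oracle — returns the true labels, for testing).
#' @return function with attribute `method`.
#' @export
methodReconstructor <- function(method, context = list()) {
  fn <- switch(method,
    tikhonov = function(Um) {
      out <- tikhonovReconstruct(Um, context$W, context$lam)
      attributes(out) <- attributes(out)["dim"]
      out
    },
    bp = ,
    cnn = function(Um) {
      Us <- normalizeFeatures(Um, stats = context$uStats)$X
      predictVelocity(context$model, Us)
    },
    cae_cnn = function(Um) {
      vp <- domainTransform(Um, inv = context$inv)
      vpn <- normalizeFeatures(vp, stats = context$vpStats)$X
      predictVelocity(context$model, vpn)
    },
    oracle = function(Um) context$labels,
    stopf("unknown method '%s'", method)
  )
  if (method %in% c("bp", "cnn", "cae_cnn") && is.null(context$model))
    stopf("method '%s' needs a trained model in the context", method)
  attr(fn, "method") <- method
  fn
}

#' Noise robustness sweep
#'
#' Re-evaluates each method with white Gaussian noise added to the
#' measured voltages at each SNR. All methods see the same noisy voltages
#' at a given SNR; `Inf` reproduces the noiseless evaluation exactly.
#'
#' @param reconstructors named list of [methodReconstructor()] closures.
#' @param dataset a [FlowDataset-class].
#' @param snrDb SNR levels in dB.
#' @param indices,subsetSize,seed as in [evaluateMethod()].
#' @return data.frame with one row per (method, SNR): meanRmse, meanCc.
#' @export
noiseSweep <- function(reconstructors, dataset,
                       snrDb = c(60, 50, 40, 30, 20),
                       indices = NULL, subsetSize = NULL, seed = 1L) {
  rows <- list()
  for (s in snrDb) {
    Unoisy <- if (is.finite(s))
      addNoise(dataset@U, s, seed = subSeed(seed, paste0("noise", s)))
    else dataset@U
    for (nm in names(reconstructors)) {
      rpt <- evaluateMethod(reconstructors[[nm]], dataset, indices = indices,
                            subsetSize = subsetSize, seed = seed, U = Unoisy)
      rows[[length(rows) + 1L]] <- data.frame(
        method = nm, snrDb = s, meanRmse = rpt$meanRmse, meanCc = rpt$meanCc)
    }
  }
  do.call(rbind, rows)
}

#' Render a velocity vector as an image and a matrix file
#'
#' Reshapes the n-vector onto the ROI window (x-fastest order, matching
#' [roiCells()]), writes a colormapped PNG (blue = -, white = 0, red = +)
#' and a plain-text CSV matrix. The CSV round-trips losslessly.
#'
#' @param v velocity vector of length `prod(roiDim)`.
#' @param roiDim integer(2) window extents.
#' @param pngFile,csvFile output paths (either may be NULL to skip).
#' @return the ROI matrix, invisibly.
#' @export
renderVelocityImage <- function(v, roiDim, pngFile = NULL, csvFile = NULL) {
  roiDim <- rep(as.integer(roiDim), length.out = 2)
  if (length(v) != prod(roiDim)) stopf("length(v) != prod(roiDim)")
  M <- matrix(v, roiDim[1], roiDim[2])
  if (!is.null(csvFile))
    utils::write.table(M, csvFile, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(pngFile)) {
    lim <- max(abs(v), 1e-12)
    ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
    rgbv <- ramp((as.numeric(M) / lim + 1) / 2) / 255
    img <- array(0, c(roiDim[2], roiDim[1], 3))
    for (ch in 1:3)
      img[, , ch] <- t(matrix(rgbv[, ch], roiDim[1], roiDim[2]))[roiDim[2]:1, , drop = FALSE]
    png::writePNG(img, pngFile)
  }
  invisible(M)
}

#' Read back a velocity matrix written by [renderVelocityImage()]
#'
#' @param csvFile path to the CSV matrix.
#' @return numeric vector in ROI (x-fastest) order.
#' @export
readVelocityMatrix <- function(csvFile) {
  M <- as.matrix(utils::read.table(csvFile, sep = ","))
  dimnames(M) <- NULL
  as.numeric(M)
}
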