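# Layer specifications. Tensors are (batch, height, width, channels); all
# kernels are 1 x l (they slide along the width only), so the electrode
# dimension m is preserved through every convolutional stage.

#' @rdname layerSpecs
#' @param kernel kernel width l (the kernel is 1 x l).
#' @param filters number of output channels.
#' @param activation one of "tanh", "sigmoid", "relu", "none".
#' @param padding "valid" or "same".
#' @param stride stride along the width.
#' @param bn apply batch normalization between the linear map and the
#'   activation.
#' @export
layerConv <- function(kernel, filters, activation = "tanh",
                      padding = "valid", stride = 1L, bn = FALSE) {
  stopifnot(kernel >= 1, filters >= 1)
  list(kind = "conv", kernel = as.integer(kernel), filters = as.integer(filters),
       activation = match.arg(activation, c("tanh", "sigmoid", "relu", "none")),
       padding = match.arg(padding, c("valid", "same")),
       stride = as.integer(stride), bn = isTRUE(bn))
}

#' @rdname layerSpecs
#' @export
layerDeconv <- function(kernel, filters, activation = "tanh",
                        padding = "valid", stride = 1L) {
  stopifnot(kernel >= 1, filters >= 1)
  padding <- match.arg(padding, c("valid", "same"))
  stride <- as.integer(stride)
  if (padding == "valid" && stride != 1L)
    stopf("valid-padded deconvolution supports stride 1 only")
  list(kind = "deconv", kernel = as.integer(kernel),
       filters = as.integer(filters),
       activation = match.arg(activation, c("tanh", "sigmoid", "relu", "none")),
       padding = padding, stride = stride, bn = FALSE)
}

#' @rdname layerSpecs
#' @export
layerMaxPool <- function(kernel) {
  stopifnot(kernel >= 1)
  list(kind = "maxpool", kernel = as.integer(kernel))
}

#' @rdname layerSpecs
#' @param outWidth target width of the bilinear resize.
#' @export
layerBilinear <- function(outWidth) {
  stopifnot(outWidth >= 1)
  list(kind = "bilinear", outWidth = as.integer(outWidth))
}

#' @rdname layerSpecs
#' @export
layerFlatten <- function() list(kind = "flatten")

#' @rdname layerSpecs
#' @param units output dimension of the fully connected layer.
#' @export
layerDense <- function(units, activation = "none") {
  stopifnot(units >= 1)
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation, c("tanh", "sigmoid", "relu", "none")))
}

#' Layer specification constructors
#'
#' Building blocks for [propagateShapes()], [buildNet()] and the network
#' spec constructors. Convolutions and max-pooling default to stride 1 with
#' valid padding (the stride the published layer tables imply); deconvolution
#' supports stride-1 valid (width grows by l - 1) and stride-s same (width
#' grows s-fold).
#'
#' @param rate dropout probability.
#' @return a layer spec list.
#' @name layerSpecs
#' @export
layerDropout <- function(rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", rate = rate)
}

samePadding <- function(W, l, stride) {
  out <- ceiling(W / stride)
  tot <- max((out - 1L) * stride + l - W, 0L)
  c(tot %/% 2L, tot - tot %/% 2L)
}

convGeom <- function(W, l, stride, padding) {
  pads <- if (padding == "same") samePadding(W, l, stride) else c(0L, 0L)
  Wout <- (W + sum(pads) - l) %/% stride + 1L
  list(pads = as.integer(pads), Wout = as.integer(Wout))
}

#' Propagate tensor shapes through a network specification
#'
#' Returns the (height, width, channels) shape after every layer; flattened
#' and dense stages are reported as (1, 1, length). Any layer that would
#' produce a non-positive extent aborts with the layer named.
#'
#' @param spec list of layer specs (see [layerSpecs]).
#' @param inputShape integer(3) (height, width, channels).
#' @return list of integer(3), one per layer.
#' @export
propagateShapes <- function(spec, inputShape) {
  sh <- as.integer(inputShape)
  out <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    sh <- switch(ly$kind,
      conv = {
        geo <- convGeom(sh[2], ly$kernel, ly$stride, ly$padding)
        c(sh[1], geo$Wout, ly$filters)
      },
      deconv = {
        Wout <- if (ly$padding == "same") sh[2] * ly$stride else sh[2] + ly$kernel - 1L
        c(sh[1], as.integer(Wout), ly$filters)
      },
      maxpool = c(sh[1], sh[2] - ly$kernel + 1L, sh[3]),
      bilinear = c(sh[1], ly$outWidth, sh[3]),
      flatten = c(1L, 1L, prod(sh)),
      dense = {
        if (sh[1] != 1L || sh[2] != 1L)
          stopf("layer %d (dense): input must be flattened first", i)
        c(1L, 1L, ly$units)
      },
      dropout = sh,
      stopf("layer %d: unknown kind '%s'", i, ly$kind)
    )
    if (any(sh < 1L))
      stopf("layer %d (%s) produces a non-positive extent (%s)",
            i, ly$kind, paste(sh, collapse = " x "))
    out[[i]] <- as.integer(sh)
  }
  out
}

# ---- network spec constructors --------------------------------------------

#' CAE encoder specification
#'
#' Three blocks of (conv, conv, max-pool) with tanh activations and 1 x l
#' valid kernels at stride 1, compressing an m x n weight matrix to an
#' m x m x p feature tensor. For the reference size (n = 2601, m = 11,
#' p = 60) the published layer table is reproduced exactly; for other sizes
#' a width planner interpolates the intermediate widths geometrically while
#' keeping the block pattern, making the last two convolutions exact
#' halvings (so the mirrored decoder can undo them with stride-2
#' deconvolutions) and landing the final pool on width m.
#'
#' @param n input width (ROI unit count).
#' @param m input height (measuring electrode count).
#' @param p output channel count.
#' @return list of layer specs.
#' @export
caeEncoderSpec <- function(n = 2601, m = 11, p = 60) {
  if (n == 2601 && m == 11 && p == 60) {
    return(list(
      layerConv(602, 2), layerConv(1001, 4), layerMaxPool(201),
      layerConv(401, 8), layerConv(201, 16), layerMaxPool(101),
      layerConv(51, 32), layerConv(26, 60), layerMaxPool(15)
    ))
  }
  c8 <- max(m + 2L, round(2.27 * m))
  c7 <- 2L * c8
  W6 <- 2L * c7
  if (n <= W6 + 6L)
    stopf("ROI width n = %d too small for the CAE block pattern (need > %d)", n, W6 + 6L)
  Wmid <- round(n * (W6 / n)^((1:5) / 6))
  widths <- c(n, Wmid, W6)
  for (i in 2:7) widths[i] <- min(widths[i], widths[i - 1] - 1L)
  f <- pmax(2L, round(2 * (p / 2)^((0:5) / 5)))
  f <- cummax(f); f[6] <- p
  k <- widths[1:6] - widths[2:7] + 1L
  list(
    layerConv(k[1], f[1]), layerConv(k[2], f[2]), layerMaxPool(k[3]),
    layerConv(k[4], f[3]), layerConv(k[5], f[4]), layerMaxPool(k[6]),
    layerConv(c7 + 1L, f[5]), layerConv(c8 + 1L, f[6]),
    layerMaxPool(c8 - m + 1L)
  )
}

#' CAE decoder specification mirroring an encoder
#'
#' Three blocks of (bilinear upsample, deconv, deconv) followed by a 1 x 1
#' same-padded convolution back to one channel. Each bilinear layer restores
#' the width its mirrored pooling layer consumed; the two deconvolutions
#' mirroring the last encoder block run at stride 2 with same padding
#' (undoing the exact halvings), the others at stride 1 valid with the
#' mirrored kernel widths and filter counts.
#'
#' @param encoder result of [caeEncoderSpec()].
#' @param n,m input width and height of the encoder.
#' @return list of layer specs.
#' @export
caeDecoderSpec <- function(encoder, n = 2601, m = 11) {
  shapes <- propagateShapes(encoder, c(m, n, 1L))
  wAfter <- vapply(shapes, `[`, integer(1), 2)
  widthIn <- function(i) if (i == 1) n else wAfter[i - 1]
  cv <- function(i) encoder[[i]]
  list(
    layerBilinear(widthIn(9)),
    layerDeconv(cv(8)$kernel, cv(8)$filters, stride = 2L, padding = "same"),
    layerDeconv(cv(7)$kernel, cv(7)$filters, stride = 2L, padding = "same"),
    layerBilinear(widthIn(6)),
    layerDeconv(cv(5)$kernel, cv(5)$filters),
    layerDeconv(cv(4)$kernel, cv(4)$filters),
    layerBilinear(widthIn(3)),
    layerDeconv(cv(2)$kernel, cv(2)$filters),
    layerDeconv(cv(1)$kernel, cv(1)$filters),
    layerConv(1, 1, activation = "tanh", padding = "same")
  )
}

#' Reconstruction CNN specification
#'
#' Three blocks of (conv + batch-norm + activation, max-pool) with
#' activations sigmoid, sigmoid, relu and filter counts 6, 12, 24, then
#' flatten, a relu fully connected layer of n units, dropout 0.5, and a
#' linear fully connected output of n units. The reference size (p = 60,
#' n = 2601) reproduces the published table (flatten length 1584); other
#' feature widths use scaled kernels with the same block pattern.
#'
#' @param p feature width (channels of v'); `p = 1` accommodates the plain
#'   CNN baseline that consumes the 11 voltages directly.
#' @param n output length (ROI unit count).
#' @param m electrode count (input height).
#' @param dropout dropout probability between the two dense layers.
#' @return list of layer specs.
#' @export
cnnSpec <- function(p = 60, n = 2601, m = 11, dropout = 0.5) {
  if (p == 60 && n == 2601) {
    k <- list(c(31, 16), c(1, 9), c(1, 2))
  } else {
    w <- p
    k <- vector("list", 3)
    for (b in 1:3) {
      kc <- if (b == 1) min(w, max(1L, w %/% 2L + 1L)) else 1L
      w <- w - kc + 1L
      kp <- if (w >= 2) max(2L, w %/% 2L + 1L) else 1L
      if (b == 3) kp <- if (w >= 2) 2L else 1L
      k[[b]] <- c(kc, kp)
      w <- w - kp + 1L
    }
  }
  list(
    layerConv(k[[1]][1], 6, activation = "sigmoid", bn = TRUE),
    layerMaxPool(k[[1]][2]),
    layerConv(k[[2]][1], 12, activation = "sigmoid", bn = TRUE),
    layerMaxPool(k[[2]][2]),
    layerConv(k[[3]][1], 24, activation = "relu", bn = TRUE),
    layerMaxPool(k[[3]][2]),
    layerFlatten(),
    layerDense(n, activation = "relu"),
    layerDropout(dropout),
    layerDense(n, activation = "none")
  )
}

#' Fully connected (back-propagation) baseline specification
#'
#' A plain multilayer perceptron from the m voltages to the n velocity
#' units. The hidden width is a package choice (the comparison baseline's
#' architecture is not pinned down by the published tables).
#'
#' @param n output length.
#' @param hidden hidden layer sizes.
#' @return list of layer specs.
#' @export
bpSpec <- function(n, hidden = 512) {
  c(list(layerFlatten()),
    lapply(hidden, function(h) layerDense(h, activation = "relu")),
    list(layerDense(n, activation = "none")))
}
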