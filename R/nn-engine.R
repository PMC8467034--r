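# Network engine: plain-R forward/backward passes over (N, H, W, C) arrays
# with im2col matrix-multiplication convolutions, manual adjoints for the
# transposed convolutions and resizes, and an Adam optimizer. Everything is
# double precision and seed-deterministic (single-threaded semantics; the
# only BLAS calls are dense matrix products).

actForward <- function(z, kind) {
  switch(kind,
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    relu = pmax(z, 0),
    none = z)
}

actBackward <- function(da, a, z, kind) {
  switch(kind,
    tanh = da * (1 - a^2),
    sigmoid = da * a * (1 - a),
    relu = da * (z > 0),
    none = da)
}

padWidth <- function(x, pl, pr) {
  if (pl == 0L && pr == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + pl + pr, d[4]))
  out[, , pl + seq_len(d[3]), ] <- x
  out
}

unpadWidth <- function(x, pl, pr) {
  if (pl == 0L && pr == 0L) return(x)
  d <- dim(x)
  x[, , (pl + 1L):(d[3] - pr), , drop = FALSE]
}

im2colIdx <- function(Wp, l, stride) {
  Wout <- (Wp - l) %/% stride + 1L
  outer(seq_len(l), (seq_len(Wout) - 1L) * stride, `+`)  # l x Wout
}

# Gather sliding windows into an (N*H*Wout) x (l*C) matrix.
gatherCols <- function(xp, idx) {
  d <- dim(xp)
  l <- nrow(idx); Wout <- ncol(idx)
  cols <- xp[, , as.vector(idx), , drop = FALSE]
  dim(cols) <- c(d[1], d[2], l, Wout, d[4])
  cols <- aperm(cols, c(1, 2, 4, 3, 5))
  dim(cols) <- c(d[1] * d[2] * Wout, l * d[4])
  cols
}

# Adjoint of gatherCols: scatter-add an (N*H*Wout) x (l*C) matrix back onto
# the padded tensor.
scatterCols <- function(Xm, idx, dims) {
  N <- dims[1]; H <- dims[2]; Wp <- dims[3]; C <- dims[4]
  l <- nrow(idx); Wout <- ncol(idx)
  dim(Xm) <- c(N, H, Wout, l, C)
  out <- array(0, dims)
  for (kk in seq_len(l)) {
    sl <- Xm[, , , kk, , drop = FALSE]
    dim(sl) <- c(N, H, Wout, C)
    cols <- idx[kk, ]
    out[, , cols, ] <- out[, , cols, , drop = FALSE] + sl
  }
  out
}

glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

bilinearMatrix <- function(Win, Wout) {
  M <- matrix(0, Wout, Win)
  if (Win == 1L) { M[, 1] <- 1; return(M) }
  src <- seq(1, Win, length.out = Wout)
  i0 <- pmin(floor(src), Win - 1L)
  fr <- src - i0
  for (j in seq_len(Wout)) {
    M[j, i0[j]] <- 1 - fr[j]
    M[j, i0[j] + 1L] <- M[j, i0[j] + 1L] + fr[j]
  }
  M
}

# Per-layer geometry (pads, widths, bilinear matrices), derived from the
# spec and input shape only, so trained models can be rebuilt from slots.
netGeometry <- function(spec, inputShape) {
  shapes <- propagateShapes(spec, inputShape)
  geom <- vector("list", length(spec))
  sh <- as.integer(inputShape)
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    geom[[i]] <- switch(ly$kind,
      conv = {
        g <- convGeom(sh[2], ly$kernel, ly$stride, ly$padding)
        list(pads = g$pads, Win = sh[2], Wout = g$Wout, Cin = sh[3],
             idx = im2colIdx(sh[2] + sum(g$pads), ly$kernel, ly$stride))
      },
      deconv = {
        Wbig <- shapes[[i]][2]
        g <- convGeom(Wbig, ly$kernel, ly$stride, ly$padding)
        if (g$Wout != sh[2])
          stopf("layer %d (deconv): width %d is not reachable from %d", i, Wbig, sh[2])
        list(pads = g$pads, Win = sh[2], Wbig = Wbig, Cin = sh[3],
             idx = im2colIdx(Wbig + sum(g$pads), ly$kernel, ly$stride))
      },
      maxpool = list(Win = sh[2], Wout = shapes[[i]][2]),
      bilinear = list(M = bilinearMatrix(sh[2], ly$outWidth)),
      flatten = list(inShape = sh),
      dense = list(D = prod(sh)),
      dropout = NULL)
    sh <- shapes[[i]]
  }
  list(shapes = shapes, geom = geom)
}

initParams <- function(spec, inputShape, seed) {
  gg <- netGeometry(spec, inputShape)
  withSeed(seed, {
    params <- vector("list", length(spec))
    state <- vector("list", length(spec))
    for (i in seq_along(spec)) {
      ly <- spec[[i]]
      g <- gg$geom[[i]]
      if (ly$kind == "conv") {
        l <- ly$kernel; Cin <- g$Cin; Cout <- ly$filters
        params[[i]] <- list(W = glorot(l * Cin, l * Cout, c(l * Cin, Cout)),
                            b = numeric(Cout))
        if (ly$bn) {
          params[[i]]$gamma <- rep(1, Cout)
          params[[i]]$beta <- numeric(Cout)
          state[[i]] <- list(rmean = numeric(Cout), rvar = rep(1, Cout))
        }
      } else if (ly$kind == "deconv") {
        l <- ly$kernel; Ci <- g$Cin; Co <- ly$filters
        # kernel parameterized as the underlying strided conv Co -> Ci
        params[[i]] <- list(W = glorot(l * Ci, l * Co, c(l * Co, Ci)),
                            b = numeric(Co))
      } else if (ly$kind == "dense") {
        D <- g$D
        params[[i]] <- list(W = glorot(D, ly$units, c(D, ly$units)),
                            b = numeric(ly$units))
      }
    }
    list(params = params, state = state)
  })
}

#' Build an untrained network
#'
#' @param spec list of layer specs (see [layerSpecs]).
#' @param inputShape integer(3) (height, width, channels).
#' @param seed seed for the fan-based uniform (Glorot) initialization.
#' @return internal network object (list) consumed by [trainNet()].
#' @export
buildNet <- function(spec, inputShape, seed = 1L) {
  gg <- netGeometry(spec, inputShape)
  ps <- initParams(spec, inputShape, seed)
  # Zero-initialized linear readout: a trailing linear dense layer starts at
  # exactly zero so the initial prediction is unbiased. With the MAE loss
  # and relu hidden units this prevents the early sign(output) gradients of
  # the majority zero-velocity units from ratcheting the hidden layer into
  # the dead-relu regime.
  last <- length(spec)
  if (spec[[last]]$kind == "dense" && spec[[last]]$activation == "none")
    ps$params[[last]] <- lapply(ps$params[[last]], function(a) a * 0)
  structure(list(spec = spec, inputShape = as.integer(inputShape),
                 shapes = gg$shapes, geom = gg$geom,
                 params = ps$params, state = ps$state),
            class = "nnetCore")
}

netForward <- function(net, x, training = FALSE, upto = length(net$spec)) {
  caches <- vector("list", upto)
  state <- net$state
  for (i in seq_len(upto)) {
    ly <- net$spec[[i]]
    g <- net$geom[[i]]
    P <- net$params[[i]]
    if (ly$kind == "conv") {
      xp <- padWidth(x, g$pads[1], g$pads[2])
      Xm <- gatherCols(xp, g$idx)
      Z <- Xm %*% P$W
      Z <- Z + rep(P$b, each = nrow(Z))
      N <- dim(x)[1]
      dim(Z) <- c(N, dim(x)[2], ncol(g$idx), ly$filters)
      bnCache <- NULL
      if (ly$bn) {
        bn <- bnForward(Z, P$gamma, P$beta, state[[i]], training)
        state[[i]] <- bn$state
        bnCache <- bn$cache
        Z2 <- bn$out
      } else Z2 <- Z
      A <- actForward(Z2, ly$activation)
      caches[[i]] <- list(Xm = Xm, dimsPad = dim(xp), z = Z2, a = A, bn = bnCache)
      x <- A
    } else if (ly$kind == "deconv") {
      N <- dim(x)[1]; H <- dim(x)[2]
      xm <- x
      dim(xm) <- c(N * H * dim(x)[3], dim(x)[4])
      Xbig <- xm %*% t(P$W)
      dimsPad <- c(N, H, g$Wbig + sum(g$pads), ly$filters)
      Yp <- scatterCols(Xbig, g$idx, dimsPad)
      Z <- unpadWidth(Yp, g$pads[1], g$pads[2])
      Z <- Z + rep(P$b, each = N * H * g$Wbig)
      A <- actForward(Z, ly$activation)
      caches[[i]] <- list(xm = xm, dimsPad = dimsPad, z = Z, a = A)
      x <- A
    } else if (ly$kind == "maxpool") {
      l <- ly$kernel
      Wout <- g$Wout
      cur <- x[, , seq_len(Wout), , drop = FALSE]
      arg <- array(1L, dim(cur))
      if (l > 1) for (kk in 2:l) {
        cand <- x[, , (kk):(kk + Wout - 1L), , drop = FALSE]
        upd <- cand > cur
        cur[upd] <- cand[upd]
        arg[upd] <- kk
      }
      caches[[i]] <- list(arg = arg, Win = dim(x)[3])
      x <- cur
    } else if (ly$kind == "bilinear") {
      d <- dim(x)
      xm <- aperm(x, c(1, 2, 4, 3))
      dim(xm) <- c(d[1] * d[2] * d[4], d[3])
      ym <- xm %*% t(g$M)
      dim(ym) <- c(d[1], d[2], d[4], nrow(g$M))
      x <- aperm(ym, c(1, 2, 4, 3))
      caches[[i]] <- list(dimIn = d)
    } else if (ly$kind == "flatten") {
      d <- dim(x)
      xm <- aperm(x, c(2, 3, 4, 1))
      dim(xm) <- c(prod(d[2:4]), d[1])
      x <- t(xm)
      dim(x) <- c(d[1], 1L, 1L, prod(d[2:4]))
      caches[[i]] <- list(dimIn = d)
    } else if (ly$kind == "dense") {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1], g$D)
      Z <- xm %*% P$W
      Z <- Z + rep(P$b, each = d[1])
      A <- actForward(Z, ly$activation)
      x <- A
      dim(x) <- c(d[1], 1L, 1L, ly$units)
      caches[[i]] <- list(xm = xm, z = Z, a = A)
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- array((stats::runif(length(x)) < keep) / keep, dim(x))
        x <- x * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    }
  }
  list(out = x, caches = caches, state = state)
}

netBackward <- function(net, caches, dout) {
  grads <- vector("list", length(net$spec))
  dx <- dout
  for (i in rev(seq_along(net$spec))) {
    ly <- net$spec[[i]]
    g <- net$geom[[i]]
    P <- net$params[[i]]
    cc <- caches[[i]]
    if (ly$kind == "conv") {
      dz <- actBackward(dx, cc$a, cc$z, ly$activation)
      if (ly$bn) {
        bb <- bnBackward(dz, cc$bn, P$gamma)
        grads[[i]] <- list(W = NULL, b = NULL, gamma = bb$dgamma, beta = bb$dbeta)
        dz <- bb$dx
      }
      d <- dim(dz)
      dzm <- dz
      dim(dzm) <- c(prod(d[1:3]), d[4])
      dW <- crossprod(cc$Xm, dzm)
      db <- colSums(dzm)
      dXm <- dzm %*% t(P$W)
      dxp <- scatterCols(dXm, g$idx, cc$dimsPad)
      dx <- unpadWidth(dxp, g$pads[1], g$pads[2])
      if (is.null(grads[[i]])) grads[[i]] <- list()
      grads[[i]]$W <- dW
      grads[[i]]$b <- db
    } else if (ly$kind == "deconv") {
      dz <- actBackward(dx, cc$a, cc$z, ly$activation)
      d <- dim(dz)
      db <- colSums(matrix(dz, prod(d[1:3]), d[4]))
      dzp <- padWidth(dz, g$pads[1], g$pads[2])
      Xbig <- gatherCols(dzp, g$idx)
      dxm <- Xbig %*% P$W
      dW <- crossprod(Xbig, cc$xm)
      dx <- dxm
      dim(dx) <- c(d[1], d[2], g$Win, dim(cc$xm)[2])
      grads[[i]] <- list(W = dW, b = db)
    } else if (ly$kind == "maxpool") {
      l <- ly$kernel
      d <- dim(dx)
      big <- array(0, c(d[1], d[2], cc$Win, d[4]))
      for (kk in seq_len(l)) {
        sl <- dx * (cc$arg == kk)
        big[, , kk:(kk + d[3] - 1L), ] <-
          big[, , kk:(kk + d[3] - 1L), , drop = FALSE] + sl
      }
      dx <- big
    } else if (ly$kind == "bilinear") {
      d <- dim(dx)
      dm <- aperm(dx, c(1, 2, 4, 3))
      dim(dm) <- c(d[1] * d[2] * d[4], d[3])
      xm <- dm %*% g$M
      dim(xm) <- c(d[1], d[2], d[4], ncol(g$M))
      dx <- aperm(xm, c(1, 2, 4, 3))
    } else if (ly$kind == "flatten") {
      d <- cc$dimIn
      dm <- dx
      dim(dm) <- c(d[1], prod(d[2:4]))
      dm <- t(dm)
      dim(dm) <- c(d[2], d[3], d[4], d[1])
      dx <- aperm(dm, c(4, 1, 2, 3))
    } else if (ly$kind == "dense") {
      dz <- actBackward(matrix(dx, nrow(cc$z), ncol(cc$z)), cc$a, cc$z, ly$activation)
      grads[[i]] <- list(W = crossprod(cc$xm, dz), b = colSums(dz))
      dxm <- dz %*% t(P$W)
      d <- dim(cc$xm)
      dx <- dxm
      dim(dx) <- c(d[1], 1L, 1L, ncol(cc$xm))
    } else if (ly$kind == "dropout") {
      if (!is.null(cc$mask)) dx <- dx * cc$mask
    }
  }
  list(grads = grads, dx = dx)
}

bnForward <- function(z, gamma, beta, state, training, eps = 1e-5, momentum = 0.9) {
  d <- dim(z)
  C <- d[4]
  zm <- z
  dim(zm) <- c(prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(zm)
    va <- colMeans(zm^2) - mu^2
    state$rmean <- momentum * state$rmean + (1 - momentum) * mu
    state$rvar <- momentum * state$rvar + (1 - momentum) * va
  } else {
    mu <- state$rmean
    va <- state$rvar
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (zm - rep(mu, each = nrow(zm))) * rep(inv, each = nrow(zm))
  out <- xhat * rep(gamma, each = nrow(zm)) + rep(beta, each = nrow(zm))
  dim(out) <- d
  list(out = out,
       cache = if (training) list(xhat = xhat, inv = inv, dims = d) else
         list(xhat = xhat, inv = inv, dims = d, frozen = TRUE),
       state = state)
}

bnBackward <- function(dout, cache, gamma) {
  d <- cache$dims
  dm <- dout
  dim(dm) <- c(prod(d[1:3]), d[4])
  n <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(gamma, each = n)
  if (isTRUE(cache$frozen)) {
    dz <- dxhat * rep(cache$inv, each = n)
  } else {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dz <- (dxhat - rep(s1 / n, each = n) -
             cache$xhat * rep(s2 / n, each = n)) * rep(cache$inv, each = n)
  }
  dim(dz) <- d
  list(dx = dz, dgamma = dgamma, dbeta = dbeta)
}

# ---- optimizer and training loop ------------------------------------------

adamInit <- function(params) {
  zero <- function(p) if (is.null(p)) NULL else lapply(p, function(a) a * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      gr <- grads[[i]][[nm]]
      if (is.null(gr)) next
      opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * gr
      opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * gr^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (opt$m[[i]][[nm]] / bc1) / (sqrt(opt$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}

#' Mean absolute error
#'
#' @param a,b numeric arrays of identical shape.
#' @return scalar mean of the absolute elementwise differences.
#' @export
mae <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("mae: shape mismatch")
  mean(abs(a - b))
}

#' Train a network with Adam on the MAE loss
#'
#' `iterations` counts optimizer steps; when `batch` is smaller than the
#' sample count each step draws a random minibatch, otherwise every step is
#' full-batch. Training is deterministic given the seed.
#'
#' @param net a [buildNet()] object.
#' @param x input array (N, H, W, C).
#' @param y target array with N leading.
#' @param iterations number of optimizer steps.
#' @param lr learning rate.
#' @param batch minibatch size (capped at N).
#' @param seed RNG seed for batching and dropout.
#' @param beta1,beta2,epsAdam Adam moment parameters.
#' @return the trained network with a `lossHistory` element.
#' @export
trainNet <- function(net, x, y, iterations, lr, batch = Inf, seed = 1L,
                     beta1 = 0.9, beta2 = 0.999, epsAdam = 1e-8) {
  N <- dim(x)[1]
  batch <- min(batch, N)
  dim(y) <- c(N, prod(dim(y)) / N)
  opt <- adamInit(net$params)
  history <- numeric(iterations)
  withSeed(subSeed(seed, "trainloop"), {
    for (it in seq_len(iterations)) {
      ids <- if (batch < N) sample.int(N, batch) else seq_len(N)
      xb <- x[ids, , , , drop = FALSE]
      yb <- y[ids, , drop = FALSE]
      fw <- netForward(net, xb, training = TRUE)
      net$state <- fw$state
      out <- fw$out
      dim(out) <- dim(yb)
      loss <- mean(abs(out - yb))
      history[it] <- loss
      if (!is.finite(loss)) {
        err <- simpleError(sprintf("training diverged at step %d (loss %g)", it, loss))
        err$history <- history[seq_len(it)]
        stop(err)
      }
      dout <- sign(out - yb) / length(out)
      dim(dout) <- dim(fw$out)
      bw <- netBackward(net, fw$caches, dout)
      st <- adamStep(net$params, bw$grads, opt, lr, beta1, beta2, epsAdam)
      net$params <- st$params
      opt <- st$opt
    }
  })
  net$lossHistory <- history
  net
}

netPredict <- function(net, x, upto = length(net$spec)) {
  netForward(net, x, training = FALSE, upto = upto)$out
}
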