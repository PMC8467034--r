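# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

tinyPhantom <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- buildPhantom(phantomConfig("tiny"))
  .fixtures$tiny
}

tinySolver <- function() {
  if (is.null(.fixtures$tinySolver)) .fixtures$tinySolver <- makeSolver(tinyPhantom())
  .fixtures$tinySolver
}

smallPhantom <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- buildPhantom(phantomConfig("small"))
  .fixtures$small
}

smallSolver <- function() {
  if (is.null(.fixtures$smallSolver)) .fixtures$smallSolver <- makeSolver(smallPhantom())
  .fixtures$smallSolver
}

# Uniform-conductivity rectangle phantom (odd grid => exact mirror symmetry
# about the centre column).
uniformPhantom <- function(ng = 33L, sigma = 1, roiDim = 5L) {
  buildPhantom(phantomConfig("tiny", nx = ng, ny = ng, dx = 1 / ng, dy = 1 / ng,
                             uniformTissue = "muscle",
                             tissues = list(muscle = sigma), roiDim = roiDim))
}

# Relative numeric-vs-analytic gradient errors over a probe of parameters.
gradCheckErrors <- function(spec, inShape, N = 3, seed = 7, nprobe = 15,
                            eps = 1e-6) {
  net <- buildNet(spec, inShape, seed = seed)
  set.seed(seed + 1)
  x <- array(rnorm(N * prod(inShape)), c(N, inShape))
  outShape <- dim(emflowtomo:::netForward(net, x, training = FALSE)$out)
  y <- array(rnorm(prod(outShape)), outShape)
  lossOf <- function(nn)
    mean(abs(emflowtomo:::netForward(nn, x, training = TRUE)$out - y))
  fw <- emflowtomo:::netForward(net, x, training = TRUE)
  dout <- sign(fw$out - y) / length(fw$out)
  bw <- emflowtomo:::netBackward(net, fw$caches, dout)
  rels <- numeric()
  for (i in seq_along(net$params)) {
    P <- net$params[[i]]
    if (is.null(P)) next
    for (nm in names(P)) {
      g <- bw$grads[[i]][[nm]]
      if (is.null(g)) next
      idx <- sample(length(P[[nm]]), min(nprobe, length(P[[nm]])))
      for (j in idx) {
        n1 <- net; n1$params[[i]][[nm]][j] <- n1$params[[i]][[nm]][j] + eps
        n2 <- net; n2$params[[i]][[nm]][j] <- n2$params[[i]][[nm]][j] - eps
        num <- (lossOf(n1) - lossOf(n2)) / (2 * eps)
        rels <- c(rels, abs(num - g[j]) / max(1e-8, abs(num) + abs(g[j])))
      }
    }
  }
  rels
}
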