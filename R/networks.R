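#' Standardize a weight matrix
#'
#' Z-scores all entries with a single mean and standard deviation (floored
#' at 1e-12 for degenerate input). The statistics are returned so the exact
#' transform can be reapplied or undone.
#'
#' @param W numeric matrix.
#' @param stats optional previously computed statistics to reapply.
#' @return list with `W` (standardized), `mean`, `sd`.
#' @export
standardizeWeights <- function(W, stats = NULL) {
  if (is.null(stats)) stats <- list(mean = mean(W), sd = max(stats::sd(as.numeric(W)), 1e-12))
  list(W = (W - stats$mean) / stats$sd, mean = stats$mean, sd = stats$sd)
}

#' Normalize a feature set per feature
#'
#' Z-scores every feature position across the sample dimension (the first
#' array extent), with the standard deviation floored at 1e-12 so constant
#' features map to zero. Statistics computed on the training set are
#' reapplied verbatim at inference.
#'
#' @param X samples-first array (N x ...) or matrix (N x d).
#' @param stats optional previously computed statistics to reapply.
#' @return list with `X` (normalized, same shape), `mean`, `sd`.
#' @export
normalizeFeatures <- function(X, stats = NULL) {
  d <- dim(X)
  Xm <- X
  dim(Xm) <- c(d[1], prod(d[-1]))
  if (is.null(stats)) {
    mu <- colMeans(Xm)
    sdv <- pmax(apply(Xm, 2, stats::sd), 1e-12)
    stats <- list(mean = mu, sd = sdv)
  }
  Xm <- (Xm - rep(stats$mean, each = d[1])) / rep(stats$sd, each = d[1])
  dim(Xm) <- d
  list(X = Xm, mean = stats$mean, sd = stats$sd)
}

wrapTrained <- function(net, cfg, normStats, extra) {
  new("TrainedNet", spec = net$spec, params = net$params,
      state = lapply(net$state, function(s) if (is.null(s)) list() else s),
      lossHistory = net$lossHistory, trainConfig = cfg,
      inputShape = net$inputShape, normStats = normStats, extra = extra)
}

# Rebuild the internal network object (geometry is derived, not stored).
asCore <- function(model) {
  gg <- netGeometry(model@spec, model@inputShape)
  structure(list(spec = model@spec, inputShape = model@inputShape,
                 shapes = gg$shapes, geom = gg$geom, params = model@params,
                 state = lapply(model@state, function(s) if (length(s)) s else NULL)),
            class = "nnetCore")
}

#' Train the convolutional auto-encoder on a weight matrix
#'
#' Unsupervised training of the encoder/decoder pair (see
#' [caeEncoderSpec()]) that reconstructs the standardized weight matrix
#' under the MAE loss with Adam; "iterations" are full passes over the
#' single input matrix.
#'
#' @param Wstd standardized m x n weight matrix (see [standardizeWeights()]).
#' @param p encoder output channel count.
#' @param iterations,lr optimizer steps and learning rate.
#' @param seed seed controlling initialization and training.
#' @param spec optional list with elements `encoder` and `decoder` to
#'   override the planned architecture.
#' @return a [TrainedNet-class] holding encoder + decoder.
#' @export
trainCAE <- function(Wstd, p = 60, iterations = 3000, lr = 1e-4, seed = 1L,
                     spec = NULL) {
  m <- nrow(Wstd); n <- ncol(Wstd)
  enc <- spec$encoder %||% caeEncoderSpec(n = n, m = m, p = p)
  dec <- spec$decoder %||% caeDecoderSpec(enc, n = n, m = m)
  net <- buildNet(c(enc, dec), c(m, n, 1L), seed = subSeed(seed, "init"))
  x <- array(Wstd, c(1L, m, n, 1L))
  net <- trainNet(net, x, x, iterations = iterations, lr = lr, batch = Inf,
                  seed = seed)
  wrapTrained(net, list(iterations = iterations, lr = lr, seed = seed, p = p),
              normStats = list(),
              extra = list(type = "cae", encoderLayers = length(enc)))
}

#' Encode a weight matrix into the feature tensor W'
#'
#' Runs the trained encoder half of the CAE; the result is the m x m x p
#' stack of sub-feature matrices consumed by [invertSubfeatures()].
#'
#' @param model a CAE [TrainedNet-class] from [trainCAE()].
#' @param Wstd the standardized weight matrix (same preprocessing as
#'   training).
#' @return numeric array m x m x p.
#' @export
encodeWeights <- function(model, Wstd) {
  if (!identical(model@extra$type, "cae"))
    stopf("model is not a trained CAE")
  m <- model@inputShape[1]
  core <- asCore(model)
  x <- array(Wstd, c(1L, m, ncol(Wstd), 1L))
  out <- netPredict(core, x, upto = model@extra$encoderLayers)
  array(out[1, , , ], dim(out)[2:4])
}

#' Train the reconstruction CNN
#'
#' Supervised training from normalized velocity-domain features v'
#' (N x m x p) to the n-unit velocity labels with MAE loss, Adam, and the
#' blocked architecture of [cnnSpec()]. With `p = 1` this trains the plain
#' CNN baseline directly on the measured voltages.
#'
#' @param features normalized feature array (N x m x p) or matrix (N x m).
#' @param labels N x n matrix of velocity labels (m/s).
#' @param iterations,lr,batch training protocol.
#' @param seed controls initialization, batching and dropout.
#' @param spec optional layer spec override.
#' @param dropout dropout probability of the planned spec.
#' @return a [TrainedNet-class].
#' @export
trainCNN <- function(features, labels, iterations = 1500, lr = 1e-5,
                     batch = 817, seed = 1L, spec = NULL, dropout = 0.5) {
  if (length(dim(features)) == 2L)
    features <- array(features, c(dim(features), 1L))
  N <- dim(features)[1]; m <- dim(features)[2]; p <- dim(features)[3]
  if (nrow(labels) != N) stopf("feature and label sample counts differ")
  n <- ncol(labels)
  spec <- spec %||% cnnSpec(p = p, n = n, m = m, dropout = dropout)
  net <- buildNet(spec, c(m, p, 1L), seed = subSeed(seed, "init"))
  x <- array(features, c(N, m, p, 1L))
  y <- array(labels, c(N, 1L, 1L, n))
  net <- trainNet(net, x, y, iterations = iterations, lr = lr, batch = batch,
                  seed = seed)
  wrapTrained(net, list(iterations = iterations, lr = lr, batch = batch,
                        seed = seed),
              normStats = list(), extra = list(type = "cnn"))
}

#' Train the fully connected baseline
#'
#' @param U standardized voltage matrix (N x m).
#' @param labels N x n velocity labels.
#' @param hidden hidden layer sizes of [bpSpec()].
#' @param iterations,lr,batch,seed training protocol.
#' @return a [TrainedNet-class].
#' @export
trainBP <- function(U, labels, hidden = 512, iterations = 1500, lr = 1e-5,
                    batch = 817, seed = 1L) {
  N <- nrow(U); m <- ncol(U); n <- ncol(labels)
  spec <- bpSpec(n, hidden = hidden)
  net <- buildNet(spec, c(m, 1L, 1L), seed = subSeed(seed, "init"))
  x <- array(U, c(N, m, 1L, 1L))
  y <- array(labels, c(N, 1L, 1L, n))
  net <- trainNet(net, x, y, iterations = iterations, lr = lr, batch = batch,
                  seed = seed)
  wrapTrained(net, list(iterations = iterations, lr = lr, batch = batch,
                        seed = seed, hidden = hidden),
              normStats = list(), extra = list(type = "bp"))
}

#' Predict velocity vectors from a trained network
#'
#' Inference pass (dropout off, batch-norm on its frozen running
#' statistics). Input must already carry the training normalization.
#'
#' @param model a [TrainedNet-class] from [trainCNN()] or [trainBP()].
#' @param features array (N x m x p), matrix (N x m), or a single feature
#'   matrix (m x p) for one sample.
#' @return N x n matrix of predicted velocities (m/s).
#' @export
predictVelocity <- function(model, features) {
  sh <- model@inputShape
  if (is.matrix(features) && all(dim(features) == sh[1:2]) && sh[2] > 1)
    features <- array(features, c(1L, dim(features)))
  if (length(dim(features)) == 2L)
    features <- array(features, c(dim(features), 1L))
  d <- dim(features)
  if (!all(d[-1] == sh[2:3] * c(1, 1)) && !all(d[2:3] == sh[1:2]))
    stopf("feature shape (%s) does not match model input (%s)",
          paste(d[-1], collapse = " x "), paste(sh, collapse = " x "))
  x <- array(features, c(d[1], sh))
  out <- netPredict(asCore(model), x)
  matrix(out, d[1], dim(out)[4])
}

#' Save a trained network checkpoint
#'
#' Plain-text checkpoint directory: `spec.json` (layer specs, input shape,
#' training config, extras), `normstats.json`, `loss.csv`, and one
#' `params-<layer>-<name>.csv` per parameter array (17 significant digits,
#' so doubles round-trip exactly).
#'
#' @param model a [TrainedNet-class].
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "emflowtomo-model", version = 1L,
               package = as.character(utils::packageVersion("emflowtomo")),
               spec = model@spec, inputShape = model@inputShape,
               trainConfig = model@trainConfig, extra = model@extra,
               paramDims = lapply(model@params, function(P)
                 if (is.null(P)) NULL else lapply(P, function(a) dim(a) %||% length(a))))
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(model@normStats, file.path(dir, "normstats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(data.frame(step = seq_along(model@lossHistory),
                              loss = model@lossHistory),
                   file.path(dir, "loss.csv"), row.names = FALSE)
  dumpArr <- function(a, f)
    writeLines(sprintf("%.17g", as.numeric(a)), file.path(dir, f))
  for (i in seq_along(model@params)) {
    P <- model@params[[i]]
    if (is.null(P)) next
    for (nm in names(P)) dumpArr(P[[nm]], sprintf("params-%d-%s.csv", i, nm))
  }
  for (i in seq_along(model@state)) {
    S <- model@state[[i]]
    if (!length(S)) next
    for (nm in names(S)) dumpArr(S[[nm]], sprintf("state-%d-%s.csv", i, nm))
  }
  invisible(dir)
}

#' Load a trained network checkpoint written by [saveModel()]
#'
#' @param dir checkpoint directory.
#' @return a [TrainedNet-class]; predictions reproduce the saved model's
#'   bitwise.
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = FALSE)
  if (!identical(meta$format, "emflowtomo-model"))
    stopf("'%s' is not an emflowtomo model checkpoint", dir)
  spec <- lapply(meta$spec, function(ly) {
    ly <- lapply(ly, function(x) if (is.list(x)) unlist(x) else x)
    for (nm in c("kernel", "filters", "stride", "units", "outWidth"))
      if (!is.null(ly[[nm]])) ly[[nm]] <- as.integer(ly[[nm]])
    ly
  })
  inputShape <- as.integer(unlist(meta$inputShape))
  nL <- length(spec)
  params <- vector("list", nL)
  state <- vector("list", nL)
  readArr <- function(f, d) {
    v <- as.numeric(readLines(file.path(dir, f)))
    if (length(d) > 1) array(v, unlist(d)) else v
  }
  for (i in seq_len(nL)) {
    pd <- meta$paramDims[[i]]
    if (is.null(pd)) { state[[i]] <- list(); next }
    params[[i]] <- lapply(stats::setNames(names(pd), names(pd)), function(nm)
      readArr(sprintf("params-%d-%s.csv", i, nm), pd[[nm]]))
    st <- list()
    for (nm in c("rmean", "rvar")) {
      f <- sprintf("state-%d-%s.csv", i, nm)
      if (file.exists(file.path(dir, f))) st[[nm]] <- as.numeric(readLines(file.path(dir, f)))
    }
    state[[i]] <- st
  }
  loss <- utils::read.csv(file.path(dir, "loss.csv"))$loss
  norm <- jsonlite::read_json(file.path(dir, "normstats.json"), simplifyVector = TRUE)
  new("TrainedNet", spec = spec, params = params, state = state,
      lossHistory = as.numeric(loss),
      trainConfig = lapply(meta$trainConfig, unlist),
      inputShape = inputShape,
      normStats = if (length(norm)) norm else list(),
      extra = lapply(meta$extra, unlist))
}
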