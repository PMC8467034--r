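#' Train the full reconstruction chain on a dataset
#'
#' Runs the complete training protocol: standardize W, train the CAE and
#' encode W', invert the sub-features, transform all voltages to
#' velocity-domain features, normalize on the training split, train the
#' CNN on v' (and the BP / plain-CNN baselines directly on standardized
#' voltages), and tune the Tikhonov weight on a held-out training slice.
#' Returns models plus ready-to-use [methodReconstructor()] closures.
#'
#' @param dataset a [FlowDataset-class].
#' @param p CAE feature channel count.
#' @param caeIterations,caeLr CAE protocol.
#' @param cnnIterations,cnnLr,batch CNN/BP protocol.
#' @param bpHidden hidden width of the BP baseline.
#' @param methods which reconstructors to build.
#' @param seed master seed; every stage derives a named substream.
#' @return list with models, statistics, inversion report and
#'   `reconstructors` (named list).
#' @export
trainPipeline <- function(dataset, p = 60,
                          caeIterations = 3000, caeLr = 1e-4,
                          cnnIterations = 1500, cnnLr = 1e-5, batch = 817,
                          bpHidden = 512,
                          methods = c("tikhonov", "bp", "cnn", "cae_cnn"),
                          seed = 1L) {
  W <- unclass(dataset@W)
  tr <- dataset@trainIdx
  labelsTr <- dataset@V[tr, , drop = FALSE]
  out <- list(methods = methods, seed = seed)
  recon <- list()

  if ("tikhonov" %in% methods) {
    sel <- chooseTikhonovLambda(dataset, seed = subSeed(seed, "tik"))
    out$tikhonov <- sel
    recon$tikhonov <- methodReconstructor("tikhonov",
      list(W = W, lam = sel$lam))
  }

  if (any(c("bp", "cnn") %in% methods)) {
    uNorm <- normalizeFeatures(dataset@U[tr, , drop = FALSE])
    out$uStats <- list(mean = uNorm$mean, sd = uNorm$sd)
  }
  if ("bp" %in% methods) {
    out$bpModel <- trainBP(uNorm$X, labelsTr, hidden = bpHidden,
                           iterations = cnnIterations, lr = cnnLr,
                           batch = batch, seed = subSeed(seed, "bp"))
    recon$bp <- methodReconstructor("bp",
      list(model = out$bpModel, uStats = out$uStats))
  }
  if ("cnn" %in% methods) {
    out$cnnPlainModel <- trainCNN(uNorm$X, labelsTr,
                                  iterations = cnnIterations, lr = cnnLr,
                                  batch = batch, seed = subSeed(seed, "cnnplain"))
    recon$cnn <- methodReconstructor("cnn",
      list(model = out$cnnPlainModel, uStats = out$uStats))
  }

  if ("cae_cnn" %in% methods) {
    ws <- standardizeWeights(W)
    out$wStats <- ws[c("mean", "sd")]
    out$caeModel <- trainCAE(ws$W, p = p, iterations = caeIterations,
                             lr = caeLr, seed = subSeed(seed, "cae"))
    out$Wp <- encodeWeights(out$caeModel, ws$W)
    inv <- invertSubfeatures(out$Wp)
    out$inversionReport <- inv$report
    vpTr <- domainTransform(dataset@U[tr, , drop = FALSE], inv = inv)
    vpNorm <- normalizeFeatures(vpTr)
    out$vpStats <- list(mean = vpNorm$mean, sd = vpNorm$sd)
    out$caeCnnModel <- trainCNN(vpNorm$X, labelsTr,
                                iterations = cnnIterations, lr = cnnLr,
                                batch = batch, seed = subSeed(seed, "caecnn"))
    recon$cae_cnn <- methodReconstructor("cae_cnn",
      list(model = out$caeCnnModel, inv = inv, vpStats = out$vpStats))
  }

  out$reconstructors <- recon
  out
}

#' Scaled-down end-to-end benchmark
#'
#' A desk-scale version of the full study: small phantom (21 x 21 ROI, 441
#' reconstruction units), one field strength (0.10 T), all 19 stenosis
#' configurations, 10 time samples per period (190 samples, 152/38 split),
#' reduced-width networks honoring the published block patterns (p = 12
#' CAE channels), and at most 500 optimizer steps per network. Evaluates
#' every method noiselessly on a seeded half of the test split and across
#' the 60..20 dB noise sweep. Problem sizes and protocol are fixed package
#' choices documented in the methods vignette.
#'
#' @param seed master seed for generation, training and evaluation.
#' @param snrDb noise levels for the sweep.
#' @return list with `dataset`, `pipeline`, `reports` (named evalReports),
#'   `noise` (data.frame from [noiseSweep()]), `subset` indices.
#' @export
runSmallBenchmark <- function(seed = 1L, snrDb = c(60, 50, 40, 30, 20)) {
  phantom <- buildPhantom(phantomConfig("small"))
  flow <- flowConfig()
  sim <- simulationConfig(BValues = 0.10,
                          times = seq(0, flow$period, length.out = 11)[1:10],
                          seed = subSeed(seed, "data"))
  dataset <- generateDataset(phantom, sim, flow)
  pipe <- trainPipeline(dataset, p = 12,
                        caeIterations = 500, caeLr = 1e-3,
                        cnnIterations = 500, cnnLr = 1e-3, batch = Inf,
                        bpHidden = 128, seed = seed)
  test <- dataset@testIdx
  subsetSize <- max(1L, length(test) %/% 2L)
  reports <- lapply(pipe$reconstructors, evaluateMethod, dataset = dataset,
                    indices = test, subsetSize = subsetSize,
                    seed = subSeed(seed, "eval"))
  noise <- noiseSweep(pipe$reconstructors, dataset, snrDb = snrDb,
                      indices = test, subsetSize = subsetSize,
                      seed = subSeed(seed, "eval"))
  list(dataset = dataset, pipeline = pipe, reports = reports, noise = noise,
       subsetSize = subsetSize, seed = seed)
}
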