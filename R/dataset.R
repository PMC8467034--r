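#' Simulation configuration
#'
#' The factorial design of the dataset: magnetic field strengths, stenosis
#' rates expanded separately along +x and -y (rate 0 counted once), and the
#' time samples of one pulsation period. Under the defaults this is
#' 5 x 19 x 86 = 8170 samples.
#'
#' @param BValues field strengths (T).
#' @param rates stenosis rates, subset of {0, 0.1, ..., 0.9}.
#' @param directions stenosis growth axes.
#' @param weightB field strength (T) for the weight matrix.
#' @param seed master seed (split and any other randomness derive from it).
#' @param times optional explicit time samples (s); default is one period
#'   sampled every `dt` with inclusive endpoints.
#' @param stenosisAltersConductivity if TRUE the stenosed cells are also
#'   removed from the conduction model (treated as insulating); by default
#'   only the velocity is zeroed. Both readings of "removing a portion of
#'   the artery" are supported.
#' @param coefTable optional stenosis-coefficient table
#'   (see [stenosisVelocityCoefficient()]).
#' @param trainFraction train share of the random split.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(BValues = c(0.02, 0.04, 0.06, 0.08, 0.10),
                             rates = seq(0, 0.9, by = 0.1),
                             directions = c("+x", "-y"),
                             weightB = 0.1, seed = 1L, times = NULL,
                             stenosisAltersConductivity = FALSE,
                             coefTable = NULL, trainFraction = 0.8) {
  if (any(BValues <= 0)) stopf("all B values must be positive")
  if (!all(directions %in% c("+x", "-y"))) stopf("directions must be '+x' or '-y'")
  structure(list(BValues = BValues, rates = rates, directions = directions,
                 weightB = weightB, seed = as.integer(seed), times = times,
                 stenosisAltersConductivity = isTRUE(stenosisAltersConductivity),
                 coefTable = coefTable, trainFraction = trainFraction),
            class = "SimulationConfig")
}

#' Enumerate the stenosis configurations of a design
#'
#' Rate 0 is direction-independent and appears once; every positive rate is
#' paired with each growth direction (19 configurations under the defaults).
#'
#' @param sim a [simulationConfig()].
#' @return data.frame with columns `rate`, `direction`.
#' @export
stenosisConfigs <- function(sim = simulationConfig()) {
  rates <- sim$rates
  out <- data.frame(rate = numeric(), direction = character())
  if (any(rates == 0))
    out <- rbind(out, data.frame(rate = 0, direction = sim$directions[1]))
  pos <- sort(rates[rates > 0])
  if (length(pos))
    for (d in sim$directions)
      out <- rbind(out, data.frame(rate = pos, direction = d))
  out[order(out$rate, out$direction), , drop = FALSE]
}

#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' Noise standard deviation is `RMS(U) * 10^(-snrDb/20)` per sample
#' (`SNR = 20 log10(Us/Un)` with Us, Un the RMS signal and noise voltages).
#' `snrDb = Inf` returns the input unchanged.
#'
#' @param U numeric measurement vector, or a matrix with one sample per row
#'   (each row gets noise scaled to its own RMS).
#' @param snrDb signal-to-noise ratio (dB).
#' @param seed integer seed; same seed, same noise.
#' @return noisy vector/matrix with attributes `snrDb` and `seed`.
#' @export
addNoise <- function(U, snrDb, seed = 1L) {
  if (!is.finite(snrDb)) return(U)
  vec <- is.null(dim(U))
  Um <- if (vec) matrix(U, nrow = 1) else U
  sdrow <- apply(Um, 1, rms) * 10^(-snrDb / 20)
  if (any(sdrow == 0))
    stopf("all-zero measurement vector: signal RMS undefined for finite SNR")
  noisy <- withSeed(seed, {
    Um + matrix(stats::rnorm(length(Um)), nrow(Um)) * sdrow
  })
  out <- if (vec) as.numeric(noisy) else noisy
  attr(out, "snrDb") <- snrDb
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate the (voltage, velocity-label) dataset
#'
#' Iterates field strengths x stenosis configurations x time samples. For
#' every flow state the potential equation is solved once on the full
#' heterogeneous phantom at unit field strength and scaled to each B (the
#' PDE is exactly linear in B; see the methods vignette), giving the 11
#' electrode potential differences; the label is the ROI velocity image
#' flattened x-fastest. The weight matrix is computed once from the
#' stenosis-free phantom at `weightB`. An 80/20 random split is drawn from
#' the recorded seed.
#'
#' @param phantom a [NeckPhantom-class].
#' @param sim a [simulationConfig()].
#' @param flow a [flowConfig()].
#' @return a [FlowDataset-class].
#' @export
generateDataset <- function(phantom, sim = simulationConfig(), flow = flowConfig()) {
  times <- sim$times %||% seq(0, flow$period, by = flow$dt)
  cfgs <- stenosisConfigs(sim)
  nB <- length(sim$BValues); nC <- nrow(cfgs); nT <- length(times)
  N <- nB * nC * nT

  solver <- makeSolver(phantom)
  W <- assembleWeightMatrix(phantom, sim$weightB, solver)
  idx <- roiCells(phantom)
  n <- length(idx)

  U <- matrix(0, N, 11L)
  V <- matrix(0, N, n)
  meta <- data.frame(B = numeric(N), rate = numeric(N),
                     direction = character(N), time = numeric(N))

  for (ic in seq_len(nC)) {
    rate <- cfgs$rate[ic]; dir <- cfgs$direction[ic]
    slv <- solver
    if (sim$stenosisAltersConductivity && rate > 0) {
      sig2 <- phantom@sigma
      sig2[stenosisMask(phantom, rate, dir)] <- 0
      slv <- makeSolver(phantom, sigma = sig2)
    }
    for (it in seq_len(nT)) {
      t <- times[it]
      vel <- velocityField(phantom, rate, dir, t, flow, coefTable = sim$coefTable)
      u1 <- tryCatch(
        solveFlowPotential(phantom, vel, B = 1, solver = slv),
        error = function(e) stopf(
          "potential solve failed at rate=%.1f dir=%s t=%.3f: %s", rate, dir, t,
          conditionMessage(e)))
      U1 <- electrodeVoltages(u1, phantom)
      lab <- vel$vz[idx]
      for (ib in seq_len(nB)) {
        row <- ((ib - 1L) * nC + (ic - 1L)) * nT + it
        U[row, ] <- sim$BValues[ib] * U1
        V[row, ] <- lab
        meta$B[row] <- sim$BValues[ib]
        meta$rate[row] <- rate
        meta$direction[row] <- dir
        meta$time[row] <- t
      }
    }
  }

  ntrain <- round(sim$trainFraction * N)
  trainIdx <- withSeed(subSeed(sim$seed, "split"), sort(sample.int(N, ntrain)))
  testIdx <- setdiff(seq_len(N), trainIdx)

  new("FlowDataset", U = U, V = V, meta = meta, W = W,
      trainIdx = as.integer(trainIdx), testIdx = as.integer(testIdx),
      seed = as.integer(sim$seed),
      config = list(sim = unclass(sim), flow = unclass(flow),
                    phantom = phantom@config, times = times))
}
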