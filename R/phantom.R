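#' Flow configuration
#'
#' Timing and speed parameters of the pulsatile artery / steady vein flow.
#' The artery carries a two-harmonic pulsatile waveform (see
#' [pulsatileWaveform()]); the vein flows steadily in the opposite axial
#' direction.
#'
#' @param period pulsation period (s).
#' @param dt sampling interval (s); one period sampled inclusively gives
#'   `floor(period/dt) + 1` instants (86 under the defaults).
#' @param veinSpeed constant vein speed magnitude (m/s).
#' @param waveform list of waveform coefficients `a0, a1, a2, phi, vmax`.
#' @return a list of class `FlowConfig`.
#' @export
flowConfig <- function(period = 0.85, dt = 0.01, veinSpeed = 0.08,
                       waveform = list(a0 = 0.8, a1 = 0.55, a2 = 0.25,
                                       phi = pi / 4, vmax = 1.0)) {
  if (period <= 0) stopf("period must be positive")
  if (dt <= 0 || dt > period) stopf("dt must be in (0, period]")
  if (veinSpeed < 0) stopf("veinSpeed must be nonnegative")
  structure(list(period = period, dt = dt, veinSpeed = veinSpeed,
                 waveform = waveform), class = "FlowConfig")
}

#' Pulsatile artery speed waveform
#'
#' A clipped two-harmonic systolic pulse
#' `w(t) = vmax * max(0, a0 + a1 sin(2 pi t/T) + a2 sin(4 pi t/T + phi)) / peak`,
#' normalized so its maximum equals `vmax` (1 m/s by default), peaking in
#' early systole near `t = 0.13 T`. Any published carotid waveform can be
#' substituted through the `waveform` coefficients of [flowConfig()].
#'
#' @param t time (s), vectorized; reduced modulo the period.
#' @param flow a [flowConfig()].
#' @return nonnegative speed(s) in m/s.
#' @export
pulsatileWaveform <- function(t, flow = flowConfig()) {
  wf <- flow$waveform
  raw <- function(tt) {
    th <- 2 * pi * tt / flow$period
    wf$a0 + wf$a1 * sin(th) + wf$a2 * sin(2 * th + wf$phi)
  }
  tg <- seq(0, flow$period, length.out = 4096L)
  peak <- max(raw(tg))
  if (peak <= 0) stopf("waveform coefficients give a nonpositive pulse")
  wf$vmax * pmax(0, raw(t %% flow$period)) / peak
}

#' Stenosis speed-up coefficient
#'
#' Multiplier applied to the artery waveform at the residual lumen when a
#' fraction `rate` of the cross-section is occluded. The default model is
#' flux continuity through a two-segment pipe, `c(rate) = 1 / (1 - rate)`,
#' capped at `cap`; a user-supplied `rate -> coefficient` table (linearly
#' interpolated) overrides it, so coefficients read off a CFD study can be
#' substituted.
#'
#' @param rate occluded fraction, `0 <= rate < 1`.
#' @param table optional data.frame with columns `rate` and `coef`.
#' @param cap upper bound on the default continuity coefficient.
#' @return dimensionless multiplier(s).
#' @export
stenosisVelocityCoefficient <- function(rate, table = NULL, cap = 10) {
  if (any(rate < 0) || any(rate >= 1))
    stopf("rate must lie in [0, 1); a fully occluded vessel has no throughflow")
  if (!is.null(table)) {
    if (!all(c("rate", "coef") %in% names(table)))
      stopf("coefficient table needs columns 'rate' and 'coef'")
    return(stats::approx(table$rate, table$coef, xout = rate, rule = 2)$y)
  }
  pmin(1 / (1 - rate), cap)
}

# ---- phantom geometry ------------------------------------------------------

#' Phantom configuration presets
#'
#' Parametric 2D neck geometry: an elliptical cross-section with annular
#' skin/fat layers over muscle, disc-shaped organs (trachea, esophagus,
#' cervical spine, two glands) and disc-shaped artery and vein, plus 12
#' equally spaced boundary electrodes. All placements are fractions of the
#' domain so the same anatomy scales across grid resolutions. `scale`
#' selects a resolution preset:
#' \describe{
#'   \item{full}{160 x 160 cells, 51 x 51 ROI (2601 reconstruction units).}
#'   \item{small}{48 x 48 cells, 21 x 21 ROI (441 units).}
#'   \item{tiny}{36 x 36 cells, 13 x 13 ROI (169 units).}
#' }
#'
#' @param scale preset name.
#' @param ... named overrides of any configuration entry.
#' @return configuration list for [buildPhantom()].
#' @export
phantomConfig <- function(scale = c("full", "small", "tiny"), ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    full  = list(nx = 160L, ny = 160L, dx = 7.5e-4, dy = 7.5e-4, roiDim = 51L,
                 arteryRadius = 0.0065, veinRadius = 0.0050,
                 tracheaRadius = 0.0100, esophagusRadius = 0.0050,
                 spineRadius = 0.0080, glandRadius = 0.0040),
    small = list(nx = 48L, ny = 48L, dx = 2.5e-3, dy = 2.5e-3, roiDim = 21L,
                 arteryRadius = 0.0095, veinRadius = 0.0070,
                 tracheaRadius = 0.0080, esophagusRadius = 0.0050,
                 spineRadius = 0.0080, glandRadius = 0.0040),
    tiny  = list(nx = 36L, ny = 36L, dx = 1/300, dy = 1/300, roiDim = 13L,
                 arteryRadius = 0.0100, veinRadius = 0.0070,
                 tracheaRadius = 0.0085, esophagusRadius = 0.0050,
                 spineRadius = 0.0078, glandRadius = 0.0040)
  )
  cfg <- c(base, list(
    scale = scale,
    neckFraction = c(0.95, 0.95),
    skinThickness = 0.0020, fatThickness = 0.0045,
    arteryCenter = c(0.60, 0.40), veinCenter = c(0.72, 0.52),
    tracheaCenter = c(0.50, 0.74), esophagusCenter = c(0.40, 0.58),
    spineCenter = c(0.38, 0.22),
    glandCenters = list(c(0.30, 0.62), c(0.68, 0.72)),
    e0Angle = -90, tissues = NULL, uniformTissue = NULL
  ))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown phantom config entries: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Build the 2D neck phantom
#'
#' Rasterizes the parametric geometry of [phantomConfig()] onto a
#' cell-centred grid, assigns per-tissue conductivities (see
#' [tissueConductivities()], overridable via `config$tissues`), places the
#' 12 boundary electrodes at 30-degree spacing starting from `e0Angle`, and
#' delimits the square ROI window of `roiDim^2` reconstruction units around
#' the vessels.
#'
#' @param config list from [phantomConfig()].
#' @return a [NeckPhantom-class].
#' @export
buildPhantom <- function(config = phantomConfig()) {
  nx <- as.integer(config$nx); ny <- as.integer(config$ny)
  if (nx < 32L || ny < 32L) stopf("grid must be at least 32 x 32")
  dx <- config$dx; dy <- config$dy
  if (config$arteryRadius <= 0 || config$veinRadius <= 0)
    stopf("vessel radii must be positive")
  Lx <- nx * dx; Ly <- ny * dy
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  sig0 <- tissueConductivities()
  if (!is.null(config$tissues)) {
    bad <- setdiff(names(config$tissues), names(sig0))
    if (length(bad)) stopf("unknown tissues in override: %s", paste(bad, collapse = ", "))
    sig0[names(config$tissues)] <- unlist(config$tissues)
    if (any(sig0 < 0)) stopf("conductivities must be nonnegative")
  }

  labels <- matrix(TISSUES[["background"]], nx, ny)

  if (!is.null(config$uniformTissue)) {
    if (!config$uniformTissue %in% names(TISSUES))
      stopf("unknown tissue '%s'", config$uniformTissue)
    labels[] <- TISSUES[[config$uniformTissue]]
  } else {
    a <- config$neckFraction[1] * Lx / 2
    b <- config$neckFraction[2] * Ly / 2
    cx <- Lx / 2; cy <- Ly / 2
    rho <- sqrt(((X - cx) / a)^2 + ((Y - cy) / b)^2)
    sbar <- (a + b) / 2
    inNeck <- rho <= 1
    labels[inNeck] <- TISSUES[["muscle"]]
    labels[inNeck & rho > 1 - (config$skinThickness + config$fatThickness) / sbar] <-
      TISSUES[["fat"]]
    labels[inNeck & rho > 1 - config$skinThickness / sbar] <- TISSUES[["skin"]]

    disc <- function(centerFrac, radius) {
      (X - centerFrac[1] * Lx)^2 + (Y - centerFrac[2] * Ly)^2 <= radius^2
    }
    carve <- function(labels, mask, tissue) {
      sel <- mask & labels == TISSUES[["muscle"]]
      labels[sel] <- TISSUES[[tissue]]
      labels
    }
    labels <- carve(labels, disc(config$tracheaCenter, config$tracheaRadius), "trachea")
    labels <- carve(labels, disc(config$esophagusCenter, config$esophagusRadius), "esophagus")
    labels <- carve(labels, disc(config$spineCenter, config$spineRadius), "cervical spine")
    for (g in config$glandCenters)
      labels <- carve(labels, disc(g, config$glandRadius), "glands")

    actr <- config$arteryCenter * c(Lx, Ly)
    vctr <- config$veinCenter * c(Lx, Ly)
    gap <- sqrt(sum((actr - vctr)^2))
    if (gap <= config$arteryRadius + config$veinRadius)
      stopf(paste("artery and vein discs overlap (centre gap %.4g m,",
                  "radii sum %.4g m); adjust centres or radii"),
            gap, config$arteryRadius + config$veinRadius)
    aMask <- disc(config$arteryCenter, config$arteryRadius)
    vMask <- disc(config$veinCenter, config$veinRadius)
    if (!any(aMask & labels == TISSUES[["muscle"]]))
      stopf("artery disc does not land on muscle tissue")
    labels <- carve(labels, aMask, "artery")
    labels <- carve(labels, vMask, "vein")
  }

  sigma <- matrix(unname(sig0[names(TISSUES)[labels + 1L]]), nx, ny)

  # ROI window centred between the vessels (or domain centre when uniform)
  roiDim <- as.integer(config$roiDim)
  if (is.null(config$uniformTissue)) {
    ctrFrac <- (config$arteryCenter + config$veinCenter) / 2
  } else ctrFrac <- c(0.5, 0.5)
  cxCell <- round(ctrFrac[1] * nx); cyCell <- round(ctrFrac[2] * ny)
  x0 <- as.integer(max(1, min(nx - roiDim + 1, cxCell - roiDim %/% 2)))
  y0 <- as.integer(max(1, min(ny - roiDim + 1, cyCell - roiDim %/% 2)))
  roi <- c(x0, y0, roiDim, roiDim)

  electrodes <- placeElectrodes(sigma, dx, dy, config$e0Angle)

  new("NeckPhantom", nx = nx, ny = ny, dx = dx, dy = dy,
      origin = c(dx / 2, dy / 2), labels = labels, sigma = sigma,
      electrodes = electrodes, roi = roi, config = config)
}

# Outermost conducting cell along 12 rays at 30-degree spacing.
placeElectrodes <- function(sigma, dx, dy, e0Angle) {
  nx <- nrow(sigma); ny <- ncol(sigma)
  cx <- nx * dx / 2; cy <- ny * dy / 2
  angles <- (e0Angle + 30 * (0:11)) * pi / 180
  rmax <- sqrt(cx^2 + cy^2) * 1.01
  idx <- integer(12)
  for (k in 1:12) {
    tt <- seq(0, 1, length.out = 4 * max(nx, ny))
    px <- cx + cos(angles[k]) * rmax * tt
    py <- cy + sin(angles[k]) * rmax * tt
    ix <- pmin(pmax(ceiling(px / dx), 1L), nx)
    iy <- pmin(pmax(ceiling(py / dy), 1L), ny)
    lin <- ix + (iy - 1L) * nx
    act <- sigma[lin] > 0
    if (!any(act)) stopf("no conducting cell along electrode ray %d", k)
    idx[k] <- lin[max(which(act))]
  }
  if (anyDuplicated(idx))
    stopf("electrode cells collide; grid too coarse for 12 distinct boundary cells")
  as.integer(idx)
}

# ---- stenosis and velocity fields -----------------------------------------

VALID_RATES <- seq(0, 0.9, by = 0.1)

#' Stenosis occlusion mask
#'
#' Accretes `round(rate * |artery|)` artery cells by a half-plane sweep:
#' direction `"+x"` sweeps the plane in +x (cells with smallest x first),
#' `"-y"` sweeps in -y (largest y first). Ties at equal coordinate are
#' broken by ascending linear cell index, so masks are nested across rates.
#'
#' @param phantom a [NeckPhantom-class].
#' @param rate occluded fraction, one of 0, 0.1, ..., 0.9.
#' @param direction `"+x"` or `"-y"`.
#' @return logical matrix mask (subset of the artery mask).
#' @export
stenosisMask <- function(phantom, rate, direction = c("+x", "-y")) {
  direction <- match.arg(direction)
  if (min(abs(rate - VALID_RATES)) > 1e-9)
    stopf("rate must be one of {0, 0.1, ..., 0.9}")
  aIdx <- which(tissueMask(phantom, "artery"))
  if (!length(aIdx)) stopf("phantom has an empty artery mask")
  count <- round(rate * length(aIdx))
  mask <- matrix(FALSE, phantom@nx, phantom@ny)
  if (count > 0) {
    ix <- ((aIdx - 1L) %% phantom@nx) + 1L
    iy <- ((aIdx - 1L) %/% phantom@nx) + 1L
    ord <- if (direction == "+x") order(ix, aIdx) else order(-iy, aIdx)
    mask[aIdx[ord[seq_len(count)]]] <- TRUE
  }
  mask
}

#' Axial velocity field at one instant
#'
#' Non-stenosed artery cells carry `+ w(t) * c(rate)` (pulsatile waveform
#' times the stenosis speed-up), stenosed cells exactly 0, vein cells
#' `- veinSpeed`, everything else 0. Flow is axial (+z out of plane for the
#' artery).
#'
#' @param phantom a [NeckPhantom-class].
#' @param rate,direction stenosis configuration (see [stenosisMask()]).
#' @param t time instant (s).
#' @param flow a [flowConfig()].
#' @param coefTable optional stenosis-coefficient override table.
#' @return object of class `VelocityField`: list with `vz` (matrix, m/s),
#'   `stenosisMask` (logical matrix) and `time`.
#' @export
velocityField <- function(phantom, rate = 0, direction = "+x", t = 0,
                          flow = flowConfig(), coefTable = NULL) {
  mask <- stenosisMask(phantom, rate, direction)
  vz <- matrix(0, phantom@nx, phantom@ny)
  speed <- pulsatileWaveform(t, flow) *
    stenosisVelocityCoefficient(rate, table = coefTable)
  vz[tissueMask(phantom, "artery") & !mask] <- speed
  vz[tissueMask(phantom, "vein")] <- -flow$veinSpeed
  structure(list(vz = vz, stenosisMask = mask, time = t),
            class = "VelocityField")
}

#' @export
print.VelocityField <- function(x, ...) {
  cat(sprintf("VelocityField t = %.3f s: artery peak %.3f m/s, %d stenosed cells\n",
              x$time, max(x$vz), sum(x$stenosisMask)))
  invisible(x)
}
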