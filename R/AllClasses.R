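#' @import methods
NULL

TISSUES <- c(
  background = 0L, skin = 1L, fat = 2L, muscle = 3L, esophagus = 4L,
  `cervical spine` = 5L, glands = 6L, trachea = 7L, artery = 8L, vein = 9L
)

#' Reference tissue conductivities (S/m)
#'
#' Literature values for the nine neck tissues of the phantom. Trachea and
#' esophagus are air-filled lumina and carry zero conductivity; the solver
#' treats them as internal insulating holes.
#'
#' @return named numeric vector of conductivities in S/m.
#' @export
tissueConductivities <- function() {
  c(skin = 0.005, fat = 0.1, muscle = 0.2, esophagus = 0,
    `cervical spine` = 0.001, glands = 0.6, trachea = 0,
    artery = 1.12, vein = 1.12, background = 0)
}

#' NeckPhantom: discretized 2D neck cross-section
#'
#' A cell-centred regular grid with a tissue label and a conductivity per
#' cell, 12 boundary electrode cells (the first is the grounded reference
#' e0), and a rectangular reconstruction window (ROI) that contains the
#' artery and the vein. Matrices are indexed `[ix, iy]` with x increasing
#' rightward and y upward; linear cell indices follow R's column-major
#' order, so within the ROI the flattening runs x-fastest.
#'
#' @slot nx,ny integer grid extents.
#' @slot dx,dy numeric cell sizes (m).
#' @slot origin numeric(2), physical coordinate of the centre of cell (1,1).
#' @slot labels integer matrix of tissue codes (see `TISSUES`).
#' @slot sigma numeric matrix of conductivities (S/m).
#' @slot electrodes integer(12) linear cell indices, e0 first.
#' @slot roi integer(4): c(x0, y0, width, height) of the ROI window (1-based).
#' @slot config list, the generating configuration.
#' @export
setClass("NeckPhantom", representation(
  nx = "integer", ny = "integer", dx = "numeric", dy = "numeric",
  origin = "numeric", labels = "matrix", sigma = "matrix",
  electrodes = "integer", roi = "integer", config = "list"
))

setValidity("NeckPhantom", function(object) {
  msg <- character()
  if (object@nx < 3L || object@ny < 3L) msg <- c(msg, "grid must be at least 3 x 3")
  if (object@dx <= 0 || object@dy <= 0) msg <- c(msg, "cell sizes must be positive")
  if (!all(dim(object@labels) == c(object@nx, object@ny)))
    msg <- c(msg, "labels dimension mismatch")
  if (!all(dim(object@sigma) == c(object@nx, object@ny)))
    msg <- c(msg, "sigma dimension mismatch")
  if (any(object@sigma < 0)) msg <- c(msg, "conductivities must be nonnegative")
  if (length(object@electrodes) != 12L) msg <- c(msg, "exactly 12 electrodes required")
  if (anyDuplicated(object@electrodes)) msg <- c(msg, "electrode cells must be distinct")
  r <- object@roi
  if (length(r) != 4L || r[1] < 1L || r[2] < 1L ||
      r[1] + r[3] - 1L > object@nx || r[2] + r[4] - 1L > object@ny)
    msg <- c(msg, "roi window outside grid")
  amask <- object@labels == TISSUES[["artery"]]
  vmask <- object@labels == TISSUES[["vein"]]
  if (any(amask & vmask)) msg <- c(msg, "artery and vein masks overlap")
  inroi <- matrix(FALSE, object@nx, object@ny)
  inroi[r[1]:(r[1] + r[3] - 1L), r[2]:(r[2] + r[4] - 1L)] <- TRUE
  if (any(amask & !inroi) || any(vmask & !inroi))
    msg <- c(msg, "artery and vein must lie inside the roi window")
  if (length(msg)) msg else TRUE
})

#' WeightMatrix: linear sensitivity map from ROI velocities to voltages
#'
#' An m x n matrix (V per m/s) whose row k is the reciprocal-field
#' sensitivity of measuring electrode k: `W[k, i] = -J_Ay(cell i) * B * S_i`.
#'
#' @slot areas numeric, per-unit cross-section area S_i (m^2).
#' @slot weightB numeric, field strength (T) used for the sensitivity map.
#' @slot roiDim integer(2), ROI window extents (cells).
#' @export
setClass("WeightMatrix", contains = "matrix",
         representation(areas = "numeric", weightB = "numeric", roiDim = "integer"))

setValidity("WeightMatrix", function(object) {
  if (!all(is.finite(object@.Data))) return("weight matrix entries must be finite")
  if (ncol(object) != prod(object@roiDim)) return("column count must equal ROI cell count")
  TRUE
})

#' FlowDataset: (voltage, velocity-label) sample collection
#'
#' Rows of `U` are 11-vectors of electrode potential differences (V); rows
#' of `V` are the flattened ROI velocity labels (m/s). `meta` records the
#' field strength, stenosis rate/direction and time instant of every sample.
#'
#' @slot U numeric matrix, N x m.
#' @slot V numeric matrix, N x n.
#' @slot meta data.frame with columns B, rate, direction, time.
#' @slot W the [WeightMatrix-class] computed from the stenosis-free phantom.
#' @slot trainIdx,testIdx integer sample indices of the 80/20 split.
#' @slot seed integer master seed of the generating run.
#' @slot config list, configuration snapshot.
#' @export
setClass("FlowDataset", representation(
  U = "matrix", V = "matrix", meta = "data.frame", W = "WeightMatrix",
  trainIdx = "integer", testIdx = "integer", seed = "integer", config = "list"
))

setValidity("FlowDataset", function(object) {
  msg <- character()
  n <- nrow(object@U)
  if (nrow(object@V) != n || nrow(object@meta) != n)
    msg <- c(msg, "U, V and meta must have one row per sample")
  if (ncol(object@V) != ncol(object@W))
    msg <- c(msg, "label length must equal weight-matrix column count")
  idx <- sort(c(object@trainIdx, object@testIdx))
  if (length(idx) && !identical(idx, seq_len(n)))
    msg <- c(msg, "train/test split must be disjoint and exhaustive")
  if (length(msg)) msg else TRUE
})

#' TrainedNet: a trained network with its full provenance
#'
#' @slot spec list of layer specifications.
#' @slot params list of per-layer parameter arrays.
#' @slot state list of per-layer persistent state (batch-norm running stats).
#' @slot lossHistory numeric, loss per optimizer step.
#' @slot trainConfig list of the training hyper-parameters and seed.
#' @slot inputShape integer(3) (height, width, channels).
#' @slot normStats list, input (and optional label) normalization statistics.
#' @slot extra list, model-specific extras (e.g. encoder layer count).
#' @export
setClass("TrainedNet", representation(
  spec = "list", params = "list", state = "list", lossHistory = "numeric",
  trainConfig = "list", inputShape = "integer", normStats = "list", extra = "list"
))

setMethod("show", "NeckPhantom", function(object) {
  counts <- table(factor(object@labels, levels = TISSUES, labels = names(TISSUES)))
  cat(sprintf("NeckPhantom %d x %d cells (%.1f x %.1f mm), %d conducting\n",
              object@nx, object@ny, object@nx * object@dx * 1e3,
              object@ny * object@dy * 1e3, sum(object@sigma > 0)))
  cat(sprintf("  ROI %d x %d (%d units), artery %d cells, vein %d cells\n",
              object@roi[3], object@roi[4], prod(object@roi[3:4]),
              counts[["artery"]], counts[["vein"]]))
  cat(sprintf("  12 electrodes, reference e0 at cell %d\n", object@electrodes[1]))
})

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf("WeightMatrix %d x %d (B = %.3g T, S_i = %.3g m^2)\n",
              nrow(object), ncol(object), object@weightB, object@areas[1]))
})

setMethod("show", "FlowDataset", function(object) {
  cat(sprintf("FlowDataset: %d samples (%d train / %d test), m = %d, n = %d\n",
              nrow(object@U), length(object@trainIdx), length(object@testIdx),
              ncol(object@U), ncol(object@V)))
  cat(sprintf("  B values: %s T; stenosis rates: %s\n",
              paste(sort(unique(object@meta$B)), collapse = ", "),
              paste(sort(unique(object@meta$rate)), collapse = ", ")))
})

setMethod("show", "TrainedNet", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = FALSE),
                   length, integer(1)))
  cat(sprintf("TrainedNet: %d layers, %d parameters, %d training steps, final loss %.4g\n",
              length(object@spec), np, length(object@lossHistory),
              utils::tail(object@lossHistory, 1)))
})

# ---- accessors -------------------------------------------------------------

#' @rdname NeckPhantom-class
#' @param object,x a `NeckPhantom`.
#' @export
setGeneric("conductivity", function(object) standardGeneric("conductivity"))
#' @rdname NeckPhantom-class
#' @export
setMethod("conductivity", "NeckPhantom", function(object) object@sigma)

#' @rdname NeckPhantom-class
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname NeckPhantom-class
#' @export
setMethod("tissueLabels", "NeckPhantom", function(object) {
  m <- object@labels
  structure(m, class = NULL)
})

#' @rdname NeckPhantom-class
#' @export
setGeneric("electrodeCells", function(object) standardGeneric("electrodeCells"))
#' @rdname NeckPhantom-class
#' @export
setMethod("electrodeCells", "NeckPhantom", function(object) object@electrodes)

#' @rdname NeckPhantom-class
#' @export
setGeneric("roiWindow", function(object) standardGeneric("roiWindow"))
#' @rdname NeckPhantom-class
#' @export
setMethod("roiWindow", "NeckPhantom", function(object) object@roi)

#' Per-cell mask of a named tissue
#' @param object a `NeckPhantom`.
#' @param tissue tissue name, e.g. "artery".
#' @return logical matrix.
#' @export
setGeneric("tissueMask", function(object, tissue) standardGeneric("tissueMask"))
#' @rdname tissueMask
#' @export
setMethod("tissueMask", "NeckPhantom", function(object, tissue) {
  if (!tissue %in% names(TISSUES)) stopf("unknown tissue '%s'", tissue)
  object@labels == TISSUES[[tissue]]
})

#' Linear cell indices of the ROI window, x-fastest
#' @param phantom a `NeckPhantom`.
#' @return integer vector of length `prod(roiWindow(phantom)[3:4])`.
#' @export
roiCells <- function(phantom) {
  r <- phantom@roi
  ix <- r[1]:(r[1] + r[3] - 1L)
  iy <- r[2]:(r[2] + r[4] - 1L)
  as.integer(outer(ix, (iy - 1L) * phantom@nx, `+`))
}

#' Cell cross-section area S_i (m^2)
#' @param phantom a `NeckPhantom`.
#' @export
cellArea <- function(phantom) phantom@dx * phantom@dy

#' @rdname FlowDataset-class
#' @param object a `FlowDataset`.
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))
#' @rdname FlowDataset-class
#' @export
setMethod("voltages", "FlowDataset", function(object) object@U)

#' @rdname FlowDataset-class
#' @export
setGeneric("velocityLabels", function(object) standardGeneric("velocityLabels"))
#' @rdname FlowDataset-class
#' @export
setMethod("velocityLabels", "FlowDataset", function(object) object@V)

#' @rdname FlowDataset-class
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))
#' @rdname FlowDataset-class
#' @export
setMethod("weightMatrix", "FlowDataset", function(object) object@W)

#' @rdname FlowDataset-class
#' @export
setGeneric("trainIndices", function(object) standardGeneric("trainIndices"))
#' @rdname FlowDataset-class
#' @export
setMethod("trainIndices", "FlowDataset", function(object) object@trainIdx)

#' @rdname FlowDataset-class
#' @export
setGeneric("testIndices", function(object) standardGeneric("testIndices"))
#' @rdname FlowDataset-class
#' @export
setMethod("testIndices", "FlowDataset", function(object) object@testIdx)

#' @rdname FlowDataset-class
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))
#' @rdname FlowDataset-class
#' @export
setMethod("sampleMeta", "FlowDataset", function(object) object@meta)

#' @rdname TrainedNet-class
#' @param object a `TrainedNet`.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
#' @rdname TrainedNet-class
#' @export
setMethod("lossHistory", "TrainedNet", function(object) object@lossHistory)
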