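#' Save a dataset container
#'
#' Writes a versioned plain-text container directory: `U.csv`, `V.csv`,
#' `W.csv` (comma-separated numeric matrices), `meta.csv`, and
#' `manifest.json` holding the split, seeds, configuration snapshot and
#' package version.
#'
#' @param dataset a [FlowDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(m, f) data.table::fwrite(data.table::as.data.table(m),
                                          file.path(dir, f), col.names = FALSE)
  fw(dataset@U, "U.csv")
  fw(dataset@V, "V.csv")
  fw(unclass(dataset@W), "W.csv")
  data.table::fwrite(dataset@meta, file.path(dir, "meta.csv"))
  manifest <- list(
    format = "emflowtomo-dataset", version = 1L,
    package = as.character(utils::packageVersion("emflowtomo")),
    seed = dataset@seed, trainIdx = dataset@trainIdx, testIdx = dataset@testIdx,
    weightB = dataset@W@weightB, roiDim = dataset@W@roiDim,
    cellArea = dataset@W@areas[1], config = dataset@config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a dataset container written by [saveDataset()]
#'
#' @param dir container directory.
#' @return a [FlowDataset-class].
#' @export
loadDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (!identical(man$format, "emflowtomo-dataset"))
    stopf("'%s' is not an emflowtomo dataset container", dir)
  fr <- function(f) as.matrix(data.table::fread(file.path(dir, f), header = FALSE))
  U <- unname(fr("U.csv")); V <- unname(fr("V.csv")); Wm <- unname(fr("W.csv"))
  meta <- as.data.frame(data.table::fread(file.path(dir, "meta.csv")))
  W <- new("WeightMatrix", Wm, areas = rep(man$cellArea, ncol(Wm)),
           weightB = man$weightB, roiDim = as.integer(man$roiDim))
  new("FlowDataset", U = U, V = V, meta = meta, W = W,
      trainIdx = as.integer(man$trainIdx), testIdx = as.integer(man$testIdx),
      seed = as.integer(man$seed), config = as.list(man$config))
}

#' Save / load a phantom
#'
#' The container holds `labels.csv` and `sigma.csv` grids plus a JSON
#' metadata block with grid geometry, electrodes, ROI and the generating
#' configuration.
#'
#' @param phantom a [NeckPhantom-class].
#' @param dir container directory.
#' @return `dir` (save) or the phantom (load), invisibly for save.
#' @export
savePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(phantom@labels),
                     file.path(dir, "labels.csv"), col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(phantom@sigma),
                     file.path(dir, "sigma.csv"), col.names = FALSE)
  meta <- list(format = "emflowtomo-phantom", version = 1L,
               package = as.character(utils::packageVersion("emflowtomo")),
               nx = phantom@nx, ny = phantom@ny, dx = phantom@dx, dy = phantom@dy,
               origin = phantom@origin, electrodes = phantom@electrodes,
               roi = phantom@roi, config = phantom@config)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname savePhantom
#' @export
loadPhantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "emflowtomo-phantom"))
    stopf("'%s' is not an emflowtomo phantom container", dir)
  labels <- unname(as.matrix(data.table::fread(file.path(dir, "labels.csv"),
                                               header = FALSE)))
  sigma <- unname(as.matrix(data.table::fread(file.path(dir, "sigma.csv"),
                                              header = FALSE)))
  storage.mode(labels) <- "integer"
  cfg <- as.list(meta$config)
  if (!is.null(cfg$glandCenters) && is.matrix(cfg$glandCenters))
    cfg$glandCenters <- lapply(seq_len(nrow(cfg$glandCenters)),
                               function(i) as.numeric(cfg$glandCenters[i, ]))
  new("NeckPhantom", nx = as.integer(meta$nx), ny = as.integer(meta$ny),
      dx = meta$dx, dy = meta$dy, origin = as.numeric(meta$origin),
      labels = labels, sigma = sigma, electrodes = as.integer(meta$electrodes),
      roi = as.integer(meta$roi), config = cfg)
}

#' Read and validate a run configuration
#'
#' YAML with sections `phantom`, `simulation`, `flow`, `train`, `evaluate`
#' and a top-level `seed`/`scale`. Unknown sections or unknown keys inside a
#' section are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return nested list of class `RunConfig` with defaults filled in.
#' @export
readRunConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- list(
    seed = 1L, scale = "small",
    phantom = list(),   # any phantomConfig() override
    simulation = list(BValues = NULL, rates = NULL, directions = NULL,
                      weightB = NULL, times = NULL, nTimes = NULL,
                      stenosisAltersConductivity = NULL),
    flow = list(period = NULL, dt = NULL, veinSpeed = NULL),
    train = list(p = NULL, caeIterations = NULL, caeLr = NULL,
                 cnnIterations = NULL, cnnLr = NULL, batch = NULL,
                 bpHidden = NULL, methods = NULL),
    evaluate = list(subsetSize = NULL, snrDb = NULL)
  )
  bad <- setdiff(names(raw), names(known))
  if (length(bad)) stopf("unknown config sections: %s", paste(bad, collapse = ", "))
  for (sec in intersect(names(raw), c("simulation", "flow", "train", "evaluate"))) {
    badk <- setdiff(names(raw[[sec]]), names(known[[sec]]))
    if (length(badk)) stopf("unknown keys in [%s]: %s", sec, paste(badk, collapse = ", "))
  }
  out <- utils::modifyList(known, raw)
  structure(out, class = "RunConfig")
}
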