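#' @import methods
#' @importFrom stats cor glm predict quantile sd step rnorm runif binomial
#'   coef pt setNames aggregate as.formula complete.cases
#' @importFrom utils head read.csv write.csv
NULL

#' Georeferenced raster grid
#'
#' A minimal raster container: a numeric matrix of cell values (row 1 is the
#' northern edge), a square cell size in map units, and the coordinates of the
#' lower-left corner of the grid. `NA` cells are nodata.
#'
#' @slot values numeric matrix of cell values; `NA` marks nodata.
#' @slot cellSize positive scalar, cell edge length in map units (e.g. m).
#' @slot origin numeric length-2, (x, y) of the lower-left grid corner.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), cellSize = 1, origin = c(0, 0))
)

setValidity("RasterGrid", function(object) {
  msg <- character(0)
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite coordinates")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' Labeled symmetric distance matrix
#'
#' Container for pairwise site distances: least-cost distance (`"LCD"`),
#' resistance distance (`"IBR"`), Euclidean (`"EUCLIDEAN"`) or genetic
#' differentiation (`"FST"`). Values are nonnegative with a zero diagonal;
#' `Inf` is the sentinel for disconnected pairs.
#'
#' @slot values symmetric numeric matrix with labeled dimnames.
#' @slot kind one of "LCD", "IBR", "EUCLIDEAN", "FST".
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", kind = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "matrix must carry identical row and column labels")
  if (nrow(v) > 0) {
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    fin <- is.finite(v)
    if (any(v[fin] < -1e-12)) msg <- c(msg, "distances must be nonnegative")
    if (max(abs(v[fin] - t(v)[fin])) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  }
  if (!object@kind %in% c("LCD", "IBR", "EUCLIDEAN", "FST"))
    msg <- c(msg, "kind must be one of LCD, IBR, EUCLIDEAN, FST")
  if (length(msg)) msg else TRUE
})

#' Resistance (cost) surface
#'
#' Per-cell movement cost derived from habitat suitability via anchored
#' log-linear interpolation, with road cells burnt in at a fixed barrier cost.
#'
#' @slot cost a [RasterGrid] of per-cell costs (>= 1 on valid cells).
#' @slot roadMask a binary [RasterGrid]; 1 marks road cells.
#' @slot roadCost scalar cost assigned to road cells.
#' @slot anchors two-column matrix (suitability, cost) of the transform anchors.
#' @export
setClass("ResistanceSurface",
  representation(cost = "RasterGrid", roadMask = "RasterGrid",
                 roadCost = "numeric", anchors = "matrix"))

setValidity("ResistanceSurface", function(object) {
  msg <- character(0)
  v <- object@cost@values
  if (any(v[!is.na(v)] < 1 - 1e-9)) msg <- c(msg, "costs must be >= 1")
  if (!identical(dim(v), dim(object@roadMask@values)))
    msg <- c(msg, "cost and road mask must share dimensions")
  rm <- object@roadMask@values
  road <- !is.na(rm) & rm > 0 & !is.na(v)
  if (any(road) && any(abs(v[road] - object@roadCost) > 1e-9))
    msg <- c(msg, "road cells must carry the road cost exactly")
  if (length(msg)) msg else TRUE
})

#' Committee-averaged ensemble habitat map
#'
#' @slot committee [RasterGrid] of vote fractions in \{0, 1/n, ..., 1\}.
#' @slot suitableMask binary [RasterGrid], 1 where committee > 0.5.
#' @slot nModels number of member models.
#' @export
setClass("EnsembleMap",
  representation(committee = "RasterGrid", suitableMask = "RasterGrid",
                 nModels = "integer"))

setValidity("EnsembleMap", function(object) {
  v <- object@committee@values
  ok <- v[!is.na(v)]
  msg <- character(0)
  if (any(ok < -1e-9 | ok > 1 + 1e-9)) msg <- c(msg, "committee must lie in [0,1]")
  m <- object@suitableMask@values
  if (!identical(dim(v), dim(m))) msg <- c(msg, "mask must match committee dims")
  if (any((ok > 0.5) != (m[!is.na(v)] > 0)))
    msg <- c(msg, "suitableMask must equal committee > 0.5")
  if (length(msg)) msg else TRUE
})

#' A fitted species distribution model
#'
#' Wraps one base learner (GLM, MARS, BRT, RF or MAXENT) behind a common
#' predict contract: [predictSdm()] maps a covariate data.frame to occurrence
#' probabilities in \[0, 1\].
#'
#' @slot kind one of "GLM", "MARS", "BRT", "RF", "MAXENT".
#' @slot fit the underlying fitted object (learner specific).
#' @slot varNames covariate names the model was fitted on.
#' @slot settings list of learner settings used.
#' @export
setClass("SdmFit",
  representation(kind = "character", fit = "ANY", varNames = "character",
                 settings = "list"))

setValidity("SdmFit", function(object) {
  if (!object@kind %in% c("GLM", "MARS", "BRT", "RF", "MAXENT"))
    "kind must be one of GLM, MARS, BRT, RF, MAXENT" else TRUE
})

#' Thresholded habitat network
#'
#' Nodes are suitable habitat cells (capacity 1 by default); links connect
#' node pairs whose least-cost distance over the resistance surface is below
#' the threshold, searched up to a maximum cost.
#'
#' @slot nodes data.frame with columns id, x, y, capacity, cell.
#' @slot edges data.frame with columns from, to (node ids) and weight
#'   (the pairwise least-cost distance, used as link resistance).
#' @slot threshold cost-distance threshold that defined the links.
#' @slot maxCost truncation cap used during the least-cost searches.
#' @export
setClass("HabitatGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 threshold = "numeric", maxCost = "numeric"))

setValidity("HabitatGraph", function(object) {
  msg <- character(0)
  if (!all(c("id", "x", "y", "capacity") %in% names(object@nodes)))
    msg <- c(msg, "nodes need id, x, y, capacity columns")
  if (nrow(object@edges)) {
    if (!all(c("from", "to", "weight") %in% names(object@edges)))
      msg <- c(msg, "edges need from, to, weight columns")
    else {
      if (any(object@edges$weight <= 0)) msg <- c(msg, "link weights must be positive")
      if (any(object@edges$weight >= object@threshold))
        msg <- c(msg, "links must have cost distance below the threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), object@cellSize, object@origin[1], object@origin[2]))
  ok <- v[!is.na(v)]
  if (length(ok))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
                min(ok), max(ok), sum(is.na(v))))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d sites\n", object@kind, nrow(object@values)))
  if (nrow(object@values) <= 10) print(round(object@values, 4))
})

setMethod("show", "ResistanceSurface", function(object) {
  cat("ResistanceSurface\n  "); show(object@cost)
  cat(sprintf("  road cells: %d at cost %g\n",
              sum(object@roadMask@values > 0, na.rm = TRUE), object@roadCost))
})

setMethod("show", "EnsembleMap", function(object) {
  cat(sprintf("EnsembleMap: %d models, %d suitable cells\n", object@nModels,
              sum(object@suitableMask@values > 0, na.rm = TRUE)))
})

setMethod("show", "SdmFit", function(object) {
  cat(sprintf("SdmFit<%s> on %d covariates: %s\n", object@kind,
              length(object@varNames), paste(object@varNames, collapse = ", ")))
})

setMethod("show", "HabitatGraph", function(object) {
  cat(sprintf("HabitatGraph: %d nodes, %d links (threshold %g, max cost %g)\n",
              nrow(object@nodes), nrow(object@edges), object@threshold,
              object@maxCost))
})
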