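## Suitability -> movement cost transform and road barrier composition.

#' Default suitability-cost anchor table
#'
#' Six anchors with cost decreasing exponentially from the least to the most
#' suitable habitat: 100, 40, 15, 5, 2, 1 at suitabilities 0 to 1 in steps
#' of 0.2.
#'
#' @return two-column matrix (suitability, cost).
#' @examples
#' defaultAnchors()
#' @export
defaultAnchors <- function() {
  cbind(suitability = c(0, 0.2, 0.4, 0.6, 0.8, 1),
        cost = c(100, 40, 15, 5, 2, 1))
}

#' Convert habitat suitability to movement cost
#'
#' Exponentially decreasing cost anchored at six suitability levels:
#' cost 100 at suitability 0, 40 at 0.2, 15 at 0.4, 5 at 0.6, 2 at 0.8 and
#' 1 at 1. Between anchors the transform is log-linear (piecewise exponential),
#' exact at every anchor; `mode = "bin"` instead assigns each suitability to
#' the cost of the anchor interval it falls in (left-closed bins).
#'
#' @param s suitability scalar, vector or [RasterGrid-class], values in \[0, 1\].
#' @param anchors two-column matrix (suitability, cost), strictly increasing in
#'   suitability and nonincreasing in cost.
#' @param mode "interpolate" (default) or "bin".
#' @return costs with the shape of `s`.
#' @examples
#' suitabilityToCost(c(0, 0.2, 0.4, 0.6, 0.8, 1))
#' suitabilityToCost(0.5)   # sqrt(15 * 5)
#' @export
suitabilityToCost <- function(s, anchors = defaultAnchors(),
                              mode = c("interpolate", "bin")) {
  mode <- match.arg(mode)
  if (is(s, "RasterGrid")) {
    out <- s
    out@values[] <- suitabilityToCost(as.vector(s@values), anchors, mode)
    return(out)
  }
  x <- as.numeric(s)
  ok <- !is.na(x)
  if (any(x[ok] < -1e-12 | x[ok] > 1 + 1e-12))
    stop("suitability must lie within [0, 1]")
  x[ok] <- pmin(1, pmax(0, x[ok]))
  sa <- anchors[, 1]; ca <- anchors[, 2]
  if (is.unsorted(sa, strictly = TRUE)) stop("anchor suitabilities must increase")
  if (any(diff(ca) > 0)) stop("anchor costs must be nonincreasing")
  out <- rep(NA_real_, length(x))
  if (mode == "interpolate") {
    out[ok] <- exp(stats::approx(sa, log(ca), xout = x[ok], rule = 2)$y)
    ## exp(log(.)) perturbs the last bit; anchors themselves must map exactly
    hit <- match(x[ok], sa)
    out[ok][!is.na(hit)] <- ca[hit[!is.na(hit)]]
  } else {
    bin <- findInterval(x[ok], sa, rightmost.closed = TRUE)
    out[ok] <- ca[bin]
  }
  if (is.matrix(s)) dim(out) <- dim(s)
  out
}

#' Compose a resistance surface from suitability and roads
#'
#' Applies [suitabilityToCost()] cellwise and burns road cells in at
#' `roadCost` (the barrier cost for major roads). Nodata propagates from
#' either input.
#'
#' @param suitability a [RasterGrid-class] in \[0, 1\].
#' @param roads aligned binary [RasterGrid-class] (1 = road); `NULL` for a
#'   road-free surface.
#' @param roadCost cost on road cells; must be at least the maximum non-road
#'   cost (default 10000).
#' @param anchors,mode passed to [suitabilityToCost()].
#' @return a [ResistanceSurface-class].
#' @export
composeResistance <- function(suitability, roads = NULL, roadCost = 10000,
                              anchors = defaultAnchors(),
                              mode = c("interpolate", "bin")) {
  mode <- match.arg(mode)
  if (is.null(roads))
    roads <- rasterGrid(matrix(0, nrow(suitability@values), ncol(suitability@values)),
                        cellSize = suitability@cellSize, origin = suitability@origin)
  if (!sameGeometry(suitability, roads)) stop("suitability and roads are misaligned")
  if (roadCost < max(anchors[, 2])) stop("roadCost must be >= the maximum non-road cost")
  cost <- suitabilityToCost(suitability, anchors, mode)
  road <- !is.na(roads@values) & roads@values > 0
  v <- cost@values
  v[road & !is.na(v)] <- roadCost
  v[is.na(roads@values)] <- NA
  cost@values <- v
  new("ResistanceSurface", cost = cost, roadMask = roads, roadCost = roadCost,
      anchors = anchors)
}

#' @rdname composeResistance
#' @param x a ResistanceSurface.
#' @export
costRaster <- function(x) x@cost

#' @rdname composeResistance
#' @export
roadMask <- function(x) x@roadMask
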