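## Least-cost distances on the resistance raster treated as an 8-connected
## lattice. Edge cost between neighboring cells is the mean of the two cell
## resistances times the center-to-center distance (cell size, or cell size *
## sqrt(2) on diagonals) -- the PATHMATRIX/Circuitscape convention.

#' Build the lattice graph of a resistance surface
#'
#' @param resistance a [ResistanceSurface-class] or a cost [RasterGrid-class].
#' @return a `latticeGraph`: list with `cells` (valid cell indices), `edges`
#'   (from, to, weight in cost-distance units), the underlying igraph, and the
#'   grid geometry.
#' @export
buildLattice <- function(resistance) {
  r <- if (is(resistance, "ResistanceSurface")) resistance@cost else resistance
  v <- r@values
  nr <- nrow(v); nc <- ncol(v); cs <- r@cellSize
  valid <- !is.na(v)
  if (!any(valid)) stop("resistance raster has no valid cells")
  vid <- matrix(NA_integer_, nr, nc)
  vid[valid] <- seq_len(sum(valid))

  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))   # E, S, SE, NE
  edges <- vector("list", length(offs))
  rows <- row(v); cols <- col(v)
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    r2 <- rows + dr; c2 <- cols + dc
    ok <- valid & r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    i <- which(ok)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    both <- valid[j]
    i <- i[both]; j <- j[both]
    dist <- cs * if (dr != 0 && dc != 0) sqrt(2) else 1
    edges[[k]] <- data.frame(from = vid[i], to = vid[j],
                             weight = (v[i] + v[j]) / 2 * dist,
                             cellFrom = i, cellTo = j)
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = sum(valid), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                           weight = edges$weight)
  structure(list(cells = which(valid), edges = edges, graph = g,
                 nrow = nr, ncol = nc, cellSize = cs, origin = r@origin,
                 vid = vid),
            class = "latticeGraph")
}

## map site coordinates to lattice vertex ids, snapping to the nearest valid
## cell center when a site falls on nodata or outside the grid
snapSites <- function(lattice, sites) {
  rg <- rasterGrid(matrix(0, lattice$nrow, lattice$ncol),
                   cellSize = lattice$cellSize, origin = lattice$origin)
  cells <- cellFromXY(rg, sites$x, sites$y)
  verts <- integer(nrow(sites)); snap <- numeric(nrow(sites))
  cc <- cellCenters(rg, lattice$cells)
  for (i in seq_len(nrow(sites))) {
    if (!is.na(cells[i]) && !is.na(lattice$vid[cells[i]])) {
      verts[i] <- lattice$vid[cells[i]]
      snap[i] <- 0
    } else {
      d2 <- (cc$x - sites$x[i])^2 + (cc$y - sites$y[i])^2
      k <- which.min(d2)
      verts[i] <- lattice$vid[lattice$cells[k]]
      snap[i] <- sqrt(d2[k])
    }
  }
  if (any(snap > 0))
    message(sum(snap > 0), " site(s) snapped to the nearest valid cell (max ",
            format(max(snap)), " map units)")
  data.frame(id = sites$id, vertex = verts, snapDist = snap)
}

#' Pairwise least-cost distances between sites
#'
#' Exact Dijkstra shortest-path cost over the lattice for every site pair.
#' Pairs in different connected components get `Inf` with a warning.
#'
#' @param lattice a `latticeGraph` from [buildLattice()].
#' @param sites point set data.frame (id, x, y).
#' @return a [DistanceMatrix-class] of kind "LCD".
#' @export
lcdMatrix <- function(lattice, sites) {
  sn <- snapSites(lattice, sites)
  D <- igraph::distances(lattice$graph, v = sn$vertex, to = sn$vertex,
                         algorithm = "dijkstra")
  dimnames(D) <- list(sites$id, sites$id)
  ## Dijkstra sums edge weights in a direction-dependent order, so D can be
  ## asymmetric at the last bit; both directions are valid, keep the smaller
  D <- pmin(D, t(D))
  ## sites snapped to the same cell are at distance 0; enforce exact zeros
  diag(D) <- 0
  if (any(is.infinite(D)))
    warning("some site pairs are in disconnected components; Inf recorded")
  distanceMatrix(D, "LCD", labels = sites$id)
}

#' One least-cost path between two sites
#'
#' Backtracks over the exact Dijkstra distance field; at ties the neighbor
#' with the smallest cell index is taken, so the path is deterministic.
#'
#' @param lattice a `latticeGraph`.
#' @param a,b single-row point sets or (x, y) vectors.
#' @return data.frame of ordered path cells (cell, x, y) with attribute
#'   `cost`, the accumulated cost distance.
#' @export
leastCostPath <- function(lattice, a, b) {
  toPs <- function(p, id) if (is.data.frame(p)) p else pointSet(p[1], p[2], id = id)
  sa <- snapSites(lattice, toPs(a, "a"))$vertex
  sb <- snapSites(lattice, toPs(b, "b"))$vertex
  d <- as.numeric(igraph::distances(lattice$graph, v = sa, algorithm = "dijkstra"))
  if (is.infinite(d[sb])) stop("sites are in disconnected components")
  ## neighbor lists keyed by vertex
  e <- lattice$edges
  adj <- rbind(data.frame(v = e$from, u = e$to, w = e$weight),
               data.frame(v = e$to, u = e$from, w = e$weight))
  path <- sb
  tol <- 1e-9 * max(1, d[sb])
  while (path[1] != sa) {
    cur <- path[1]
    nb <- adj[adj$v == cur, ]
    pred <- nb$u[abs(d[nb$u] + nb$w - d[cur]) <= tol]
    if (!length(pred)) stop("path reconstruction failed")  # should not happen
    pick <- pred[which.min(lattice$cells[pred])]
    path <- c(pick, path)
  }
  cells <- lattice$cells[path]
  rg <- rasterGrid(matrix(0, lattice$nrow, lattice$ncol),
                   cellSize = lattice$cellSize, origin = lattice$origin)
  cc <- cellCenters(rg, cells)
  structure(cc, cost = d[sb])
}
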