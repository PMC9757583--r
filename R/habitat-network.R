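## Thresholded habitat networks and current-flow betweenness centrality.
## Nodes are suitable habitat cells; links join pairs whose least-cost
## distance over the resistance surface falls below a threshold; link
## resistance equals the least-cost distance. CFBC sums the per-pair current
## throughflow of pairThroughflow() over all unordered source-target pairs,
## with endpoint throughflow 1 (so every node of a component of size >= 2
## scores at least 1) and pair weight (cap_s * cap_t)^beta.

#' Extract habitat nodes from an ensemble map
#'
#' One node per suitable cell (committee value strictly above 0.5), placed at
#' the cell center with capacity 1. Cells that are nodata on the resistance
#' surface are dropped.
#'
#' @param ensemble an [EnsembleMap-class], or a binary suitable-mask
#'   [RasterGrid-class].
#' @param resistance optional [ResistanceSurface-class] used to drop nodata
#'   cells.
#' @return data.frame of nodes: id, x, y, capacity, cell.
#' @export
extractHabitatNodes <- function(ensemble, resistance = NULL) {
  mask <- if (is(ensemble, "EnsembleMap")) ensemble@suitableMask else ensemble
  suitable <- !is.na(mask@values) & mask@values > 0
  if (!is.null(resistance))
    suitable <- suitable & !is.na(resistance@cost@values)
  cells <- which(suitable)
  if (!length(cells)) stop("no suitable habitat cells")
  cc <- cellCenters(mask, cells)
  data.frame(id = paste0("n", seq_along(cells)), x = cc$x, y = cc$y,
             capacity = 1, cell = cells, stringsAsFactors = FALSE)
}

## pairwise least-cost distances between habitat nodes over the lattice,
## truncated at maxCost (distances beyond the cap become Inf)
nodeLcd <- function(nodes, resistance, maxCost = 250000) {
  lat <- buildLattice(resistance)
  verts <- lat$vid[nodes$cell]
  D <- igraph::distances(lat$graph, v = verts, to = verts,
                         algorithm = "dijkstra")
  D[D > maxCost] <- Inf
  dimnames(D) <- list(nodes$id, nodes$id)
  D
}

#' Build the thresholded habitat graph
#'
#' Links connect node pairs with least-cost distance strictly below
#' `threshold`; searches are truncated at `maxCost`. A precomputed node
#' distance matrix can be passed through `lcd` when building several
#' thresholds from one surface.
#'
#' @param nodes node data.frame from [extractHabitatNodes()].
#' @param resistance a [ResistanceSurface-class].
#' @param threshold cost-distance threshold (must not exceed `maxCost`).
#' @param maxCost truncation cap for the least-cost searches (default 250000).
#' @param lcd optional precomputed node-pair LCD matrix.
#' @return a [HabitatGraph-class].
#' @export
buildThresholdGraph <- function(nodes, resistance, threshold,
                                maxCost = 250000, lcd = NULL) {
  if (threshold > maxCost) stop("threshold must not exceed maxCost")
  if (is.null(lcd)) lcd <- nodeLcd(nodes, resistance, maxCost)
  n <- nrow(nodes)
  sel <- which(upper.tri(lcd) & is.finite(lcd) & lcd < threshold, arr.ind = TRUE)
  edges <- data.frame(from = sel[, 1], to = sel[, 2],
                      weight = lcd[sel])
  new("HabitatGraph", nodes = nodes, edges = edges, threshold = threshold,
      maxCost = maxCost)
}

#' Current-flow betweenness centrality of habitat nodes
#'
#' Treats each link as a resistor with resistance equal to its cost distance
#' and sums per-node current throughflow over all unordered source-target
#' pairs within each connected component, weighting pair (s, t) by
#' `(capacity_s * capacity_t)^beta`; `beta = 0` gives unit amperage for every
#' pair. Endpoints count 1, so nodes in components of size >= 2 have CFBC
#' >= 1 (for beta = 0); isolated nodes score 0.
#'
#' @param graph a [HabitatGraph-class].
#' @param beta capacity exponent (default 0).
#' @return data.frame (class `centralityResult`): node, cfbc; attributes
#'   `beta` and `threshold`.
#' @export
cfbc <- function(graph, beta = 0) {
  n <- nrow(graph@nodes)
  if (!n) stop("graph has no nodes")
  e <- graph@edges
  out <- numeric(n)
  cw <- graph@nodes$capacity^beta
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$from, e$to))
  comp <- igraph::components(g)$membership
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    nc <- length(idx)
    if (nc < 2) next
    sub <- e[comp[e$from] == cid, , drop = FALSE]
    loc <- match(c(sub$from, sub$to), idx)
    lf <- loc[seq_len(nrow(sub))]; lt <- loc[-seq_len(nrow(sub))]
    cond <- 1 / sub$weight
    A <- Matrix::sparseMatrix(i = c(lf, lt), j = c(lt, lf),
                              x = c(cond, cond), dims = c(nc, nc))
    L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
    ## grounded inverse at node 1, extended by a zero row/column
    M <- matrix(0, nc, nc)
    if (nc > 1)
      M[-1, -1] <- as.matrix(Matrix::solve(L[-1, -1, drop = FALSE],
                                           Matrix::Diagonal(nc - 1)))
    u <- cw[idx]
    U <- sum(u)
    main <- numeric(nc); corr <- numeric(nc)
    for (k in seq_len(nrow(sub))) {
      i <- lf[k]; j <- lt[k]; Ce <- cond[k]
      F <- M[i, ] - M[j, ]
      o <- order(F)
      Fo <- F[o]; uo <- u[o]
      cum <- cumsum(uo)
      S <- sum(uo * Fo * (2 * cum - uo - U))   # weighted sum of pair gaps
      main[i] <- main[i] + Ce * S / 2
      main[j] <- main[j] + Ce * S / 2
      corr[i] <- corr[i] + Ce * u[i] * sum(u * abs(F[i] - F)) / 2
      corr[j] <- corr[j] + Ce * u[j] * sum(u * abs(F[j] - F)) / 2
    }
    out[idx] <- main - corr + u * (U - u)
  }
  structure(data.frame(node = graph@nodes$id, cfbc = out,
                       stringsAsFactors = FALSE),
            beta = beta, threshold = graph@threshold,
            class = c("centralityResult", "data.frame"))
}

#' Assign each population to its nearest habitat node
#'
#' Euclidean nearest; at exact ties the lowest node index wins, so the
#' assignment is deterministic.
#'
#' @param populations point set (id, x, y).
#' @param graph a [HabitatGraph-class].
#' @return data.frame: id, node (node id), nodeIndex, dist.
#' @export
assignPopulationNodes <- function(populations, graph) {
  nd <- graph@nodes
  if (!nrow(nd)) stop("graph has no nodes")
  res <- lapply(seq_len(nrow(populations)), function(i) {
    d2 <- (nd$x - populations$x[i])^2 + (nd$y - populations$y[i])^2
    k <- which.min(d2)    # first minimum = lowest index
    data.frame(id = populations$id[i], node = nd$id[k], nodeIndex = k,
               dist = sqrt(d2[k]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Top-centrality priority nodes
#'
#' Nodes with CFBC at or above the (1 - quantile) percentile, ranked
#' descending; ties at the cutoff are included.
#'
#' @param result a `centralityResult` from [cfbc()].
#' @param quantile upper tail fraction in (0, 1) (default 0.05, the top 5%).
#' @return the selected rows of `result`, ordered by decreasing CFBC.
#' @export
prioritizeNodes <- function(result, quantile = 0.05) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  cut <- stats::quantile(result$cfbc, probs = 1 - quantile, names = FALSE)
  sel <- result[result$cfbc >= cut, , drop = FALSE]
  sel[order(-sel$cfbc), , drop = FALSE]
}
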