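## Circuit-theory primitives: resistor networks from weighted graphs,
## effective resistance (resistance distance) via grounded Laplacian solves,
## and per-pair current throughflow for current-flow betweenness.

#' Build a resistor network
#'
#' Edges carry resistances; the network stores the conductance Laplacian and
#' its connected-component structure. Parallel edges combine in parallel
#' (conductances add).
#'
#' @param n number of nodes.
#' @param edges data.frame with columns from, to and resistance (> 0).
#' @param labels optional node labels.
#' @return a `resistorNetwork` list: n, edges, conductance Laplacian `L`
#'   (dgCMatrix), component membership `comp`, labels.
#' @export
resistorNetwork <- function(n, edges, labels = NULL) {
  if (nrow(edges) && any(edges$resistance <= 0))
    stop("edge resistances must be strictly positive")
  cond <- if (nrow(edges)) 1 / edges$resistance else numeric(0)
  A <- Matrix::sparseMatrix(i = c(edges$from, edges$to),
                            j = c(edges$to, edges$from),
                            x = c(cond, cond), dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  comp <- igraph::components(g)$membership
  structure(list(n = n, edges = edges, L = L, comp = comp,
                 labels = labels %||% as.character(seq_len(n))),
            class = "resistorNetwork")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## grounded potentials: solve L[-g,-g] x = rhs[-g], zero at the ground node
groundedSolve <- function(net, ground, rhs) {
  idx <- which(net$comp == net$comp[ground])
  keep <- setdiff(idx, ground)
  x <- numeric(net$n)
  if (length(keep)) {
    sol <- Matrix::solve(net$L[keep, keep, drop = FALSE], rhs[keep])
    x[keep] <- as.numeric(sol)
  }
  x
}

#' Effective resistance between two nodes
#'
#' The circuit-theory resistance distance: potential difference per unit
#' current injected at `a` and extracted at `b`, obtained from the grounded
#' Laplacian system.
#'
#' @param net a `resistorNetwork`.
#' @param a,b node indices.
#' @return scalar effective resistance.
#' @export
effectiveResistance <- function(net, a, b) {
  if (a == b) return(0)
  if (net$comp[a] != net$comp[b])
    stop("nodes are in different connected components")
  rhs <- numeric(net$n); rhs[a] <- 1
  x <- groundedSolve(net, ground = b, rhs)
  x[a]
}

#' Pairwise resistance distances between sites on a resistance raster
#'
#' The lattice of [buildLattice()] is read as a resistor network whose edge
#' resistances equal the lattice edge costs (so least-cost and circuit
#' distances share one conductance model), and effective resistance is
#' computed for every site pair from one sparse factorization per component.
#'
#' @param resistance a [ResistanceSurface-class] or cost [RasterGrid-class].
#' @param sites point set data.frame (id, x, y).
#' @return a [DistanceMatrix-class] of kind "IBR".
#' @export
ibrMatrix <- function(resistance, sites) {
  lat <- buildLattice(resistance)
  net <- resistorNetwork(igraph::vcount(lat$graph),
                         data.frame(from = lat$edges$from, to = lat$edges$to,
                                    resistance = lat$edges$weight))
  sn <- snapSites(lat, sites)
  K <- nrow(sn)
  D <- matrix(Inf, K, K); diag(D) <- 0
  for (cmp in unique(net$comp[sn$vertex])) {
    sel <- which(net$comp[sn$vertex] == cmp)
    if (length(sel) < 2) next
    verts <- sn$vertex[sel]
    ground <- verts[1]
    idx <- which(net$comp == cmp)
    keep <- setdiff(idx, ground)
    pos <- match(verts, keep)            # NA for the ground site
    X <- if (length(keep) && any(!is.na(pos))) {
      Lk <- net$L[keep, keep, drop = FALSE]
      rhs <- Matrix::sparseMatrix(i = as.integer(stats::na.omit(pos)),
                                  j = which(!is.na(pos)),
                                  x = 1, dims = c(length(keep), length(verts)))
      as.matrix(Matrix::solve(Lk, rhs))
    } else matrix(0, length(keep), length(verts))
    G <- matrix(0, length(verts), length(verts))   # grounded inverse entries
    for (ai in seq_along(verts)) for (bi in seq_along(verts)) {
      G[ai, bi] <- if (is.na(pos[ai]) || is.na(pos[bi])) 0 else X[pos[ai], bi]
    }
    for (ai in seq_along(verts)) for (bi in seq_along(verts)) {
      if (ai == bi) next
      D[sel[ai], sel[bi]] <- G[ai, ai] + G[bi, bi] - 2 * G[ai, bi]
    }
  }
  if (any(is.infinite(D)))
    warning("some site pairs are in disconnected components; Inf recorded")
  ## symmetrize away solver round-off
  D <- (D + t(D)) / 2
  distanceMatrix(D, "IBR", labels = sites$id)
}

#' Per-node current throughflow for one source-target pair
#'
#' Unit current is injected at `s` and extracted at `t`; interior nodes get
#' half the sum of absolute edge currents incident to them, and the endpoints
#' get 1 (the Newman convention). Nodes outside the pair's component get 0.
#'
#' @param net a `resistorNetwork`.
#' @param s,t distinct node indices in the same component.
#' @return numeric vector of length `net$n`.
#' @export
pairThroughflow <- function(net, s, t) {
  if (s == t) stop("s and t must differ")
  if (net$comp[s] != net$comp[t]) stop("s and t are in different components")
  rhs <- numeric(net$n); rhs[s] <- 1
  v <- groundedSolve(net, ground = t, rhs)
  e <- net$edges
  Iedge <- (v[e$from] - v[e$to]) / e$resistance
  Tv <- numeric(net$n)
  agg <- rowsum(c(abs(Iedge), abs(Iedge)), c(e$from, e$to))
  Tv[as.integer(rownames(agg))] <- agg[, 1] / 2
  Tv[c(s, t)] <- 1
  Tv
}
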