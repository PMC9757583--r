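# shared builders for small deterministic test fixtures

# uniform-value raster
uniformRaster <- function(value, nrow = 3, ncol = 3, cellSize = 1) {
  rasterGrid(matrix(value, nrow, ncol), cellSize = cellSize)
}

# random suitability raster in (0, 1)
randomSuitability <- function(nrow, ncol, seed, cellSize = 1) {
  set.seed(seed)
  rasterGrid(matrix(runif(nrow * ncol, 0.01, 0.99), nrow, ncol),
             cellSize = cellSize)
}

# independent edge construction for a resistance raster: 8-connected lattice,
# edge weight = mean of endpoint resistances x cell size (x sqrt(2) diagonal)
bruteForceEdges <- function(cost, cellSize) {
  nr <- nrow(cost); nc <- ncol(cost)
  idx <- function(r, c) (c - 1L) * nr + r
  out <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(cost[r, c])) next
    for (dd in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(cost[r2, c2])) next
      w <- (cost[r, c] + cost[r2, c2]) / 2 * cellSize *
        if (all(dd != 0)) sqrt(2) else 1
      out[[length(out) + 1L]] <- c(idx(r, c), idx(r2, c2), w)
    }
  }
  m <- do.call(rbind, out)
  data.frame(from = m[, 1], to = m[, 2], w = m[, 3])
}

# all-pairs shortest path by Floyd-Warshall on a dense weight matrix
floydWarshall <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$w[i]
    D[a, b] <- min(D[a, b], w); D[b, a] <- min(D[b, a], w)
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# dense graph Laplacian from an edge list with resistances
denseLaplacian <- function(n, edges) {
  L <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; g <- 1 / edges$resistance[i]
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
  }
  L
}

# reference current-flow betweenness (unit injections over all pairs in a
# connected graph; endpoint convention T_s = T_t = 1)
referenceCfbc <- function(n, edges) {
  Linv <- MASS::ginv(denseLaplacian(n, edges))
  tot <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    v <- Linv[, s] - Linv[, t]
    I <- (v[edges$from] - v[edges$to]) / edges$resistance
    Tv <- numeric(n)
    for (i in seq_len(nrow(edges))) {
      Tv[edges$from[i]] <- Tv[edges$from[i]] + abs(I[i])
      Tv[edges$to[i]] <- Tv[edges$to[i]] + abs(I[i])
    }
    Tv <- Tv / 2
    Tv[c(s, t)] <- 1
    tot <- tot + Tv
  }
  tot
}

# random connected resistor graph
randomResistorGraph <- function(n, seed, extraEdges = n) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {                       # random spanning tree
    from <- c(from, sample(v - 1, 1)); to <- c(to, v)
  }
  for (k in seq_len(extraEdges)) {
    ab <- sample(n, 2)
    if (any(from == ab[1] & to == ab[2]) || any(from == ab[2] & to == ab[1]))
      next
    from <- c(from, ab[1]); to <- c(to, ab[2])
  }
  data.frame(from = from, to = to,
             resistance = runif(length(from), 0.5, 4))
}

# tiny world + two fitted models, reused by ensemble-level tests
smallSdmSetup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- simulateWorld(shape = c(25, 25), nOcc = 60, nRoads = 2, seed = 42)
    bg <- sampleBackground(w$envLayers, 150, seed = 43)
    pts <- rbind(w$occurrences[c("x", "y", "label")],
                 data.frame(x = bg$x, y = bg$y, label = 0L))
    fits <- lapply(c("GLM", "MARS"), function(k)
      fitSdm(k, pts[pts$label == 1, ], pts[pts$label == 0, ],
             w$envLayers, seed = 44))
    cache <<- list(world = w, bg = bg, pts = pts, fits = fits)
    cache
  }
})
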