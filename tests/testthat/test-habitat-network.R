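# build a HabitatGraph directly from an edge list, bypassing the raster layer
graphFromEdges <- function(n, edges, threshold = NULL) {
  if (is.null(threshold)) threshold <- max(edges$resistance) * 2 + 1
  set.seed(99)
  nodes <- data.frame(id = paste0("n", seq_len(n)),
                      x = runif(n, 0, 100), y = runif(n, 0, 100),
                      capacity = 1, cell = seq_len(n),
                      stringsAsFactors = FALSE)
  new("HabitatGraph", nodes = nodes,
      edges = data.frame(from = edges$from, to = edges$to,
                         weight = edges$resistance),
      threshold = threshold, maxCost = threshold)
}

test_that("habitat nodes are the suitable, data-valued cells", {
  mask <- rasterGrid(matrix(c(1, 0, NA, 1, 1, 0, 0, 0, 1), 3, 3),
                     cellSize = 10)
  nodes <- extractHabitatNodes(mask)
  expect_identical(nodes$cell, c(1L, 4L, 5L, 9L))
  cc <- cellCenters(mask, nodes$cell)
  expect_equal(nodes$x, cc$x)
  expect_equal(nodes$y, cc$y)
  expect_true(all(nodes$capacity == 1))
  expect_identical(anyDuplicated(nodes$id), 0L)
  ## resistance nodata drops nodes
  cost <- rasterGrid(matrix(1, 3, 3), cellSize = 10)
  cost@values[1] <- NA
  rs <- new("ResistanceSurface", cost = cost,
            roadMask = rasterGrid(matrix(0, 3, 3), cellSize = 10),
            roadCost = 10000, anchors = defaultAnchors())
  nodes2 <- extractHabitatNodes(mask, rs)
  expect_identical(nodes2$cell, c(4L, 5L, 9L))
  expect_error(extractHabitatNodes(rasterGrid(matrix(0, 2, 2))))
})

test_that("threshold links follow the least-cost distances exactly", {
  set.seed(12)
  suit <- rasterGrid(matrix(runif(49, 0.2, 1), 7, 7), cellSize = 10)
  mask <- rasterGrid(matrix(as.numeric(runif(49) < 0.3), 7, 7), cellSize = 10)
  if (sum(gridValues(mask)) < 4) mask@values[c(1, 10, 25, 40)] <- 1
  rs <- composeResistance(suit, roads = rasterGrid(matrix(0, 7, 7), cellSize = 10))
  nodes <- extractHabitatNodes(mask, rs)
  lcd <- connectgene:::nodeLcd(nodes, rs, maxCost = 1e9)
  ## oracle distances via Floyd-Warshall on brute-force lattice edges
  bf <- bruteForceEdges(gridValues(rs@cost), 10)
  D <- floydWarshall(49, bf)[nodes$cell, nodes$cell]
  expect_equal(unname(lcd), D, tolerance = 1e-9)
  thr <- stats::median(lcd[upper.tri(lcd)])
  g <- buildThresholdGraph(nodes, rs, thr, maxCost = 1e9, lcd = lcd)
  want <- which(upper.tri(lcd) & lcd < thr, arr.ind = TRUE)
  expect_identical(nrow(g@edges), nrow(want))
  expect_true(all(g@edges$weight < thr))
  for (k in seq_len(nrow(g@edges)))
    expect_equal(g@edges$weight[k], lcd[g@edges$from[k], g@edges$to[k]])
  ## edges grow monotonically with the threshold
  gBig <- buildThresholdGraph(nodes, rs, max(lcd) + 1, maxCost = 1e9, lcd = lcd)
  expect_gte(nrow(gBig@edges), nrow(g@edges))
  expect_true(all(paste(g@edges$from, g@edges$to) %in%
                  paste(gBig@edges$from, gBig@edges$to)))
  ## maxCost truncation turns long pairs into non-links
  lcdCap <- connectgene:::nodeLcd(nodes, rs, maxCost = thr)
  expect_true(all(is.infinite(lcdCap[is.finite(lcd) & lcd > thr])))
  expect_error(buildThresholdGraph(nodes, rs, threshold = 10, maxCost = 5))
})

test_that("cfbc reproduces the path-graph closed form", {
  edges <- data.frame(from = c(1, 2), to = c(2, 3), resistance = c(1, 2))
  g <- graphFromEdges(3, edges)
  got <- cfbc(g)
  expect_s3_class(got, "centralityResult")
  expect_equal(got$cfbc, c(2, 3, 2), tolerance = 1e-10)
  expect_identical(got$node, g@nodes$id)
  expect_identical(attr(got, "beta"), 0)
})

test_that("cfbc matches the dense pair-by-pair reference on random graphs", {
  for (s in 1:10) {
    n <- sample(6:25, 1)
    edges <- randomResistorGraph(n, seed = 100 + s)
    g <- graphFromEdges(n, edges)
    expect_equal(cfbc(g)$cfbc, referenceCfbc(n, edges), tolerance = 1e-8)
  }
})

test_that("cfbc treats components independently and scores isolates zero", {
  ## two disjoint paths (1-2-3) and (4-5), plus isolated node 6
  edges <- data.frame(from = c(1, 2, 4), to = c(2, 3, 5),
                      resistance = c(1, 1, 3))
  g <- graphFromEdges(6, edges)
  got <- cfbc(g)$cfbc
  expect_equal(got[1:3], c(2, 3, 2), tolerance = 1e-10)
  expect_equal(got[4:5], c(1, 1), tolerance = 1e-10)
  expect_identical(got[6], 0)
  ## each component equals its standalone value
  alone <- cfbc(graphFromEdges(3, edges[1:2, ]))$cfbc
  expect_equal(got[1:3], alone, tolerance = 1e-10)
})

test_that("capacity weighting with beta follows the pair-weight definition", {
  edges <- data.frame(from = c(1, 2), to = c(2, 3), resistance = c(1, 1))
  g <- graphFromEdges(3, edges)
  g@nodes$capacity <- c(2, 1, 4)
  ## beta = 0 ignores capacities entirely
  expect_equal(cfbc(g, beta = 0)$cfbc, c(2, 3, 2), tolerance = 1e-10)
  ## beta = 1: pair (s,t) injects cap_s * cap_t amperes; on P3 the midpoint
  ## carries pair (1,3) fully plus its own endpoint pairs
  got <- cfbc(g, beta = 1)$cfbc
  w12 <- 2 * 1; w13 <- 2 * 4; w23 <- 1 * 4
  expect_equal(got[2], w13 + w12 + w23, tolerance = 1e-10)
  expect_equal(got[1], w12 + w13, tolerance = 1e-10)
  expect_equal(got[3], w13 + w23, tolerance = 1e-10)
})

test_that("populations snap to the euclidean-nearest node deterministically", {
  edges <- data.frame(from = 1, to = 2, resistance = 1)
  g <- graphFromEdges(4, edges)
  g@nodes$x <- c(0, 10, 20, 30); g@nodes$y <- rep(0, 4)
  pops <- pointSet(c(1, 24, 15), c(0, 0, 0), id = c("p1", "p2", "p3"))
  asg <- assignPopulationNodes(pops, g)
  expect_identical(asg$nodeIndex, c(1L, 3L, 2L))
  expect_equal(asg$dist, c(1, 4, 5))
  ## exact tie (15 is equidistant from nodes 2 and 3): lowest index wins
  expect_identical(asg$node[3], "n2")
  ## brute-force cross-check on random points
  set.seed(7)
  rp <- pointSet(runif(20, 0, 30), runif(20, -5, 5),
                 id = paste0("q", 1:20))
  asg2 <- assignPopulationNodes(rp, g)
  for (i in 1:20) {
    d <- sqrt((g@nodes$x - rp$x[i])^2 + (g@nodes$y - rp$y[i])^2)
    expect_identical(asg2$nodeIndex[i], which.min(d))
    expect_equal(asg2$dist[i], min(d))
  }
})

test_that("priority selection keeps the top tail including cutoff ties", {
  res <- structure(data.frame(node = paste0("n", 1:100),
                              cfbc = as.numeric(1:100),
                              stringsAsFactors = FALSE),
                   beta = 0, threshold = 5000,
                   class = c("centralityResult", "data.frame"))
  top <- prioritizeNodes(res, 0.05)
  ## sort-and-slice oracle: everything at or above the 95th percentile
  cut <- quantile(1:100, 0.95, names = FALSE)
  expect_identical(sort(top$cfbc), sort(res$cfbc[res$cfbc >= cut]))
  expect_identical(top$cfbc, sort(top$cfbc, decreasing = TRUE))
  ## ties at the cutoff are all included
  tied <- res; tied$cfbc <- c(rep(1, 90), rep(2, 10))
  expect_identical(nrow(prioritizeNodes(tied, 0.05)), 10L)
  expect_error(prioritizeNodes(res, 0))
  expect_error(prioritizeNodes(res, 1))
})
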