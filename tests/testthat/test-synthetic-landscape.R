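test_that("environmental layers are standardized, autocorrelated, deterministic", {
  a <- generateEnvLayers(c(30, 30), 2, corrLength = 5, seed = 5)
  b <- generateEnvLayers(c(30, 30), 2, corrLength = 5, seed = 5)
  expect_identical(lapply(a, gridValues), lapply(b, gridValues))
  v <- gridValues(a[[1]])
  expect_equal(mean(v), 0, tolerance = 1e-8)
  expect_equal(sd(v), 1, tolerance = 1e-8)
  ## smoothing induces positive lag-1 autocorrelation along rows
  expect_gt(cor(as.vector(v[, -1]), as.vector(v[, -30])), 0.5)
})

test_that("true suitability is the logistic of the linear combination", {
  l1 <- rasterGrid(matrix(c(-1, 0, 1, 2), 2, 2))
  l2 <- rasterGrid(matrix(c(2, 1, 0, -1), 2, 2))
  s <- makeTrueSuitability(list(l1, l2), c(1.5, -0.5), intercept = 0.2)
  expect_equal(gridValues(s),
               plogis(0.2 + 1.5 * gridValues(l1) - 0.5 * gridValues(l2)))
  expect_error(makeTrueSuitability(list(l1, l2), 1))
})

test_that("occurrence sampling honours support, count and weighting", {
  empty <- sampleOccurrences(uniformRaster(0.5), 0)
  expect_identical(nrow(empty), 0L)
  ## nonzero suitability on exactly n cells -> those cells
  v <- matrix(0, 3, 3); v[c(2, 5, 9)] <- 0.7
  r <- rasterGrid(v)
  occ <- sampleOccurrences(r, 3, seed = 1)
  expect_setequal(cellFromXY(r, occ$x, occ$y), c(2L, 5L, 9L))
  expect_error(sampleOccurrences(r, 4))
  ## first draw follows the suitability weights (0.8 vs 0.2 = 4:1)
  two <- rasterGrid(matrix(c(0.8, 0.2), 1, 2))
  first <- vapply(1:2000, function(s) {
    o <- sampleOccurrences(two, 1, seed = s)
    cellFromXY(two, o$x, o$y)
  }, integer(1))
  k <- sum(first == 1)
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.8)
  expect_true(k >= bounds[1] && k <= bounds[2])
})

test_that("roads are binary, deterministic, contiguous transects", {
  none <- generateRoads(c(10, 10), 0, seed = 1)
  expect_true(all(gridValues(none) == 0))
  ## one horizontal transect crosses all columns
  horiz <- connectgene:::rasterizeLine(5, 1, 5, 10)
  expect_identical(nrow(horiz), 10L)
  expect_true(all(horiz[, 1] == 5))
  for (style in c("span", "radial", "ring")) {
    a <- generateRoads(c(20, 20), 3, seed = 9, style = style)
    b <- generateRoads(c(20, 20), 3, seed = 9, style = style)
    expect_identical(gridValues(a), gridValues(b))
    expect_true(all(gridValues(a) %in% c(0, 1)))
    expect_gt(sum(gridValues(a)), 0)
  }
})

test_that("diagonal transects have no diagonal gaps", {
  cells <- connectgene:::rasterizeLine(1, 1, 8, 10)
  m <- matrix(0, 8, 10); m[cells] <- 1
  ## consecutive path cells always share a side (4-connectivity)
  for (i in seq_len(nrow(cells) - 1)) {
    d <- abs(cells[i + 1, ] - cells[i, ])
    expect_lte(sum(d), 1)
  }
})

test_that("ring roads avoid and nontrivially partition the supplied sites", {
  sites <- cbind(c(5, 5, 35, 35, 20), c(5, 35, 5, 35, 20))
  r <- generateRoads(c(40, 40), 4, seed = 3, style = "ring", avoid = sites)
  m <- gridValues(r)
  expect_true(all(m[sites] == 0))
  expect_gt(sum(m), 0)
})

test_that("genetic simulation follows the documented linear models", {
  D <- distanceMatrix(matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
                             dimnames = list(letters[1:3], letters[1:3])),
                      "LCD")
  flat <- simulateGeneticData(D, a = 0.07, b = 0, sigma = 0,
                              centrality = c(1, 1, 1), d = 0, tau = 0)
  off <- dmValues(flat$fst)[upper.tri(diag(3))]
  expect_true(all(off == 0.07))
  ## sigma = 0, b > 0: FST is affine in D, so Mantel r = 1 exactly
  lin <- simulateGeneticData(D, a = 0.01, b = 0.01, sigma = 0,
                             centrality = c(1, 2, 3), d = 0.02, tau = 0)
  expect_equal(cor(connectgene:::upperVec(dmValues(lin$fst)),
                   connectgene:::upperVec(dmValues(D))), 1)
  f <- dmValues(lin$fst)
  expect_identical(f, t(f))
  expect_true(all(diag(f) == 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(simulateGeneticData(D, centrality = c(1, 0, 2), d = 0.1))
  ## reproducible by seed
  g1 <- simulateGeneticData(D, sigma = 0.05, centrality = 1:3, seed = 4)
  g2 <- simulateGeneticData(D, sigma = 0.05, centrality = 1:3, seed = 4)
  expect_identical(g1, g2)
})

test_that("simulated worlds satisfy their invariants and are bit-identical", {
  w1 <- simulateWorld(shape = c(30, 30), nOcc = 60, nRoads = 2, seed = 3)
  w2 <- simulateWorld(shape = c(30, 30), nOcc = 60, nRoads = 2, seed = 3)
  expect_identical(w1, w2)
  w3 <- simulateWorld(shape = c(30, 30), nOcc = 60, nRoads = 2, seed = 4)
  expect_false(identical(w1$fst, w3$fst))
  s <- w1$trueSuitability
  expect_true(all(gridValues(s) >= 0 & gridValues(s) <= 1))
  for (l in w1$envLayers)
    expect_true(connectgene:::sameGeometry(l, s))
  expect_true(connectgene:::sameGeometry(w1$roads, s))
  ## occurrences sit on cells with positive suitability
  occSuit <- extractValues(list(s = s), w1$occurrences)$s
  expect_true(all(occSuit > 0))
  ## populations sit on suitable habitat
  popSuit <- extractValues(list(s = s), w1$populations)$s
  expect_true(all(popSuit > 0.5))
  f <- dmValues(w1$fst)
  expect_identical(f, t(f))
  expect_true(all(diag(f) == 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_identical(length(w1$he), nrow(w1$populations))
  expect_true(all(w1$he >= 0 & w1$he <= 1))
})

test_that("ring-style worlds keep populations off roads", {
  w <- simulateWorld(shape = c(30, 30), nOcc = 60, nPop = 6, nRoads = 4,
                     roadStyle = "ring", seed = 6)
  onRoad <- extractValues(list(r = w$roads), w$populations)$r
  expect_true(all(onRoad == 0))
})
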