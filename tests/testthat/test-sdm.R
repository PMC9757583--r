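test_that("rank AUC equals the Mann-Whitney statistic with midranks", {
  set.seed(2)
  labels <- rep(c(1, 0), c(20, 30))
  scores <- c(rnorm(20, 1), rnorm(30))
  w <- wilcox.test(scores[labels == 1], scores[labels == 0], exact = FALSE)
  expect_equal(connectgene:::rankAuc(labels, scores),
               unname(w$statistic) / (20 * 30), tolerance = 1e-12)
  ## ties handled by midranks
  expect_equal(connectgene:::rankAuc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(connectgene:::rankAuc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
})

test_that("evaluatePredictions reproduces a worked maxSSS example", {
  m <- evaluatePredictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1))
  expect_equal(m$auc, 0.75)
  expect_equal(m$threshold, 0.4)
  expect_equal(m$tss, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.5)
  perfect <- evaluatePredictions(c(1, 1, 0), c(0.8, 0.9, 0.2))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tss, 1)
  ## a supplied threshold is honoured
  fixed <- evaluatePredictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1),
                               threshold = 0.6)
  expect_equal(fixed$threshold, 0.6)
  expect_equal(fixed$sensitivity, 0.5)
  expect_error(evaluatePredictions(c(1, 1), c(0.2, 0.3)))
})

test_that("maxSSS threshold maximizes sensitivity + specificity", {
  set.seed(3)
  labels <- rep(c(1, 0), each = 40)
  scores <- c(runif(40, 0.3, 1), runif(40, 0, 0.7))
  m <- evaluatePredictions(labels, scores)
  ss <- function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / 40 + sum(!pred & labels == 0) / 40
  }
  best <- max(vapply(sort(unique(scores)), ss, numeric(1)))
  expect_equal(ss(m$threshold), best, tolerance = 1e-12)
})

test_that("background sampling is uniform over valid non-excluded cells", {
  r <- rasterGrid(matrix(1, 10, 10))
  r@values[1:5] <- NA
  bg <- sampleBackground(list(env = r), 60, seed = 4)
  cells <- cellFromXY(r, bg$x, bg$y)
  expect_false(any(cells %in% 1:5))
  expect_identical(nrow(bg), 60L)
  expect_true(all(bg$label == 0))
  ## excluded points are avoided
  occ <- cellCenters(r, 6:20)
  bg2 <- sampleBackground(list(env = r), 50,
                          exclude = pointSet(occ$x, occ$y), seed = 4)
  expect_false(any(cellFromXY(r, bg2$x, bg2$y) %in% 6:20))
  ## deterministic
  bg3 <- sampleBackground(list(env = r), 60, seed = 4)
  expect_identical(bg, bg3)
})

test_that("the split is stratified and errors on degenerate classes", {
  pts <- data.frame(x = runif(100), y = runif(100),
                    label = rep(c(1L, 0L), c(30, 70)))
  sp <- splitTrainTest(pts, fraction = 0.7, seed = 5)
  expect_identical(sum(sp$train$label == 1), 21L)
  expect_identical(sum(sp$train$label == 0), 49L)
  expect_identical(nrow(sp$train) + nrow(sp$test), 100L)
  expect_error(splitTrainTest(pts, fraction = 1.2))
  one <- data.frame(x = 1:3, y = 1:3, label = c(1L, 0L, 0L))
  expect_error(splitTrainTest(one, fraction = 0.7))
})

test_that("folds are stratified and cover every fold", {
  labels <- rep(c(1L, 0L), c(40, 60))
  f <- connectgene:::makeFolds(labels, 5, seed = 6)
  expect_identical(sort(unique(f)), 1:5)
  tab <- table(f[labels == 1])
  expect_true(all(tab == 8))
})

test_that("every learner fits, predicts in [0,1] and is seed-reproducible", {
  s <- smallSdmSetup()
  pts <- s$pts
  pres <- pts[pts$label == 1, ]; bg <- pts[pts$label == 0, ]
  X <- extractValues(s$world$envLayers, pts)
  for (k in sdmKinds()) {
    f1 <- fitSdm(k, pres, bg, s$world$envLayers, seed = 7)
    f2 <- fitSdm(k, pres, bg, s$world$envLayers, seed = 7)
    p1 <- predictSdm(f1, X); p2 <- predictSdm(f2, X)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_s4_class(f1, "SdmFit")
    expect_identical(f1@kind, k)
    ## better than random on its own training data
    expect_gt(connectgene:::rankAuc(pts$label, p1), 0.7)
  }
  expect_error(fitSdm("GLM", pres[1, , drop = FALSE], bg,
                      s$world$envLayers))
})

test_that("constant covariates are rejected by name", {
  set.seed(8)
  flat <- uniformRaster(3, 20, 20)
  ok <- randomSuitability(20, 20, seed = 8)
  ext <- 20 * ok@cellSize
  pres <- data.frame(x = runif(10, 0, ext), y = runif(10, 0, ext))
  bg <- data.frame(x = runif(10, 0, ext), y = runif(10, 0, ext))
  expect_error(fitSdm("GLM", pres, bg, list(good = ok, bad = flat)),
               "bad")
})

test_that("raster prediction propagates nodata", {
  s <- smallSdmSetup()
  env <- s$world$envLayers
  env[[1]]@values[3] <- NA
  pr <- predictRaster(s$fits[[1]], env)
  expect_true(is.na(gridValues(pr)[3]))
  v <- gridValues(pr)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
})

test_that("cross-validation selection applies the gates strictly", {
  s <- smallSdmSetup()
  train <- s$pts
  cv <- crossValidateSelect(c("GLM", "MARS"), train, s$world$envLayers,
                            k = 3, aucGate = 0.5, tssGate = 0, seed = 9)
  expect_identical(sort(names(cv)), c("selected", "table"))
  expect_true(all(cv$selected %in% c("GLM", "MARS")))
  expect_identical(nrow(cv$table), 2L)
  ## impossible gate: empty selection with a warning
  expect_warning(
    none <- crossValidateSelect("GLM", train, s$world$envLayers,
                                k = 3, aucGate = 1, tssGate = 1, seed = 9),
    "gate")
  expect_identical(length(none$selected), 0L)
})

test_that("permutation importance separates signal from noise", {
  set.seed(10)
  good <- randomSuitability(25, 25, seed = 11)
  noise <- randomSuitability(25, 25, seed = 12)
  suit <- rasterGrid(plogis(6 * (gridValues(good) - 0.5)))
  occ <- sampleOccurrences(suit, 80, seed = 13)
  bg <- sampleBackground(list(a = good), 200, seed = 14)
  pts <- rbind(occ[c("x", "y", "label")],
               data.frame(x = bg$x, y = bg$y, label = 0L))
  env <- list(signal = good, noise = noise)
  f <- fitSdm("GLM", pts[pts$label == 1, ], pts[pts$label == 0, ], env,
              seed = 15)
  dSig <- permutationImportance(f, pts, env, "signal", nRepeats = 20, seed = 16)
  dNoise <- permutationImportance(f, pts, env, "noise", nRepeats = 20, seed = 16)
  expect_gt(dSig, dNoise)
  expect_gt(dSig, 0.05)
  expect_error(permutationImportance(f, pts, env, "absent"))
  tab <- importanceTable(list(f), pts, env, nRepeats = 5, seed = 17)
  expect_identical(tab$variable[tab$rank == 1], "signal")
})

test_that("committee averaging binarizes members at their own thresholds", {
  s <- smallSdmSetup()
  thr <- vapply(s$fits, function(f) {
    sc <- predictSdm(f, extractValues(s$world$envLayers, s$pts))
    evaluatePredictions(s$pts$label, sc)$threshold
  }, numeric(1))
  em <- committeeEnsemble(s$fits, thr, s$world$envLayers)
  expect_s4_class(em, "EnsembleMap")
  com <- gridValues(em@committee)
  expect_true(all(com >= 0 & com <= 1, na.rm = TRUE))
  ## committee values are multiples of 1/nModels
  expect_true(all(abs(com * em@nModels - round(com * em@nModels)) < 1e-9,
                  na.rm = TRUE))
  ## mask is committee > 0.5
  mask <- gridValues(em@suitableMask)
  expect_equal(mask, ifelse(is.na(com), NA, as.numeric(com > 0.5)))
  expect_error(committeeEnsemble(s$fits, thr[1], s$world$envLayers))
})

test_that("response curves hold other covariates at their means", {
  s <- smallSdmSetup()
  rc <- responseCurve(s$fits, s$world$envLayers, s$pts,
                      names(s$world$envLayers)[1], nGrid = 11)
  expect_true(all(c("value", "kind", "prediction") %in% names(rc)))
  expect_identical(nrow(rc), 11L * length(s$fits))
  expect_true(all(rc$prediction >= 0 & rc$prediction <= 1))
})
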