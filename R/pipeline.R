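## End-to-end orchestration: synthetic world (or user inputs) -> ensemble SDM
## -> resistance surface -> least-cost and circuit distances -> Mantel tests
## -> thresholded habitat networks -> scale selection -> priority nodes.

#' Pipeline configuration
#'
#' Defaults are the study configuration: 10000 background points, a 70-30
#' stratified split, 10-fold cross-validation with selection gates AUC > 0.75
#' and TSS > 0.4, the six-anchor suitability-to-cost transform
#' (100/40/15/5/2/1), road cost 10000, ensemble suitability cutoff 0.5,
#' network thresholds 5000-25000 in steps of 5000 capped at cost 250000,
#' 10000 Mantel permutations, priority quantile 0.05 and capacity exponent
#' beta = 0. Pass `world` to override the synthetic-world parameters of
#' [simulateWorld()] (e.g. smaller grids for desk-scale runs).
#'
#' @param nBackground number of background points.
#' @param trainFraction training fraction of the split.
#' @param cvFolds cross-validation folds.
#' @param aucGate,tssGate model selection gates.
#' @param kinds candidate model kinds.
#' @param anchors suitability-cost anchor matrix.
#' @param roadCost road barrier cost.
#' @param ensembleCutoff committee cutoff defining suitable habitat.
#' @param thresholds habitat-network cost-distance thresholds.
#' @param maxCost least-cost search cap for network links.
#' @param mantelPermutations Mantel test permutations.
#' @param priorityQuantile upper tail defining priority nodes.
#' @param beta capacity exponent in CFBC.
#' @param deltaAucRepeats permutation-importance repeats.
#' @param world list of [simulateWorld()] overrides (synthetic mode).
#' @param seed master seed; all stages derive seeds from it.
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(nBackground = 10000, trainFraction = 0.7,
                           cvFolds = 10, aucGate = 0.75, tssGate = 0.4,
                           kinds = sdmKinds(), anchors = defaultAnchors(),
                           roadCost = 10000, ensembleCutoff = 0.5,
                           thresholds = seq(5000, 25000, by = 5000),
                           maxCost = 250000, mantelPermutations = 10000,
                           priorityQuantile = 0.05, beta = 0,
                           deltaAucRepeats = 10, world = list(), seed = 1) {
  cfg <- list(nBackground = nBackground, trainFraction = trainFraction,
              cvFolds = cvFolds, aucGate = aucGate, tssGate = tssGate,
              kinds = kinds, anchors = anchors, roadCost = roadCost,
              ensembleCutoff = ensembleCutoff, thresholds = thresholds,
              maxCost = maxCost, mantelPermutations = mantelPermutations,
              priorityQuantile = priorityQuantile, beta = beta,
              deltaAucRepeats = deltaAucRepeats, world = world, seed = seed)
  stopifnot(nBackground >= 0, trainFraction > 0, trainFraction < 1,
            cvFolds >= 2, all(thresholds > 0), all(thresholds <= maxCost),
            roadCost >= max(anchors[, 2]), mantelPermutations >= 1,
            priorityQuantile > 0, priorityQuantile < 1,
            all(kinds %in% sdmKinds()))
  structure(cfg, class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return a `pipelineConfig`.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$anchors)) vals$anchors <- do.call(cbind, vals$anchors)
  do.call(pipelineConfig, vals)
}

#' Run the full inference chain
#'
#' Stages: simulate (synthetic mode) -> background sampling -> 70-30 split ->
#' cross-validation model selection -> fit + evaluate + maxSSS thresholds ->
#' permutation importance -> committee ensemble -> resistance surfaces (with
#' and without roads) -> least-cost and circuit distance matrices -> Mantel
#' tests (LCD with roads, LCD without roads, IBR) -> per-threshold habitat
#' networks with CFBC -> He-CFBC scale selection -> priority nodes. The run
#' is deterministic given the master seed.
#'
#' @param config a `pipelineConfig`.
#' @param inputs optional list of user data overriding the synthetic world:
#'   envLayers (named list of [RasterGrid-class]), occurrences, roads,
#'   populations, fst ([DistanceMatrix-class]), he (named vector).
#' @return a `runReport` list with the stage outputs.
#' @export
runPipeline <- function(config = pipelineConfig(), inputs = NULL) {
  seed <- config$seed
  stage <- function(tag, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", tag, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", tag,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  if (is.null(inputs)) {
    world <- stage("simulate", do.call(simulateWorld,
      c(config$world, list(seed = deriveSeed(seed, "world")))))
    inputs <- list(envLayers = world$envLayers, occurrences = world$occurrences,
                   roads = world$roads, populations = world$populations,
                   fst = world$fst, he = world$he)
  } else world <- NULL

  env <- inputs$envLayers
  occ <- inputs$occurrences

  bg <- stage("background", sampleBackground(env, config$nBackground,
              exclude = occ, seed = deriveSeed(seed, "background")))
  pts <- rbind(occ[c("id", "x", "y")], bg[c("id", "x", "y")])
  pts$label <- c(rep(1L, nrow(occ)), rep(0L, nrow(bg)))
  sp <- stage("split", splitTrainTest(pts, config$trainFraction,
                                      seed = deriveSeed(seed, "split")))

  cv <- stage("cv-select", crossValidateSelect(config$kinds, sp$train, env,
              k = config$cvFolds, aucGate = config$aucGate,
              tssGate = config$tssGate, seed = deriveSeed(seed, "cv")))
  if (!length(cv$selected))
    stop("pipeline halted: no model passed the cross-validation gates ",
         "(AUC > ", config$aucGate, ", TSS > ", config$tssGate, ")")

  fits <- stage("fit", lapply(cv$selected, function(kind)
    fitSdm(kind, sp$train[sp$train$label == 1, ],
           sp$train[sp$train$label == 0, ], env,
           seed = deriveSeed(seed, paste0("fit", kind)))))
  names(fits) <- cv$selected

  metrics <- stage("evaluate", lapply(fits, function(f) {
    trainScores <- predictSdm(f, extractValues(env, sp$train))
    thr <- evaluatePredictions(sp$train$label, trainScores)$threshold
    testScores <- predictSdm(f, extractValues(env, sp$test))
    m <- evaluatePredictions(sp$test$label, testScores, threshold = thr)
    m$threshold <- thr
    m
  }))
  metricsTable <- data.frame(
    kind = names(metrics),
    auc = vapply(metrics, `[[`, 0, "auc"),
    tss = vapply(metrics, `[[`, 0, "tss"),
    threshold = vapply(metrics, `[[`, 0, "threshold"),
    row.names = NULL)

  importance <- stage("importance", importanceTable(fits, sp$test, env,
    nRepeats = config$deltaAucRepeats, seed = deriveSeed(seed, "importance")))

  ensemble <- stage("ensemble", committeeEnsemble(fits,
    metricsTable$threshold, env))

  resistRoads <- stage("resistance", composeResistance(
    ensemble@committee, inputs$roads, roadCost = config$roadCost,
    anchors = config$anchors))
  resistFree <- composeResistance(ensemble@committee, NULL,
    roadCost = config$roadCost, anchors = config$anchors)

  pops <- inputs$populations
  lcdRoads <- stage("lcd", lcdMatrix(buildLattice(resistRoads), pops))
  lcdFree <- lcdMatrix(buildLattice(resistFree), pops)
  ibr <- stage("ibr", ibrMatrix(resistRoads, pops))

  mt <- stage("mantel", {
    tests <- list(lcd_roads = lcdRoads, lcd_noroads = lcdFree, ibr = ibr)
    do.call(rbind, lapply(names(tests), function(nm) {
      m <- mantelTest(inputs$fst, tests[[nm]],
                      nPerm = config$mantelPermutations,
                      seed = deriveSeed(seed, paste0("mantel", nm)))
      data.frame(test = nm, r = m$r, p = m$p, nPerm = m$nPerm)
    }))
  })

  network <- stage("network", {
    nodes <- extractHabitatNodes(ensemble, resistRoads)
    D <- nodeLcd(nodes, resistRoads, config$maxCost)
    perThreshold <- lapply(config$thresholds, function(th) {
      g <- buildThresholdGraph(nodes, resistRoads, th,
                               maxCost = config$maxCost, lcd = D)
      cf <- cfbc(g, beta = config$beta)
      assign <- assignPopulationNodes(pops, g)
      list(graph = g, cfbc = cf,
           he = inputs$he[assign$id],
           centrality = setNames(cf$cfbc[assign$nodeIndex], assign$id))
    })
    names(perThreshold) <- as.character(config$thresholds)
    perThreshold
  })

  scale <- stage("select-scale", selectScale(
    lapply(network, function(x) list(he = x$he, centrality = x$centrality))))
  bestKey <- as.character(scale$best)
  priority <- stage("prioritize", prioritizeNodes(network[[bestKey]]$cfbc,
                                                  config$priorityQuantile))

  com <- ensemble@committee@values
  structure(list(
    config = config, world = world,
    cvTable = cv$table, selected = cv$selected,
    modelMetrics = metricsTable, importance = importance,
    ensemble = ensemble,
    suitableFraction = mean(com[!is.na(com)] > 0.5),
    resistance = resistRoads,
    distances = list(lcd_roads = lcdRoads, lcd_noroads = lcdFree, ibr = ibr),
    mantelTable = mt,
    scaleTable = scale$table, bestThreshold = scale$best,
    scaleSignificant = scale$significant,
    network = network[[bestKey]]$graph,
    cfbc = network[[bestKey]]$cfbc,
    priority = priority,
    seed = seed,
    versions = c(R = as.character(getRversion()),
                 connectgene = as.character(utils::packageVersion("connectgene")))),
    class = "runReport")
}

#' Write a run report to disk
#'
#' JSON summary plus CSV tables, ASCII-grid rasters, a GraphML habitat graph
#' and GeoJSON node/priority points. The directory is created when missing.
#'
#' @param report a `runReport` from [runPipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$cvTable, file.path(dir, "cv_selection.csv"), row.names = FALSE)
  write.csv(report$modelMetrics, file.path(dir, "model_metrics.csv"), row.names = FALSE)
  write.csv(report$importance, file.path(dir, "importance.csv"), row.names = FALSE)
  write.csv(report$mantelTable, file.path(dir, "mantel.csv"), row.names = FALSE)
  write.csv(report$scaleTable, file.path(dir, "scale_selection.csv"), row.names = FALSE)
  writeAsciiGrid(report$ensemble@committee, file.path(dir, "ensemble_committee.asc"))
  writeAsciiGrid(report$ensemble@suitableMask, file.path(dir, "suitable_mask.asc"))
  writeAsciiGrid(report$resistance@cost, file.path(dir, "resistance.asc"))
  for (nm in names(report$distances))
    writeMatrixCsv(dmValues(report$distances[[nm]]),
                   file.path(dir, paste0(nm, ".csv")))
  ## habitat graph: GraphML + node CSV + GeoJSON
  g <- report$network
  ig <- igraph::make_empty_graph(n = nrow(g@nodes), directed = FALSE)
  if (nrow(g@edges))
    ig <- igraph::add_edges(ig, rbind(g@edges$from, g@edges$to),
                            weight = g@edges$weight)
  ig <- igraph::set_vertex_attr(ig, "id", value = g@nodes$id)
  ig <- igraph::set_vertex_attr(ig, "x", value = g@nodes$x)
  ig <- igraph::set_vertex_attr(ig, "y", value = g@nodes$y)
  ig <- igraph::set_vertex_attr(ig, "cfbc", value = report$cfbc$cfbc)
  igraph::write_graph(ig, file.path(dir, "habitat_graph.graphml"),
                      format = "graphml")
  nodesOut <- cbind(g@nodes[c("id", "x", "y")], cfbc = report$cfbc$cfbc,
                    priority = g@nodes$id %in% report$priority$node)
  write.csv(nodesOut, file.path(dir, "nodes.csv"), row.names = FALSE)
  writeGeoJsonPoints(nodesOut, file.path(dir, "nodes.geojson"))
  writeGeoJsonPoints(nodesOut[nodesOut$priority, , drop = FALSE],
                     file.path(dir, "priority_nodes.geojson"))
  summary <- list(
    schemaVersion = 1,
    seed = report$seed,
    versions = as.list(report$versions),
    selected = report$selected,
    modelMetrics = report$modelMetrics,
    importance = report$importance,
    suitableFraction = report$suitableFraction,
    mantel = report$mantelTable,
    scale = report$scaleTable,
    bestThreshold = report$bestThreshold,
    scaleSignificant = report$scaleSignificant,
    priorityNodeCount = nrow(report$priority))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## minimal GeoJSON FeatureCollection of points
writeGeoJsonPoints <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.runReport <- function(x, ...) {
  cat("connectgene run report\n")
  cat("  models selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  mean test AUC %.3f, mean TSS %.3f\n",
              mean(x$modelMetrics$auc), mean(x$modelMetrics$tss)))
  cat(sprintf("  suitable habitat fraction: %.3f\n", x$suitableFraction))
  print(x$mantelTable)
  cat(sprintf("  best network threshold: %g (He-CFBC r = %.3f)\n",
              x$bestThreshold,
              x$scaleTable$r[x$scaleTable$threshold == x$bestThreshold]))
  cat(sprintf("  priority nodes: %d of %d\n", nrow(x$priority),
              nrow(x$network@nodes)))
  invisible(x)
}
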