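## Paper-defined SDM machinery: background design, rank AUC, maxSSS
## thresholding, TSS, stratified splitting, cross-validation selection gates,
## permutation variable importance, response curves and committee averaging.

#' Sample uniform background points
#'
#' Draws `n` distinct cell centers uniformly from cells valid (non-nodata) in
#' every raster, excluding cells that contain any point of `exclude`.
#'
#' @param rasters named list of aligned [RasterGrid-class] layers.
#' @param n number of background points.
#' @param exclude point set whose cells are excluded (e.g. occurrences).
#' @param seed integer seed.
#' @return point set data.frame (id, x, y, label = 0).
#' @export
sampleBackground <- function(rasters, n, exclude = NULL, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  tmpl <- rasters[[1]]
  valid <- !is.na(tmpl@values)
  for (r in rasters[-1]) {
    if (!sameGeometry(r, tmpl)) stop("rasters are misaligned")
    valid <- valid & !is.na(r@values)
  }
  cells <- which(valid)
  if (!is.null(exclude) && nrow(exclude))
    cells <- setdiff(cells, cellFromXY(tmpl, exclude$x, exclude$y))
  if (n > length(cells))
    stop("not enough valid cells for ", n, " background points")
  if (n == 0) return(pointSet(numeric(0), numeric(0), label = integer(0)))
  drawn <- withSeed(seed, sample(cells, n))
  cc <- cellCenters(tmpl, drawn)
  pointSet(cc$x, cc$y, id = paste0("bg", seq_len(n)), label = rep(0L, n))
}

## rank (Mann-Whitney) AUC with midrank tie handling
rankAuc <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate presence-background predictions
#'
#' AUC by the rank statistic with midrank ties; the classification threshold
#' is the observed score maximizing sensitivity + specificity (maxSSS, with
#' predicted presence meaning score >= threshold); TSS = sensitivity +
#' specificity - 1 at that threshold. A fixed `threshold` (e.g. carried over
#' from training data) can be supplied instead.
#'
#' @param labels binary vector (1 = presence, 0 = background).
#' @param scores numeric prediction scores.
#' @param threshold optional fixed threshold; default maxSSS over `scores`.
#' @return list (class `evalMetrics`): auc, tss, threshold, sensitivity,
#'   specificity.
#' @export
evaluatePredictions <- function(labels, scores, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  stopifnot(length(labels) == length(scores))
  auc <- rankAuc(labels, scores)
  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    ss <- vapply(cand, function(t) {
      pred <- scores >= t
      sum(pred & labels == 1) / sum(labels == 1) +
        sum(!pred & labels == 0) / sum(labels == 0)
    }, numeric(1))
    threshold <- cand[which.max(ss)]
  }
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  structure(list(auc = auc, tss = sens + spec - 1, threshold = threshold,
                 sensitivity = sens, specificity = spec),
            class = "evalMetrics")
}

#' Stratified train-test split
#'
#' Partitions a labeled point set into train and test parts, stratified by
#' label, with per-class training counts rounded to the nearest integer.
#'
#' @param points point set with a `label` column.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitTrainTest <- function(points, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  idx <- withSeed(seed, {
    unlist(lapply(split(seq_len(nrow(points)), points$label), function(ix) {
      k <- round(fraction * length(ix))
      if (k == 0 || k == length(ix))
        stop("a class is too small to appear in both parts")
      sample(ix, k)
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  list(train = points[idx, , drop = FALSE],
       test = points[-idx, , drop = FALSE])
}

## stratified fold assignment
makeFolds <- function(labels, k, seed) {
  withSeed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      f[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    f
  })
}

#' Cross-validation model selection gates
#'
#' k-fold cross-validation on the training points for each candidate model
#' kind; a kind is retained when its mean fold test AUC exceeds `aucGate` and
#' its mean fold TSS exceeds `tssGate` (strict inequalities). TSS uses the
#' maxSSS threshold computed on each fold's training part.
#'
#' @param kinds character vector of model kinds.
#' @param train labeled point set.
#' @param rasters covariate layers.
#' @param k number of folds (default 10).
#' @param aucGate,tssGate selection gates (defaults 0.75 and 0.4).
#' @param settings per-kind settings list.
#' @param seed integer seed.
#' @return list: `selected` (character vector, possibly empty with a warning)
#'   and `table` (per-kind mean AUC/TSS data.frame).
#' @export
crossValidateSelect <- function(kinds, train, rasters, k = 10,
                                aucGate = 0.75, tssGate = 0.4,
                                settings = list(), seed = 1) {
  if (k < 2) stop("k must be >= 2")
  folds <- makeFolds(train$label, k, deriveSeed(seed, "folds"))
  if (any(tapply(train$label, folds, function(l) length(unique(l))) < 2))
    stop("too few points per fold for both classes")
  res <- lapply(kinds, function(kind) {
    aucs <- numeric(k); tsss <- numeric(k)
    for (f in seq_len(k)) {
      tr <- train[folds != f, ]; te <- train[folds == f, ]
      fit <- fitSdm(kind, tr[tr$label == 1, ], tr[tr$label == 0, ], rasters,
                    settings = settings[[kind]] %||% list(),
                    seed = deriveSeed(seed, paste0("cv", kind, f)))
      thr <- evaluatePredictions(tr$label,
               predictSdm(fit, extractValues(rasters, tr)))$threshold
      m <- evaluatePredictions(te$label,
             predictSdm(fit, extractValues(rasters, te)), threshold = thr)
      aucs[f] <- m$auc; tsss[f] <- m$tss
    }
    c(auc = mean(aucs), tss = mean(tsss))
  })
  tab <- data.frame(kind = kinds, meanAuc = vapply(res, `[[`, 0, "auc"),
                    meanTss = vapply(res, `[[`, 0, "tss"))
  selected <- tab$kind[tab$meanAuc > aucGate & tab$meanTss > tssGate]
  if (!length(selected))
    warning("no model passed the cross-validation gates (AUC > ", aucGate,
            ", TSS > ", tssGate, ")")
  list(selected = as.character(selected), table = tab)
}

#' Permutation variable importance (delta AUC)
#'
#' The drop in AUC when one covariate is permuted across the evaluation
#' points: `deltaAUC = AUC(original) - mean(AUC(permuted))` over `nRepeats`
#' permutations. May be negative for uninformative covariates.
#'
#' @param fit an [SdmFit-class].
#' @param evalPoints labeled point set used for evaluation.
#' @param rasters covariate layers.
#' @param variable covariate name to permute.
#' @param nRepeats number of permutations (default 10).
#' @param seed integer seed.
#' @return scalar delta AUC.
#' @export
permutationImportance <- function(fit, evalPoints, rasters, variable,
                                  nRepeats = 10, seed = 1) {
  if (!variable %in% fit@varNames) stop("unknown variable: ", variable)
  X <- extractValues(rasters, evalPoints)
  base <- rankAuc(evalPoints$label, predictSdm(fit, X))
  perm <- withSeed(seed, vapply(seq_len(nRepeats), function(i) {
    Xp <- X
    Xp[[variable]] <- sample(Xp[[variable]])
    rankAuc(evalPoints$label, predictSdm(fit, Xp))
  }, numeric(1)))
  base - mean(perm)
}

#' Importance table across models
#'
#' Per (model, variable) delta AUC, the per-variable mean over models, and
#' descending ranks by that mean.
#'
#' @param fits list of [SdmFit-class] objects.
#' @param evalPoints,rasters,nRepeats,seed passed to [permutationImportance()].
#' @return data.frame with one row per variable: per-model delta AUC columns,
#'   meanDeltaAuc, rank (1 = most important).
#' @export
importanceTable <- function(fits, evalPoints, rasters, nRepeats = 10, seed = 1) {
  vars <- fits[[1]]@varNames
  kinds <- vapply(fits, slot, "", "kind")
  tab <- vapply(fits, function(f)
    vapply(vars, function(v)
      permutationImportance(f, evalPoints, rasters, v, nRepeats,
                            seed = deriveSeed(seed, paste0("imp", f@kind, v))),
      numeric(1)),
    numeric(length(vars)))
  tab <- matrix(tab, nrow = length(vars), dimnames = list(vars, kinds))
  out <- data.frame(variable = vars, tab, row.names = NULL, check.names = FALSE)
  out$meanDeltaAuc <- rowMeans(tab)
  out$rank <- rank(-out$meanDeltaAuc, ties.method = "first")
  out[order(out$rank), ]
}

#' Response curve along one covariate
#'
#' Evaluation-strip curves: the target covariate varies over its observed
#' range at the supplied points while every other covariate is held at its
#' mean over those points.
#'
#' @param fits list of [SdmFit-class].
#' @param rasters covariate layers.
#' @param points presence + background point set defining range and means.
#' @param variable covariate to vary.
#' @param nGrid number of strip points (>= 2).
#' @return data.frame: value (covariate), kind, prediction.
#' @export
responseCurve <- function(fits, rasters, points, variable, nGrid = 50) {
  if (nGrid < 2) stop("nGrid must be >= 2")
  X <- extractValues(rasters, points)
  if (!variable %in% names(X)) stop("unknown variable: ", variable)
  rng <- range(X[[variable]], na.rm = TRUE)
  if (diff(rng) == 0) stop("variable '", variable, "' is constant")
  strip <- as.data.frame(lapply(X, function(col) rep(mean(col, na.rm = TRUE), nGrid)))
  strip[[variable]] <- seq(rng[1], rng[2], length.out = nGrid)
  do.call(rbind, lapply(fits, function(f)
    data.frame(value = strip[[variable]], kind = f@kind,
               prediction = predictSdm(f, strip))))
}

#' Committee-average an ensemble of SDMs
#'
#' Each model's probability raster is binarized at its own maxSSS threshold
#' (score >= threshold = suitable) and the binary maps are averaged. Cells
#' with committee support strictly above 0.5 form the suitable mask, so with
#' five members at least three must agree.
#'
#' @param fits list of [SdmFit-class].
#' @param thresholds one maxSSS threshold per fit.
#' @param rasters covariate layers.
#' @return an [EnsembleMap-class].
#' @export
committeeEnsemble <- function(fits, thresholds, rasters) {
  if (length(fits) != length(thresholds))
    stop("need exactly one threshold per fit")
  tmpl <- rasters[[1]]
  votes <- 0
  valid <- NULL
  for (i in seq_along(fits)) {
    p <- predictRaster(fits[[i]], rasters)@values
    if (is.null(valid)) valid <- !is.na(p)
    votes <- votes + (p >= thresholds[i])
  }
  committee <- votes / length(fits)
  committee[!valid] <- NA
  comR <- rasterGrid(committee, cellSize = tmpl@cellSize, origin = tmpl@origin)
  mask <- ifelse(is.na(committee), NA, as.numeric(committee > 0.5))
  new("EnsembleMap", committee = comR,
      suitableMask = rasterGrid(mask, cellSize = tmpl@cellSize,
                                origin = tmpl@origin),
      nModels = length(fits))
}
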