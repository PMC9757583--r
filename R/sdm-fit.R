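## Five presence-background base learners behind one SdmFit contract:
## GLM   - binomial GLM with AIC-guided bidirectional stepwise selection over
##         all pairwise interactions and squared terms
## MARS  - in-repo degree-1 adaptive regression splines, GCV knot penalty 2.0
## BRT   - gradient-boosted trees, bag fraction 0.75, boosting length chosen
##         by 3-fold cross-validation
## RF    - random forest with the per-split variable count tuned by
##         out-of-bag error
## MAXENT- elastic-net penalized presence-background logistic regression on
##         linear, quadratic and pairwise-product features (the standard
##         maximum-entropy equivalence)

#' The five supported SDM kinds
#' @return character vector of model kind tags.
#' @export
sdmKinds <- function() c("GLM", "MARS", "BRT", "RF", "MAXENT")

## assemble the modeling frame from points and rasters
sdmFrame <- function(presences, background, rasters) {
  pts <- rbind(
    data.frame(x = presences$x, y = presences$y, label = 1L),
    data.frame(x = background$x, y = background$y, label = 0L))
  X <- extractValues(rasters, pts)
  ok <- complete.cases(X)
  if (!all(ok)) {
    warning(sum(!ok), " point(s) on nodata cells dropped")
    pts <- pts[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  }
  cbind(pts["label"], X)
}

checkDesign <- function(df) {
  vars <- setdiff(names(df), "label")
  sds <- vapply(df[vars], sd, numeric(1))
  if (any(sds < 1e-12))
    stop("degenerate design: covariate '", vars[which(sds < 1e-12)[1]],
         "' is constant")
  vars
}

## quadratic + product feature expansion used by the MaxEnt learner
maxentFeatures <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- X
  nms <- colnames(X)
  for (j in seq_len(p)) {
    out <- cbind(out, X[, j]^2); nms <- c(nms, paste0(colnames(X)[j], "^2"))
  }
  if (p > 1) for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    out <- cbind(out, X[, j] * X[, k])
    nms <- c(nms, paste0(colnames(X)[j], ":", colnames(X)[k]))
  }
  colnames(out) <- nms
  out
}

#' Fit one species distribution model
#'
#' Presence points (label 1) against background points (label 0) on raster
#' covariates. Settings follow the configuration used for the study system:
#' GLM is a bidirectional AIC stepwise search whose scope includes all
#' pairwise interactions and squared terms; MARS uses degree 1 and a
#' generalized cross-validation penalty of 2.0 per knot; BRT uses a bag
#' fraction of 0.75 with the boosting length selected by 3-fold
#' cross-validation; RF tunes its per-split variable count by out-of-bag
#' error; MaxEnt is fitted as penalized presence-background logistic
#' regression.
#'
#' @param kind one of "GLM", "MARS", "BRT", "RF", "MAXENT".
#' @param presences,background point sets (data.frames with x, y).
#' @param rasters named list of aligned covariate [RasterGrid-class] layers.
#' @param settings named list of learner overrides (e.g. `eta`, `maxDepth`,
#'   `nTree`, `alpha`, `nKnots`).
#' @param seed integer seed; stochastic learners are reproducible given it.
#' @return an [SdmFit-class].
#' @export
fitSdm <- function(kind, presences, background, rasters, settings = list(),
                   seed = 1) {
  kind <- match.arg(kind, sdmKinds())
  if (nrow(presences) < 2 || nrow(background) < 2)
    stop("need at least 2 presences and 2 background points")
  df <- sdmFrame(presences, background, rasters)
  vars <- checkDesign(df)
  y <- df$label
  X <- as.matrix(df[vars])
  fit <- withSeed(seed, switch(kind,
    GLM = {
      scope <- as.formula(paste(
        "~ (", paste(vars, collapse = " + "), ")^2 +",
        paste(sprintf("I(%s^2)", vars), collapse = " + ")))
      base <- glm(as.formula(paste("label ~", paste(vars, collapse = " + "))),
                  family = binomial(), data = df)
      suppressWarnings(step(base, scope = list(lower = ~1, upper = scope),
                            direction = "both", trace = 0))
    },
    MARS = fitMars(X, y,
                   penalty = settings$penalty %||% 2,
                   nKnots = settings$nKnots %||% 15),
    BRT = {
      params <- list(objective = "binary:logistic",
                     eta = settings$eta %||% 0.05,
                     max_depth = settings$maxDepth %||% 3,
                     subsample = settings$bagFraction %||% 0.75,
                     nthread = 1)
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      cv <- xgboost::xgb.cv(params = params, data = dtrain,
                            nrounds = settings$maxRounds %||% 400,
                            nfold = settings$cvFolds %||% 3,
                            early_stopping_rounds = 20, verbose = 0)
      log <- as.data.frame(cv$evaluation_log)
      best <- which.min(log[["test_logloss_mean"]])
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = best, verbose = 0)
    },
    RF = {
      nTree <- settings$nTree %||% 500
      nodesize <- settings$nodesize %||% 10
      yf <- factor(y, levels = c(0, 1))
      oob <- vapply(seq_len(ncol(X)), function(m) {
        set.seed(seed + m)
        rf <- randomForest::randomForest(X, yf, mtry = m, ntree = 250,
                                         nodesize = nodesize)
        mean(rf$err.rate[, "OOB"])
      }, numeric(1))
      set.seed(seed)
      randomForest::randomForest(X, yf, mtry = which.min(oob), ntree = nTree,
                                 nodesize = nodesize)
    },
    MAXENT = {
      F <- maxentFeatures(X)
      foldid <- sample(rep_len(1:5, nrow(F)))
      cv <- glmnet::cv.glmnet(F, y, family = "binomial",
                              alpha = settings$alpha %||% 1,
                              foldid = foldid, standardize = TRUE)
      structure(list(cv = cv, lambda = cv$lambda.1se), class = "maxentFit")
    }))
  new("SdmFit", kind = kind, fit = fit, varNames = vars,
      settings = settings)
}

#' Predict occurrence probability from a fitted SDM
#'
#' @param object an [SdmFit-class].
#' @param newdata data.frame containing the fitted covariates.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
setGeneric("predictSdm", function(object, newdata) standardGeneric("predictSdm"))

#' @rdname predictSdm
#' @export
setMethod("predictSdm", "SdmFit", function(object, newdata) {
  X <- as.matrix(newdata[, object@varNames, drop = FALSE])
  p <- switch(object@kind,
    GLM = predict(object@fit, newdata = as.data.frame(newdata), type = "response"),
    MARS = predictMars(object@fit, X),
    BRT = predict(object@fit, xgboost::xgb.DMatrix(X)),
    RF = predict(object@fit, X, type = "prob")[, "1"],
    MAXENT = as.numeric(predict(object@fit$cv, maxentFeatures(X),
                                s = object@fit$lambda, type = "response")))
  as.numeric(pmin(1, pmax(0, p)))
})

#' Predict an SDM over a whole raster stack
#'
#' @param fit an [SdmFit-class].
#' @param rasters named list of covariate [RasterGrid-class] layers.
#' @return a [RasterGrid-class] of occurrence probabilities (NA on nodata).
#' @export
predictRaster <- function(fit, rasters) {
  tmpl <- rasters[[1]]
  df <- data.frame(lapply(rasters, function(r) as.vector(r@values)))
  names(df) <- names(rasters)
  ok <- complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) out[ok] <- predictSdm(fit, df[ok, , drop = FALSE])
  rasterGrid(matrix(out, nrow(tmpl@values), ncol(tmpl@values)),
             cellSize = tmpl@cellSize, origin = tmpl@origin)
}
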