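## Degree-1 multivariate adaptive regression splines: forward hinge-pair
## selection and backward pruning under generalized cross-validation with a
## penalty of 2 effective parameters per knot, followed by a logistic refit of
## the selected basis so predictions are probabilities. Hinge knot candidates
## sit at data quantiles.

marsBasis <- function(X, terms) {
  B <- matrix(1, nrow(X), 1)
  for (tm in terms) {
    h <- if (tm$dir > 0) pmax(X[, tm$var] - tm$knot, 0) else pmax(tm$knot - X[, tm$var], 0)
    B <- cbind(B, h)
  }
  B
}

marsGcv <- function(rss, n, nTerms, penalty) {
  enp <- nTerms + penalty * (nTerms - 1) / 2     # knots = (terms - 1) / 2 pairs
  denom <- max(1 - enp / n, 1e-6)
  (rss / n) / denom^2
}

fitMars <- function(X, y, penalty = 2, maxTerms = NULL, nKnots = 15) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(maxTerms)) maxTerms <- min(21, max(7, floor(n / 10)))
  knots <- lapply(seq_len(p), function(j)
    unique(as.numeric(quantile(X[, j], probs = seq(0.05, 0.95, length.out = nKnots)))))
  terms <- list()
  B <- matrix(1, n, 1)
  rss <- sum((y - mean(y))^2)
  repeat {
    if (ncol(B) + 2 > maxTerms) break
    best <- NULL
    for (j in seq_len(p)) for (k in knots[[j]]) {
      h1 <- pmax(X[, j] - k, 0); h2 <- pmax(k - X[, j], 0)
      if (sd(h1) < 1e-12 && sd(h2) < 1e-12) next
      fit <- stats::lm.fit(cbind(B, h1, h2), y)
      r <- sum(fit$residuals^2)
      if (is.null(best) || r < best$rss - 1e-12)
        best <- list(rss = r, var = j, knot = k)
    }
    if (is.null(best) || best$rss > rss * (1 - 1e-4)) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot, dir = 1),
                           list(var = best$var, knot = best$knot, dir = -1)))
    B <- marsBasis(X, terms)
    rss <- best$rss
  }
  ## backward pruning by GCV
  keepSets <- list(seq_along(terms))
  gcvs <- marsGcv(rss, n, length(terms) + 1, penalty)
  cur <- seq_along(terms)
  while (length(cur) > 0) {
    bestG <- Inf; bestSet <- NULL
    for (drop in seq_along(cur)) {
      set <- cur[-drop]
      Bs <- marsBasis(X, terms[set])
      r <- sum(stats::lm.fit(Bs, y)$residuals^2)
      g <- marsGcv(r, n, length(set) + 1, penalty)
      if (g < bestG) { bestG <- g; bestSet <- set }
    }
    cur <- bestSet
    keepSets <- c(keepSets, list(cur))
    gcvs <- c(gcvs, bestG)
  }
  sel <- keepSets[[which.min(gcvs)]]
  terms <- terms[sel]
  B <- marsBasis(X, terms)
  ## logistic refit of the selected basis keeps predictions in [0, 1]
  glmFit <- suppressWarnings(
    stats::glm.fit(B, y, family = binomial(), control = list(maxit = 50)))
  list(terms = terms, coef = glmFit$coefficients, gcv = min(gcvs),
       penalty = penalty)
}

predictMars <- function(model, X) {
  B <- marsBasis(X, model$terms)
  cf <- model$coef
  cf[is.na(cf)] <- 0
  as.numeric(stats::plogis(B %*% cf))
}
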