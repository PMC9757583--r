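## Association of genetic structure with landscape distances (Mantel
## permutation tests) and of genetic diversity with habitat connectivity
## (Pearson correlation on log-transformed centrality, with scale selection
## across network thresholds).

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the vectorized upper triangles; the null is built by
#' jointly permuting rows and columns of `B`. The p-value carries the +1
#' correction, `p = (1 + #{r_perm at least as extreme}) / (1 + nPerm)`, so it
#' can never be zero. Default alternative is one-tailed "greater" (isolation
#' predicts a positive correlation).
#'
#' @param A,B [DistanceMatrix-class] objects with identical labels, size >= 4.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return list (class `mantelResult`): r, p, nPerm, alternative.
#' @export
mantelTest <- function(A, B, nPerm = 10000, seed = 1,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- dmValues(A); b <- dmValues(B)
  if (!identical(dmLabels(A), dmLabels(B))) stop("matrix labels do not match")
  n <- nrow(a)
  if (n < 4) stop("need at least 4 sites")
  if (any(is.infinite(a)) || any(is.infinite(b)))
    stop("matrices contain infinite (disconnected) entries")
  ut <- which(upper.tri(a), arr.ind = TRUE)
  av <- a[ut]; bv <- b[ut]
  if (sd(av) == 0 || sd(bv) == 0) stop("a matrix has zero variance")
  r <- cor(av, bv)
  ac <- av - mean(av)
  denomA <- sqrt(sum(ac^2))
  withSeed(seed, {
    P <- replicate(nPerm, sample.int(n))           # n x nPerm permutations
    idx <- (P[ut[, 2], , drop = FALSE] - 1L) * n + P[ut[, 1], , drop = FALSE]
    Bp <- matrix(b[idx], nrow = nrow(ut))
    Bc <- sweep(Bp, 2, colMeans(Bp))
    rPerm <- as.numeric(crossprod(ac, Bc)) / (denomA * sqrt(colSums(Bc^2)))
  })
  eps <- 1e-12
  extreme <- switch(alternative,
    greater = sum(rPerm >= r - eps),
    less = sum(rPerm <= r + eps),
    two.sided = sum(abs(rPerm) >= abs(r) - eps))
  structure(list(r = r, p = (1 + extreme) / (1 + nPerm), nPerm = nPerm,
                 alternative = alternative),
            class = "mantelResult")
}

#' @export
print.mantelResult <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$nPerm))
  invisible(x)
}

#' Correlation between gene diversity and habitat centrality
#'
#' Pearson correlation between per-population expected heterozygosity and
#' (natural-log-transformed) current-flow betweenness centrality, with the
#' two-sided t-distribution p-value (df = n - 2). The log transform addresses
#' the right skew of centrality scores; the log base only rescales and leaves
#' r unchanged.
#'
#' @param he per-population gene diversity in \[0, 1\].
#' @param centrality per-population centrality, strictly positive when
#'   `logTransform`.
#' @param logTransform take the natural log of `centrality` first (default TRUE).
#' @return list with r and p.
#' @export
diversityCentralityCorrelation <- function(he, centrality, logTransform = TRUE) {
  if (length(he) != length(centrality)) stop("he and centrality lengths differ")
  n <- length(he)
  if (n < 3) stop("need at least 3 populations")
  x <- if (logTransform) {
    if (any(centrality <= 0)) stop("centrality must be strictly positive for the log transform")
    log(centrality)
  } else centrality
  if (sd(he) == 0 || sd(x) == 0) stop("correlation undefined: constant input")
  r <- cor(he, x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Select the network scale best related to gene diversity
#'
#' Given per-threshold (he, centrality) pairs, computes the He-centrality
#' correlation at each threshold and returns the threshold with the largest r
#' among significant ones (p < 0.05); ties go to the smallest threshold. When
#' no threshold is significant, the max-r threshold is returned with
#' `significant = FALSE` and a warning.
#'
#' @param results named list: threshold -> list(he, centrality).
#' @param alpha significance level (default 0.05).
#' @param logTransform passed to [diversityCentralityCorrelation()].
#' @return list: `best` (numeric threshold), `significant` (flag) and `table`
#'   (threshold, r, p).
#' @export
selectScale <- function(results, alpha = 0.05, logTransform = TRUE) {
  if (!length(results)) stop("need at least one threshold")
  thr <- as.numeric(names(results))
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    ct <- diversityCentralityCorrelation(results[[i]]$he,
                                         results[[i]]$centrality,
                                         logTransform = logTransform)
    data.frame(threshold = thr[i], r = ct$r, p = ct$p)
  }))
  tab <- tab[order(tab$threshold), ]
  sig <- tab[tab$p < alpha, ]
  if (nrow(sig)) {
    best <- sig$threshold[order(-sig$r, sig$threshold)][1]
    significant <- TRUE
  } else {
    warning("no threshold reached significance; returning the max-r threshold")
    best <- tab$threshold[order(-tab$r, tab$threshold)][1]
    significant <- FALSE
  }
  list(best = best, significant = significant, table = tab)
}
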