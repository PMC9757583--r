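#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a stage tag, so stages are reproducible independently and adding a
#' stage never perturbs the randomness of another. The derivation is a small
#' multiplicative hash of the tag folded into the master seed, kept below
#' 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param tag character stage label.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h) %% 2147483647) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Construct a point set
#'
#' Point sets are plain data.frames with columns `id`, `x`, `y` and optionally
#' `label` (1 = presence, 0 = background).
#'
#' @param x,y coordinates in raster CRS units.
#' @param id point labels (default p1, p2, ...).
#' @param label optional presence/background indicator.
#' @return a data.frame point set.
#' @export
pointSet <- function(x, y, id = NULL, label = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(id)) id <- if (length(x)) paste0("p", seq_along(x)) else character(0)
  df <- data.frame(id = as.character(id), x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.integer(label)
  df
}

#' Construct a DistanceMatrix
#'
#' @param values square symmetric numeric matrix with zero diagonal.
#' @param kind one of "LCD", "IBR", "EUCLIDEAN", "FST".
#' @param labels site labels; defaults to existing dimnames.
#' @return a [DistanceMatrix-class].
#' @export
distanceMatrix <- function(values, kind, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  new("DistanceMatrix", values = values, kind = kind)
}

#' @rdname distanceMatrix
#' @param x a DistanceMatrix.
#' @export
dmValues <- function(x) x@values

#' @rdname distanceMatrix
#' @export
dmKind <- function(x) x@kind

#' @rdname distanceMatrix
#' @export
dmLabels <- function(x) rownames(x@values)

#' Pairwise Euclidean distances between sites
#'
#' @param sites point set (data.frame with id, x, y).
#' @return a [DistanceMatrix-class] of kind "EUCLIDEAN".
#' @export
euclideanMatrix <- function(sites) {
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  distanceMatrix(d, "EUCLIDEAN", labels = sites$id)
}

## upper-triangle vector of a square matrix
upperVec <- function(m) m[upper.tri(m)]

clip01 <- function(x) {
  d <- dim(x)
  out <- pmin(1, pmax(0, x))
  dim(out) <- d
  out
}

## read/write labeled square matrices as CSV
writeMatrixCsv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

readMatrixCsv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
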