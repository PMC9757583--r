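#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northern edge); `NA` is nodata.
#' @param cellSize cell edge length in map units.
#' @param origin (x, y) of the lower-left corner of the grid.
#' @return a [RasterGrid-class] object.
#' @examples
#' r <- rasterGrid(matrix(runif(12), 3, 4), cellSize = 50)
#' gridValues(r)[1, 1]
#' @export
rasterGrid <- function(values, cellSize = 1, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = cellSize,
      origin = as.numeric(origin))
}

#' @rdname rasterGrid
#' @param x a RasterGrid.
#' @export
gridValues <- function(x) x@values

#' @rdname rasterGrid
#' @export
cellSize <- function(x) x@cellSize

#' @rdname rasterGrid
#' @export
gridOrigin <- function(x) x@origin

#' @rdname rasterGrid
#' @export
gridDim <- function(x) dim(x@values)

## two grids are aligned when shape, cell size and origin agree
sameGeometry <- function(a, b, tol = 1e-9) {
  identical(dim(a@values), dim(b@values)) &&
    abs(a@cellSize - b@cellSize) < tol &&
    max(abs(a@origin - b@origin)) < tol
}

#' Cell-center coordinates
#'
#' @param x a [RasterGrid-class].
#' @param cells optional linear cell indices (column-major, as in R matrices);
#'   default all cells.
#' @return data.frame with columns cell, x, y.
#' @export
cellCenters <- function(x, cells = NULL) {
  nr <- nrow(x@values)
  if (is.null(cells)) cells <- seq_along(x@values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  data.frame(cell = cells,
             x = x@origin[1] + (col - 0.5) * x@cellSize,
             y = x@origin[2] + (nr - row + 0.5) * x@cellSize)
}

#' Locate the cell containing each coordinate
#'
#' @param r a [RasterGrid-class].
#' @param x,y coordinate vectors.
#' @return linear cell indices; `NA` for points outside the extent.
#' @export
cellFromXY <- function(r, x, y) {
  nr <- nrow(r@values); nc <- ncol(r@values); cs <- r@cellSize
  col <- floor((x - r@origin[1]) / cs) + 1L
  rowFromBottom <- floor((y - r@origin[2]) / cs) + 1L
  row <- nr - rowFromBottom + 1L
  ## points on the top/right extent boundary belong to the outermost cell
  col[x == r@origin[1] + nc * cs] <- nc
  row[y == r@origin[2] + nr * cs] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  idx <- (col - 1L) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Extract raster values at point locations
#'
#' @param rasters a [RasterGrid-class] or a named list of them.
#' @param points data.frame with x and y columns.
#' @return numeric vector, or a data.frame with one column per raster.
#' @export
extractValues <- function(rasters, points) {
  if (is(rasters, "RasterGrid")) {
    idx <- cellFromXY(rasters, points$x, points$y)
    return(rasters@values[idx])
  }
  stopifnot(is.list(rasters), length(rasters) > 0)
  nm <- names(rasters)
  if (is.null(nm)) nm <- paste0("env", seq_along(rasters))
  out <- lapply(rasters, function(r) {
    r@values[cellFromXY(r, points$x, points$y)]
  })
  names(out) <- nm
  as.data.frame(out)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of cell values, north
#' row first.
#'
#' @param path file path.
#' @return [readAsciiGrid()] returns a [RasterGrid-class];
#'   [writeAsciiGrid()] returns `path` invisibly.
#' @export
readAsciiGrid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, 1)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos); break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid body size mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  rasterGrid(m, cellSize = hdr$cellsize, origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname readAsciiGrid
#' @param x a [RasterGrid-class] to write.
#' @param nodata value used to encode `NA` cells.
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  v <- x@values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x@origin[1]),
    sprintf("yllcorner %.10g", x@origin[2]),
    sprintf("cellsize %.10g", x@cellSize),
    sprintf("NODATA_value %.10g", nodata))
  ## 17 significant digits round-trip IEEE doubles exactly
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
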