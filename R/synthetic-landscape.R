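## Synthetic landscapes with known ground truth: spatially autocorrelated
## covariates, a logistic true-suitability surface, occurrences sampled from
## it, linear road barriers, population sites in suitable habitat, and genetic
## summaries (pairwise FST, per-population He) generated from true landscape
## distances and connectivity.

## row-normalized Gaussian band matrix; dividing by the kernel mass at the
## edges avoids variance inflation near borders
gaussBand <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  K / rowSums(K)
}

#' Generate spatially autocorrelated environmental layers
#'
#' White noise smoothed with a separable Gaussian kernel of bandwidth
#' `corrLength` (in cells) and re-standardized to mean 0, sd 1. The
#' autocorrelation range grows with `corrLength`; 0 gives standardized white
#' noise.
#'
#' @param shape integer (nrow, ncol) of the grid.
#' @param nLayers number of covariate layers.
#' @param corrLength Gaussian smoothing bandwidth in cells (>= 0).
#' @param seed integer seed; identical seeds give bit-identical layers.
#' @param cellSize,origin grid geometry passed to [rasterGrid()].
#' @return named list of [RasterGrid-class] layers (env1, env2, ...).
#' @export
generateEnvLayers <- function(shape, nLayers, corrLength = 5, seed = 1,
                              cellSize = 50, origin = c(0, 0)) {
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be two positive integers")
  if (corrLength < 0) stop("corrLength must be >= 0")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  Kr <- if (corrLength > 0) gaussBand(nr, corrLength) else NULL
  Kc <- if (corrLength > 0) gaussBand(nc, corrLength) else NULL
  withSeed(seed, {
    layers <- lapply(seq_len(nLayers), function(i) {
      z <- matrix(rnorm(nr * nc), nr, nc)
      if (!is.null(Kr)) z <- Kr %*% z %*% t(Kc)
      z <- (z - mean(z)) / sd(z)
      rasterGrid(z, cellSize = cellSize, origin = origin)
    })
    names(layers) <- paste0("env", seq_len(nLayers))
    layers
  })
}

#' True suitability surface from a logistic linear model
#'
#' Cellwise `plogis(intercept + sum(beta_i * layer_i))`, the virtual-species
#' standard for a known habitat-suitability truth.
#'
#' @param layers list of aligned [RasterGrid-class] covariates.
#' @param coefficients one coefficient per layer.
#' @param intercept scalar intercept.
#' @return a [RasterGrid-class] with values in (0, 1).
#' @export
makeTrueSuitability <- function(layers, coefficients, intercept = 0) {
  if (length(layers) != length(coefficients))
    stop("need one coefficient per layer")
  lin <- matrix(intercept, nrow(layers[[1]]@values), ncol(layers[[1]]@values))
  for (i in seq_along(layers)) {
    if (!sameGeometry(layers[[i]], layers[[1]])) stop("layers are not aligned")
    lin <- lin + coefficients[i] * layers[[i]]@values
  }
  rasterGrid(stats::plogis(lin), cellSize = layers[[1]]@cellSize,
             origin = layers[[1]]@origin)
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; points sit at cell centers. Draws closer than `minSep` cells
#' (center-to-center, in cell units) to an already accepted point are thinned,
#' mirroring a minimum-separation rule at the working resolution.
#'
#' @param suitability a [RasterGrid-class] in \[0, 1\].
#' @param n number of occurrences.
#' @param seed integer seed.
#' @param minSep minimum separation in cell units (default 1 = distinct cells).
#' @return point set data.frame (id, x, y, label = 1).
#' @export
sampleOccurrences <- function(suitability, n, seed = 1, minSep = 1) {
  if (n < 0) stop("n must be >= 0")
  v <- suitability@values
  pos <- which(!is.na(v) & v > 0)
  if (n > length(pos))
    stop("n exceeds the number of positive-suitability cells")
  if (n == 0) return(pointSet(numeric(0), numeric(0), label = integer(0)))
  cs <- suitability@cellSize
  drawn <- withSeed(seed, {
    sample(pos, length(pos), prob = v[pos])   # full weighted order
  })
  cc <- cellCenters(suitability, drawn)
  keep <- integer(0)
  for (i in seq_along(drawn)) {
    if (length(keep) == n) break
    if (length(keep)) {
      d2 <- (cc$x[keep] - cc$x[i])^2 + (cc$y[keep] - cc$y[i])^2
      if (min(d2) < (minSep * cs)^2 - 1e-9) next
    }
    keep <- c(keep, i)
  }
  if (length(keep) < n)
    warning("minimum-separation thinning left only ", length(keep), " of ",
            n, " requested occurrences")
  pointSet(cc$x[keep], cc$y[keep], id = paste0("occ", seq_along(keep)),
           label = rep(1L, length(keep)))
}

## Bresenham line, padded to 4-connectivity so transects have no diagonal gaps
rasterizeLine <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  cells <- list(c(r, c))
  while (!(r == r1 && c == c1)) {
    e2 <- 2 * err
    stepC <- e2 > -dr
    stepR <- e2 < dc
    if (stepC && stepR) cells[[length(cells) + 1L]] <- c(r, c + sc)  # fill corner
    if (stepC) { err <- err - dr; c <- c + sc }
    if (stepR) { err <- err + dc; r <- r + sr }
    cells[[length(cells) + 1L]] <- c(r, c)
  }
  do.call(rbind, cells)
}

## rasterize one circular transect as a closed 72-segment polyline
rasterizeRing <- function(shape, cy, cx, radius) {
  theta <- seq(0, 2 * pi, length.out = 73)
  px <- pmin(pmax(round(cx + radius * cos(theta)), 1), shape[2])
  py <- pmin(pmax(round(cy + radius * sin(theta)), 1), shape[1])
  m <- matrix(0, shape[1], shape[2])
  for (k in seq_len(72))
    m[rasterizeLine(py[k], px[k], py[k + 1], px[k + 1])] <- 1
  m
}

#' Generate a binary road mask of random transects
#'
#' Each transect is rasterized one cell wide with no diagonal gaps, so roads
#' act as contiguous barriers on an 8-connected lattice. With
#' `style = "span"` transects run between random boundary cells (left-right
#' or top-bottom at random); with `style = "radial"` all transects pass
#' through one random interior hub at random angles, emulating major roads
#' radiating from a junction; with `style = "ring"` transects are concentric
#' circular beltways around a random hub, with radii drawn from `band`
#' (fractions of `0.7 * min(shape)`).
#'
#' For ring roads an optional set of site cells (`avoid`) constrains the
#' draw: hub and radii are resampled until the beltways partition the sites
#' nontrivially (between 30 and 80 percent of site pairs separated, and at
#' least one pair separated by two or more rings), and site cells are always
#' cleared from the mask. This guarantees the barrier system neither misses
#' all sites nor encloses them all, without reference to any distances.
#'
#' @param shape integer (nrow, ncol).
#' @param nRoads number of transects (>= 0).
#' @param seed integer seed.
#' @param style "span", "radial" or "ring".
#' @param cellSize,origin grid geometry.
#' @param band radial band for ring transects, as fractions of
#'   `0.7 * min(shape)`.
#' @param avoid optional two-column matrix of (row, col) site cells for ring
#'   balancing.
#' @return a binary [RasterGrid-class] (1 = road).
#' @export
generateRoads <- function(shape, nRoads, seed = 1,
                          style = c("span", "radial", "ring"), cellSize = 50,
                          origin = c(0, 0), band = c(0.35, 0.60),
                          avoid = NULL) {
  style <- match.arg(style)
  if (nRoads < 0) stop("nRoads must be >= 0")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  m <- matrix(0, nr, nc)
  withSeed(seed, {
    if (style == "ring") {
      if (nRoads > 0) {
        maxr <- 0.7 * min(nr, nc)
        for (try in seq_len(100)) {
          cy <- runif(1, 0.3, 0.7) * nr
          cx <- runif(1, 0.3, 0.7) * nc
          radii <- sort(runif(nRoads, band[1], band[2]) * maxr)
          if (is.null(avoid) || nrow(avoid) < 2) break
          hd <- sqrt((avoid[, 1] - cy)^2 + (avoid[, 2] - cx)^2)
          z <- vapply(hd, function(d) sum(radii < d), numeric(1))
          cross <- abs(outer(z, z, "-"))[upper.tri(diag(length(z)))]
          fc <- mean(cross > 0)
          if (fc >= 0.3 && fc <= 0.8 && max(cross) >= 2) break
        }
        for (r in radii) m <- pmax(m, rasterizeRing(c(nr, nc), cy, cx, r))
        if (!is.null(avoid)) m[avoid] <- 0
      }
    } else {
      if (style == "radial" && nRoads > 0) {
        hub <- c(sample(seq(ceiling(nr * 0.2), floor(nr * 0.8)), 1),
                 sample(seq(ceiling(nc * 0.2), floor(nc * 0.8)), 1))
      }
      for (i in seq_len(nRoads)) {
        cells <- if (style == "span") {
          if (runif(1) < 0.5)
            rasterizeLine(sample.int(nr, 1), 1L, sample.int(nr, 1), nc)
          else
            rasterizeLine(1L, sample.int(nc, 1), nr, sample.int(nc, 1))
        } else {
          theta <- runif(1, 0, pi)
          dr <- sin(theta); dc <- cos(theta)
          ## extend from the hub to the grid boundary in both directions
          tmax <- function(sgn) {
            tr <- if (abs(dr) > 1e-9) max((1 - hub[1]) / (sgn * dr),
                                          (nr - hub[1]) / (sgn * dr)) else Inf
            tc <- if (abs(dc) > 1e-9) max((1 - hub[2]) / (sgn * dc),
                                          (nc - hub[2]) / (sgn * dc)) else Inf
            min(tr, tc)
          }
          p1 <- round(hub + tmax(1) * c(dr, dc))
          p2 <- round(hub - tmax(-1) * c(dr, dc))
          p1 <- pmin(pmax(p1, 1L), c(nr, nc)); p2 <- pmin(pmax(p2, 1L), c(nr, nc))
          rasterizeLine(p1[1], p1[2], p2[1], p2[2])
        }
        m[cells] <- 1
      }
    }
  })
  rasterGrid(m, cellSize = cellSize, origin = origin)
}

#' Simulate genetic summaries from landscape distances and connectivity
#'
#' Pairwise differentiation follows an isolation-by-resistance line,
#' `FST(i,j) = clip(a + b * D(i,j) + eps, 0, 1)` with symmetric Gaussian noise
#' on the upper triangle; per-population gene diversity follows
#' `He(i) = clip(c + d * log(centrality_i) + eta, 0, 1)`. A linear-plus-noise
#' stand-in, not a coalescent simulation.
#'
#' @param distances a [DistanceMatrix-class] of true landscape distances.
#' @param a,b intercept and slope of the FST-distance line.
#' @param sigma sd of the symmetric FST noise (>= 0).
#' @param centrality strictly positive per-population connectivity scores.
#' @param c,d intercept and slope of the He vs log-centrality line.
#' @param tau sd of the He noise (>= 0).
#' @param seed integer seed.
#' @return list with `fst` (a [DistanceMatrix-class], kind "FST") and `he`
#'   (named numeric vector).
#' @export
simulateGeneticData <- function(distances, a = 0.05, b = 1e-6, sigma = 0.01,
                                centrality = NULL, c = 0.6, d = 0.05,
                                tau = 0.02, seed = 1) {
  if (sigma < 0 || tau < 0) stop("sigma and tau must be >= 0")
  D <- dmValues(distances)
  K <- nrow(D)
  withSeed(seed, {
    eps <- matrix(0, K, K)
    eps[upper.tri(eps)] <- rnorm(K * (K - 1) / 2, sd = sigma)
    eps <- eps + t(eps)
    fst <- clip01(a + b * D + eps)
    diag(fst) <- 0
    he <- NULL
    if (!is.null(centrality)) {
      if (d != 0 && any(centrality <= 0))
        stop("centrality must be strictly positive when d != 0")
      he <- clip01(c + d * log(centrality) + rnorm(length(centrality), sd = tau))
      names(he) <- names(centrality)
    }
    list(fst = distanceMatrix(fst, "FST", labels = dmLabels(distances)),
         he = he)
  })
}

#' Generate a complete synthetic world
#'
#' Assembles all pipeline inputs with known ground truth: autocorrelated
#' covariates, a logistic true suitability surface, occurrences, road
#' transects, population sites inside suitable habitat, the true resistance
#' surface and with-road least-cost distances between populations, pairwise
#' FST generated from those distances, and per-population He generated from
#' true current-flow betweenness centrality at a known network threshold.
#'
#' @param shape grid dimensions (default 40 x 40).
#' @param nLayers number of covariates.
#' @param coefficients true suitability coefficients, ordered by effect size.
#' @param suitableFraction when non-NULL (default 0.06), the intercept is set
#'   per world to the value that makes this fraction of the landscape suitable
#'   (probability > 0.5) -- prevalence control, as for a riparian habitat
#'   specialist occupying a small share of a basin.
#' @param intercept fixed logistic intercept, used when `suitableFraction`
#'   is NULL.
#' @param corrLength covariate autocorrelation bandwidth in cells.
#' @param nOcc number of occurrence points.
#' @param occPower exponent on the suitability sampling weight (default 1 =
#'   weight proportional to suitability). Larger values concentrate
#'   occurrences in high-quality habitat, emulating a species with little
#'   vagrancy; used by the strong-signal recovery experiments.
#' @param nRoads number of road transects.
#' @param roadStyle transect style passed to [generateRoads()]: "radial"
#'   (default) emulates major roads radiating from one junction; "ring"
#'   emulates concentric beltways around a hub, balanced so they partition
#'   the population sites nontrivially -- the geometry used for the
#'   road-barrier experiments, because the number of beltways between two
#'   sites is nearly unrelated to how far apart they are; "span" gives
#'   independent random transects.
#' @param nPop number of genetic sampling populations.
#' @param cellSize cell size in m (default 50, the working resolution).
#' @param a,sigma FST line intercept and noise sd; the slope is set so the
#'   largest pairwise distance maps to an FST increment of `bSpan`.
#' @param bSpan FST range spanned by the distance signal.
#' @param heThreshold network threshold (cost units) generating He.
#' @param dHe,tau He slope per log-centrality unit and noise sd.
#' @param seed master seed; all stages derive their own seeds from it.
#' @return a list (class `syntheticWorld`) with elements envLayers,
#'   trueSuitability, occurrences, roads, populations, resistance (true,
#'   with roads), lcd (with-road LCD between populations), fst, he,
#'   trueCfbc, params.
#' @export
simulateWorld <- function(shape = c(40, 40), nLayers = 3,
                          coefficients = c(2.5, 1.2, 0.5),
                          suitableFraction = 0.06, intercept = -5,
                          corrLength = 6, nOcc = 150, occPower = 1,
                          nRoads = 3,
                          roadStyle = "radial", nPop = 8,
                          cellSize = 50, a = 0.05, sigma = 0.01, bSpan = 0.15,
                          heThreshold = 5000, dHe = NULL, tau = 0.02,
                          seed = 1) {
  env <- generateEnvLayers(shape, nLayers, corrLength,
                           seed = deriveSeed(seed, "env"), cellSize = cellSize)
  if (!is.null(suitableFraction)) {
    lin <- Reduce(`+`, Map(function(l, b) b * l@values, env, coefficients))
    intercept <- -as.numeric(quantile(lin, 1 - suitableFraction))
  }
  suit <- makeTrueSuitability(env, coefficients, intercept)
  if (sum(suit@values > 0.5) < nPop)
    stop("true suitability surface has fewer than nPop suitable cells; ",
         "raise the intercept or enlarge the grid")
  occWeights <- suit
  if (occPower != 1) occWeights@values <- occWeights@values^occPower
  occ <- sampleOccurrences(occWeights, nOcc, seed = deriveSeed(seed, "occ"))

  placePops <- function(mask) {
    ## spread populations out as far as the suitable patches allow, so that
    ## sampling sites occupy distinct habitat patches across the landscape
    pops <- NULL
    for (sep in c(floor(min(shape) / 5), floor(min(shape) / 8), 4, 3, 2, 1)) {
      pops <- suppressWarnings(
        sampleOccurrences(mask, nPop, seed = deriveSeed(seed, "pops"),
                          minSep = sep))
      if (nrow(pops) == nPop) break
    }
    if (nrow(pops) < nPop)
      stop("could not place ", nPop, " populations in suitable habitat")
    pops
  }
  suitPop <- suit
  suitPop@values[suitPop@values <= 0.5] <- 0
  if (roadStyle == "ring") {
    ## beltway transects are balanced against the population sites, so the
    ## sites are placed first and the mask is cleared on their cells
    pops <- placePops(suitPop)
    cell <- cellFromXY(suit, pops$x, pops$y)
    nr <- nrow(suit@values)
    rc <- cbind((cell - 1L) %% nr + 1L, (cell - 1L) %/% nr + 1L)
    roads <- generateRoads(shape, nRoads, seed = deriveSeed(seed, "roads"),
                           style = roadStyle, cellSize = cellSize, avoid = rc)
  } else {
    roads <- generateRoads(shape, nRoads, seed = deriveSeed(seed, "roads"),
                           style = roadStyle, cellSize = cellSize)
    suitPop@values[roads@values > 0] <- 0
    pops <- placePops(suitPop)
  }
  pops$id <- paste0("pop", seq_len(nrow(pops)))
  pops$label <- NULL

  resist <- composeResistance(suit, roads)
  lat <- buildLattice(resist)
  lcd <- lcdMatrix(lat, pops)

  nodes <- extractHabitatNodes(suitabilityMask(suit, 0.5), resist)
  hg <- buildThresholdGraph(nodes, resist, threshold = heThreshold)
  cf <- cfbc(hg)
  popNodes <- assignPopulationNodes(pops, hg)
  trueCfbc <- setNames(cf$cfbc[match(popNodes$node, cf$node)], pops$id)
  ## nodes isolated at the generating threshold get a nominal half-unit of
  ## connectivity so the log-linear He model stays defined
  trueCfbc <- pmax(trueCfbc, 0.5)

  b <- bSpan / max(upperVec(dmValues(lcd)))
  lc <- log(trueCfbc)
  d <- if (is.null(dHe)) {
    span <- diff(range(lc))
    if (span > 0) 0.15 / span else 0
  } else dHe
  cHe <- 0.6 - d * mean(lc)
  gen <- simulateGeneticData(lcd, a = a, b = b, sigma = sigma,
                             centrality = trueCfbc, c = cHe, d = d, tau = tau,
                             seed = deriveSeed(seed, "genetics"))
  structure(list(
    envLayers = env, trueSuitability = suit, occurrences = occ, roads = roads,
    populations = pops, resistance = resist, lcd = lcd, fst = gen$fst,
    he = gen$he, trueCfbc = trueCfbc,
    params = list(coefficients = coefficients, intercept = intercept, a = a,
                  b = b, sigma = sigma, heThreshold = heThreshold, c = cHe,
                  d = d, tau = tau, seed = seed)),
    class = "syntheticWorld")
}

## binary mask raster of suitability strictly above a cutoff
suitabilityMask <- function(suitability, cutoff = 0.5) {
  m <- suitability@values
  out <- ifelse(is.na(m), NA, as.numeric(m > cutoff))
  rasterGrid(out, cellSize = suitability@cellSize, origin = suitability@origin)
}

#' Write a synthetic world to disk
#'
#' Layers and masks as ESRI ASCII grids, point sets as CSV, FST as a labeled
#' CSV matrix and He as a two-column CSV.
#'
#' @param world a `syntheticWorld` from [simulateWorld()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeWorld <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(world$envLayers))
    writeAsciiGrid(world$envLayers[[nm]], file.path(dir, paste0(nm, ".asc")))
  writeAsciiGrid(world$trueSuitability, file.path(dir, "true_suitability.asc"))
  writeAsciiGrid(world$roads, file.path(dir, "roads.asc"))
  write.csv(world$occurrences, file.path(dir, "occurrences.csv"), row.names = FALSE)
  write.csv(world$populations, file.path(dir, "populations.csv"), row.names = FALSE)
  writeMatrixCsv(dmValues(world$fst), file.path(dir, "fst.csv"))
  write.csv(data.frame(id = names(world$he), he = as.numeric(world$he)),
            file.path(dir, "he.csv"), row.names = FALSE)
  invisible(dir)
}
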