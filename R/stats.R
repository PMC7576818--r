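#' @include AllClasses.R
NULL

#' Particle density with tile-to-tile dispersion
#'
#' The density is the particle count divided by the scanned area. The
#' dispersion is the tile-to-tile sample standard deviation of per-tile
#' densities, propagated to the lamella scale (divided by the square root
#' of the number of tiles); per-tile densities are already expressed in
#' particles/mm^2, so no further unit scaling is needed. When no tile
#' partition is supplied the dispersion is `NA`.
#'
#' @param table particle table (one row per particle).
#' @param scannedAreaMm2 total scanned area (mm^2), > 0.
#' @param partition optional tile partition: a list with `tileId`
#'   (integer tile assignment per particle, 1-based), `nTiles` and
#'   `tileAreaMm2`; see [stackPartition()].
#' @return named numeric `c(d = , sd = )` in particles/mm^2.
#' @examples
#' tab <- data.frame(area_um2 = rep(100, 400))
#' particleDensity(tab, 244)
#' @export
particleDensity <- function(table, scannedAreaMm2, partition = NULL) {
  if (scannedAreaMm2 <= 0) stop("scanned area must be > 0")
  n <- nrow(table)
  if (n == 0L) return(c(d = 0, sd = 0))
  d <- n / scannedAreaMm2
  sdv <- NA_real_
  if (!is.null(partition)) {
    if (length(partition$tileId) != n)
      stop("partition must assign every particle to a tile")
    counts <- tabulate(partition$tileId, nbins = partition$nTiles)
    dens <- counts / partition$tileAreaMm2
    sdv <- stats::sd(dens) / sqrt(partition$nTiles)
  }
  c(d = d, sd = sdv)
}

#' Build a tile partition for a detected particle table
#'
#' Assigns each particle of a table to the tile of the stack its centroid
#' falls in, and reports the tile count and per-tile area, for use as the
#' `partition` argument of [particleDensity()].
#'
#' @param table particle table with `x_um`, `y_um` columns.
#' @param stack the [TileStack-class] the table was detected on.
#' @return list with `tileId`, `nTiles`, `tileAreaMm2`,
#'   `scannedAreaMm2`.
#' @export
stackPartition <- function(table, stack) {
  scan <- stack@scan
  px <- scan@pixelSizeUm
  tileWUm <- scan@tileWidthPx * px
  tileHUm <- scan@tileHeightPx * px
  gRow <- pmin(pmax(floor(table$y_um / tileHUm) + 1L, 1L), max(stack@grid$row))
  gCol <- pmin(pmax(floor(table$x_um / tileWUm) + 1L, 1L), max(stack@grid$col))
  tileId <- match(paste(gRow, gCol), paste(stack@grid$row, stack@grid$col))
  if (anyNA(tileId))
    stop("some particles fall on tiles absent from the stack")
  areas <- vapply(stack@tiles, function(t)
    prod(dim(t)[1:2]) * px^2 * 1e-6, numeric(1))
  list(tileId = tileId, nTiles = length(stack@tiles),
       tileAreaMm2 = mean(areas), scannedAreaMm2 = sum(areas))
}

#' Coating-by-holder density summary grid
#'
#' Assembles per-cell densities into a summary grid with marginal means:
#' each row (coating) and column (holder) marginal is the arithmetic mean
#' of its cells, with the sample (n-1) standard deviation as dispersion.
#'
#' @param d numeric matrix of densities (particles/mm^2), coatings in
#'   rows, holders in columns, no missing cells.
#' @param sd,nParticles,scannedAreaMm2 optional same-shaped matrices of
#'   per-cell dispersions, counts and areas.
#' @return a [DensitySummary-class].
#' @examples
#' d <- rbind(FDTS = c(1.99, 3.25, 2.12),
#'            SiOCH = c(1.54, 1.39, 1.22),
#'            Parylene = c(1.37, 1.70, 0.90))
#' colnames(d) <- c("RGHS1", "RGHS2", "EPM")
#' summaryGrid(d)
#' @export
summaryGrid <- function(d, sd = NULL, nParticles = NULL,
                        scannedAreaMm2 = NULL) {
  if (!is.matrix(d)) stop("d must be a coatings x holders matrix")
  if (anyNA(d)) stop("missing cell in the density grid")
  blank <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  if (is.null(sd)) sd <- blank
  if (is.null(nParticles)) nParticles <- blank
  if (is.null(scannedAreaMm2)) scannedAreaMm2 <- blank
  new("DensitySummary",
      d = d, sd = sd, nParticles = nParticles,
      scannedAreaMm2 = scannedAreaMm2,
      rowMean = apply(d, 1L, mean), rowSd = apply(d, 1L, stats::sd),
      colMean = apply(d, 2L, mean), colSd = apply(d, 2L, stats::sd))
}

#' Cumulative particle size function
#'
#' Computes the binned cumulative size function of a set of particle
#' areas within a size-class range: at each of the logarithmically spaced
#' bin edges, the percentage of particles with area at or below the edge.
#' The last edge is the class upper bound, so the function ends at 100%.
#'
#' @param areas particle areas (um^2), all within `classRange`.
#' @param classRange length-2 range `c(lower, upper)` (um^2).
#' @param nBins number of bins (>= 2); edges are `nBins + 1` log-spaced
#'   values spanning the range.
#' @param coating,holder optional grouping labels stored on the result.
#' @return a [CumulativeSizeFunction-class].
#' @examples
#' csf <- cumulativeSizeFunction(runif(500, 50, 1500), c(50, 1500))
#' plot(binEdges(csf), cumFraction(csf), log = "x", type = "s")
#' @export
cumulativeSizeFunction <- function(areas, classRange, nBins = 30L,
                                   coating = NA_character_,
                                   holder = NA_character_) {
  if (!length(areas)) stop("empty area list")
  if (nBins < 2L) stop("need at least 2 bins")
  if (any(areas < classRange[1L] | areas > classRange[2L]))
    stop("all areas must lie within the class range")
  edges <- exp(seq(log(classRange[1L]), log(classRange[2L]),
                   length.out = nBins + 1L))
  cf <- 100 * vapply(edges, function(e) mean(areas <= e), numeric(1))
  cf[length(cf)] <- 100     # guard against floating-point edge placement
  new("CumulativeSizeFunction", binEdges = edges, cumFraction = cf,
      coating = as.character(coating), holder = as.character(holder),
      n = length(areas))
}

#' Unpaired two-sample Student t-test
#'
#' Pooled-variance Student t statistic with `n_a + n_b - 2` degrees of
#' freedom and a two-sided p-value. Degenerate samples are handled
#' explicitly: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means gives `p = 0` with a warning.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return named numeric `c(t = , df = , p = )`.
#' @examples
#' tTestUnpaired(c(1, 2, 3), c(4, 5, 7))
#' @export
tTestUnpaired <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must have at least 2 observations")
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1L) * stats::var(a) + (length(b) - 1L) * stats::var(b)) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(c(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: p = 0")
    return(c(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pairwise coating comparison of cumulative size functions
#'
#' For each pair of coatings, collects the per-holder cumulative fractions
#' at the bin edges inside `areaRange` and compares the two collections
#' with the unpaired pooled-variance t-test. The contested range defaults
#' to 200-900 um^2, where coarse-particle size functions differ most
#' between coatings.
#'
#' @param csfs list of [CumulativeSizeFunction-class] objects carrying
#'   `coating` and `holder` labels; at least 2 holders per coating.
#' @param areaRange length-2 area window (um^2) selecting the compared
#'   edges.
#' @return data.frame with columns `coating_a`, `coating_b`, `t`, `df`,
#'   `p`, symmetric under label swap.
#' @export
compareCoatings <- function(csfs, areaRange = c(200, 900)) {
  coatings <- vapply(csfs, function(x) x@coating, character(1))
  holders  <- vapply(csfs, function(x) x@holder, character(1))
  uc <- unique(coatings)
  if (length(uc) < 2L) stop("need at least two coatings to compare")
  pull <- function(coat) {
    idx <- which(coatings == coat)
    if (length(unique(holders[idx])) < 2L)
      stop("need at least 2 holders per coating (", coat, ")")
    unlist(lapply(idx, function(i) {
      sel <- csfs[[i]]@binEdges >= areaRange[1L] &
             csfs[[i]]@binEdges <= areaRange[2L]
      if (!any(sel)) stop("no bin edges inside the comparison range")
      csfs[[i]]@cumFraction[sel]
    }))
  }
  prs <- utils::combn(uc, 2L)
  out <- lapply(seq_len(ncol(prs)), function(j) {
    r <- tTestUnpaired(pull(prs[1L, j]), pull(prs[2L, j]))
    data.frame(coating_a = prs[1L, j], coating_b = prs[2L, j],
               t = r[["t"]], df = r[["df"]], p = r[["p"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extrapolate long-horizon surface coverage
#'
#' Linear extrapolation of the fractional surface coverage: per exposure
#' period each size class contributes `density (mm^-2) x E[area] (um^2) x
#' 1e-6` of the surface, with the expected area taken from the truncated
#' log-normal size law ([truncLnormMean()]). Coverage over `horizonPeriods`
#' periods is the per-period sum scaled linearly, in percent.
#'
#' @param classes data.frame with columns `class`, `density_mm2`, `mode`,
#'   `sigma_log`, `lower`, `upper` (one row per size class).
#' @param horizonPeriods number of exposure periods (>= 0).
#' @return a [CoverageForecast-class].
#' @examples
#' cls <- data.frame(class = c("coarse", "fine"),
#'                   density_mm2 = c(1.6, 3.3),
#'                   mode = c(155, 2), sigma_log = c(0.7, 1.0),
#'                   lower = c(50, 0.5), upper = c(1500, 50))
#' extrapolateCoverage(cls, 40)
#' @export
extrapolateCoverage <- function(classes, horizonPeriods) {
  if (horizonPeriods < 0) stop("horizon must be >= 0")
  if (any(classes$density_mm2 < 0)) stop("densities must be >= 0")
  meanArea <- mapply(truncLnormMean, classes$mode, classes$sigma_log,
                     classes$lower, classes$upper)
  contrib <- 100 * horizonPeriods * classes$density_mm2 * meanArea * 1e-6
  new("CoverageForecast",
      horizonPeriods = horizonPeriods,
      coveragePercent = sum(contrib),
      perClass = data.frame(class = classes$class,
                            density_mm2 = classes$density_mm2,
                            mean_area_um2 = meanArea,
                            coverage_percent = contrib,
                            stringsAsFactors = FALSE))
}

#' Surface cleanliness class by particle concentration
#'
#' Log-decade classification of the areal concentration of particles with
#' equivalent diameter at or above 1 um: the class is the smallest
#' integer `N` such that the density (per m^2) is at most `10^N`,
#' floored at class 0.
#'
#' @param densityPerM2 particles per m^2 (equivalent diameter >= 1 um),
#'   >= 0.
#' @return integer class.
#' @examples
#' cleanlinessClass(1e6)     # class 6
#' cleanlinessClass(1.01e6)  # class 7
#' @export
cleanlinessClass <- function(densityPerM2) {
  if (densityPerM2 < 0) stop("density must be >= 0")
  if (densityPerM2 == 0) return(0L)
  max(0L, as.integer(ceiling(log10(densityPerM2) - 1e-12)))
}

#' Equivalent circular diameter of a particle area
#'
#' @param area projected area (um^2).
#' @return diameter (um) of the circle with the same area.
#' @export
equivalentDiameter <- function(area) 2 * sqrt(area / pi)

#' Most probable size from a particle-area histogram
#'
#' Histogram-mode estimator: fixed-width bins (default 50 um^2, matching
#' the coarse-class binning) anchored at the class lower bound; the mode
#' is the centre of the tallest bin (ties: the smallest such bin).
#'
#' @param areas particle areas (um^2).
#' @param binWidth bin width (um^2).
#' @param anchor lower edge of the first bin.
#' @return the bin-centre estimate of the most probable area.
#' @examples
#' histogramMode(truncLnormSample(1e4, 155, 0.7, 50, 1500))
#' @export
histogramMode <- function(areas, binWidth = 50, anchor = 50) {
  if (!length(areas)) stop("empty area list")
  bin <- floor((areas - anchor) / binWidth)
  counts <- table(bin)
  top <- as.integer(names(counts)[which.max(counts)])
  anchor + (top + 0.5) * binWidth
}
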