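#' @import methods
NULL

.SIZE_CLASSES <- c("fine", "coarse", "macroscopic")
.MORPHOTYPES  <- c("polygon", "fiber", "round", "dividing")
.COATINGS     <- c("FDTS", "SiOCH", "Parylene", "Glass")

#' SceneSpec: parameters of a synthetic contamination scene
#'
#' A `SceneSpec` fixes everything needed to generate one synthetic lamella
#' scene: the physical field extent, per-size-class particle densities,
#' truncated log-normal size laws (parameterised by the distribution mode so
#' a target most-probable area can be planted directly), morphotype mixtures,
#' rendering levels (background, particle, halo, occluder grey values),
#' noise, illumination gradient, and the RNG seed.
#'
#' Size laws are given per class as `c(mode, sigma_log, lower, upper)` in
#' square micrometres; densities in particles per square millimetre.
#'
#' @slot fieldWidthMm,fieldHeightMm physical extent of the scene (mm).
#' @slot densities named numeric, particles/mm^2 for classes
#'   `fine`, `coarse`, `macroscopic`.
#' @slot sizeLaws named list of numeric vectors
#'   `c(mode, sigma_log, lower, upper)` (areas in um^2).
#' @slot morphotypeMix named list (per class) of probabilities over
#'   `polygon`, `fiber`, `round`, `dividing`; each sums to 1.
#' @slot backgroundLevel background grey level (0-255).
#' @slot particleLevel grey level of particle interiors on the blue channel.
#' @slot noiseSigma additive Gaussian noise, grey levels.
#' @slot gradientAmplitude peak-to-peak linear illumination gradient across
#'   the field, grey levels.
#' @slot haloFraction probability that a particle carries a bright drying
#'   halo.
#' @slot haloAmplitude halo brightness above background, grey levels.
#' @slot haloWidthUm radial width of the rendered halo annulus (um).
#' @slot occluderCount number of macroscopic dark occluders to inject.
#' @slot occluderLevel grey level of occluders.
#' @slot occluderExtentUm length-2 range of occluder diameters (um).
#' @slot seed integer RNG seed.
#'
#' @name SceneSpec-class
#' @rdname SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  fieldWidthMm      = "numeric",
  fieldHeightMm     = "numeric",
  densities         = "numeric",
  sizeLaws          = "list",
  morphotypeMix     = "list",
  backgroundLevel   = "numeric",
  particleLevel     = "numeric",
  noiseSigma        = "numeric",
  gradientAmplitude = "numeric",
  haloFraction      = "numeric",
  haloAmplitude     = "numeric",
  haloWidthUm       = "numeric",
  occluderCount     = "integer",
  occluderLevel     = "numeric",
  occluderExtentUm  = "numeric",
  seed              = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@fieldWidthMm <= 0 || object@fieldHeightMm <= 0)
    msg <- c(msg, "field extent must be positive")
  if (!all(.SIZE_CLASSES %in% names(object@densities)))
    msg <- c(msg, "densities must be named for fine, coarse, macroscopic")
  if (any(object@densities < 0))
    msg <- c(msg, "densities must be >= 0")
  for (cl in intersect(names(object@sizeLaws), .SIZE_CLASSES)) {
    law <- object@sizeLaws[[cl]]
    if (length(law) != 4L || any(!is.finite(law[1:3])))
      msg <- c(msg, sprintf("size law for '%s' must be c(mode, sigma_log, lower, upper)", cl))
    else if (!(law[3L] > 0 && law[3L] < law[1L] && law[1L] < law[4L]))
      msg <- c(msg, sprintf("size law for '%s' needs 0 < lower < mode < upper", cl))
    else if (law[2L] < 0)
      msg <- c(msg, sprintf("size law for '%s' needs sigma_log >= 0", cl))
  }
  for (cl in names(object@morphotypeMix)) {
    mix <- object@morphotypeMix[[cl]]
    if (!all(names(mix) %in% .MORPHOTYPES) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-8)
      msg <- c(msg, sprintf("morphotype mix for '%s' must be probabilities over %s summing to 1",
                            cl, paste(.MORPHOTYPES, collapse = "/")))
  }
  if (object@backgroundLevel < 0 || object@backgroundLevel > 255)
    msg <- c(msg, "backgroundLevel must lie in [0, 255]")
  if (object@particleLevel < 0 || object@particleLevel >= object@backgroundLevel)
    msg <- c(msg, "particleLevel must lie in [0, backgroundLevel): particles are dark-on-bright")
  if (object@noiseSigma < 0 || object@gradientAmplitude < 0)
    msg <- c(msg, "noiseSigma and gradientAmplitude must be >= 0")
  if (object@haloFraction < 0 || object@haloFraction > 1)
    msg <- c(msg, "haloFraction must lie in [0, 1]")
  if (object@occluderCount < 0L)
    msg <- c(msg, "occluderCount must be >= 0")
  if (length(object@occluderExtentUm) != 2L ||
      any(object@occluderExtentUm <= 0) ||
      object@occluderExtentUm[1L] > object@occluderExtentUm[2L])
    msg <- c(msg, "occluderExtentUm must be an increasing positive length-2 range")
  if (length(msg)) msg else TRUE
})

#' SceneTruth: planted ground truth of a synthetic scene
#'
#' Holds the particle table planted by [sampleTruth()] (id, centroid in um,
#' true area in um^2, morphotype, halo flag, size class), the injected
#' occluders, and the generating [SceneSpec-class].
#'
#' @slot particles data.frame with columns `id`, `x_um`, `y_um`,
#'   `area_um2`, `morphotype`, `has_halo`, `size_class`.
#' @slot occluders data.frame with columns `x_um`, `y_um`, `extent_um`.
#' @slot spec the generating [SceneSpec-class].
#'
#' @name SceneTruth-class
#' @rdname SceneTruth-class
#' @exportClass SceneTruth
setClass("SceneTruth", representation(
  particles = "data.frame",
  occluders = "data.frame",
  spec      = "SceneSpec"
))

setValidity("SceneTruth", function(object) {
  msg <- character()
  p <- object@particles
  need <- c("id", "x_um", "y_um", "area_um2", "morphotype", "has_halo", "size_class")
  if (!all(need %in% names(p)))
    return(paste("particles must have columns:", paste(need, collapse = ", ")))
  spec <- object@spec
  wUm <- spec@fieldWidthMm * 1e3
  hUm <- spec@fieldHeightMm * 1e3
  if (nrow(p)) {
    if (any(p$x_um < 0 | p$x_um > wUm | p$y_um < 0 | p$y_um > hUm))
      msg <- c(msg, "particle centroids must lie inside the field")
    for (cl in unique(p$size_class)) {
      law <- spec@sizeLaws[[cl]]
      a <- p$area_um2[p$size_class == cl]
      if (!is.null(law) && any(a < law[3L] | a > law[4L]))
        msg <- c(msg, sprintf("areas of class '%s' must lie within its law bounds", cl))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScanConfig: acquisition and detection parameters for one magnification
#'
#' Carries the per-zoom detection parameters: the pixel size, the constant
#' global grey-level threshold applied to the blue channel, the
#' frame-rejection multiplier `k` of the stack-average standard deviation,
#' the size window in um^2, the local-refinement fraction `alpha` of the
#' crop mean, the crop padding, the working channel used for local
#' refinement (`"blue"` or the 8-bit rescaled `"rgbsum"`), and the tile
#' geometry in pixels.
#'
#' @slot zoom `"low"` or `"high"`.
#' @slot pixelSizeUm pixel pitch in um/pixel.
#' @slot globalThreshold constant grey-level threshold (0-255); a pixel is
#'   particle when strictly below it.
#' @slot rejectionK frame-rejection multiplier of the average per-tile
#'   standard deviation.
#' @slot minAreaUm2,maxAreaUm2 detection size window (um^2).
#' @slot localAlpha local threshold = `localAlpha * mean(crop)`.
#' @slot cropMarginPx padding around candidate bounding boxes (pixels).
#' @slot refineChannel working channel for local refinement.
#' @slot tileWidthPx,tileHeightPx tile geometry (pixels).
#'
#' @name ScanConfig-class
#' @rdname ScanConfig-class
#' @exportClass ScanConfig
setClass("ScanConfig", representation(
  zoom            = "character",
  pixelSizeUm     = "numeric",
  globalThreshold = "numeric",
  rejectionK      = "numeric",
  minAreaUm2      = "numeric",
  maxAreaUm2      = "numeric",
  localAlpha      = "numeric",
  cropMarginPx    = "integer",
  refineChannel   = "character",
  tileWidthPx     = "integer",
  tileHeightPx    = "integer"
))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (!object@zoom %in% c("low", "high"))
    msg <- c(msg, "zoom must be 'low' or 'high'")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@globalThreshold < 0 || object@globalThreshold > 255)
    msg <- c(msg, "globalThreshold must lie in [0, 255]")
  if (object@minAreaUm2 >= object@maxAreaUm2)
    msg <- c(msg, "minAreaUm2 must be < maxAreaUm2")
  if (object@localAlpha <= 0 || object@localAlpha > 1)
    msg <- c(msg, "localAlpha must lie in (0, 1]")
  if (!object@refineChannel %in% c("blue", "rgbsum"))
    msg <- c(msg, "refineChannel must be 'blue' or 'rgbsum'")
  if (object@tileWidthPx < 8L || object@tileHeightPx < 8L)
    msg <- c(msg, "tile geometry unreasonably small")
  if (length(msg)) msg else TRUE
})

#' TileStack: an ordered mosaic of 8-bit RGB tiles with metadata
#'
#' Tiles are stored as integer arrays `height x width x 3` with values in
#' 0-255, on a (row, col) mosaic grid; the last row/column may hold partial
#' (smaller) tiles. Metadata identify the holder, lamella and coating, and
#' a [ScanConfig-class] fixes the acquisition parameters.
#'
#' @slot tiles list of integer arrays `h x w x 3` (0-255).
#' @slot grid data.frame with columns `row`, `col` (1-based grid positions,
#'   one per tile, unique).
#' @slot holder,lamella sample identifiers.
#' @slot coating one of FDTS, SiOCH, Parylene, Glass.
#' @slot scan a [ScanConfig-class].
#'
#' @name TileStack-class
#' @rdname TileStack-class
#' @exportClass TileStack
setClass("TileStack", representation(
  tiles   = "list",
  grid    = "data.frame",
  holder  = "character",
  lamella = "character",
  coating = "character",
  scan    = "ScanConfig"
))

setValidity("TileStack", function(object) {
  msg <- character()
  n <- length(object@tiles)
  if (!all(c("row", "col") %in% names(object@grid)) || nrow(object@grid) != n)
    return("grid must have one (row, col) entry per tile")
  if (anyDuplicated(object@grid[, c("row", "col")]))
    msg <- c(msg, "grid positions must be unique")
  if (!object@coating %in% .COATINGS)
    msg <- c(msg, paste("coating must be one of", paste(.COATINGS, collapse = ", ")))
  full <- c(object@scan@tileHeightPx, object@scan@tileWidthPx)
  maxR <- if (n) max(object@grid$row) else 0L
  maxC <- if (n) max(object@grid$col) else 0L
  for (i in seq_len(n)) {
    tl <- object@tiles[[i]]
    if (!is.array(tl) || length(dim(tl)) != 3L || dim(tl)[3L] != 3L) {
      msg <- c(msg, "tiles must be h x w x 3 arrays"); break
    }
    if (!is.integer(tl) || min(tl) < 0L || max(tl) > 255L) {
      msg <- c(msg, "tiles must be 8-bit (integer 0-255)"); break
    }
    d <- dim(tl)[1:2]
    okH <- d[1L] == full[1L] || (object@grid$row[i] == maxR && d[1L] < full[1L])
    okW <- d[2L] == full[2L] || (object@grid$col[i] == maxC && d[2L] < full[2L])
    if (!(okH && okW)) {
      msg <- c(msg, "tiles must share dimensions (partial tiles only in the last row/column)")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' DensitySummary: coating-by-holder particle density grid
#'
#' Stores per-cell densities (particles/mm^2) with dispersion, particle
#' counts and scanned areas, plus row (coating) and column (holder)
#' marginal means and sample standard deviations.
#'
#' @slot d,sd,nParticles,scannedAreaMm2 matrices (coating x holder).
#' @slot rowMean,rowSd,colMean,colSd named numeric marginals.
#'
#' @name DensitySummary-class
#' @rdname DensitySummary-class
#' @exportClass DensitySummary
setClass("DensitySummary", representation(
  d              = "matrix",
  sd             = "matrix",
  nParticles     = "matrix",
  scannedAreaMm2 = "matrix",
  rowMean        = "numeric",
  rowSd          = "numeric",
  colMean        = "numeric",
  colSd          = "numeric"
))

#' CumulativeSizeFunction: binned cumulative fraction of particle areas
#'
#' `cumFraction[i]` is the percentage of particles with area at or below
#' `binEdges[i]`; edges ascend within the size-class range and the final
#' value is 100.
#'
#' @slot binEdges ascending area edges (um^2).
#' @slot cumFraction percentages in [0, 100], non-decreasing.
#' @slot coating,holder grouping labels (may be `NA`).
#' @slot n number of particles summarised.
#'
#' @name CumulativeSizeFunction-class
#' @rdname CumulativeSizeFunction-class
#' @exportClass CumulativeSizeFunction
setClass("CumulativeSizeFunction", representation(
  binEdges    = "numeric",
  cumFraction = "numeric",
  coating     = "character",
  holder      = "character",
  n           = "integer"
))

setValidity("CumulativeSizeFunction", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@cumFraction))
    msg <- c(msg, "binEdges and cumFraction must have equal length")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly ascending")
  if (is.unsorted(object@cumFraction))
    msg <- c(msg, "cumFraction must be non-decreasing")
  if (any(object@cumFraction < 0 | object@cumFraction > 100))
    msg <- c(msg, "cumFraction must lie in [0, 100]")
  if (length(object@cumFraction) &&
      abs(object@cumFraction[length(object@cumFraction)] - 100) > 1e-9)
    msg <- c(msg, "final cumulative fraction must be 100")
  if (length(msg)) msg else TRUE
})

#' CoverageForecast: long-horizon surface coverage extrapolation
#'
#' Linear extrapolation of the fractional area covered by deposited
#' particles over a number of exposure periods, from per-class densities
#' and expected areas of the truncated log-normal size laws.
#'
#' @slot horizonPeriods number of exposure periods extrapolated over.
#' @slot coveragePercent forecast coverage, percent of the surface.
#' @slot perClass data.frame with columns `class`, `density_mm2`,
#'   `mean_area_um2`, `coverage_percent`.
#'
#' @name CoverageForecast-class
#' @rdname CoverageForecast-class
#' @exportClass CoverageForecast
setClass("CoverageForecast", representation(
  horizonPeriods  = "numeric",
  coveragePercent = "numeric",
  perClass        = "data.frame"
))
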