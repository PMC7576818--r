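#' @include AllClasses.R
NULL

#' Accessors for scene and stack objects
#'
#' @param x an object of the corresponding class.
#' @return `particles()` and `occluders()` return data.frames;
#'   `sceneSpecOf()` the generating [SceneSpec-class]; `tiles()` the list
#'   of tile arrays; `tileGrid()` the (row, col) grid; `scanConfigOf()`
#'   the [ScanConfig-class]; `coating()`, `holder()`, `lamella()` the
#'   metadata strings; `coveragePercent()` the forecast coverage;
#'   `binEdges()` / `cumFraction()` the cumulative-size-function vectors;
#'   `densityGrid()` the coating-by-holder density matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setGeneric("occluders", function(x) standardGeneric("occluders"))
#' @rdname accessors
#' @export
setGeneric("sceneSpecOf", function(x) standardGeneric("sceneSpecOf"))
#' @rdname accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setGeneric("tileGrid", function(x) standardGeneric("tileGrid"))
#' @rdname accessors
#' @export
setGeneric("scanConfigOf", function(x) standardGeneric("scanConfigOf"))
#' @rdname accessors
#' @export
setGeneric("coating", function(x) standardGeneric("coating"))
#' @rdname accessors
#' @export
setGeneric("holder", function(x) standardGeneric("holder"))
#' @rdname accessors
#' @export
setGeneric("lamella", function(x) standardGeneric("lamella"))
#' @rdname accessors
#' @export
setGeneric("coveragePercent", function(x) standardGeneric("coveragePercent"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("cumFraction", function(x) standardGeneric("cumFraction"))
#' @rdname accessors
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

setMethod("particles", "SceneTruth", function(x) x@particles)
setMethod("occluders", "SceneTruth", function(x) x@occluders)
setMethod("sceneSpecOf", "SceneTruth", function(x) x@spec)
setMethod("tiles", "TileStack", function(x) x@tiles)
setMethod("tileGrid", "TileStack", function(x) x@grid)
setMethod("scanConfigOf", "TileStack", function(x) x@scan)
setMethod("coating", "TileStack", function(x) x@coating)
setMethod("holder", "TileStack", function(x) x@holder)
setMethod("lamella", "TileStack", function(x) x@lamella)
setMethod("coveragePercent", "CoverageForecast", function(x) x@coveragePercent)
setMethod("binEdges", "CumulativeSizeFunction", function(x) x@binEdges)
setMethod("cumFraction", "CumulativeSizeFunction", function(x) x@cumFraction)
setMethod("densityGrid", "DensitySummary", function(x) x@d)

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@fieldWidthMm, "x", object@fieldHeightMm, "mm field\n")
  cat("  densities (/mm^2):",
      paste(sprintf("%s=%.3g", names(object@densities), object@densities),
            collapse = ", "), "\n")
  for (cl in names(object@sizeLaws)) {
    law <- object@sizeLaws[[cl]]
    cat(sprintf("  %s law: mode %.3g um^2, sigma_log %.2f on [%.3g, %.3g]\n",
                cl, law[1L], law[2L], law[3L], law[4L]))
  }
  cat(sprintf("  background %g, particle %g, noise sd %g, gradient %g\n",
              object@backgroundLevel, object@particleLevel,
              object@noiseSigma, object@gradientAmplitude))
  cat(sprintf("  halos: fraction %.2f, +%g grey; occluders: %d; seed %d\n",
              object@haloFraction, object@haloAmplitude,
              object@occluderCount, object@seed))
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@particles), "planted particles,",
      nrow(object@occluders), "occluders\n")
  if (nrow(object@particles))
    print(table(object@particles$size_class, object@particles$morphotype))
})

setMethod("show", "ScanConfig", function(object) {
  cat(sprintf("ScanConfig (%s zoom): %.3g um/px, global threshold %g, k = %g\n",
              object@zoom, object@pixelSizeUm, object@globalThreshold,
              object@rejectionK))
  cat(sprintf("  size window [%g, %g] um^2, alpha %.2f, refine on %s, tiles %dx%d px\n",
              object@minAreaUm2, object@maxAreaUm2, object@localAlpha,
              object@refineChannel, object@tileWidthPx, object@tileHeightPx))
})

setMethod("show", "TileStack", function(object) {
  cat(sprintf("TileStack: %d tiles (%s zoom), coating %s, holder %s, lamella %s\n",
              length(object@tiles), object@scan@zoom, object@coating,
              object@holder, object@lamella))
})

setMethod("show", "DensitySummary", function(object) {
  cat("DensitySummary (particles/mm^2):\n")
  m <- cbind(object@d, `<d>` = object@rowMean)
  m <- rbind(m, `<d>` = c(object@colMean, NA))
  print(round(m, 2))
})

setMethod("show", "CumulativeSizeFunction", function(object) {
  cat(sprintf("CumulativeSizeFunction: %d particles (%s / %s), %d edges on [%.3g, %.3g] um^2\n",
              object@n, object@coating, object@holder, length(object@binEdges),
              min(object@binEdges), max(object@binEdges)))
})

setMethod("show", "CoverageForecast", function(object) {
  cat(sprintf("CoverageForecast: %.3g%% after %g exposure periods\n",
              object@coveragePercent, object@horizonPeriods))
  print(object@perClass, row.names = FALSE)
})
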