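#' @include AllClasses.R
NULL

# ---- tile stacks ---------------------------------------------------------

#' Read and write tile stacks
#'
#' A tile stack on disk is a directory of 8-bit RGB TIFF files, one per
#' tile, named `{scene}_{row}_{col}.tif`, with a JSON metadata sidecar
#' (`{scene}_meta.json`) holding the holder/lamella/coating labels and the
#' [ScanConfig-class]. `readTileStack()` also accepts PNG tiles.
#'
#' @param stack a [TileStack-class].
#' @param dir directory to write into / read from.
#' @param scene scene name used as the file prefix.
#' @return `writeTileStack()` returns `dir` invisibly; `readTileStack()`
#'   returns a [TileStack-class].
#' @export
writeTileStack <- function(stack, dir, scene = "scene") {
  stopifnot(is(stack, "TileStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(stack@tiles)) {
    fn <- file.path(dir, sprintf("%s_%d_%d.tif", scene,
                                 stack@grid$row[i], stack@grid$col[i]))
    tiff::writeTIFF(stack@tiles[[i]] / 255, fn, bits.per.sample = 8L)
  }
  meta <- list(scene = scene, holder = stack@holder, lamella = stack@lamella,
               coating = stack@coating, scan = .scanToList(stack@scan),
               grid = stack@grid)
  jsonlite::write_json(meta, file.path(dir, paste0(scene, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeTileStack
#' @export
readTileStack <- function(dir, scene = "scene") {
  meta <- jsonlite::read_json(file.path(dir, paste0(scene, "_meta.json")),
                              simplifyVector = TRUE)
  scan <- .scanFromList(meta$scan)
  grid <- as.data.frame(meta$grid)
  tilesList <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    base <- file.path(dir, sprintf("%s_%d_%d", scene, grid$row[i], grid$col[i]))
    img <- if (file.exists(paste0(base, ".tif"))) {
      tiff::readTIFF(paste0(base, ".tif"))
    } else if (file.exists(paste0(base, ".png"))) {
      png::readPNG(paste0(base, ".png"))
    } else stop("missing tile image: ", base, ".{tif,png}")
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    tilesList[[i]] <- array(as.integer(round(img[, , 1:3] * 255)),
                            dim = c(dim(img)[1:2], 3L))
  }
  new("TileStack", tiles = tilesList, grid = grid, holder = meta$holder,
      lamella = meta$lamella, coating = meta$coating, scan = scan)
}

.scanToList <- function(scan) {
  list(zoom = scan@zoom, pixel_size_um = scan@pixelSizeUm,
       global_threshold = scan@globalThreshold, rejection_k = scan@rejectionK,
       min_area_um2 = scan@minAreaUm2, max_area_um2 = scan@maxAreaUm2,
       local_alpha = scan@localAlpha, crop_margin_px = scan@cropMarginPx,
       refine_channel = scan@refineChannel,
       tile_width_px = scan@tileWidthPx, tile_height_px = scan@tileHeightPx)
}

.scanFromList <- function(x) {
  scanConfig(zoom = x$zoom, pixelSizeUm = x$pixel_size_um,
             globalThreshold = x$global_threshold, rejectionK = x$rejection_k,
             minAreaUm2 = x$min_area_um2, maxAreaUm2 = x$max_area_um2,
             localAlpha = x$local_alpha, cropMarginPx = x$crop_margin_px,
             refineChannel = x$refine_channel,
             tileWidthPx = x$tile_width_px, tileHeightPx = x$tile_height_px)
}

# ---- scene specs and truth ----------------------------------------------

#' Read and write scene specifications and ground truth
#'
#' [SceneSpec-class] objects round-trip through JSON; [SceneTruth-class]
#' particle tables through CSV with header
#' `id,x_um,y_um,area_um2,morphotype,has_halo` (plus `size_class`), with
#' occluders in a companion `*_occluders.csv` when present.
#'
#' @param spec a [SceneSpec-class].
#' @param truth a [SceneTruth-class].
#' @param path file path.
#' @return readers return the reconstructed object; writers their `path`,
#'   invisibly.
#' @export
writeSceneSpec <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  x <- list(field_width_mm = spec@fieldWidthMm,
            field_height_mm = spec@fieldHeightMm,
            density_per_class = as.list(spec@densities),
            size_law_per_class = lapply(spec@sizeLaws, function(l)
              list(mode = unname(l[1L]), sigma_log = unname(l[2L]),
                   lower = unname(l[3L]), upper = unname(l[4L]))),
            morphotype_mix = lapply(spec@morphotypeMix, as.list),
            background_level = spec@backgroundLevel,
            particle_level = spec@particleLevel,
            noise_sigma = spec@noiseSigma,
            gradient_amplitude = spec@gradientAmplitude,
            halo_fraction = spec@haloFraction,
            halo_amplitude = spec@haloAmplitude,
            halo_width_um = spec@haloWidthUm,
            occluder_count = spec@occluderCount,
            occluder_level = spec@occluderLevel,
            occluder_extent_um = spec@occluderExtentUm,
            seed = spec@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSceneSpec
#' @export
readSceneSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sceneSpec(
    fieldWidthMm = x$field_width_mm, fieldHeightMm = x$field_height_mm,
    densities = unlist(x$density_per_class),
    sizeLaws = lapply(x$size_law_per_class, function(l)
      c(mode = l$mode, sigma_log = l$sigma_log, lower = l$lower,
        upper = l$upper)),
    morphotypeMix = lapply(x$morphotype_mix, unlist),
    backgroundLevel = x$background_level, particleLevel = x$particle_level,
    noiseSigma = x$noise_sigma, gradientAmplitude = x$gradient_amplitude,
    haloFraction = x$halo_fraction, haloAmplitude = x$halo_amplitude,
    haloWidthUm = x$halo_width_um, occluderCount = x$occluder_count,
    occluderLevel = x$occluder_level,
    occluderExtentUm = x$occluder_extent_um, seed = x$seed)
}

#' @rdname writeSceneSpec
#' @export
writeSceneTruth <- function(truth, path) {
  stopifnot(is(truth, "SceneTruth"))
  utils::write.csv(truth@particles, path, row.names = FALSE)
  if (nrow(truth@occluders))
    utils::write.csv(truth@occluders,
                     sub("\\.csv$", "_occluders.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname writeSceneSpec
#' @param spec the generating [SceneSpec-class] (readers cannot recover it
#'   from the CSV alone).
#' @export
readSceneTruth <- function(path, spec) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  occPath <- sub("\\.csv$", "_occluders.csv", path)
  occ <- if (file.exists(occPath)) utils::read.csv(occPath) else
    data.frame(x_um = numeric(), y_um = numeric(), extent_um = numeric())
  new("SceneTruth", particles = p, occluders = occ, spec = spec)
}

# ---- particle tables -----------------------------------------------------

.PARTICLE_COLS <- c("id", "holder", "lamella", "coating", "zoom",
                    "x_um", "y_um", "area_um2", "elongation",
                    "touches_border", "has_halo")

#' Read and write particle tables
#'
#' Particle tables are CSV files with the canonical column set
#' `id,holder,lamella,coating,zoom,x_um,y_um,area_um2,elongation,touches_border,has_halo`
#' plus any classification columns (`size_class`, `morphotype`). Leading
#' `#` comment lines (provenance stamps) are skipped on read.
#'
#' @param table particle table.
#' @param path CSV path.
#' @param stamp optional character vector written as leading `#` comment
#'   lines.
#' @return `readParticleTable()` returns a data.frame.
#' @export
writeParticleTable <- function(table, path, stamp = NULL) {
  keep <- intersect(c(.PARTICLE_COLS, "size_class", "morphotype"),
                    names(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  utils::write.csv(table[, keep, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeParticleTable
#' @export
readParticleTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
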