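#' @include detection.R
NULL

#' Assign particle areas to size classes
#'
#' Size classes partition the detectable area range by projected area:
#' fine `[0.5, 50)` um^2, coarse `[50, 1500]` um^2, macroscopic
#' `(1500, Inf)` um^2. The boundary convention is half-open at 50 and
#' closed at 1500, which keeps the conventional "50-1500" coarse count
#' definition intact.
#'
#' @param area numeric vector of areas (um^2); values below the 0.5 um^2
#'   detection floor are an error.
#' @return character vector in `fine`, `coarse`, `macroscopic`.
#' @examples
#' sizeClass(c(0.5, 49.999, 50, 155, 1500, 1500.1))
#' @export
sizeClass <- function(area) {
  if (any(area < 0.5))
    stop("areas below the 0.5 um^2 detection floor cannot be classified")
  out <- character(length(area))
  out[area < 50] <- "fine"
  out[area >= 50 & area <= 1500] <- "coarse"
  out[area > 1500] <- "macroscopic"
  out
}

#' Flag fiber morphotypes by elongation ratio
#'
#' Fibers (ribbon-like particles) separate cleanly from compact particles
#' by the elongation ratio of the equivalent ellipse; a particle is
#' flagged `fiber` when its elongation is at or above the cut.
#'
#' @param elongation numeric vector of elongation ratios (>= 1).
#' @param cut elongation threshold, default 5.
#' @return character vector in `fiber`, `compact`.
#' @examples
#' morphotypeFlag(c(1, 4.9, 5, 8))
#' @export
morphotypeFlag <- function(elongation, cut = 5) {
  ifelse(elongation >= cut, "fiber", "compact")
}

#' Detect a bright drying halo around a particle
#'
#' Tests whether the mean blue intensity in an annulus extending 1 to
#' `ringWidthPx` pixels beyond the particle boundary exceeds the tile
#' background mean by `k` times the tile background standard deviation.
#' Background statistics are taken over the tile pixels at or above the
#' global segmentation threshold (i.e. non-particle pixels). If the
#' annulus would fall outside the tile the flag is `FALSE` with a reason.
#'
#' @param tile 8-bit RGB array.
#' @param pixels list with integer vectors `rows`, `cols`: the particle's
#'   tile-local pixel coordinates.
#' @param scan a [ScanConfig-class] (supplies the background threshold).
#' @param ringWidthPx annulus width in pixels.
#' @param k multiplier of the background standard deviation.
#' @return logical flag with attribute `reason` when `FALSE` for a
#'   structural cause.
#' @export
detectHalo <- function(tile, pixels, scan, ringWidthPx = 5L, k = 2) {
  .check8bit(tile)
  d <- dim(tile)
  rows <- pixels$rows; cols <- pixels$cols
  if (!length(rows)) stop("empty particle pixel set")
  pad <- as.integer(ringWidthPx) + 1L
  r1 <- min(rows) - pad; r2 <- max(rows) + pad
  c1 <- min(cols) - pad; c2 <- max(cols) + pad
  m <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
  m[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- TRUE
  dil <- EBImage::dilate(m * 1, EBImage::makeBrush(2L * as.integer(ringWidthPx) + 1L, "disc")) > 0.5
  ring <- dil & !m
  # clip the annulus to the tile; give up only when too little of it is left
  fullRing <- sum(ring)
  ridx <- which(ring, arr.ind = TRUE)
  inTile <- ridx[, 1L] + r1 - 1L >= 1L & ridx[, 1L] + r1 - 1L <= d[1L] &
            ridx[, 2L] + c1 - 1L >= 1L & ridx[, 2L] + c1 - 1L <= d[2L]
  if (sum(inTile) < fullRing / 4) {
    out <- FALSE
    attr(out, "reason") <- "annulus falls outside the tile"
    return(out)
  }
  ring[ridx[!inTile, , drop = FALSE]] <- FALSE
  blue <- .blue(tile)
  bgv <- blue[blue >= scan@globalThreshold]
  if (length(bgv) < 2L) {
    out <- FALSE
    attr(out, "reason") <- "no background pixels to compare against"
    return(out)
  }
  ringIdx <- which(ring, arr.ind = TRUE)
  ringVals <- blue[cbind(ringIdx[, 1L] + r1 - 1L, ringIdx[, 2L] + c1 - 1L)]
  mean(ringVals) > mean(bgv) + k * stats::sd(bgv)
}

#' Classify a detected particle table
#'
#' Adds `size_class` (fine / coarse / macroscopic), `morphotype`
#' (fiber / compact by elongation) and fills `has_halo` by testing each
#' particle's annulus against the tile background (when the stack and the
#' detection masks are available; particles merged across tiles keep
#' `has_halo = NA`).
#'
#' @param table particle table from [runDetection()].
#' @param stack the [TileStack-class] the table was detected on (optional;
#'   required for halo flags).
#' @param elongationCut fiber elongation threshold.
#' @param ringWidthPx,haloK halo-detection parameters.
#' @return the table with `size_class`, `morphotype` and `has_halo`
#'   columns filled.
#' @export
classifyParticles <- function(table, stack = NULL, elongationCut = 5,
                              ringWidthPx = 5L, haloK = 2) {
  table$size_class <- if (nrow(table)) sizeClass(table$area_um2) else character()
  table$morphotype <- if (nrow(table)) morphotypeFlag(table$elongation, elongationCut)
                      else character()
  masks <- attr(table, "masks")
  if (!is.null(stack) && !is.null(masks) && nrow(table)) {
    scan <- stack@scan
    halo <- rep(NA, nrow(table))
    for (i in seq_len(nrow(table))) {
      m <- masks[[i]]
      if (is.na(m$tile)) next                      # merged across tiles
      tb <- m$tileBounds
      ti <- which(stack@grid$row == m$gridRow & stack@grid$col == m$gridCol)
      halo[i] <- as.logical(detectHalo(
        stack@tiles[[ti]],
        list(rows = m$rows - tb[1L] + 1L, cols = m$cols - tb[3L] + 1L),
        scan, ringWidthPx = ringWidthPx, k = haloK))
    }
    table$has_halo <- halo
  }
  table
}
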