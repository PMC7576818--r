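#' @include AllClasses.R
NULL

#' Construct a per-magnification scan configuration
#'
#' Returns a [ScanConfig-class] with the defaults of the two-zoom
#' acquisition: at low zoom 1.55 um/px with a 50-1500 um^2 size window, at
#' high zoom 0.155 um/px with a 0.5-50 um^2 window (both windows give the
#' same ~21-pixel minimum particle footprint). The global segmentation
#' threshold is a constant grey level of 75 applied strictly (`<`) to the
#' blue channel; frame rejection uses `k = 2` times the stack-average
#' per-tile standard deviation; local refinement thresholds at
#' `alpha = 0.6` times the crop mean, on the blue channel at low zoom and
#' on the 8-bit rescaled R+G+B sum at high zoom.
#'
#' @param zoom `"low"` or `"high"`.
#' @param pixelSizeUm,globalThreshold,rejectionK,minAreaUm2,maxAreaUm2,localAlpha,cropMarginPx,refineChannel,tileWidthPx,tileHeightPx
#'   overrides of the per-zoom defaults (see [ScanConfig-class]).
#' @return a validated [ScanConfig-class].
#' @examples
#' scanConfig("low")
#' scanConfig("high", tileWidthPx = 128, tileHeightPx = 128)
#' @export
scanConfig <- function(zoom = c("low", "high"),
                       pixelSizeUm = NULL,
                       globalThreshold = 75,
                       rejectionK = 2,
                       minAreaUm2 = NULL,
                       maxAreaUm2 = NULL,
                       localAlpha = 0.6,
                       cropMarginPx = 10L,
                       refineChannel = NULL,
                       tileWidthPx = 256L,
                       tileHeightPx = 256L) {
  zoom <- match.arg(zoom)
  if (is.null(pixelSizeUm))   pixelSizeUm   <- if (zoom == "low") 1.55 else 0.155
  if (is.null(minAreaUm2))    minAreaUm2    <- if (zoom == "low") 50   else 0.5
  if (is.null(maxAreaUm2))    maxAreaUm2    <- if (zoom == "low") 1500 else 50
  if (is.null(refineChannel)) refineChannel <- if (zoom == "low") "blue" else "rgbsum"
  new("ScanConfig", zoom = zoom, pixelSizeUm = pixelSizeUm,
      globalThreshold = globalThreshold, rejectionK = rejectionK,
      minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2,
      localAlpha = localAlpha, cropMarginPx = as.integer(cropMarginPx),
      refineChannel = refineChannel, tileWidthPx = as.integer(tileWidthPx),
      tileHeightPx = as.integer(tileHeightPx))
}

.blue <- function(tile) tile[, , 3L]

.check8bit <- function(tile) {
  if (!is.array(tile) || length(dim(tile)) != 3L || dim(tile)[3L] != 3L)
    stop("tile must be an h x w x 3 RGB array")
  if (!is.integer(tile) || min(tile) < 0L || max(tile) > 255L)
    stop("tile must be 8-bit (integer values in 0-255)")
  invisible(TRUE)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged through the components of their adjacency
# graph.
.label8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask))
  nlab <- max(lab)
  if (nlab > 1L && nrow(mask) > 1L && ncol(mask) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(edges)) {
      g <- igraph::make_graph(edges = as.vector(t(unique(edges))),
                              n = nlab, directed = FALSE)
      mem <- as.integer(igraph::components(g)$membership)
      lab[lab > 0L] <- mem[lab[lab > 0L]]
    }
  }
  lab
}

# drop labels below a pixel-count floor and renumber consecutively
.filterRelabel <- function(lab, minPx) {
  if (max(lab) == 0L) return(lab)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * 1 >= minPx)
  if (!length(keep)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(length(counts))
  map[keep] <- seq_along(keep)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Reject frames dominated by macroscopic objects
#'
#' Quality control for tile stacks: tiles containing macroscopic objects
#' whose shadows mask the small particles are removed before segmentation.
#' The per-tile mean of the blue channel is compared against the
#' stack-wide median of tile means (the background level); a tile is
#' rejected when `|mean - median| > k x sigma_bar`, where `sigma_bar` is
#' the average over tiles of the per-tile standard deviation. The
#' criterion is two-sided: dark occluders pull the tile mean below the
#' median, bright artefacts push it above. Statistics are computed once
#' from the full stack, not iteratively.
#'
#' @param stack a non-empty [TileStack-class].
#' @param k multiplier of the average standard deviation; defaults to the
#'   stack's `rejectionK` (2).
#' @return list with `kept` (the pruned [TileStack-class]), `rejected`
#'   (integer indices into the input stack), and the statistics
#'   `tileMeans`, `medianMean`, `avgSd`.
#' @export
rejectFrames <- function(stack, k = NULL) {
  stopifnot(is(stack, "TileStack"))
  if (!length(stack@tiles)) stop("empty tile stack")
  if (is.null(k)) k <- stack@scan@rejectionK
  means <- vapply(stack@tiles, function(t) mean(.blue(t)), numeric(1))
  sds   <- vapply(stack@tiles, function(t) stats::sd(.blue(t)), numeric(1))
  med <- stats::median(means)
  avgSd <- mean(sds)
  rejected <- which(abs(means - med) > k * avgSd)
  kept <- stack
  if (length(rejected)) {
    kept@tiles <- stack@tiles[-rejected]
    kept@grid  <- stack@grid[-rejected, , drop = FALSE]
    rownames(kept@grid) <- NULL
  }
  list(kept = kept, rejected = rejected, tileMeans = means,
       medianMean = med, avgSd = avgSd)
}

#' Global segmentation of one tile
#'
#' Thresholds the blue channel at the constant global threshold (a pixel
#' is particle when strictly below it), labels connected components with
#' 8-connectivity, and discards components whose area (pixel count times
#' pixel area) falls below the zoom's minimum particle area.
#'
#' @param tile an 8-bit RGB array `h x w x 3`.
#' @param scan a [ScanConfig-class].
#' @return integer label matrix (0 = background, labels consecutive).
#' @export
segmentGlobal <- function(tile, scan) {
  .check8bit(tile)
  mask <- .blue(tile) < scan@globalThreshold
  lab <- .label8(mask)
  minPx <- scan@minAreaUm2 / scan@pixelSizeUm^2
  .filterRelabel(lab, minPx)
}

#' Local refinement of a candidate crop
#'
#' Extracts a crop around a candidate bounding box (padded by
#' `cropMarginPx`, clipped to the tile), computes the local threshold
#' `T = alpha x mean(crop)` on the working channel (blue, or the 8-bit
#' rescaled per-pixel R+G+B sum, per `scan@refineChannel`), thresholds
#' strictly below `T`, and restricts the result to the connected component
#' overlapping the candidate box. An empty refined mask is not an error:
#' the candidate is dropped with a reason.
#'
#' @param tile an 8-bit RGB array.
#' @param bbox candidate bounding box `c(rmin, rmax, cmin, cmax)` in
#'   tile-local 1-based pixels.
#' @param scan a [ScanConfig-class].
#' @return list with `mask` (logical matrix over the crop), `r1`, `c1`
#'   (tile-local 1-based origin of the crop), `dropped` (logical) and
#'   `reason`.
#' @export
refineCrop <- function(tile, bbox, scan) {
  .check8bit(tile)
  d <- dim(tile)
  if (bbox[1L] < 1L || bbox[3L] < 1L || bbox[2L] > d[1L] || bbox[4L] > d[2L])
    stop("candidate bbox lies outside the tile")
  m <- scan@cropMarginPx
  r1 <- max(1L, bbox[1L] - m); r2 <- min(d[1L], bbox[2L] + m)
  c1 <- max(1L, bbox[3L] - m); c2 <- min(d[2L], bbox[4L] + m)
  work <- if (scan@refineChannel == "blue") {
    tile[r1:r2, c1:c2, 3L]
  } else {
    (tile[r1:r2, c1:c2, 1L] + tile[r1:r2, c1:c2, 2L] +
       tile[r1:r2, c1:c2, 3L]) / 3
  }
  thr <- scan@localAlpha * mean(work)
  mask <- work < thr
  drop <- function(reason)
    list(mask = NULL, r1 = r1, c1 = c1, dropped = TRUE, reason = reason)
  if (!any(mask)) return(drop("no pixel below local threshold"))
  lab <- .label8(mask)
  # candidate box in crop coordinates
  cr <- (bbox[1L]:bbox[2L]) - r1 + 1L
  cc <- (bbox[3L]:bbox[4L]) - c1 + 1L
  inBox <- lab[cr, cc, drop = FALSE]
  inBox <- inBox[inBox > 0L]
  if (!length(inBox)) return(drop("no component overlaps the candidate"))
  winner <- as.integer(names(which.max(table(inBox))))
  list(mask = lab == winner, r1 = r1, c1 = c1, dropped = FALSE, reason = NA_character_)
}

# moment measurement of a pixel set (tile- or mosaic-level 1-based px).
# The 1/12 term is the second moment of a unit pixel; it makes the
# equivalent-ellipse axes exact for solid rectangles and keeps 1-px-wide
# masks finite.
.measurePixels <- function(rows, cols, scan, tileBoundsPx = NULL) {
  n <- length(rows)
  px <- scan@pixelSizeUm
  cx <- mean(cols); cy <- mean(rows)
  mu20 <- mean((cols - cx)^2) + 1 / 12
  mu02 <- mean((rows - cy)^2) + 1 / 12
  mu11 <- mean((cols - cx) * (rows - cy))
  tr2 <- (mu20 + mu02) / 2
  det <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det; l2 <- max(tr2 - det, .Machine$double.eps)
  touches <- if (is.null(tileBoundsPx)) FALSE else
    any(rows == tileBoundsPx[1L] | rows == tileBoundsPx[2L] |
        cols == tileBoundsPx[3L] | cols == tileBoundsPx[4L])
  data.frame(
    x_um = (cx - 0.5) * px, y_um = (cy - 0.5) * px,
    area_um2 = n * px^2,
    elongation = sqrt(l1 / l2),
    xmin_um = (min(cols) - 1) * px, xmax_um = max(cols) * px,
    ymin_um = (min(rows) - 1) * px, ymax_um = max(rows) * px,
    touches_border = touches, n_px = n)
}

#' Measure a single-particle mask
#'
#' Computes the particle descriptors from a binary mask: area (pixel count
#' times squared pixel size), intensity-equivalent centroid in mosaic
#' micrometre coordinates (origin at the top-left, x rightward, y
#' downward), the elongation ratio (major/minor axis of the ellipse with
#' the same second central moments, always >= 1), the bounding box in um,
#' and whether the mask touches the tile border.
#'
#' @param mask logical matrix containing exactly one 8-connected
#'   component.
#' @param scan a [ScanConfig-class].
#' @param originPx 0-based (row, col) pixel offset of `mask[1, 1]` in the
#'   mosaic.
#' @param tileBoundsPx optional `c(rmin, rmax, cmin, cmax)` mosaic-pixel
#'   bounds of the enclosing tile, used for the border flag.
#' @return one-row data.frame with columns `x_um`, `y_um`, `area_um2`,
#'   `elongation`, `xmin_um`, `xmax_um`, `ymin_um`, `ymax_um`,
#'   `touches_border`, `n_px`.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' measureMask(m, scanConfig("low", pixelSizeUm = 1))
#' @export
measureMask <- function(mask, scan, originPx = c(0L, 0L), tileBoundsPx = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("cannot measure an empty mask")
  lab <- .label8(mask)
  if (max(lab) != 1L) stop("mask must contain exactly one connected component")
  idx <- which(mask, arr.ind = TRUE)
  .measurePixels(idx[, 1L] + originPx[1L], idx[, 2L] + originPx[2L],
                 scan, tileBoundsPx)
}

#' Run the full detection chain on a tile stack
#'
#' Applies the two-zoom detection chain: frame rejection (high zoom only,
#' where macroscopic objects shadow the fine particles), global
#' segmentation of each kept tile, local refinement of every candidate,
#' cross-tile merging of particles split over adjacent tiles (bounding
#' boxes adjacent within 1 px in mosaic coordinates), and per-particle
#' measurement. Refined particles below the zoom's minimum area are
#' dropped. Records carry the stack metadata; output order (and ids) are
#' by mosaic position, so the result is invariant to tile traversal order.
#'
#' @param stack a [TileStack-class].
#' @param keepMasks keep per-particle pixel masks as an attribute (needed
#'   downstream by halo detection).
#' @return a particle table: data.frame with columns `id`, `holder`,
#'   `lamella`, `coating`, `zoom`, `x_um`, `y_um`, `area_um2`,
#'   `elongation`, `touches_border`, `has_halo` (NA until
#'   [classifyParticles()]), plus attributes `rejected` (frame-rejection
#'   report), `dropped` (refinement drop log) and `masks`.
#' @export
runDetection <- function(stack, keepMasks = TRUE) {
  stopifnot(is(stack, "TileStack"))
  validObject(stack)
  scan <- stack@scan
  rej <- if (scan@zoom == "high") rejectFrames(stack)
         else list(kept = stack, rejected = integer(),
                   tileMeans = NULL, medianMean = NULL, avgSd = NULL)
  kept <- rej$kept
  tileH <- scan@tileHeightPx; tileW <- scan@tileWidthPx

  recs <- list(); masks <- list(); dropLog <- list()
  for (i in seq_along(kept@tiles)) {
    tile <- kept@tiles[[i]]
    lab <- segmentGlobal(tile, scan)
    nlab <- max(lab)
    if (nlab == 0L) next
    r0 <- (kept@grid$row[i] - 1L) * tileH   # 0-based mosaic offset
    c0 <- (kept@grid$col[i] - 1L) * tileW
    idxAll <- which(lab > 0L, arr.ind = TRUE)
    labv <- lab[lab > 0L]
    for (l in seq_len(nlab)) {
      pr <- idxAll[labv == l, , drop = FALSE]
      bbox <- c(range(pr[, 1L]), range(pr[, 2L]))
      ref <- refineCrop(tile, bbox, scan)
      if (ref$dropped) {
        dropLog[[length(dropLog) + 1L]] <- data.frame(
          tile = i, row = kept@grid$row[i], col = kept@grid$col[i],
          reason = ref$reason)
        next
      }
      ridx <- which(ref$mask, arr.ind = TRUE)
      tl <- dim(tile)
      masks[[length(masks) + 1L]] <- list(
        rows = ridx[, 1L] + ref$r1 - 1L + r0,   # mosaic 1-based
        cols = ridx[, 2L] + ref$c1 - 1L + c0,
        tile = i,
        gridRow = kept@grid$row[i], gridCol = kept@grid$col[i],
        tileBounds = c(r0 + 1L, r0 + tl[1L], c0 + 1L, c0 + tl[2L]),
        touchesTileEdge = any(ridx[, 1L] + ref$r1 - 1L == 1L,
                              ridx[, 1L] + ref$r1 - 1L == tl[1L],
                              ridx[, 2L] + ref$c1 - 1L == 1L,
                              ridx[, 2L] + ref$c1 - 1L == tl[2L]))
    }
  }

  # ---- cross-tile merging ------------------------------------------------
  nrec <- length(masks)
  if (nrec) {
    border <- which(vapply(masks, `[[`, logical(1), "touchesTileEdge"))
    if (length(border) > 1L) {
      bb <- t(vapply(border, function(j)
        c(range(masks[[j]]$rows), range(masks[[j]]$cols)), numeric(4)))
      pairs <- NULL
      for (a in seq_len(length(border) - 1L)) for (b in (a + 1L):length(border)) {
        if (bb[a, 1L] <= bb[b, 2L] + 1L && bb[b, 1L] <= bb[a, 2L] + 1L &&
            bb[a, 3L] <= bb[b, 4L] + 1L && bb[b, 3L] <= bb[a, 4L] + 1L &&
            masks[[border[a]]]$tile != masks[[border[b]]]$tile)
          pairs <- rbind(pairs, c(a, b))
      }
      if (!is.null(pairs)) {
        g <- igraph::make_graph(edges = as.vector(t(pairs)),
                                n = length(border), directed = FALSE)
        mem <- igraph::components(g)$membership
        for (grp in unique(mem[duplicated(mem) | duplicated(mem, fromLast = TRUE)])) {
          members <- border[mem == grp]
          head <- members[1L]
          masks[[head]]$rows <- unlist(lapply(members, function(j) masks[[j]]$rows))
          masks[[head]]$cols <- unlist(lapply(members, function(j) masks[[j]]$cols))
          masks[[head]]$tile <- NA_integer_          # spans several tiles
          masks[[head]]$tileBounds <- NULL
          masks[[head]]$touchesTileEdge <- FALSE
          for (j in members[-1L]) masks[j] <- list(NULL)
        }
        masks <- masks[!vapply(masks, is.null, logical(1))]
      }
    }
  }

  minArea <- scan@minAreaUm2
  keepIdx <- logical(length(masks))
  for (j in seq_along(masks)) {
    m <- masks[[j]]
    rec <- .measurePixels(m$rows, m$cols, scan, m$tileBounds)
    if (rec$area_um2 < minArea) {
      dropLog[[length(dropLog) + 1L]] <- data.frame(
        tile = ifelse(is.na(m$tile), NA_integer_, m$tile),
        row = NA_integer_, col = NA_integer_,
        reason = "refined area below minimum")
      next
    }
    keepIdx[j] <- TRUE
    recs[[length(recs) + 1L]] <- rec
  }
  masks <- masks[keepIdx]

  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
               elongation = numeric(), xmin_um = numeric(), xmax_um = numeric(),
               ymin_um = numeric(), ymax_um = numeric(),
               touches_border = logical(), n_px = integer())
  ord <- order(tab$y_um, tab$x_um)
  tab <- tab[ord, , drop = FALSE]
  masks <- masks[ord]
  out <- data.frame(
    id = seq_len(nrow(tab)),
    holder = rep(stack@holder, nrow(tab)),
    lamella = rep(stack@lamella, nrow(tab)),
    coating = rep(stack@coating, nrow(tab)),
    zoom = rep(scan@zoom, nrow(tab)),
    tab, has_halo = rep(NA, nrow(tab)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- rej[c("rejected", "tileMeans", "medianMean", "avgSd")]
  attr(out, "dropped") <- if (length(dropLog)) do.call(rbind, dropLog) else
    data.frame(tile = integer(), row = integer(), col = integer(),
               reason = character())
  if (keepMasks) attr(out, "masks") <- masks
  out
}
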