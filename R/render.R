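#' @include scene-spec.R
NULL

# ---- shape rasterisation -------------------------------------------------
#
# Shapes are defined in continuous um coordinates and rasterised onto the
# pixel grid by 4x4 subsampling: a pixel belongs to the mask when at least
# half of its subsamples fall inside the shape. This keeps the rendered
# pixel count an unbiased estimate of true_area / pixel_area (the residual
# quantisation error lives at the rim).

.rasterCoverage <- function(xlim, ylim, px, insideFun, ns = 4L) {
  c1 <- max(1L, floor(xlim[1L] / px)); c2 <- ceiling(xlim[2L] / px) + 1L
  r1 <- max(1L, floor(ylim[1L] / px)); r2 <- ceiling(ylim[2L] / px) + 1L
  if (c2 < c1 || r2 < r1) return(NULL)
  nr <- r2 - r1 + 1L; nc <- c2 - c1 + 1L
  off <- ((seq_len(ns) - 0.5) / ns) - 0.5
  counts <- matrix(0L, nr, nc)
  colC <- (seq.int(c1, c2) - 0.5) * px
  rowC <- (seq.int(r1, r2) - 0.5) * px
  for (ox in off) for (oy in off) {
    X <- matrix(colC + ox * px, nr, nc, byrow = TRUE)
    Y <- matrix(rowC + oy * px, nr, nc)
    counts <- counts + insideFun(X, Y)
  }
  mask <- counts >= (ns * ns) / 2
  if (!any(mask)) return(NULL)
  list(r1 = r1, c1 = c1, mask = mask)
}

.insideDisk <- function(cx, cy, r) {
  force(cx); force(cy); force(r)
  function(X, Y) (X - cx)^2 + (Y - cy)^2 <= r^2
}

# convex polygon given as vertex matrix (counterclockwise); inside = on the
# inner side of every edge
.insidePolygon <- function(verts) {
  force(verts)
  function(X, Y) {
    inside <- TRUE
    nv <- nrow(verts)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      ex <- verts[j, 1L] - verts[i, 1L]
      ey <- verts[j, 2L] - verts[i, 2L]
      inside <- inside & (ex * (Y - verts[i, 2L]) - ey * (X - verts[i, 1L]) >= 0)
    }
    inside
  }
}

# ribbon: within halfWidth of a polyline (rounded caps come for free)
.insideRibbon <- function(pts, halfWidth) {
  force(pts); force(halfWidth)
  function(X, Y) {
    d2 <- Inf
    for (i in seq_len(nrow(pts) - 1L)) {
      ax <- pts[i, 1L]; ay <- pts[i, 2L]
      bx <- pts[i + 1L, 1L] - ax; by <- pts[i + 1L, 2L] - ay
      len2 <- bx * bx + by * by
      t <- ((X - ax) * bx + (Y - ay) * by) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- pmin(d2, (X - ax - t * bx)^2 + (Y - ay - t * by)^2)
    }
    d2 <= halfWidth^2
  }
}

# sample the geometry of one particle; consumes RNG (shape jitter).
# Returns list(insideFun, xlim, ylim) in um.
.sampleShape <- function(morphotype, areaUm2, cx, cy) {
  switch(morphotype,
    round = {
      r <- sqrt(areaUm2 / pi)
      list(f = .insideDisk(cx, cy, r),
           xlim = c(cx - r, cx + r), ylim = c(cy - r, cy + r))
    },
    dividing = {
      # two overlapping equal disks, centres 1.2 r apart: union area
      # = 5.38860 r^2, with a visible constriction at the waist
      r <- sqrt(areaUm2 / 5.38860)
      phi <- stats::runif(1, 0, 2 * pi)
      dx <- 0.6 * r * cos(phi); dy <- 0.6 * r * sin(phi)
      f1 <- .insideDisk(cx - dx, cy - dy, r)
      f2 <- .insideDisk(cx + dx, cy + dy, r)
      ext <- abs(dx) + r
      eyt <- abs(dy) + r
      list(f = function(X, Y) f1(X, Y) | f2(X, Y),
           xlim = c(cx - ext, cx + ext), ylim = c(cy - eyt, cy + eyt))
    },
    polygon = {
      nv <- sample(4:7, 1L)
      ang <- sort(stats::runif(nv, 0, 2 * pi))
      rad <- stats::runif(nv, 0.6, 1.4)
      vx <- rad * cos(ang); vy <- rad * sin(ang)
      hull <- grDevices::chull(vx, vy)     # ensures convexity
      vx <- vx[hull]; vy <- vy[hull]
      signed <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy) / 2
      if (signed < 0) { vx <- rev(vx); vy <- rev(vy) }  # force counterclockwise
      a0 <- abs(signed)
      s <- sqrt(areaUm2 / a0)
      vx <- s * vx; vy <- s * vy
      # translate so the polygon centroid sits at the planted centroid
      cr <- vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy
      gx <- sum((vx + c(vx[-1], vx[1])) * cr) / (6 * areaUm2)
      gy <- sum((vy + c(vy[-1], vy[1])) * cr) / (6 * areaUm2)
      verts <- cbind(cx + vx - gx, cy + vy - gy)
      list(f = .insidePolygon(verts),
           xlim = range(verts[, 1L]), ylim = range(verts[, 2L]))
    },
    fiber = {
      # curved ribbon of aspect ratio ~12 along a quadratic Bezier arc
      w <- sqrt(areaUm2 / 12)
      Ls <- (areaUm2 - pi * w^2 / 4) / w
      if (Ls <= w) return(.sampleShape("round", areaUm2, cx, cy))
      phi <- stats::runif(1, 0, 2 * pi)
      bow <- stats::runif(1, 0.08, 0.2) * Ls
      u <- c(cos(phi), sin(phi)); v <- c(-sin(phi), cos(phi))
      t <- seq(0, 1, length.out = 25L)
      bx <- (t - 0.5) * Ls * u[1L] + 4 * t * (1 - t) * bow * v[1L]
      by <- (t - 0.5) * Ls * u[2L] + 4 * t * (1 - t) * bow * v[2L]
      arc <- sum(sqrt(diff(bx)^2 + diff(by)^2))
      sc <- Ls / arc                       # rescale arc length to target
      # centre on the length-weighted ribbon centroid
      seg <- sqrt(diff(bx)^2 + diff(by)^2)
      mx <- sum((bx[-1] + bx[-length(bx)]) / 2 * seg) / sum(seg)
      my <- sum((by[-1] + by[-length(by)]) / 2 * seg) / sum(seg)
      pts <- cbind(cx + sc * (bx - mx), cy + sc * (by - my))
      list(f = .insideRibbon(pts, w / 2),
           xlim = range(pts[, 1L]) + c(-w, w), ylim = range(pts[, 2L]) + c(-w, w))
    },
    stop("unknown morphotype: ", morphotype)
  )
}

# paint mask into channel matrices (by reference semantics via returned list)
.paintMask <- function(channels, rast, dims, values, additive = FALSE) {
  rows <- rast$r1 + which(rast$mask, arr.ind = TRUE)[, 1L] - 1L
  cols <- rast$c1 + which(rast$mask, arr.ind = TRUE)[, 2L] - 1L
  keep <- rows >= 1L & rows <= dims[1L] & cols >= 1L & cols <= dims[2L]
  if (!any(keep)) return(channels)
  idx <- cbind(rows[keep], cols[keep])
  for (ch in seq_along(channels)) {
    if (additive) channels[[ch]][idx] <- channels[[ch]][idx] + values[ch]
    else channels[[ch]][idx] <- values[ch]
  }
  channels
}

# ---- scene rendering -----------------------------------------------------

#' Render a synthetic scene into a tile stack
#'
#' Rasterises the planted ground truth into an 8-bit RGB mosaic and cuts it
#' into tiles of the [ScanConfig-class] geometry (the last row/column may
#' be partial). Particles are drawn darker than the background on all
#' channels, with the strongest contrast on the blue channel (the channel
#' the detection chain segments): the blue level inside a particle is
#' `particleLevel`, red and green sit at 40% of the blue contrast above it.
#' Morphotypes are rendered as convex 4-7-sided flat polygons, curved
#' ribbons of aspect ratio ~12 (fibers), disks, or two overlapping disks
#' with a constriction (dividing microparticles). Halo-flagged particles
#' receive a bright annulus of width `haloWidthUm` just outside their
#' boundary. Occluders are near-black disks drawn on top of everything.
#' A linear illumination gradient (random direction, peak-to-peak
#' `gradientAmplitude`) and additive Gaussian noise are applied, then the
#' image is quantised to 8 bits.
#'
#' Reproducible: seeded from `spec@seed + 1` (a stream distinct from
#' [sampleTruth()]); the caller's RNG state is left untouched.
#'
#' @param truth a [SceneTruth-class].
#' @param scan a [ScanConfig-class]; its pixel size and tile geometry tile
#'   the field.
#' @param holder,lamella,coating stack metadata.
#' @return a [TileStack-class].
#' @examples
#' spec <- sceneSpec(fieldWidthMm = 0.4, fieldHeightMm = 0.4,
#'                   densities = c(coarse = 5), seed = 2)
#' stack <- renderTiles(sampleTruth(spec), scanConfig("low"))
#' stack
#' @export
renderTiles <- function(truth, scan, holder = "H1", lamella = "L1",
                        coating = "FDTS") {
  stopifnot(is(truth, "SceneTruth"), is(scan, "ScanConfig"))
  if (scan@pixelSizeUm <= 0) stop("pixel size must be > 0")
  spec <- truth@spec
  px <- scan@pixelSizeUm
  Wpx <- as.integer(ceiling(spec@fieldWidthMm * 1e3 / px))
  Hpx <- as.integer(ceiling(spec@fieldHeightMm * 1e3 / px))
  dims <- c(Hpx, Wpx)

  .withSeed(spec@seed + 1L, {
    bg <- spec@backgroundLevel
    contrast <- bg - spec@particleLevel
    # linear illumination gradient, random direction, peak-to-peak amplitude
    if (spec@gradientAmplitude > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      gx <- cos(theta) * ((seq_len(Wpx) - 0.5) / Wpx - 0.5)
      gy <- sin(theta) * ((seq_len(Hpx) - 0.5) / Hpx - 0.5)
      proj <- outer(gy, gx, "+")
      rng <- range(proj)
      base <- bg + spec@gradientAmplitude *
        ((proj - rng[1L]) / max(rng[2L] - rng[1L], .Machine$double.eps) - 0.5)
    } else {
      base <- matrix(bg, Hpx, Wpx)
    }
    channels <- list(R = base, G = base, B = base)

    p <- truth@particles
    pLevels <- c(R = spec@particleLevel + 0.4 * contrast,
                 G = spec@particleLevel + 0.4 * contrast,
                 B = spec@particleLevel)
    haloPx <- max(1L, round(spec@haloWidthUm / px))
    if (nrow(p)) for (i in seq_len(nrow(p))) {
      sh <- .sampleShape(p$morphotype[i], p$area_um2[i], p$x_um[i], p$y_um[i])
      rast <- .rasterCoverage(sh$xlim, sh$ylim, px, sh$f)
      if (is.null(rast)) next
      if (p$has_halo[i]) {
        pad <- haloPx + 1L
        m <- rast$mask
        padded <- matrix(FALSE, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
        padded[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
        dil <- EBImage::dilate(padded, EBImage::makeBrush(2L * haloPx + 1L, "disc"))
        ring <- dil & !padded
        channels <- .paintMask(channels,
                               list(r1 = rast$r1 - pad, c1 = rast$c1 - pad,
                                    mask = ring),
                               dims, rep(spec@haloAmplitude, 3L), additive = TRUE)
      }
      channels <- .paintMask(channels, rast, dims, pLevels)
    }

    occ <- truth@occluders
    if (nrow(occ)) for (i in seq_len(nrow(occ))) {
      r <- occ$extent_um[i] / 2
      rast <- .rasterCoverage(c(occ$x_um[i] - r, occ$x_um[i] + r),
                              c(occ$y_um[i] - r, occ$y_um[i] + r), px,
                              .insideDisk(occ$x_um[i], occ$y_um[i], r))
      if (!is.null(rast))
        channels <- .paintMask(channels, rast, dims, rep(spec@occluderLevel, 3L))
    }

    if (spec@noiseSigma > 0)
      for (ch in 1:3)
        channels[[ch]] <- channels[[ch]] +
          stats::rnorm(Hpx * Wpx, 0, spec@noiseSigma)

    mosaic <- array(0L, dim = c(Hpx, Wpx, 3L))
    for (ch in 1:3)
      mosaic[, , ch] <- as.integer(round(pmin(pmax(channels[[ch]], 0), 255)))

    tileH <- scan@tileHeightPx; tileW <- scan@tileWidthPx
    nR <- ceiling(Hpx / tileH); nC <- ceiling(Wpx / tileW)
    grid <- expand.grid(row = seq_len(nR), col = seq_len(nC),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$row, grid$col), , drop = FALSE]
    rownames(grid) <- NULL
    tilesList <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      rs <- ((grid$row[i] - 1L) * tileH + 1L):min(grid$row[i] * tileH, Hpx)
      cs <- ((grid$col[i] - 1L) * tileW + 1L):min(grid$col[i] * tileW, Wpx)
      tilesList[[i]] <- mosaic[rs, cs, , drop = FALSE]
    }
    new("TileStack", tiles = tilesList, grid = grid, holder = holder,
        lamella = lamella, coating = coating, scan = scan)
  })
}
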