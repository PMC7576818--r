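stackFromTiles <- function(tilesList, scan = scanConfig("low", tileWidthPx = 64,
                                                        tileHeightPx = 64)) {
  n <- length(tilesList)
  grid <- data.frame(row = rep(1:ceiling(n / 7), each = 7,
                               length.out = n),
                     col = rep(1:7, length.out = n))
  new("TileStack", tiles = tilesList, grid = grid, holder = "H1",
      lamella = "L1", coating = "FDTS", scan = scan)
}

test_that("frame rejection: uniform stacks pass, blob tiles fail, k = Inf passes all", {
  # identical uniform tiles: all deviations zero
  st <- stackFromTiles(replicate(10, uniformTile(200), simplify = FALSE))
  expect_length(rejectFrames(st)$rejected, 0L)

  # 20 clean tiles with a mild fixed texture + one tile 30% covered by a blob
  checker <- outer(1:64, 1:64, function(r, c) 2L * ((r + c) %% 2L))
  clean <- uniformTile(200)
  for (ch in 1:3) clean[, , ch] <- clean[, , ch] + checker
  blobTile <- paintDisk(clean, 32, 32, 20, 10, 10)  # pi*20^2/64^2 ~ 31% coverage
  tilesList <- c(replicate(20, clean, simplify = FALSE), list(blobTile))
  st <- stackFromTiles(tilesList)
  # recompute the criterion by hand
  means <- vapply(tilesList, function(t) mean(t[, , 3]), numeric(1))
  sds <- vapply(tilesList, function(t) sd(t[, , 3]), numeric(1))
  expected <- which(abs(means - median(means)) > 2 * mean(sds))
  expect_identical(expected, 21L)
  expect_identical(rejectFrames(st)$rejected, 21L)

  # unbounded tolerance rejects nothing
  expect_length(rejectFrames(st, k = 1e9)$rejected, 0L)
  # second pass on its own output rejects nothing further
  expect_length(rejectFrames(rejectFrames(st)$kept)$rejected, 0L)

  empty <- stackFromTiles(list())
  expect_error(rejectFrames(empty), "empty")
})

test_that("global segmentation: strict threshold, min-area filter, 8-connectivity", {
  scan <- scanConfig("low", tileWidthPx = 64, tileHeightPx = 64)
  expect_identical(max(segmentGlobal(uniformTile(200), scan)), 0L)

  # three dark disks -> three labels (brute-force pixel scan agrees)
  t3 <- uniformTile(200)
  t3 <- paintDisk(t3, 15, 15, 5, 40)
  t3 <- paintDisk(t3, 15, 48, 5, 40)
  t3 <- paintDisk(t3, 48, 32, 5, 40)
  lab <- segmentGlobal(t3, scan)
  expect_identical(max(lab), 3L)
  expect_identical(sum(lab > 0), sum(t3[, , 3] < 75))

  # a disk exactly at the threshold grey level is not detected (strict <)
  t75 <- paintDisk(uniformTile(200), 32, 32, 6, 75, 75)
  expect_identical(max(segmentGlobal(t75, scan)), 0L)

  # diagonal contact merges under 8-connectivity
  td <- uniformTile(200)
  td[10:17, 10:17, ] <- 40L
  td[18:25, 18:25, ] <- 40L     # touches only at the (17,17)-(18,18) corner
  expect_identical(max(segmentGlobal(td, scan)), 1L)

  # components below the minimum area are discarded
  tiny <- paintDisk(uniformTile(200), 32, 32, 2, 40)  # ~13 px < 21 px floor
  expect_identical(max(segmentGlobal(tiny, scan)), 0L)

  expect_error(segmentGlobal(uniformTile(200) / 1.0, scan), "8-bit")
})

test_that("local refinement: alpha-mean threshold, candidate restriction, monotone in alpha", {
  scan <- scanConfig("low", tileWidthPx = 64, tileHeightPx = 64)
  # uniform crop: nothing below alpha * mean -> dropped, not an error
  ref <- refineCrop(uniformTile(200), c(20, 30, 20, 30), scan)
  expect_true(ref$dropped)

  tl <- paintDisk(uniformTile(200), 32, 32, 8, 40)
  lab <- segmentGlobal(tl, scan)
  idx <- which(lab == 1L, arr.ind = TRUE)
  bbox <- c(range(idx[, 1]), range(idx[, 2]))
  ref <- refineCrop(tl, bbox, scan)
  expect_false(ref$dropped)
  # direct computation on the crop: T = 0.6 * mean, mask = blue < T
  crop <- tl[(bbox[1] - 10):(bbox[2] + 10), (bbox[3] - 10):(bbox[4] + 10), 3]
  expect_identical(sum(ref$mask), sum(crop < 0.6 * mean(crop)))
  expect_identical(sum(ref$mask), sum(tl[, , 3] < 75))

  # decreasing alpha never grows the mask
  sizes <- vapply(c(0.9, 0.6, 0.3, 0.1), function(a) {
    r <- refineCrop(tl, bbox, scanConfig("low", localAlpha = a,
                                         tileWidthPx = 64, tileHeightPx = 64))
    if (r$dropped) 0L else sum(r$mask)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("measurement: area scaling, rectangle elongation, border flag", {
  scan1 <- scanConfig("low", pixelSizeUm = 1)
  m <- matrix(FALSE, 30, 30); m[11:20, 11:20] <- TRUE
  rec <- measureMask(m, scan1)
  expect_equal(rec$area_um2, 100)
  expect_equal(rec$elongation, 1)
  expect_equal(rec$x_um, 15); expect_equal(rec$y_um, 15)

  # 40 x 10 solid rectangle: second-moment oracle gives exactly 4
  m2 <- matrix(FALSE, 60, 60); m2[11:20, 11:50] <- TRUE
  expect_equal(measureMask(m2, scan1)$elongation, 4, tolerance = 1e-9)

  # area scales with the squared pixel size
  scanH <- scanConfig("high")   # 0.155 um/px
  expect_equal(measureMask(m, scanH)$area_um2, 100 * 0.155^2)

  # border contact
  mb <- matrix(FALSE, 20, 20); mb[1:5, 8:12] <- TRUE
  expect_true(measureMask(mb, scan1, tileBoundsPx = c(1, 20, 1, 20))$touches_border)
  expect_false(measureMask(m, scan1, tileBoundsPx = c(1, 30, 1, 30))$touches_border)

  expect_error(measureMask(matrix(FALSE, 5, 5), scan1), "empty")
  m3 <- matrix(FALSE, 20, 20); m3[2:5, 2:5] <- TRUE; m3[10:13, 10:13] <- TRUE
  expect_error(measureMask(m3, scan1), "exactly one")
})

test_that("full chain on noise-free scenes recovers planted count and areas", {
  spec <- sceneSpec(fieldWidthMm = 1, fieldHeightMm = 1,
                    densities = c(coarse = 10, macroscopic = 1),
                    noiseSigma = 0, gradientAmplitude = 0,
                    haloFraction = 0, seed = 4)
  truth <- sampleTruth(spec)
  tab <- runDetection(renderTiles(truth, scanConfig("low")))
  p <- particles(truth)
  expect_identical(nrow(tab), nrow(p))
  m <- matchTruth(truth, tab, maxDistUm = 5)
  expect_equal(m$recall, 1)
  big <- p$area_um2 >= 25 * 1.55^2
  relErr <- abs(tab$area_um2[m$map] / p$area_um2 - 1)
  expect_true(all(relErr[big] < 0.10))
})

test_that("blank scenes give an empty table; planted fibers exceed the elongation cut", {
  blank <- sceneSpec(fieldWidthMm = 0.5, fieldHeightMm = 0.5,
                     densities = c(fine = 0, coarse = 0, macroscopic = 0),
                     seed = 6)
  expect_identical(nrow(runDetection(renderTiles(sampleTruth(blank),
                                                 scanConfig("low")))), 0L)

  spec <- sceneSpec(fieldWidthMm = 0.6, fieldHeightMm = 0.6,
                    densities = c(coarse = 0), noiseSigma = 0,
                    gradientAmplitude = 0, seed = 9)
  truth <- manualTruth(spec, data.frame(
    id = 1L, x_um = 300, y_um = 300, area_um2 = 3000,
    morphotype = "fiber", has_halo = FALSE, size_class = "macroscopic"))
  tab <- runDetection(renderTiles(truth, scanConfig("low")))
  expect_identical(nrow(tab), 1L)
  expect_gt(tab$elongation, 5)
})

test_that("particles split across tiles are merged; output is traversal-order invariant", {
  spec <- sceneSpec(fieldWidthMm = 0.9, fieldHeightMm = 0.9,
                    densities = c(coarse = 0), noiseSigma = 0,
                    gradientAmplitude = 0, seed = 10)
  boundary <- 256 * 1.55          # x of the first vertical tile seam (um)
  truth <- manualTruth(spec, data.frame(
    id = 1:2, x_um = c(boundary, 450), y_um = c(200, 700),
    area_um2 = c(900, 300), morphotype = "round", has_halo = FALSE,
    size_class = "coarse"))
  st <- renderTiles(truth, scanConfig("low"))
  tab <- runDetection(st)
  expect_identical(nrow(tab), 2L)
  m <- matchTruth(truth, tab)
  expect_equal(m$recall, 1)
  expect_equal(tab$area_um2[m$map[1]], 900, tolerance = 0.05)

  # shuffling the tile order leaves the table unchanged
  set.seed(1)
  perm <- sample(length(tiles(st)))
  st2 <- new("TileStack", tiles = tiles(st)[perm],
             grid = tileGrid(st)[perm, ], holder = holder(st),
             lamella = lamella(st), coating = coating(st),
             scan = scanConfigOf(st))
  tab2 <- runDetection(st2)
  attributes(tab) <- attributes(tab)[c("names", "row.names", "class")]
  attributes(tab2) <- attributes(tab2)[c("names", "row.names", "class")]
  expect_equal(tab, tab2)
})

test_that("tile stacks round-trip through TIFF + JSON sidecar", {
  spec <- sceneSpec(fieldWidthMm = 0.3, fieldHeightMm = 0.3,
                    densities = c(coarse = 10), seed = 13)
  st <- renderTiles(sampleTruth(spec), scanConfig("low"),
                    holder = "RGHS1", lamella = "L2", coating = "SiOCH")
  d <- file.path(tempdir(), "stackio")
  writeTileStack(st, d, scene = "t")
  st2 <- readTileStack(d, scene = "t")
  expect_identical(tiles(st2), tiles(st))
  expect_identical(coating(st2), "SiOCH")
  expect_identical(scanConfigOf(st2)@pixelSizeUm, 1.55)
  unlink(d, recursive = TRUE)
})
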