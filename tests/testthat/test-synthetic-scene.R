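test_that("zero densities give an empty truth", {
  spec <- sceneSpec(densities = c(fine = 0, coarse = 0, macroscopic = 0),
                    seed = 1)
  truth <- sampleTruth(spec)
  expect_identical(nrow(particles(truth)), 0L)
  expect_identical(nrow(occluders(truth)), 0L)
})

test_that("planted counts are Poisson with mean density x area", {
  # lambda = 1.6 / mm^2 x 100 mm^2 = 160; over R replicates the sample
  # mean must fall within 3 sqrt(lambda / R) of lambda
  R <- 50L
  counts <- vapply(seq_len(R), function(s) {
    spec <- sceneSpec(fieldWidthMm = 10, fieldHeightMm = 10,
                      densities = c(coarse = 1.6), seed = 1000 + s)
    nrow(particles(sampleTruth(spec)))
  }, integer(1))
  lambda <- 160
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / R))
})

test_that("planted areas follow the size law (histogram mode near 155)", {
  spec <- sceneSpec(seed = 77)
  law <- spec@sizeLaws$coarse
  set.seed(spec@seed)
  draws <- truncLnormSample(1e5, law[1], law[2], law[3], law[4])
  est <- histogramMode(draws, binWidth = 50, anchor = 50)
  # within one 50 um^2 bin of the planted mode
  expect_lte(abs(est - 155), 75)
})

test_that("hard-core placement enforces pair separation and can fail loudly", {
  spec <- sceneSpec(fieldWidthMm = 2, fieldHeightMm = 2,
                    densities = c(coarse = 8), seed = 3)
  p <- particles(sampleTruth(spec))
  if (nrow(p) > 1) {
    r <- sqrt(p$area_um2 / pi)
    d <- as.matrix(dist(cbind(p$x_um, p$y_um)))
    need <- 2 * outer(r, r, pmax)
    diag(d) <- Inf
    expect_true(all(d >= need - 1e-9))
  }
  crowded <- sceneSpec(fieldWidthMm = 0.1, fieldHeightMm = 0.1,
                       densities = c(macroscopic = 2000),
                       sizeLaws = list(macroscopic = c(mode = 20000,
                                                       sigma_log = 0.3,
                                                       lower = 15000,
                                                       upper = 40000)),
                       morphotypeMix = list(macroscopic = c(round = 1)),
                       seed = 5)
  expect_error(sampleTruth(crowded, maxAttempts = 50L), "too crowded")
})

test_that("sampling and rendering are bit-reproducible for a fixed seed", {
  spec <- sceneSpec(fieldWidthMm = 0.6, fieldHeightMm = 0.6,
                    densities = c(coarse = 6), haloFraction = 0.5,
                    occluderCount = 1L, seed = 21)
  t1 <- sampleTruth(spec); t2 <- sampleTruth(spec)
  expect_identical(particles(t1), particles(t2))
  s1 <- renderTiles(t1, scanConfig("low"))
  s2 <- renderTiles(t2, scanConfig("low"))
  expect_identical(tiles(s1), tiles(s2))
  # and the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sampleTruth(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a blank noise-free scene renders uniform tiles", {
  spec <- sceneSpec(fieldWidthMm = 0.5, fieldHeightMm = 0.5,
                    densities = c(fine = 0, coarse = 0, macroscopic = 0),
                    noiseSigma = 0, gradientAmplitude = 0, seed = 2)
  st <- renderTiles(sampleTruth(spec), scanConfig("low"))
  for (tl in tiles(st)) expect_true(all(tl == spec@backgroundLevel))
})

test_that("a rendered disk covers true_area / pixel_area pixels", {
  spec <- sceneSpec(fieldWidthMm = 0.1, fieldHeightMm = 0.1,
                    densities = c(coarse = 0), noiseSigma = 0,
                    gradientAmplitude = 0, seed = 8)
  truth <- manualTruth(spec, data.frame(
    id = 1L, x_um = 50, y_um = 50, area_um2 = 100,
    morphotype = "round", has_halo = FALSE, size_class = "coarse"))
  st <- renderTiles(truth, scanConfig("low", pixelSizeUm = 1))
  dark <- sum(vapply(tiles(st), function(t)
    sum(t[, , 3] < spec@backgroundLevel), numeric(1)))
  expect_lte(abs(dark - 100), 4)   # quantisation at the rim only
})

test_that("rendered pixel count scales linearly with true area", {
  spec <- sceneSpec(fieldWidthMm = 1.2, fieldHeightMm = 1.2,
                    densities = c(coarse = 0), noiseSigma = 0,
                    gradientAmplitude = 0, seed = 12)
  areas <- seq(60, 1400, length.out = 12)
  grid <- expand.grid(x = seq(150, 1050, length.out = 4),
                      y = seq(150, 1050, length.out = 3))
  truth <- manualTruth(spec, data.frame(
    id = seq_along(areas), x_um = grid$x, y_um = grid$y,
    area_um2 = areas, morphotype = "round", has_halo = FALSE,
    size_class = "coarse"))
  scan <- scanConfig("low")
  tab <- runDetection(renderTiles(truth, scan))
  m <- matchTruth(truth, tab)
  fit <- lm(tab$n_px[m$map] ~ areas)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(unname(coef(fit)[2]), 1 / scan@pixelSizeUm^2,
               tolerance = 0.05)
})

test_that("an injected occluder makes exactly one tile trip the rejection statistic", {
  spec <- sceneSpec(fieldWidthMm = 1.6, fieldHeightMm = 1.6,
                    densities = c(coarse = 2), occluderCount = 1L,
                    seed = 31)
  truth <- sampleTruth(spec)
  st <- renderTiles(truth, scanConfig("low"))
  # recompute the rejection statistic directly from the rendered tiles
  means <- vapply(tiles(st), function(t) mean(t[, , 3]), numeric(1))
  sds <- vapply(tiles(st), function(t) sd(t[, , 3]), numeric(1))
  trip <- which(abs(means - median(means)) > 2 * mean(sds))
  occ <- occluders(truth)
  tileUm <- 256 * 1.55
  target <- which(tileGrid(st)$row == floor(occ$y_um / tileUm) + 1 &
                  tileGrid(st)$col == floor(occ$x_um / tileUm) + 1)
  expect_true(target %in% trip)
  expect_identical(sort(unique(rejectFrames(st)$rejected)), sort(trip))
})

test_that("scene spec and truth round-trip through JSON / CSV", {
  spec <- sceneSpec(fieldWidthMm = 0.7, fieldHeightMm = 0.9,
                    occluderCount = 2L, seed = 14)
  fs <- tempfile(fileext = ".json")
  writeSceneSpec(spec, fs)
  spec2 <- readSceneSpec(fs)
  expect_equal(spec2@densities, spec@densities)
  expect_equal(spec2@sizeLaws$coarse, spec@sizeLaws$coarse,
               ignore_attr = TRUE)
  expect_identical(spec2@seed, spec@seed)
  truth <- sampleTruth(spec)
  ft <- tempfile(fileext = ".csv")
  writeSceneTruth(truth, ft)
  truth2 <- readSceneTruth(ft, spec)
  expect_equal(particles(truth2), particles(truth), tolerance = 1e-12)
  expect_equal(occluders(truth2), occluders(truth), tolerance = 1e-12)
})
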