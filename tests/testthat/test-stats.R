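test_that("density is count over area, with tile-to-tile dispersion", {
  tab <- data.frame(area_um2 = rep(100, 400))
  d <- particleDensity(tab, 244)
  expect_equal(unname(d["d"]), 400 / 244, tolerance = 1e-12)
  expect_equal(unname(particleDensity(tab[0, , drop = FALSE], 244)),
               c(0, 0))
  expect_error(particleDensity(tab, 0), "area")

  part <- list(tileId = rep(1:4, each = 100), nTiles = 4L, tileAreaMm2 = 61)
  d2 <- particleDensity(tab, 244, part)
  expect_equal(unname(d2["sd"]), sd(rep(100 / 61, 4)) / 2)  # 0 here
})

test_that("density recovery through the tile partition of a detected scene", {
  spec <- sceneSpec(fieldWidthMm = 1.2, fieldHeightMm = 1.2,
                    densities = c(coarse = 6), seed = 55)
  truth <- sampleTruth(spec)
  st <- renderTiles(truth, scanConfig("low"))
  tab <- runDetection(st)
  part <- stackPartition(tab, st)
  d <- particleDensity(tab, part$scannedAreaMm2, part)
  expect_equal(unname(d["d"]), nrow(tab) / part$scannedAreaMm2)
  expect_true(is.finite(d["sd"]) && d["sd"] > 0)
})

test_that("summary grid marginals are arithmetic means with sample sd", {
  d <- rbind(A = c(2, 2, 2), B = c(1, 2, 3), C = c(4, 4, 1))
  colnames(d) <- c("h1", "h2", "h3")
  g <- summaryGrid(d)
  expect_equal(unname(g@rowMean), c(2, 2, 3))
  expect_equal(unname(g@rowSd), c(0, 1, sqrt(3)))
  expect_equal(unname(g@colMean), unname(colMeans(d)))
  d[2, 2] <- NA
  expect_error(summaryGrid(d), "missing")
})

test_that("cumulative size functions are proper empirical CDFs", {
  # all areas equal: 0 before, 100 at and after
  csf <- cumulativeSizeFunction(rep(200, 50), c(50, 1500), nBins = 20)
  expect_true(all(cumFraction(csf)[binEdges(csf) < 200] == 0))
  expect_true(all(cumFraction(csf)[binEdges(csf) >= 200] == 100))

  # empirical-CDF oracle at every edge
  set.seed(8)
  a <- runif(400, 50, 1500)
  csf2 <- cumulativeSizeFunction(a, c(50, 1500), nBins = 30)
  expect_equal(cumFraction(csf2), 100 * ecdf(a)(binEdges(csf2)),
               tolerance = 1e-12)
  mid <- sqrt(50 * 1500)
  below <- 100 * mean(a <= mid)
  atMid <- approx(binEdges(csf2), cumFraction(csf2), xout = mid)$y
  expect_equal(atMid, below, tolerance = 5)

  # invariants across random draws
  for (s in 1:5) {
    set.seed(s)
    x <- truncLnormSample(200, 155, 0.7, 50, 1500)
    cs <- cumulativeSizeFunction(x, c(50, 1500))
    expect_true(all(diff(cumFraction(cs)) >= 0))
    expect_true(all(cumFraction(cs) >= 0 & cumFraction(cs) <= 100))
    expect_equal(cumFraction(cs)[31], 100)
  }
  expect_error(cumulativeSizeFunction(numeric(), c(50, 1500)), "empty")
  expect_error(cumulativeSizeFunction(c(10, 60), c(50, 1500)), "within")
})

test_that("unpaired t-test matches stats and handles degenerate variance", {
  r <- tTestUnpaired(c(1, 2, 3), c(2, 3, 5))
  ref <- t.test(c(1, 2, 3), c(2, 3, 5), var.equal = TRUE)
  expect_equal(unname(r["t"]), unname(ref$statistic))
  expect_equal(unname(r["df"]), 4)
  expect_equal(unname(r["p"]), ref$p.value)

  same <- tTestUnpaired(c(5, 5, 5), c(5, 5, 5))
  expect_equal(unname(same["t"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_warning(sep0 <- tTestUnpaired(c(0, 0, 0, 0), c(1, 1, 1, 1)),
                 "zero pooled variance")
  expect_equal(unname(sep0["p"]), 0)

  set.seed(2)
  jit <- tTestUnpaired(rnorm(4, 0, 1e-6), 1 + rnorm(4, 0, 1e-6))
  expect_lt(unname(jit["p"]), 0.001)
  expect_error(tTestUnpaired(1, c(1, 2)), "at least 2")
})

test_that("t-test p agrees with the permutation oracle on fixed samples", {
  set.seed(17)
  for (i in 1:3) {
    a <- rnorm(12); b <- rnorm(12, mean = runif(1, 0, 1))
    p1 <- unname(tTestUnpaired(a, b)["p"])
    p2 <- permutationP(a, b, R = 2e4L)
    expect_lt(abs(p1 - p2), 0.02)
  }
})

test_that("coating comparison is symmetric and detects planted separation", {
  mk <- function(mode, coat, hold, seed) {
    set.seed(seed)
    cumulativeSizeFunction(truncLnormSample(300, mode, 0.3, 50, 1500),
                           c(50, 1500), coating = coat, holder = hold)
  }
  csfs <- list(mk(100, "FDTS", "h1", 1), mk(100, "FDTS", "h2", 2),
               mk(100, "FDTS", "h3", 3),
               mk(700, "Parylene", "h1", 4), mk(700, "Parylene", "h2", 5),
               mk(700, "Parylene", "h3", 6))
  cmp <- compareCoatings(csfs, areaRange = c(200, 900))
  expect_lt(cmp$p, 0.01)
  # label swap flips the sign of t, not p
  cmp2 <- compareCoatings(rev(csfs), areaRange = c(200, 900))
  expect_equal(cmp$p, cmp2$p, tolerance = 1e-12)

  # identical size functions across coatings: p = 1
  dup <- csfs[1:3]
  dup2 <- lapply(dup, function(x) { x@coating <- "SiOCH"; x })
  expect_equal(compareCoatings(c(dup, dup2), areaRange = c(200, 900))$p, 1)

  expect_error(compareCoatings(csfs, areaRange = c(2000, 3000)), "range")
  expect_error(compareCoatings(csfs[c(1, 4)], areaRange = c(200, 900)),
               "2 holders")
})

test_that("coverage forecast is linear in the horizon and zero at zero", {
  cls <- data.frame(class = c("coarse", "fine"),
                    density_mm2 = c(1.6, 3.3),
                    mode = c(155, 2), sigma_log = c(0.7, 1.0),
                    lower = c(50, 0.5), upper = c(1500, 50))
  expect_equal(coveragePercent(extrapolateCoverage(cls, 0)), 0)
  c1 <- coveragePercent(extrapolateCoverage(cls, 20))
  c2 <- coveragePercent(extrapolateCoverage(cls, 40))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_error(extrapolateCoverage(cls, -1), "horizon")
})

test_that("forecast matches Monte-Carlo coverage of sampled scenes", {
  cls <- data.frame(class = c("coarse", "fine"),
                    density_mm2 = c(1.6, 3.3),
                    mode = c(155, 2), sigma_log = c(0.7, 1.0),
                    lower = c(50, 0.5), upper = c(1500, 50))
  perPeriod <- coveragePercent(extrapolateCoverage(cls, 1))
  mc <- vapply(1:10, function(s) {
    spec <- sceneSpec(fieldWidthMm = 15, fieldHeightMm = 15,
                      densities = c(fine = 3.3, coarse = 1.6,
                                    macroscopic = 0),
                      seed = 7000 + s)
    p <- particles(sampleTruth(spec))
    100 * sum(p$area_um2) / (15 * 15 * 1e6)
  }, numeric(1))
  expect_lt(abs(mean(mc) / perPeriod - 1), 0.05)
})

test_that("cleanliness class follows the log-decade rule", {
  expect_identical(cleanlinessClass(1e6), 6L)
  expect_identical(cleanlinessClass(9.9e5), 6L)
  expect_identical(cleanlinessClass(1.01e6), 7L)
  expect_identical(cleanlinessClass(0), 0L)
  expect_error(cleanlinessClass(-1), ">= 0")
  expect_equal(equivalentDiameter(pi / 4), 1)
})

test_that("histogram mode estimator finds the tallest 50 um^2 bin", {
  a <- c(runif(50, 100, 150), runif(200, 150, 200), runif(30, 200, 250))
  expect_equal(histogramMode(a), 175)
  expect_error(histogramMode(numeric()), "empty")
})
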