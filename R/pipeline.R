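#' @include io.R
NULL

#' Default run configuration
#'
#' Returns the default configuration for [runPipeline()] as a nested list:
#' stage toggles, the scene roster (one synthetic scene per
#' coating-by-holder cell), [sceneSpec()] and [scanConfig()] overrides, and
#' the statistics parameters (binning, comparison range, elongation cut,
#' halo parameters, forecast horizon). Every tunable of the detection and
#' classification chain is reachable from the configuration; there are no
#' hidden constants.
#'
#' @param seed base RNG seed; scene `i` of the roster is generated with
#'   `seed + i`.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, detect = TRUE, classify = TRUE,
                  stats = TRUE),
    write_tiles = FALSE,
    scenes = list(
      list(name = "s1", coating = "FDTS", holder = "RGHS1", lamella = "L1"),
      list(name = "s2", coating = "FDTS", holder = "RGHS2", lamella = "L2"),
      list(name = "s3", coating = "Parylene", holder = "RGHS1", lamella = "L3"),
      list(name = "s4", coating = "Parylene", holder = "RGHS2", lamella = "L4")),
    spec = list(),        # sceneSpec() overrides, applied to every scene
    scan = list(zoom = "low"),
    stats = list(n_bins = 30L, compare_range = c(200, 900),
                 elongation_cut = 5, halo_ring_px = 5L, halo_k = 2,
                 horizon_periods = 40)
  )
}

#' Read a run configuration from JSON
#'
#' Reads a [runPipeline()] configuration file. Lines starting with `//`
#' are treated as comments and stripped before parsing; missing entries
#' fall back to [defaultRunConfig()].
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*//", txt)]
  user <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  .mergeConfig(defaultRunConfig(), user)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])) && nm != "scenes")
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.applyOverrides <- function(fn, overrides, ...) {
  do.call(fn, c(list(...), overrides))
}

#' Run the full simulate-detect-classify-stats pipeline
#'
#' Executes the enabled stages in order on the configured scene roster and
#' writes all artifacts into `outDir`: the configuration as run
#' (`config.json`), planted truth and particle tables (CSV), the frame
#' rejection report (JSON), the density summary grid with marginals
#' (CSV), cumulative size functions (CSV), pairwise coating comparisons
#' (JSON), the coverage forecast (JSON), a human-readable `report.txt`,
#' and a size-distribution figure. Every artifact is stamped with the
#' configuration hash and seed; a rerun with the same configuration
#' produces identical tables and reports. A stage failure aborts with the
#' stage name in the error.
#'
#' @param config configuration list (see [defaultRunConfig()]) or path to
#'   a JSON configuration.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly; the written artifacts are the result.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  hash <- unname(tools::md5sum(cfgPath))
  stamp <- sprintf("seed=%d config_md5=%s", config$seed, hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scan <- .applyOverrides(scanConfig, config$scan)
  scenes <- config$scenes
  stacks <- list(); truths <- list(); tables <- list()

  if (isTRUE(config$stages$simulate)) stage("simulate", {
    for (i in seq_along(scenes)) {
      sc <- scenes[[i]]
      spec <- .applyOverrides(sceneSpec, config$spec,
                              seed = config$seed + i)
      truths[[sc$name]] <- sampleTruth(spec)
      stacks[[sc$name]] <- renderTiles(truths[[sc$name]], scan,
                                       holder = sc$holder,
                                       lamella = sc$lamella,
                                       coating = sc$coating)
      writeSceneTruth(truths[[sc$name]],
                      file.path(outDir, paste0(sc$name, "_truth.csv")))
      if (isTRUE(config$write_tiles))
        writeTileStack(stacks[[sc$name]], file.path(outDir, "tiles"),
                       scene = sc$name)
    }
  })

  if (isTRUE(config$stages$detect)) stage("detect", {
    rejReport <- list()
    for (nm in names(stacks)) {
      tables[[nm]] <- runDetection(stacks[[nm]])
      rj <- attr(tables[[nm]], "rejected")
      rejReport[[nm]] <- list(rejected = rj$rejected,
                              median_mean = rj$medianMean,
                              avg_sd = rj$avgSd)
    }
    jsonlite::write_json(list(stamp = stamp, scenes = rejReport),
                         file.path(outDir, "rejected_frames.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  if (isTRUE(config$stages$classify)) stage("classify", {
    st <- config$stats
    for (nm in names(tables))
      tables[[nm]] <- classifyParticles(tables[[nm]], stacks[[nm]],
                                        elongationCut = st$elongation_cut,
                                        ringWidthPx = st$halo_ring_px,
                                        haloK = st$halo_k)
  })

  combined <- NULL
  for (nm in names(tables)) {
    t <- tables[[nm]]
    attributes(t)[c("rejected", "dropped", "masks")] <- NULL
    combined <- if (is.null(combined)) t else rbind(combined, t)
  }
  if (!is.null(combined))
    writeParticleTable(combined, file.path(outDir, "particles.csv"),
                       stamp = stamp)

  if (isTRUE(config$stages$stats) && length(tables)) stage("stats", {
    st <- config$stats
    coats <- vapply(scenes, `[[`, character(1), "coating")
    holds <- vapply(scenes, `[[`, character(1), "holder")
    names(coats) <- names(holds) <- vapply(scenes, `[[`, character(1), "name")

    # density per scene -> coating x holder grid (means over duplicates)
    cells <- data.frame(scene = names(tables),
                        coating = coats[names(tables)],
                        holder = holds[names(tables)],
                        d = NA_real_, sd = NA_real_, n = NA_integer_,
                        area_mm2 = NA_real_)
    for (i in seq_len(nrow(cells))) {
      nm <- cells$scene[i]
      part <- stackPartition(tables[[nm]], stacks[[nm]])
      dv <- particleDensity(tables[[nm]], part$scannedAreaMm2, part)
      cells$d[i] <- dv[["d"]]; cells$sd[i] <- dv[["sd"]]
      cells$n[i] <- nrow(tables[[nm]]); cells$area_mm2[i] <- part$scannedAreaMm2
    }
    ucoat <- unique(cells$coating); uhold <- unique(cells$holder)
    dmat <- matrix(NA_real_, length(ucoat), length(uhold),
                   dimnames = list(ucoat, uhold))
    for (i in seq_len(nrow(cells)))
      dmat[cells$coating[i], cells$holder[i]] <- cells$d[i]
    gridOut <- NULL
    if (!anyNA(dmat) && length(ucoat) > 1 && length(uhold) > 1) {
      ds <- summaryGrid(dmat)
      gridOut <- rbind(cbind(as.data.frame(dmat), `<d>` = ds@rowMean),
                       `<d>` = c(ds@colMean, NA))
    }
    con <- file(file.path(outDir, "density_summary.csv"), "w")
    writeLines(paste0("# ", stamp), con)
    utils::write.csv(cells, con, row.names = FALSE)
    close(con)
    if (!is.null(gridOut)) {
      con <- file(file.path(outDir, "density_grid.csv"), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(gridOut, con, row.names = TRUE)
      close(con)
    }

    # cumulative size functions per scene, on the zoom's size window
    rng <- c(scan@minAreaUm2, scan@maxAreaUm2)
    csfs <- list(); csfRows <- list()
    for (nm in names(tables)) {
      a <- tables[[nm]]$area_um2
      a <- a[a >= rng[1L] & a <= rng[2L]]
      if (!length(a)) next
      csf <- cumulativeSizeFunction(a, rng, nBins = st$n_bins,
                                    coating = coats[[nm]],
                                    holder = holds[[nm]])
      csfs[[length(csfs) + 1L]] <- csf
      csfRows[[length(csfRows) + 1L]] <- data.frame(
        scene = nm, coating = coats[[nm]], holder = holds[[nm]],
        edge_um2 = csf@binEdges, cum_percent = csf@cumFraction)
    }
    if (length(csfRows)) {
      con <- file(file.path(outDir, "csf.csv"), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(do.call(rbind, csfRows), con, row.names = FALSE)
      close(con)
    }

    comparisons <- NULL
    nHolders <- tapply(vapply(csfs, function(x) x@holder, character(1)),
                       vapply(csfs, function(x) x@coating, character(1)),
                       function(h) length(unique(h)))
    if (length(nHolders) >= 2 && all(nHolders >= 2)) {
      comparisons <- compareCoatings(csfs, areaRange = st$compare_range)
      jsonlite::write_json(list(stamp = stamp,
                                area_range_um2 = st$compare_range,
                                pairs = comparisons),
                           file.path(outDir, "comparisons.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    # forecast from the configured size laws and the measured densities
    spec1 <- if (length(truths)) truths[[1L]]@spec else
      .applyOverrides(sceneSpec, config$spec)
    allTab <- combined
    totalArea <- sum(cells$area_mm2)
    classes <- do.call(rbind, lapply(.SIZE_CLASSES, function(cl) {
      law <- spec1@sizeLaws[[cl]]
      nIn <- if (is.null(allTab) || !nrow(allTab)) 0L else
        sum(allTab$size_class == cl)
      data.frame(class = cl, density_mm2 = nIn / totalArea,
                 mode = law[1L], sigma_log = law[2L],
                 lower = law[3L], upper = law[4L])
    }))
    forecast <- extrapolateCoverage(classes, st$horizon_periods)
    sc6 <- if (is.null(allTab) || !nrow(allTab)) 0L else
      cleanlinessClass(sum(equivalentDiameter(allTab$area_um2) >= 1) /
                         totalArea * 1e6)
    jsonlite::write_json(
      list(stamp = stamp, horizon_periods = forecast@horizonPeriods,
           coverage_percent = forecast@coveragePercent,
           per_class = forecast@perClass, cleanliness_class = sc6),
      file.path(outDir, "forecast.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    # human-readable report + figure
    rpt <- c(sprintf("surface contamination pipeline report (%s)", stamp),
             sprintf("scenes: %d, zoom: %s", length(scenes), scan@zoom), "")
    if (!is.null(allTab) && nrow(allTab)) {
      rpt <- c(rpt, "particle counts by size class:",
               sprintf("  %-12s %d", names(table(allTab$size_class)),
                       as.integer(table(allTab$size_class))),
               "", "densities per scene (particles/mm^2):",
               sprintf("  %-4s %-10s %-6s d=%.3f sd=%.3f n=%d",
                       cells$scene, cells$coating, cells$holder,
                       cells$d, cells$sd, cells$n),
               "", sprintf("most probable coarse size: %s um^2",
                           tryCatch(format(histogramMode(
                             allTab$area_um2[allTab$size_class == "coarse"])),
                             error = function(e) "n/a")),
               sprintf("forecast coverage after %g periods: %.3f%%",
                       forecast@horizonPeriods, forecast@coveragePercent),
               sprintf("surface cleanliness class: %d", sc6))
    } else rpt <- c(rpt, "no particles detected")
    writeLines(rpt, file.path(outDir, "report.txt"))

    if (!is.null(allTab) && nrow(allTab)) {
      grDevices::png(file.path(outDir, "size_distribution.png"),
                     width = 800, height = 500)
      graphics::hist(allTab$area_um2, breaks = 30,
                     main = "Detected particle areas", xlab = "area (um^2)")
      grDevices::dev.off()
    }
  })

  invisible(outDir)
}
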