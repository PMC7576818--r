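#' Construct a synthetic scene specification
#'
#' Builds a [SceneSpec-class] describing one synthetic lamella scene. The
#' defaults reproduce the contamination regime the detection chain is
#' designed for: sparse dark particles at 3.3 fine, 1.6 coarse and 0.06
#' macroscopic particles per mm^2; a coarse size law with mode 155 um^2 on
#' 50-1500 um^2; mostly polygonal coarse particles (desquamated-scale-like
#' flat shapes), round/dividing fine microparticles, and ribbon-like fibers
#' in the macroscopic class; background 160 with particle level 40 on the
#' blue channel (contrast 120) and noise sd 24, i.e. a contrast-to-noise
#' ratio of 5.
#'
#' @param fieldWidthMm,fieldHeightMm field extent in mm.
#' @param densities named numeric, particles/mm^2 per size class.
#' @param sizeLaws named list of `c(mode, sigma_log, lower, upper)` per
#'   class (um^2).
#' @param morphotypeMix named list of morphotype probability vectors per
#'   class.
#' @param backgroundLevel,particleLevel,noiseSigma,gradientAmplitude
#'   rendering grey levels (0-255).
#' @param haloFraction,haloAmplitude,haloWidthUm drying-halo parameters.
#' @param occluderCount,occluderLevel,occluderExtentUm macroscopic occluder
#'   parameters; occluders are near-black disks large enough to dominate
#'   the tile their centre falls in.
#' @param seed integer RNG seed; [sampleTruth()] and [renderTiles()] are
#'   bit-reproducible given the spec.
#' @return a validated [SceneSpec-class].
#' @examples
#' spec <- sceneSpec(fieldWidthMm = 1, fieldHeightMm = 1, seed = 7)
#' spec
#' @export
sceneSpec <- function(fieldWidthMm = 2,
                      fieldHeightMm = 2,
                      densities = c(fine = 3.3, coarse = 1.6, macroscopic = 0.06),
                      sizeLaws = list(
                        fine        = c(mode = 2,    sigma_log = 1.0, lower = 0.5,  upper = 50),
                        coarse      = c(mode = 155,  sigma_log = 0.7, lower = 50,   upper = 1500),
                        macroscopic = c(mode = 2000, sigma_log = 0.8, lower = 1500, upper = 50000)),
                      morphotypeMix = list(
                        fine        = c(round = 0.5, dividing = 0.5),
                        coarse      = c(polygon = 0.9, round = 0.1),
                        macroscopic = c(fiber = 0.6, polygon = 0.2, round = 0.2)),
                      backgroundLevel = 160,
                      particleLevel = 40,
                      noiseSigma = 24,
                      gradientAmplitude = 15,
                      haloFraction = 0.1,
                      haloAmplitude = 70,
                      haloWidthUm = 8,
                      occluderCount = 0L,
                      occluderLevel = 5,
                      occluderExtentUm = c(800, 1000),
                      seed = 1L) {
  densities <- unlist(densities)                 # tolerate JSON-parsed lists
  sizeLaws <- lapply(sizeLaws, unlist)
  morphotypeMix <- lapply(morphotypeMix, unlist)
  dens <- c(fine = 0, coarse = 0, macroscopic = 0)
  dens[names(densities)] <- densities
  new("SceneSpec",
      fieldWidthMm = fieldWidthMm, fieldHeightMm = fieldHeightMm,
      densities = dens, sizeLaws = sizeLaws, morphotypeMix = morphotypeMix,
      backgroundLevel = backgroundLevel, particleLevel = particleLevel,
      noiseSigma = noiseSigma, gradientAmplitude = gradientAmplitude,
      haloFraction = haloFraction, haloAmplitude = haloAmplitude,
      haloWidthUm = haloWidthUm, occluderCount = as.integer(occluderCount),
      occluderLevel = occluderLevel, occluderExtentUm = occluderExtentUm,
      seed = as.integer(seed))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's generator state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample the ground truth of a synthetic scene
#'
#' Plants particles in the field according to the [SceneSpec-class]: the
#' count in each size class is Poisson with mean density x field area,
#' areas are drawn from the class's truncated log-normal law, morphotypes
#' from the class mixture, and halo flags as Bernoulli(haloFraction).
#' Positions are uniform subject to a hard-core exclusion: every pair of
#' particle centres is at least twice the larger equivalent radius apart,
#' so planted particles never overlap and truth matching is unambiguous.
#' Placement is by rejection sampling; if a position cannot be found within
#' `maxAttempts` proposals the field is considered too crowded and an
#' error is raised rather than silently truncating the count.
#'
#' Occluders (count fixed by the spec) are placed uniformly with diameters
#' drawn from `occluderExtentUm`.
#'
#' Reproducible: seeded from `spec@seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [SceneSpec-class].
#' @param maxAttempts rejection-sampling budget per particle.
#' @return a [SceneTruth-class].
#' @examples
#' truth <- sampleTruth(sceneSpec(fieldWidthMm = 1, fieldHeightMm = 1, seed = 3))
#' head(particles(truth))
#' @export
sampleTruth <- function(spec, maxAttempts = 1000L) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    wUm <- spec@fieldWidthMm * 1e3
    hUm <- spec@fieldHeightMm * 1e3
    areaMm2 <- spec@fieldWidthMm * spec@fieldHeightMm

    cls <- character(); areas <- numeric(); morpho <- character()
    for (cl in .SIZE_CLASSES) {
      lambda <- spec@densities[[cl]] * areaMm2
      if (lambda <= 0) next
      n <- stats::rpois(1L, lambda)
      if (n == 0L) next
      law <- spec@sizeLaws[[cl]]
      if (is.null(law)) stop("no size law for class '", cl, "'")
      a <- truncLnormSample(n, law[1L], law[2L], law[3L], law[4L])
      mix <- spec@morphotypeMix[[cl]]
      if (is.null(mix)) stop("no morphotype mix for class '", cl, "'")
      m <- sample(names(mix), n, replace = TRUE, prob = mix)
      cls <- c(cls, rep(cl, n)); areas <- c(areas, a); morpho <- c(morpho, m)
    }

    n <- length(areas)
    x <- y <- numeric(n)
    if (n) {
      # place large particles first: hard-core exclusion at twice the
      # larger equivalent radius of each pair
      ord <- order(areas, decreasing = TRUE)
      cls <- cls[ord]; areas <- areas[ord]; morpho <- morpho[ord]
      r <- sqrt(areas / pi)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (att in seq_len(maxAttempts)) {
          px <- stats::runif(1, 0, wUm); py <- stats::runif(1, 0, hUm)
          if (i == 1L) { ok <- TRUE } else {
            j <- seq_len(i - 1L)
            minD <- 2 * pmax(r[j], r[i])
            ok <- all((x[j] - px)^2 + (y[j] - py)^2 >= minD^2)
          }
          if (ok) { x[i] <- px; y[i] <- py; placed <- TRUE; break }
        }
        if (!placed)
          stop("hard-core placement failed after ", maxAttempts,
               " attempts: field too crowded for the requested densities")
      }
    }
    halo <- if (n) stats::runif(n) < spec@haloFraction else logical()

    occ <- data.frame(x_um = numeric(), y_um = numeric(), extent_um = numeric())
    if (spec@occluderCount > 0L) {
      occ <- data.frame(
        x_um = stats::runif(spec@occluderCount, 0, wUm),
        y_um = stats::runif(spec@occluderCount, 0, hUm),
        extent_um = stats::runif(spec@occluderCount,
                                 spec@occluderExtentUm[1L],
                                 spec@occluderExtentUm[2L]))
    }

    new("SceneTruth",
        particles = data.frame(
          id = seq_len(n), x_um = x, y_um = y, area_um2 = areas,
          morphotype = morpho, has_halo = halo, size_class = cls,
          stringsAsFactors = FALSE),
        occluders = occ, spec = spec)
  })
}
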