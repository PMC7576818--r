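---
title: "Methods: particle contamination analysis for tile-scan microscopy"
author: "SurfaceParticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle contamination analysis for tile-scan microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SurfaceParticles)
```

## The measurement problem

Surfaces exposed for months to the atmosphere of a closed habitat collect
airborne particulate contamination: flat desquamated skin scales and other
debris in the tens-to-hundreds of µm² range, micrometre-scale round and
dividing microparticles consistent with microbial cells, and occasional
macroscopic fibers. The exposed slides (lamellae) are imaged in place by
tile-scan brightfield microscopy at two magnifications: a low zoom
(~1.55 µm/px here) that resolves *coarse* particles of 50–1500 µm², and a
high zoom (~0.155 µm/px) that resolves *fine* particles of 0.5–50 µm².
Both windows correspond to a ~21-pixel minimum footprint, which is what
makes a single detection chain workable at both scales.

The analysis answers four questions: how many particles per mm² landed on
each coated surface; how their sizes are distributed (the cumulative size
function, CSF); whether coatings differ in the sizes they accumulate; and
what fraction of the surface would be covered if the observed deposition
rate continued for decades.

## Detection chain

Particles are dark objects on a bright background, with the strongest
contrast on the blue channel. The chain is:

1. **Frame rejection** (high zoom only). Tiles containing macroscopic
   objects whose shadows mask the fine particles are removed before
   segmentation. The per-tile mean of the blue channel is compared to the
   stack-wide median of tile means; a tile is rejected when
   $|\bar{I}_t - \mathrm{med}| > k\,\bar{\sigma}$ with $k = 2$ and
   $\bar{\sigma}$ the stack-average per-tile standard deviation. We apply
   the criterion two-sided: the motivating artefacts are dark (they lower
   the tile mean), but bright artefacts are equally disqualifying.
   Statistics are computed once from the full stack; on the stacks the
   generator produces, a second pass on the pruned stack rejects nothing
   further, which is the behaviour the single-pass contract expects.
2. **Global segmentation.** A constant grey-level threshold (default 75)
   applied strictly (`<`) to the blue channel; connected components are
   labelled with 8-connectivity and components below the zoom's minimum
   area (50 or 0.5 µm²) are discarded. The strict inequality and the
   dark-on-bright polarity are stated once here and used everywhere.
3. **Local refinement.** Each candidate is re-segmented inside a padded
   crop with threshold $T = \alpha \cdot \mathrm{mean(crop)}$,
   $\alpha = 0.6$ by default. $\alpha$ was fixed by requiring that on a
   noise-free dark disk the refined mask reproduces the global mask; it
   is configurable because the optimal fraction depends on the fill
   factor of typical crops. The working channel is the blue channel at
   low zoom and an 8-bit rescaled R+G+B sum at high zoom. The source
   protocol's channel-per-zoom sentence is self-contradictory (it assigns
   "high zoom" twice), so the assignment is exposed as the
   `refineChannel` switch rather than hard-wired.
4. **Measurement.** Area is pixel count × pixel size²; the centroid is
   reported in mosaic µm coordinates (origin top-left, y downward);
   elongation is the major/minor axis ratio of the ellipse with the same
   second central moments. We add the 1/12 per-pixel moment (the second
   moment of a unit square) to the covariance diagonal: this makes the
   axes exact for solid rectangles (a 40 × 10 px bar gives exactly 4.0)
   and keeps one-pixel-wide masks finite.
5. **Cross-tile merging.** Particles split by tile seams are merged when
   their bounding boxes are adjacent within 1 px in mosaic coordinates,
   then re-measured from the union of their pixels. Tiling is an
   acquisition artefact; without merging, every seam-straddling particle
   would be double-counted with half its area.

## Classification

Size classes partition the area axis as fine $[0.5, 50)$, coarse
$[50, 1500]$ and macroscopic $(1500, \infty)$ µm². The half-open boundary
at 50 and closed boundary at 1500 keep the conventional "50–1500" coarse
window intact where printed ranges share endpoints.

Fibers are flagged when elongation ≥ 5 (the `elongationCut`). The cut is
not dictated by the source statistics — only that fibers separate
"unambiguously" — and 5 separates the generator's planted morphotypes
(compact shapes measure below ~2.5, ribbons above ~6) with a wide margin.

A drying halo — the bright ring left by an evaporated droplet — is
flagged when the mean blue intensity in an annulus 1–5 px beyond the
particle boundary exceeds the tile background mean by 2 background
standard deviations (background = pixels at or above the global
threshold). Near tile edges the annulus is clipped to the tile and the
test proceeds if at least a quarter of it remains; otherwise the flag is
`FALSE` with a logged reason. Ring width and `k` are exposed in the
configuration; both are package choices, not published values.

## Statistics

- **Density**: count / scanned area. The dispersion is the tile-to-tile
  standard deviation of per-tile densities divided by $\sqrt{n_\mathrm{tiles}}$.
  Published per-cell "±" values match neither pure Poisson error nor
  across-holder spread; tile-to-tile dispersion is our documented
  interpretation.
- **Summary grid**: coating × holder densities with arithmetic-mean
  marginals and sample (n−1) standard deviations. In the fine-particle
  reference grid the printed row marginals are inconsistent with the
  printed cells (e.g. a row printing 4.45 whose cells average 4.59); the
  package always computes arithmetic means, and only the column
  marginals of that grid are used for verification.
- **CSF**: 30 logarithmically spaced bin edges per class window (binning
  is a package choice); the value at an edge is the percentage of
  particles with area ≤ edge, so the function is non-decreasing and ends
  at 100%.
- **Coating comparison**: for each coating pair, the per-holder
  cumulative fractions at the edges inside the contested window (default
  200–900 µm² for coarse particles) are pooled and compared with the
  unpaired pooled-variance Student t-test (df = $n_a + n_b - 2$,
  two-sided). No multiple-testing correction is applied, matching the
  raw pairwise reporting convention. Degenerate inputs are defined
  explicitly: zero pooled variance with equal means gives $t=0, p=1$;
  with unequal means $p=0$ plus a warning.
- **Coverage forecast**: per exposure period each class contributes
  $d \cdot \mathbb{E}[A] \cdot 10^{-6}$ of the surface ($d$ in mm⁻²,
  $\mathbb{E}[A]$ in µm²), linear in the horizon. With the calibrated
  laws below, the forecast is what `scripts/acceptance.R` recomputes.
- **Cleanliness class**: the log-decade class of the areal concentration
  of particles with equivalent diameter ≥ 1 µm (area ≥ π/4 µm²): the
  smallest integer $N$ with density ≤ $10^N$ per m², floored at 0. The
  exact particle basis for the published class is unstated; the decade
  rule is our documented choice.

## The size law

Only a monomodal, right-skewed histogram with hard range limits is
available as a constraint, so areas are modelled as a **truncated
log-normal parameterised by its mode**: with log-sd $\sigma$, the
log-mean is $\mu = \log(\mathrm{mode}) + \sigma^2$, and truncation to
$(\ell, u)$ with $\ell < \mathrm{mode} < u$ rescales the density without
moving the mode — so a target most-probable area (155 µm² for coarse
particles) is directly plantable. The truncated mean has the closed form

$$\mathbb{E}[A] = e^{\mu + \sigma^2/2}\,
\frac{\Phi(b-\sigma) - \Phi(a-\sigma)}{\Phi(b) - \Phi(a)},
\qquad a = \tfrac{\log \ell - \mu}{\sigma},\; b = \tfrac{\log u - \mu}{\sigma},$$

verified in the tests against numerical integration and rejection-sampled
Monte-Carlo draws. Calibration used throughout: coarse mode 155 µm²,
$\sigma = 0.7$ on 50–1500 µm² at 1.6 /mm²; fine mode 2 µm², $\sigma = 1.0$
on 0.5–50 µm² at 3.3 /mm². $\sigma$ values are package calibrations
chosen to give plausibly broad monomodal histograms inside each window;
they are not published quantities.

```{r coverage}
cls <- data.frame(class = c("coarse", "fine"),
                  density_mm2 = c(1.6, 3.3),
                  mode = c(155, 2), sigma_log = c(0.7, 1.0),
                  lower = c(50, 0.5), upper = c(1500, 50))
extrapolateCoverage(cls, 40)   # 40 six-month periods = 20 years
```

## The synthetic scene generator

No image data are deposited with the source study, so the generator is a
first-class module that reproduces the statistical structure the
detection chain assumes, with planted ground truth for every scene:

- particle counts per class are Poisson with mean density × field area;
- areas follow the truncated log-normal laws; morphotypes follow
  per-class mixtures (mostly polygons in the coarse class, round/dividing
  in the fine class, ribbons among macroscopic particles);
- positions are uniform with a hard-core exclusion of twice the larger
  equivalent radius per pair — at a few particles/mm² genuine overlap is
  negligible, and exclusion makes truth matching unambiguous. Placement
  failure after a bounded number of proposals is an explicit error,
  never a silent truncation;
- rendering: background 160, particle blue level 40 (contrast 120), red
  and green at 40% of that contrast; additive Gaussian noise σ = 24 so
  that the default contrast-to-noise ratio is 5 (detection should be
  reliable but not trivial); a linear illumination gradient of 15 grey
  levels peak-to-peak in a random direction; shapes rasterised by 4×4
  subsampling so the rendered pixel count is an unbiased estimate of
  true area / pixel area;
- drying halos: a bright annulus (+70 grey, 8 µm wide) around a
  configurable fraction of particles;
- occluders: near-black disks of 800–1000 µm diameter. They model
  macroscopic objects whose shadows dominate a frame; the size is chosen
  so that the tile containing the occluder centre always trips the
  2$\bar\sigma$ rejection criterion even when the disk straddles a tile
  corner — decisively larger than a tile's short dimension at low zoom.

Field size is configurable (default 2 × 2 mm): the physical lamella
dimensions are not published, and the tests deliberately use desk-scale
fields. What the generator does **not** emulate: physical optics (PSF,
depth of field, defocus), flat-field or chromatic artefacts, particle
sub-structure, overlapping particles, and spatially correlated noise.
Passing tests therefore demonstrate the correctness of the chain's logic
and its statistical calibration on idealised scenes — not robustness to
every optical artefact of real acquisitions.

Determinism: `sampleTruth()` draws from a private RNG stream seeded with
`spec@seed`, `renderTiles()` from `spec@seed + 1`; both restore the
caller's RNG state, and a fixed spec reproduces scenes bit-for-bit.

```{r scene}
spec <- sceneSpec(fieldWidthMm = 0.8, fieldHeightMm = 0.8,
                  densities = c(coarse = 6), seed = 11)
truth <- sampleTruth(spec)
stack <- renderTiles(truth, scanConfig("low"))
tab <- classifyParticles(runDetection(stack), stack)
head(tab[, c("x_um", "y_um", "area_um2", "elongation", "size_class")])
```

## Problem sizes and numerical choices

The test-suite scenes are 0.3–2 mm on a side with densities of 2–10
particles/mm² (tens of particles per scene, 10–20 seeds per property),
and distribution-level checks use 10⁴–10⁶ direct draws from the size
laws; these sizes make every property decisive at desk scale while the
whole suite stays in the minutes range. Other numerical conventions:
areas at exactly the global threshold are background (strict `<`); the
candidate-overlap winner in local refinement is the component with the
largest overlap; ties in the histogram mode resolve to the smallest bin;
`summaryGrid()` refuses missing cells rather than imputing.

## Known limitations

- Elongation of strongly curved fibers underestimates the
  length-to-width ratio of the uncurled ribbon (second moments see the
  bent envelope); the fiber cut of 5 absorbs this for the planted
  aspect ratio of ~12.
- Halo flags are `NA` for particles merged across tile seams (the
  annulus would span two tiles).
- The coverage forecast is linear by construction; it ignores saturation,
  overlap and removal (cleaning), so it is an upper-bound style
  extrapolation for the horizons considered.
- `particleDensity()` dispersion assumes tiles of (near-)equal area; the
  partial last row/column tiles are averaged into a common tile area.
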