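# shared fixtures: all synthetic, built in code at test time

# a uniform 8-bit RGB tile
uniformTile <- function(level, h = 64L, w = 64L) {
  array(as.integer(level), dim = c(h, w, 3L))
}

# paint a filled disk (value on all channels, blue may differ) into a tile
paintDisk <- function(tile, cy, cx, r, value, blueValue = value) {
  d <- dim(tile)
  rows <- matrix(seq_len(d[1L]), d[1L], d[2L])
  cols <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  m <- (rows - cy)^2 + (cols - cx)^2 <= r^2
  for (ch in 1:2) { p <- tile[, , ch]; p[m] <- as.integer(value); tile[, , ch] <- p }
  p <- tile[, , 3L]; p[m] <- as.integer(blueValue); tile[, , 3L] <- p
  tile
}

# hand-built truth with given particle rows (bypasses the sampler)
manualTruth <- function(spec, particlesDf,
                        occludersDf = data.frame(x_um = numeric(),
                                                 y_um = numeric(),
                                                 extent_um = numeric())) {
  new("SceneTruth", particles = particlesDf, occluders = occludersDf,
      spec = spec)
}

# greedy truth matching by centroid distance
matchTruth <- function(truth, tab, maxDistUm = 5) {
  p <- particles(truth)
  if (!nrow(p)) return(list(recall = NA_real_,
                            precision = if (nrow(tab)) 0 else 1,
                            map = integer()))
  if (!nrow(tab)) return(list(recall = 0, precision = NA_real_, map = integer()))
  d <- sqrt(outer(p$x_um, tab$x_um, "-")^2 + outer(p$y_um, tab$y_um, "-")^2)
  best <- apply(d, 1L, which.min)
  hit <- d[cbind(seq_len(nrow(p)), best)] <= maxDistUm
  list(recall = mean(hit),
       precision = mean(apply(d, 2L, min) <= maxDistUm),
       map = ifelse(hit, best, NA_integer_),
       dist = d[cbind(seq_len(nrow(p)), best)])
}

# independent permutation oracle for the unpaired t-test (two-sided,
# permutes group labels, recomputes the pooled-variance t each time)
permutationP <- function(a, b, R = 1e5L) {
  z <- c(a, b); z2 <- z^2
  na <- length(a); nb <- length(b); n <- na + nb
  S <- sum(z); S2 <- sum(z2)
  tFromSums <- function(sx, sx2) {
    sy <- S - sx; sy2 <- S2 - sx2
    ssx <- sx2 - sx^2 / na; ssy <- sy2 - sy^2 / nb
    sp2 <- (ssx + ssy) / (n - 2)
    (sx / na - sy / nb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  t0 <- abs(tFromSums(sum(a), sum(a^2)))
  hits <- 0L
  for (r in seq_len(R)) {
    ia <- sample.int(n, na)
    if (abs(tFromSums(sum(z[ia]), sum(z2[ia]))) >= t0 - 1e-12)
      hits <- hits + 1L
  }
  hits / R
}
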