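# Independent brute-force oracles used by the tests. These deliberately
# re-derive results by the most literal route possible and share no code
# with the package internals.

# Literal iterate-until-two-maxima Intermodes rule on a 256-bin histogram.
oracle_intermodes <- function(counts, max_iter = 10000L) {
  h <- as.numeric(counts)
  for (iter in seq_len(max_iter)) {
    maxima <- integer(0)
    for (i in 1:256) {
      left <- if (i == 1) -Inf else h[i - 1]
      right <- if (i == 256) -Inf else h[i + 1]
      if (h[i] > left && h[i] > right) maxima <- c(maxima, i)
    }
    if (length(maxima) == 2L) return((maxima[1] + maxima[2]) / 2)
    if (length(maxima) < 2L) stop("oracle: not bimodal")
    smoothed <- numeric(256)
    for (i in 1:256) {
      left <- if (i == 1) 0 else h[i - 1]
      right <- if (i == 256) 0 else h[i + 1]
      smoothed[i] <- (left + h[i] + right) / 3
    }
    h <- smoothed
  }
  stop("oracle: not bimodal")
}

# O(n^2) exhaustive nearest-neighbour colocalization fraction.
oracle_coloc_fraction <- function(ref, target, window) {
  n_hit <- 0L
  for (i in seq_len(nrow(ref))) {
    best <- Inf
    for (j in seq_len(nrow(target))) {
      d <- sqrt(sum((ref[i, ] - target[j, ])^2))
      if (d < best) best <- d
    }
    if (best <= window) n_hit <- n_hit + 1L
  }
  n_hit / nrow(ref)
}

# Scalar even-odd point-in-polygon, applied to every voxel centre.
oracle_integrated_density <- function(img2d, voxel_size, poly) {
  total <- 0
  d <- dim(img2d)
  for (iy in seq_len(d[1])) {
    for (ix in seq_len(d[2])) {
      py <- (iy - 0.5) * voxel_size[1]
      px <- (ix - 0.5) * voxel_size[2]
      inside <- FALSE
      j <- nrow(poly)
      for (i in seq_len(nrow(poly))) {
        if ((poly[i, 1] > py) != (poly[j, 1] > py)) {
          x_cross <- (poly[j, 2] - poly[i, 2]) * (py - poly[i, 1]) /
            (poly[j, 1] - poly[i, 1]) + poly[i, 2]
          if (px < x_cross) inside <- !inside
        }
        j <- i
      }
      if (inside) total <- total + img2d[iy, ix]
    }
  }
  total
}

# Two-sample equal-variance t statistic from the textbook formula.
oracle_t_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
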