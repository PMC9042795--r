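#' Intermodes histogram threshold
#'
#' The classical Intermodes automatic threshold: the 256-bin histogram is
#' smoothed iteratively with a 3-point moving mean (zero counts assumed
#' outside the range) until exactly two local maxima remain; the threshold
#' is the midpoint of the two mode bins. Deterministic; fails on histograms
#' that never become bimodal (flat or single-peaked input).
#'
#' @param counts Numeric vector of 256 histogram bin counts.
#' @param max_iter Maximum smoothing iterations before declaring the
#'   histogram not bimodal.
#' @return The threshold as a (possibly half-integer) bin position in
#'   `1..256`, with attribute `modes` giving the two mode bins.
#' @examples
#' h <- numeric(256); h[10] <- 50; h[200] <- 80
#' intermodes_threshold(h)  # 105
#' @export
intermodes_threshold <- function(counts, max_iter = 10000L) {
  if (length(counts) != 256L) stop("expected a 256-bin histogram")
  if (all(counts == 0)) stop("histogram has no nonzero bin")
  h <- as.numeric(counts)
  local_maxima <- function(y) {
    n <- length(y)
    which(y > c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  }
  for (iter in seq_len(max_iter)) {
    m <- local_maxima(h)
    if (length(m) == 2L) {
      thr <- mean(m)
      attr(thr, "modes") <- m
      attr(thr, "iterations") <- iter - 1L
      return(thr)
    }
    if (length(m) < 2L) break
    h <- (c(0, h[-256]) + h + c(h[-1], 0)) / 3
  }
  stop("not bimodal: histogram never reached exactly two modes")
}

# Map a bin position (1..256, possibly half-integer) back to intensity
# units for a histogram spanning [lo, hi] with 256 equal-width bins.
bin_to_intensity <- function(bin, lo, hi) {
  w <- (hi - lo) / 256
  lo + (bin - 0.5) * w
}

#' Threshold an image channel into a foreground mask
#'
#' Foreground is strictly above the threshold (`intensity > t`); ties fall
#' to background, which makes the constant-image case well defined. For the
#' `"intermodes"` method the channel histogram uses 256 equal-width bins
#' spanning the channel's `[min, max]`.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param method `"intermodes"`, `"fixed"` or `"fraction_of_max"`.
#' @param value Threshold intensity for `"fixed"`; fraction of the channel
#'   maximum for `"fraction_of_max"`.
#' @return A logical array, with attribute `threshold` (intensity units).
#' @export
threshold_image <- function(stack, channel = 1L,
                            method = c("intermodes", "fixed",
                                       "fraction_of_max"),
                            value = NULL) {
  method <- match.arg(method)
  img <- get_channel(stack, channel)
  thr <- switch(method,
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs `value`")
      value
    },
    fraction_of_max = {
      if (is.null(value)) stop("method 'fraction_of_max' needs `value`")
      value * max(img)
    },
    intermodes = {
      lo <- min(img); hi <- max(img)
      if (hi <= lo) stop("not bimodal: constant image")
      br <- seq(lo, hi, length.out = 257L)
      cnt <- tabulate(pmin(findInterval(img, br, rightmost.closed = TRUE),
                           256L), nbins = 256L)
      bin_to_intensity(as.numeric(intermodes_threshold(cnt)), lo, hi)
    })
  mask <- img > thr
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

#' Label connected components of a binary mask
#'
#' Connected-component labeling with selectable connectivity: `"full"`
#' (8-connectivity in 2D, 26 in 3D; the default, since small blurred spots
#' fragment under face-only connectivity) or `"face"` (4 / 6). Labels are
#' consecutive `1..n_objects` in raster order of first contact.
#'
#' @param mask A logical array (2D or 3D).
#' @param connectivity `"full"` or `"face"`.
#' @return A `labeled_objects` list: `label_map` (integer array),
#'   `n_objects`, `connectivity`.
#' @export
label_objects <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  if (!is.logical(mask)) stop("mask must be logical")
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  lab <- .cc_label(as.logical(mask), as.integer(d), connectivity == "full")
  n <- attr(lab, "n_objects")
  lab <- array(as.integer(lab), d)
  structure(list(label_map = lab, n_objects = n,
                 connectivity = connectivity),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat("labeled_objects:", x$n_objects, "object(s),",
      x$connectivity, "connectivity\n")
  invisible(x)
}

#' Measure labeled objects
#'
#' Computes per-object morphometrics and intensities: voxel count, volume
#' (voxel count x voxel volume, in cubic micrometres; area in square
#' micrometres for 2D), equivalent diameter (sphere / circle of equal
#' volume, nm), intensity-weighted centroid (nm, first channel), and mean
#' and integrated intensity per channel. Integrated intensity is exactly
#' `mean_intensity * n_voxels`.
#'
#' @param labels A `labeled_objects` from [label_objects()].
#' @param stack The [image_stack()] the labels were derived from.
#' @return A data frame with one row per object (a granule record table).
#' @export
measure_objects <- function(labels, stack) {
  stopifnot(inherits(labels, "labeled_objects"),
            inherits(stack, "image_stack"))
  if (!identical(dim(labels$label_map), dim(stack))) {
    stop("label map and stack must share the same grid")
  }
  n <- labels$n_objects
  nd <- length(dim(stack))
  ax <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  vx_vol <- voxel_volume_um3(stack)
  if (n == 0L) {
    out <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0),
                      equivalent_diameter_nm = numeric(0))
    for (a in ax) out[[paste0("centroid_", a, "_nm")]] <- numeric(0)
    for (ch in names(stack$channels)) {
      out[[paste0("mean_", ch)]] <- numeric(0)
      out[[paste0("integrated_", ch)]] <- numeric(0)
    }
    return(out)
  }
  lab_vec <- as.integer(labels$label_map)
  sel <- lab_vec > 0L
  lab_sel <- lab_vec[sel]
  n_vox <- tabulate(lab_sel, nbins = n)
  vol <- n_vox * vx_vol
  eq_diam <- if (nd == 3L) {
    (6 * vol / pi)^(1 / 3) * 1000  # um -> nm
  } else {
    2 * sqrt(vol / pi) * 1000
  }
  # voxel-centre coordinates (nm) of foreground voxels
  idx <- which(sel)
  d <- dim(stack)
  coords <- matrix(0, length(idx), nd)
  rem <- idx - 1L
  for (a in seq_len(nd)) {
    coords[, a] <- (rem %% d[a]) + 1L
    rem <- rem %/% d[a]
  }
  coords <- sweep(coords - 0.5, 2, stack$voxel_size, "*")
  w <- as.numeric(stack$channels[[1]])[idx]
  wsum <- as.numeric(tapply(w, lab_sel, sum))
  out <- data.frame(id = seq_len(n), n_voxels = n_vox, volume_um3 = vol,
                    equivalent_diameter_nm = eq_diam)
  for (a in seq_len(nd)) {
    cw <- as.numeric(tapply(w * coords[, a], lab_sel, sum)) / wsum
    out[[paste0("centroid_", ax[a], "_nm")]] <- cw
  }
  for (ch in names(stack$channels)) {
    v <- as.numeric(stack$channels[[ch]])[idx]
    s <- as.numeric(tapply(v, lab_sel, sum))
    out[[paste0("mean_", ch)]] <- s / n_vox
    out[[paste0("integrated_", ch)]] <- s
  }
  out
}
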