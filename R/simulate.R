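#' Parameters for a synthetic granule field
#'
#' Describes a field of ellipsoidal, optionally blurred and noisy,
#' fluorescent granules with known ground truth. Defaults reproduce the
#' statistical structure of RNP granules imaged by 3D STED: a Gaussian
#' diameter distribution of 400 +/- 129 nm, spherical shape, and a
#' 60 x 40 x 40 nm voxel grid.
#'
#' Granules are rendered as hard ellipsoids of the sampled diameter filled
#' at uniform density (total signal = `copies * unit_intensity`, split
#' evenly over the voxels whose centres fall inside the ellipsoid), then
#' convolved with a Gaussian PSF. This separates true size from blur so
#' morphometrics can be validated with and without the PSF. Noise is applied
#' in photon-physics order: blur, then Poisson resampling, then additive
#' Gaussian read noise.
#'
#' @param field_shape Integer grid shape, `(z, y, x)` voxels (or `(y, x)`).
#' @param voxel_size nm per voxel per axis, same order as `field_shape`.
#' @param n_granules Number of granules to place.
#' @param diameter_mean,diameter_sd Gaussian diameter distribution (nm);
#'   sampled diameters are rejection-truncated to exceed two voxels'
#'   physical extent (bounded at 10^4 attempts).
#' @param axis_ratio Major/minor axis ratio (1 = spheres). The major axis is
#'   aligned with the grid x axis; minor axes equal the sampled diameter.
#' @param unit_intensity Photons contributed by one molecule.
#' @param copies Molecules per granule: a single count, a named weight
#'   vector over counts (e.g. `c("1" = 0.7, "2" = 0.3)`), or
#'   `list(poisson = lambda)` (zero-truncated).
#' @param psf_sigma Gaussian PSF sigma in nm per axis (0 = no blur;
#'   a scalar is recycled).
#' @param background_level Uniform background photons per voxel.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`,
#'   `"poisson+gaussian"`.
#' @param noise_sd SD of the additive Gaussian read noise (used by the
#'   gaussian models).
#' @param min_separation Minimum centroid-to-centroid distance (nm).
#' @param antialias Voxelize ellipsoid boundaries by fractional coverage
#'   (a 4^3 subsample grid per voxel) instead of hard in/out tests on voxel
#'   centres. Hard voxelization (the default) keeps segmentation-support
#'   semantics crisp; fractional coverage removes quantization jitter from
#'   sub-voxel shape measurements (line-profile axis lengths).
#' @param seed Integer root seed.
#' @return A `granule_field_params` list.
#' @export
granule_field_params <- function(field_shape = c(32L, 96L, 96L),
                                 voxel_size = c(60, 40, 40),
                                 n_granules = 50L,
                                 diameter_mean = 400,
                                 diameter_sd = 129,
                                 axis_ratio = 1,
                                 unit_intensity = 1000,
                                 copies = 1L,
                                 psf_sigma = 0,
                                 background_level = 0,
                                 noise_model = c("none", "gaussian",
                                                 "poisson",
                                                 "poisson+gaussian"),
                                 noise_sd = 0,
                                 min_separation = 0,
                                 antialias = FALSE,
                                 seed = 1L) {
  noise_model <- match.arg(noise_model)
  nd <- length(field_shape)
  stopifnot(nd %in% c(2L, 3L), length(voxel_size) == nd)
  if (diameter_mean <= 0) stop("diameter_mean must be > 0")
  if (diameter_sd < 0) stop("diameter_sd must be >= 0")
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (n_granules < 0) stop("n_granules must be >= 0")
  if (length(psf_sigma) == 1L) psf_sigma <- rep(psf_sigma, nd)
  structure(list(field_shape = as.integer(field_shape),
                 voxel_size = as.numeric(voxel_size),
                 n_granules = as.integer(n_granules),
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 axis_ratio = axis_ratio, unit_intensity = unit_intensity,
                 copies = copies, psf_sigma = as.numeric(psf_sigma),
                 background_level = background_level,
                 noise_model = noise_model, noise_sd = noise_sd,
                 min_separation = min_separation,
                 antialias = isTRUE(antialias), seed = seed),
            class = "granule_field_params")
}

sample_diameters <- function(n, mean, sd, min_nm) {
  if (n == 0) return(numeric(0))
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(10000L)) {
      x <- rnorm(1, mean, sd)
      if (x > min_nm) { d[i] <- x; break }
    }
    if (is.na(d[i])) {
      stop("could not sample a diameter above the two-voxel floor (",
           signif(min_nm, 4), " nm) in 10000 attempts")
    }
  }
  d
}

sample_copies <- function(n, copies) {
  if (n == 0) return(integer(0))
  if (is.list(copies) && !is.null(copies$poisson)) {
    k <- rpois(n, copies$poisson)
    while (any(k == 0)) k[k == 0] <- rpois(sum(k == 0), copies$poisson)
    return(as.integer(k))
  }
  if (length(copies) == 1L && is.null(names(copies))) {
    return(rep(as.integer(copies), n))
  }
  w <- as.numeric(copies)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("copy weights must be non-negative and sum to 1")
  }
  ks <- as.integer(names(copies))
  sample(ks, n, replace = TRUE, prob = w)
}

# Rejection placement of n centroids (nm) with pairwise min separation.
# margin_nm keeps each granule's extent inside the field.
place_centroids <- function(n, extent_nm, margin_nm, min_sep, max_tries) {
  nd <- length(extent_nm)
  pts <- matrix(NA_real_, n, nd)
  lo <- pmin(margin_nm, extent_nm / 2)
  hi <- pmax(extent_nm - margin_nm, extent_nm / 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("field too crowded: could not place ", n,
           " granules at min_separation after ", max_tries, " attempts")
    }
    cand <- runif(nd, lo, hi)
    ok <- TRUE
    if (placed > 0L && min_sep > 0) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2)
      ok <- all(d2 >= min_sep^2)
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

# Render one uniform-density ellipsoid into `img` (modified copy returned).
# centre in nm; semi-axes in nm per grid axis; total added signal = total.
# subsamples = 1: hard voxelization (voxel centre in/out);
# subsamples > 1: fractional boundary-voxel coverage from a subsample grid.
render_ellipsoid <- function(img, voxel_size, centre, semi, total,
                             subsamples = 1L) {
  nd <- length(dim(img))
  d <- dim(img)
  s <- as.integer(subsamples)
  idx <- vector("list", nd)
  for (a in seq_len(nd)) {
    lo <- max(1L, floor((centre[a] - semi[a]) / voxel_size[a] - 1))
    hi <- min(d[a], ceiling((centre[a] + semi[a]) / voxel_size[a] + 1))
    idx[[a]] <- seq.int(lo, hi)
  }
  # per-axis sample positions: voxel centres, or s subcentres per voxel
  sub_grid <- function(a) {
    centres <- (idx[[a]] - 0.5) * voxel_size[a]
    if (s == 1L) return(centres)
    off <- ((seq_len(s) - 0.5) / s - 0.5) * voxel_size[a]
    as.numeric(outer(off, centres, "+"))
  }
  grids <- lapply(seq_len(nd), function(a) {
    ((sub_grid(a) - centre[a]) / semi[a])^2
  })
  inside_sub <- if (nd == 3L) {
    outer(outer(grids[[1]], grids[[2]], "+"), grids[[3]], "+") <= 1
  } else {
    outer(grids[[1]], grids[[2]], "+") <= 1
  }
  cover <- if (s == 1L) {
    inside_sub * 1.0
  } else {
    n <- lengths(idx)
    b <- array(inside_sub, as.integer(rbind(s, n)))
    apply(b, seq.int(2L, 2L * nd, by = 2L), sum) / s^nd
  }
  if (sum(cover) == 0) {
    vi <- pmin(pmax(round(centre / voxel_size + 0.5), 1), d)
    vi <- matrix(vi, 1)
    img[vi] <- img[vi] + total
    return(img)
  }
  add <- cover * (total / sum(cover))
  if (nd == 3L) {
    img[idx[[1]], idx[[2]], idx[[3]]] <-
      img[idx[[1]], idx[[2]], idx[[3]]] + add
  } else {
    img[idx[[1]], idx[[2]]] <- img[idx[[1]], idx[[2]]] + add
  }
  img
}

apply_psf_noise <- function(img, params) {
  if (any(params$psf_sigma > 0)) {
    sig_vox <- params$psf_sigma / params$voxel_size
    img <- array(.gauss_blur(as.numeric(img), dim(img), sig_vox), dim(img))
  }
  img <- img + params$background_level
  if (params$noise_model %in% c("poisson", "poisson+gaussian") ||
      params$noise_model == "gaussian") {
    set.seed(derive_seed(params$seed, "noise"))
    if (params$noise_model %in% c("poisson", "poisson+gaussian")) {
      img <- array(rpois(length(img), pmax(img, 0)), dim(img))
      img <- img * 1.0
    }
    if (params$noise_model %in% c("gaussian", "poisson+gaussian")) {
      img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
    }
  }
  img
}

#' Generate a synthetic granule field with ground truth
#'
#' Places `n_granules` ellipsoids with Gaussian-distributed diameters in the
#' field, renders them at uniform density, applies PSF blur, background and
#' noise per the parameters, and returns the image together with an exact
#' ground-truth table. Identical parameters and seed give bit-identical
#' output.
#'
#' With `psf_sigma = 0` and `noise_model = "none"` the sum of
#' above-background voxel intensities of each granule equals
#' `copies * unit_intensity` exactly (uniform-fill construction).
#'
#' @param params A [granule_field_params()].
#' @return A list with `image` (an [image_stack()]) and `truth`
#'   (a data frame: id, centroid nm per axis, diameter_nm, semi-axes nm,
#'   copies).
#' @export
generate_granule_image <- function(params) {
  stopifnot(inherits(params, "granule_field_params"))
  nd <- length(params$field_shape)
  extent <- params$field_shape * params$voxel_size
  img <- array(0, params$field_shape)
  set.seed(derive_seed(params$seed, "granules"))
  n <- params$n_granules
  min_d <- 2 * max(params$voxel_size)
  diam <- sample_diameters(n, params$diameter_mean, params$diameter_sd, min_d)
  copies <- sample_copies(n, params$copies)
  # keep each granule (and its blur tails) inside the field
  margin <- if (n > 0) {
    max(diam) * params$axis_ratio / 2 + 4 * max(params$psf_sigma)
  } else 0
  cen <- place_centroids(n, extent, margin, params$min_separation,
                         max_tries = max(1000L, 200L * n))
  semi <- matrix(0, n, nd)
  truth <- data.frame(id = integer(0))
  if (n > 0) {
    for (i in seq_len(n)) {
      s <- rep(diam[i] / 2, nd)
      s[nd] <- s[nd] * params$axis_ratio  # major axis along x
      semi[i, ] <- s
      img <- render_ellipsoid(img, params$voxel_size, cen[i, ], s,
                              copies[i] * params$unit_intensity,
                              subsamples = if (params$antialias) 4L else 1L)
    }
    ax <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
    truth <- data.frame(id = seq_len(n))
    for (a in seq_len(nd)) truth[[paste0(ax[a], "_nm")]] <- cen[, a]
    truth$diameter_nm <- diam
    for (a in seq_len(nd)) truth[[paste0("semi_", ax[a], "_nm")]] <- semi[, a]
    truth$copies <- copies
  }
  img <- apply_psf_noise(img, params)
  list(image = image_stack(list(granules = img), params$voxel_size),
       truth = truth)
}

#' Generate a two-channel field with a controlled colocalization fraction
#'
#' `n_ref` reference granules are placed first. Exactly
#' `round(true_coloc_fraction * n_ref)` of them receive a target-channel
#' partner displaced by isotropic Gaussian jitter; the remaining target
#' granules are placed uniformly (respecting `min_separation` within their
#' own channel). Ground truth records the partner assignment.
#'
#' @param params A [granule_field_params()] (shared rendering parameters;
#'   `n_granules` is ignored).
#' @param n_ref,n_target Object counts in the reference and target channel;
#'   `n_target` must be at least the number of partnered objects.
#' @param true_coloc_fraction Fraction of reference objects with a true
#'   partner, in `[0, 1]`.
#' @param jitter_sd Isotropic Gaussian displacement SD of partners (nm).
#' @param render Render the two channels into images (default). With
#'   `render = FALSE` only the ground-truth centroid tables are produced
#'   (`image` is `NULL`), which is much faster on large sparse fields when
#'   only point statistics are needed.
#' @return A list with `image` (two-channel [image_stack()]:
#'   `ref`, `target`), `truth_ref`, and `truth_target` (with `partner_of`:
#'   the id of the partnered reference object or `NA`).
#' @export
generate_two_channel_field <- function(params, n_ref, n_target,
                                       true_coloc_fraction, jitter_sd = 0,
                                       render = TRUE) {
  stopifnot(inherits(params, "granule_field_params"))
  if (true_coloc_fraction < 0 || true_coloc_fraction > 1) {
    stop("true_coloc_fraction must be in [0, 1]")
  }
  n_partner <- as.integer(round(true_coloc_fraction * n_ref))
  if (n_target < n_partner) {
    stop("n_target (", n_target, ") smaller than partnered count (",
         n_partner, ")")
  }
  nd <- length(params$field_shape)
  extent <- params$field_shape * params$voxel_size
  set.seed(derive_seed(params$seed, "twochannel"))
  min_d <- 2 * max(params$voxel_size)
  d_ref <- sample_diameters(n_ref, params$diameter_mean, params$diameter_sd,
                            min_d)
  d_tar <- sample_diameters(n_target, params$diameter_mean,
                            params$diameter_sd, min_d)
  margin <- max(c(d_ref, d_tar, 0)) / 2
  cen_ref <- place_centroids(n_ref, extent, margin, params$min_separation,
                             max_tries = max(1000L, 200L * n_ref))
  # partnered targets: reference centroid + jitter, clamped into the field
  partner_ids <- if (n_partner > 0) sort(sample.int(n_ref, n_partner)) else
    integer(0)
  cen_tar <- matrix(NA_real_, n_target, nd)
  if (n_partner > 0) {
    jit <- matrix(rnorm(n_partner * nd, 0, jitter_sd), n_partner, nd)
    p <- cen_ref[partner_ids, , drop = FALSE] + jit
    for (a in seq_len(nd)) {
      p[, a] <- pmin(pmax(p[, a], params$voxel_size[a] / 2),
                     extent[a] - params$voxel_size[a] / 2)
    }
    cen_tar[seq_len(n_partner), ] <- p
  }
  n_free <- n_target - n_partner
  if (n_free > 0) {
    cen_tar[n_partner + seq_len(n_free), ] <-
      place_centroids(n_free, extent, margin, params$min_separation,
                      max_tries = max(1000L, 200L * n_free))
  }
  image <- NULL
  if (render) {
    ch_ref <- array(0, params$field_shape)
    ch_tar <- array(0, params$field_shape)
    for (i in seq_len(n_ref)) {
      ch_ref <- render_ellipsoid(ch_ref, params$voxel_size, cen_ref[i, ],
                                 rep(d_ref[i] / 2, nd),
                                 params$unit_intensity,
                                 subsamples = if (params$antialias) 4L else 1L)
    }
    for (i in seq_len(n_target)) {
      ch_tar <- render_ellipsoid(ch_tar, params$voxel_size, cen_tar[i, ],
                                 rep(d_tar[i] / 2, nd),
                                 params$unit_intensity,
                                 subsamples = if (params$antialias) 4L else 1L)
    }
    ch_ref <- apply_psf_noise(ch_ref, params)
    ch_tar <- apply_psf_noise(ch_tar, params)
    image <- image_stack(list(ref = ch_ref, target = ch_tar),
                         params$voxel_size)
  }
  ax <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  mk <- function(cen, d, partner) {
    df <- data.frame(id = seq_len(nrow(cen)))
    for (a in seq_len(nd)) df[[paste0(ax[a], "_nm")]] <- cen[, a]
    df$diameter_nm <- d
    df$partner_of <- partner
    df
  }
  truth_ref <- mk(cen_ref, d_ref, NA_integer_)
  truth_ref$has_partner <- truth_ref$id %in% partner_ids
  partner_col <- rep(NA_integer_, n_target)
  partner_col[seq_len(n_partner)] <- partner_ids
  truth_tar <- mk(cen_tar, d_tar, partner_col)
  list(image = image, truth_ref = truth_ref, truth_target = truth_tar)
}

#' Write or read a ground-truth table as JSON
#'
#' Lossless sidecar serialization of the simulator's ground truth, so that
#' images written to disk keep their provenance.
#'
#' @param truth A ground-truth data frame.
#' @param path JSON path.
#' @return `read_ground_truth` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(df)
}

#' Parameters of a simulated FRAP experiment
#'
#' The post-bleach region-of-interest intensity follows the
#' single-exponential recovery model
#' `FRAP(t) = I0 + I1 * (1 - exp(-(t - t_bleach) / tau))`, where `I0` is the
#' normalized intensity just after bleach and `I1` the dynamic range of
#' recovery; `1 - I0 - I1` of the pre-bleach signal never recovers.
#'
#' @param I0 Normalized intensity just after bleach (>= 0).
#' @param I1 Dynamic range of recovery (>= 0, with `I0 + I1 <= 1`).
#' @param tau Recovery time constant (seconds, > 0).
#' @param n_prebleach Pre-bleach frames (>= 1; acquisitions here use 3).
#' @param n_postbleach Post-bleach frames.
#' @param frame_interval Seconds between frames.
#' @param acquisition_bleach_rate Per-frame multiplicative decay of the
#'   reference ROI (models acquisition photobleaching).
#' @param noise_sd Additive Gaussian noise SD on the ROI trace.
#' @param seed Integer seed.
#' @return A `frap_sim_params` list.
#' @export
frap_sim_params <- function(I0 = 0.2, I1 = 0.5, tau = 10,
                            n_prebleach = 3L, n_postbleach = 60L,
                            frame_interval = 0.35,
                            acquisition_bleach_rate = 0,
                            noise_sd = 0, seed = 1L) {
  if (I0 < 0 || I1 < 0 || I0 + I1 > 1 + 1e-12) {
    stop("need 0 <= I0, 0 <= I1, I0 + I1 <= 1")
  }
  if (tau <= 0) stop("tau must be > 0")
  if (n_prebleach < 1) stop("need at least one pre-bleach frame")
  structure(list(I0 = I0, I1 = I1, tau = tau,
                 n_prebleach = as.integer(n_prebleach),
                 n_postbleach = as.integer(n_postbleach),
                 frame_interval = frame_interval,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 noise_sd = noise_sd, seed = seed),
            class = "frap_sim_params")
}

#' Simulate a FRAP trace
#'
#' Pre-bleach ROI frames equal the reference; post-bleach frames follow the
#' recovery model scaled by the decaying reference (acquisition bleaching),
#' plus additive Gaussian noise on the ROI. The generating parameters are
#' returned as ground truth.
#'
#' @param params A [frap_sim_params()].
#' @return List with `trace` (a [frap_trace()]) and `truth`
#'   (`I0`, `I1`, `tau`, `immobile_fraction`, `t_half`).
#' @export
generate_frap_trace <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  n <- params$n_prebleach + params$n_postbleach
  t_s <- (seq_len(n) - 1) * params$frame_interval
  bleach_index <- params$n_prebleach + 1L
  ref <- (1 - params$acquisition_bleach_rate)^(seq_len(n) - 1)
  roi <- ref
  tb <- t_s[bleach_index]
  post <- seq.int(bleach_index, n)
  model <- params$I0 + params$I1 * (1 - exp(-(t_s[post] - tb) / params$tau))
  roi[post] <- model * ref[post]
  if (params$noise_sd > 0) {
    set.seed(derive_seed(params$seed, "frap"))
    roi <- roi + rnorm(n, 0, params$noise_sd)
  }
  trace <- frap_trace(time_s = t_s, roi = roi, reference = ref,
                      bleach_index = bleach_index)
  truth <- list(I0 = params$I0, I1 = params$I1, tau = params$tau,
                immobile_fraction = immobile_fraction(params$I0, params$I1),
                t_half = half_time(params$tau))
  list(trace = trace, truth = truth)
}

#' Simulate a single-molecule intensity population
#'
#' Emulates nurse-cell smFISH particle intensities dominated by one- and
#' two-copy mRNA particles: each particle carries `k` copies drawn from
#' `copy_weights` and intensity `k * unit_intensity * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)` (multiplicative model), or
#' `Poisson(k * unit_intensity)` photon noise.
#'
#' @param unit_intensity Intensity of a single molecule.
#' @param copy_weights Named weights over copy counts, e.g.
#'   `c("1" = 0.7, "2" = 0.3)`; must sum to 1.
#' @param n Number of particles (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param noise_model `"gaussian_cv"` (default) or `"poisson"`.
#' @return Data frame with `intensity` and ground-truth `copies`.
#' @export
generate_intensity_population <- function(unit_intensity, copy_weights,
                                          n, noise_cv = 0, seed = 1L,
                                          noise_model = c("gaussian_cv",
                                                          "poisson")) {
  noise_model <- match.arg(noise_model)
  if (n < 1) stop("n must be >= 1")
  w <- as.numeric(copy_weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("copy_weights must be non-negative and sum to 1")
  }
  ks <- as.integer(names(copy_weights) %||% seq_along(copy_weights))
  set.seed(derive_seed(seed, "population"))
  k <- sample(ks, n, replace = TRUE, prob = w)
  intensity <- switch(noise_model,
    gaussian_cv = k * unit_intensity * (1 + rnorm(n, 0, noise_cv)),
    poisson = as.numeric(rpois(n, k * unit_intensity)))
  data.frame(intensity = intensity, copies = k)
}

#' Simulate a posterior-biased polarity field
#'
#' Places point-like granules in a rectangular cell mask: each granule falls
#' uniformly in the posterior half of the mask with probability
#' `posterior_weight`, else uniformly in the anterior half. The analytic
#' normalized centre-of-mass displacement of the placements (positive =
#' posterior) is returned as ground truth. With uniform placement within
#' halves the expectation is `(2 * posterior_weight - 1) / 4`.
#'
#' @param mask_shape Grid shape (voxels).
#' @param ap_axis Index of the anteroposterior axis (posterior = increasing
#'   coordinate); defaults to the last axis.
#' @param posterior_weight Probability a granule falls in the posterior
#'   half, in `[0, 1]`.
#' @param n_granules Number of granules.
#' @param voxel_size nm per axis.
#' @param seed Integer seed.
#' @return List with `image` ([image_stack()]), `mask` (logical array),
#'   and `true_displacement` (normalized, from the placements).
#' @export
generate_polarity_field <- function(mask_shape, ap_axis = length(mask_shape),
                                    posterior_weight = 0.5, n_granules = 500L,
                                    voxel_size = rep(100, length(mask_shape)),
                                    seed = 1L) {
  if (posterior_weight < 0 || posterior_weight > 1) {
    stop("posterior_weight must be in [0, 1]")
  }
  nd <- length(mask_shape)
  stopifnot(ap_axis >= 1, ap_axis <= nd)
  extent <- mask_shape * voxel_size
  set.seed(derive_seed(seed, "polarity"))
  img <- array(0, mask_shape)
  pos <- matrix(runif(n_granules * nd), n_granules, nd)
  pos <- sweep(pos, 2, extent, "*")
  posterior <- runif(n_granules) < posterior_weight
  half <- extent[ap_axis] / 2
  u <- runif(n_granules, 0, half)
  pos[, ap_axis] <- ifelse(posterior, half + u, u)
  vi <- pmin(pmax(ceiling(sweep(pos, 2, voxel_size, "/")), 1),
             matrix(mask_shape, n_granules, nd, byrow = TRUE))
  for (i in seq_len(n_granules)) {
    idx <- matrix(vi[i, ], 1)
    img[idx] <- img[idx] + 1
  }
  com <- mean(pos[, ap_axis])
  true_disp <- (com - extent[ap_axis] / 2) / extent[ap_axis]
  mask <- array(TRUE, mask_shape)
  list(image = image_stack(list(signal = img), voxel_size),
       mask = mask, true_displacement = true_disp, ap_axis = ap_axis)
}

#' Simulate a fluorophore calibration ladder
#'
#' Images frames of known fluorophore concentration with a linear detector
#' response: frame mean intensity = `response_slope * concentration`, plus
#' per-voxel Gaussian noise.
#'
#' @param concentrations Molar concentrations (>= 2 distinct values).
#' @param response_slope Intensity units per molar.
#' @param noise_sd Per-voxel Gaussian noise SD.
#' @param frame_shape Frame size in voxels.
#' @param seed Integer seed.
#' @return List with `frames` (list of matrices) and `table` (data frame
#'   `concentration_M`, `mean_intensity`).
#' @export
generate_calibration_ladder <- function(concentrations, response_slope,
                                        noise_sd = 0,
                                        frame_shape = c(32L, 32L),
                                        seed = 1L) {
  if (length(unique(concentrations)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  set.seed(derive_seed(seed, "ladder"))
  frames <- lapply(concentrations, function(conc) {
    matrix(response_slope * conc + rnorm(prod(frame_shape), 0, noise_sd),
           frame_shape[1], frame_shape[2])
  })
  table <- data.frame(concentration_M = concentrations,
                      mean_intensity = vapply(frames, mean, numeric(1)))
  list(frames = frames, table = table)
}
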