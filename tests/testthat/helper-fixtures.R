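# Small reusable fixtures, all generated in code.

# One noise-free granule rendered at the given geometry.
single_granule <- function(diameter = 400, axis_ratio = 1,
                           voxel = c(40, 40, 40), shape = c(32L, 32L, 48L),
                           seed = 1L, psf_sigma = 0, antialias = FALSE) {
  p <- granule_field_params(field_shape = shape, voxel_size = voxel,
                            n_granules = 1L, diameter_mean = diameter,
                            diameter_sd = 0, axis_ratio = axis_ratio,
                            unit_intensity = 1000, copies = 1L,
                            psf_sigma = psf_sigma, antialias = antialias,
                            seed = seed)
  generate_granule_image(p)
}

# Random bimodal 256-bin histogram: two Gaussian humps of random position,
# width and mass.
random_bimodal_histogram <- function() {
  m1 <- sample(20:100, 1)
  m2 <- sample(150:240, 1)
  s1 <- runif(1, 3, 15)
  s2 <- runif(1, 3, 15)
  n1 <- sample(500:5000, 1)
  n2 <- sample(500:5000, 1)
  x <- c(rnorm(n1, m1, s1), rnorm(n2, m2, s2))
  tabulate(pmin(pmax(round(x), 1), 256), nbins = 256)
}

# Segment a noise-free field with a tiny fixed threshold and measure it.
segment_and_measure <- function(sim, connectivity = "full") {
  mask <- threshold_image(sim$image, method = "fixed", value = 1e-9)
  labels <- label_objects(mask, connectivity = connectivity)
  list(mask = mask, labels = labels,
       records = measure_objects(labels, sim$image))
}

# Match measured objects to ground-truth granules by nearest centroid (nm).
match_to_truth <- function(records, truth) {
  ax <- intersect(c("z_nm", "y_nm", "x_nm"), names(truth))
  rec_ax <- paste0("centroid_", sub("_nm", "", ax), "_nm")
  idx <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    d2 <- rowSums(sweep(as.matrix(truth[, ax]), 2,
                        as.numeric(records[i, rec_ax]), "-")^2)
    idx[i] <- which.min(d2)
  }
  idx
}
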