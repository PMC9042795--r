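test_that("aspect ratio recovers sphere and ellipsoid geometry", {
  sim <- single_granule(diameter = 400, voxel = c(40, 40, 40),
                        antialias = TRUE)
  seg <- segment_and_measure(sim)
  ar <- aspect_ratio(sim$image, seg$labels, 1)
  expect_equal(ar$ratio, 1, tolerance = 0.05)
  expect_equal(ar$major_nm, 400, tolerance = 0.15)
  # 800/400/400 nm ellipsoid at 40 nm voxels
  sime <- single_granule(diameter = 400, axis_ratio = 2,
                         voxel = c(40, 40, 40), shape = c(32L, 32L, 64L),
                         antialias = TRUE)
  sege <- segment_and_measure(sime)
  are <- aspect_ratio(sime$image, sege$labels, 1)
  expect_equal(are$ratio, 2, tolerance = 0.1)
  expect_gte(are$ratio, 1)
})

test_that("degenerate objects are rejected by the aspect-ratio estimator", {
  a <- array(0, c(8, 8, 8)); a[4, 4, 4] <- 10
  img <- image_stack(a, c(40, 40, 40))
  lab <- label_objects(a > 0)
  expect_error(aspect_ratio(img, lab, 1), "at least 3 voxels")
  expect_error(aspect_ratio(img, lab, 99), "absent")
})

test_that("aspect ratio is invariant to intensity scaling and rotation", {
  sime <- single_granule(diameter = 400, axis_ratio = 2,
                         voxel = c(40, 40, 40), shape = c(32L, 32L, 64L),
                         antialias = TRUE)
  sege <- segment_and_measure(sime)
  r0 <- aspect_ratio(sime$image, sege$labels, 1)$ratio
  # x10 intensity
  imgs <- image_stack(get_channel(sime$image) * 10, c(40, 40, 40))
  rs <- aspect_ratio(imgs, sege$labels, 1)$ratio
  expect_equal(rs, r0, tolerance = 1e-12)
  # rigid 90-degree rotation of the grid (swap y and x)
  rot <- aperm(get_channel(sime$image), c(1, 3, 2))
  imgr <- image_stack(rot, c(40, 40, 40))
  labr <- label_objects(aperm(sege$labels$label_map, c(1, 3, 2)) > 0)
  rr <- aspect_ratio(imgr, labr, 1)$ratio
  expect_equal(rr, r0, tolerance = 0.02)
})

test_that("equivalent-diameter bias stays below one voxel across sizes", {
  for (d in c(300, 400, 500, 600)) {
    sim <- single_granule(diameter = d, voxel = c(40, 40, 40),
                          shape = c(32L, 32L, 32L), seed = d)
    seg <- segment_and_measure(sim)
    expect_equal(seg$records$equivalent_diameter_nm, d, tolerance = 40 / d)
  }
})

test_that("size-distribution fits are the Gaussian MLE and equivariant", {
  f <- fit_size_distribution(c(400, 400, 400))
  expect_equal(f$mean_diameter, 400)
  expect_equal(f$sd_diameter, 0)
  expect_error(fit_size_distribution(400), "at least 2")
  set.seed(1)
  d <- rnorm(500, 400, 129)
  f1 <- fit_size_distribution(d)
  f2 <- fit_size_distribution(d + 50)
  expect_equal(f2$mean_diameter, f1$mean_diameter + 50)
  expect_equal(f2$sd_diameter, f1$sd_diameter)
  expect_equal(f1$mean_diameter, mean(d))
  expect_equal(f1$sd_diameter, sd(d))
})

test_that("volume-intensity relation flags constant vs increasing density", {
  rec <- data.frame(volume_um3 = c(0.01, 0.02, 0.04, 0.08, 0.1),
                    integrated_ch1 = c(0.01, 0.02, 0.04, 0.08, 0.1) * 500)
  r <- suppressWarnings(volume_intensity_relation(rec, "ch1"))
  expect_equal(r$slope, 0, tolerance = 1e-8)
  rec2 <- rec
  rec2$integrated_ch1 <- rec$volume_um3^2 * 500
  expect_gt(suppressWarnings(volume_intensity_relation(rec2, "ch1"))$slope,
            0)
  # constant copies-per-volume with Poisson noise: slope within 2 SE of 0
  set.seed(3)
  vol <- runif(200, 0.01, 0.2)
  intens <- rpois(200, vol * 5e4)
  recn <- data.frame(volume_um3 = vol, integrated_ch1 = intens)
  rn <- volume_intensity_relation(recn, "ch1")
  expect_lt(abs(rn$slope), 2 * rn$slope_se)
  expect_error(volume_intensity_relation(rec[1:2, ], "ch1"), "at least 3")
})

test_that("partition coefficients follow the inside/dilute intensity ratio", {
  a <- array(100, c(6, 10, 10))
  mask <- array(FALSE, c(6, 10, 10))
  mask[3:4, 4:6, 4:6] <- TRUE
  a[mask] <- 1000
  img <- image_stack(a, c(100, 100, 100))
  pc <- partition_coefficient(img, 1, mask, exclusion_halo = 0)
  expect_equal(pc$value, 10)
  # uniform image
  pu <- partition_coefficient(image_stack(array(7, c(6, 10, 10)),
                                          c(100, 100, 100)),
                              1, mask, exclusion_halo = 0)
  expect_equal(pu$value, 1)
  # scale invariance
  pc2 <- partition_coefficient(image_stack(a * 3.5, c(100, 100, 100)),
                               1, mask, exclusion_halo = 0)
  expect_equal(pc2$value, pc$value)
  # halo shrinks the dilute region but not below empty
  pch <- partition_coefficient(img, 1, mask, exclusion_halo = 1)
  expect_equal(pch$value, 10)
  expect_lt(pch$n_dilute, pc$n_dilute)
  expect_error(partition_coefficient(img, 1, array(FALSE, c(6, 10, 10))),
               "empty")
  expect_error(partition_coefficient(img, 1, array(TRUE, c(6, 10, 10))),
               "whole image")
  expect_error(partition_coefficient(img, 1, mask, exclusion_halo = 10),
               "dilute region empty")
})

test_that("noisy two-level images give the constructed partition ratio", {
  set.seed(5)
  a <- array(rnorm(40 * 40 * 40, 100, 50), c(40, 40, 40))
  mask <- array(FALSE, c(40, 40, 40))
  mask[10:30, 10:30, 10:30] <- TRUE
  a[mask] <- rnorm(sum(mask), 1000, 50)
  img <- image_stack(a, c(100, 100, 100))
  pc <- partition_coefficient(img, 1, mask, exclusion_halo = 0)
  expect_equal(pc$value, 10, tolerance = 0.02)
})

test_that("integrated density equals the exhaustive point-in-polygon sum", {
  # axis-aligned square covering exactly 10x10 voxel centres
  img <- image_stack(matrix(1, 20, 20), c(100, 100))
  sq <- rbind(c(410, 410), c(410, 1440), c(1440, 1440), c(1440, 410))
  expect_equal(integrated_density(img, 1, sq), 100)
  # linearity in intensity
  img2 <- image_stack(matrix(2, 20, 20), c(100, 100))
  expect_equal(integrated_density(img2, 1, sq), 200)
  expect_error(integrated_density(img, 1, sq[1:2, ]), "degenerate polygon")
  expect_error(integrated_density(img, 1, sq + 1e6), "inside the field")
  # random polygons on random images vs the brute-force oracle
  set.seed(8)
  for (case in 1:5) {
    im <- matrix(runif(15 * 15), 15, 15)
    stack <- image_stack(im, c(80, 80))
    k <- sample(3:7, 1)
    poly <- cbind(runif(k, 50, 1150), runif(k, 50, 1150))
    expect_equal(integrated_density(stack, 1, poly),
                 oracle_integrated_density(im, c(80, 80), poly))
  }
})
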