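test_that("granule field generation is deterministic and conserves signal", {
  p <- granule_field_params(field_shape = c(24, 128, 128),
                            voxel_size = c(60, 40, 40), n_granules = 8,
                            diameter_mean = 400, diameter_sd = 60,
                            min_separation = 1000, unit_intensity = 1000,
                            copies = c("1" = 0.5, "2" = 0.5), seed = 11)
  a <- generate_granule_image(p)
  b <- generate_granule_image(p)
  expect_identical(get_channel(a$image), get_channel(b$image))
  expect_identical(a$truth, b$truth)
  # uniform-fill construction conserves photons exactly without PSF/noise
  expect_equal(sum(get_channel(a$image)), sum(a$truth$copies) * 1000)
})

test_that("per-granule integrated signal equals copies x unit intensity", {
  sim <- single_granule(diameter = 400, voxel = c(40, 40, 40))
  expect_equal(sum(get_channel(sim$image)), 1000, tolerance = 0.01)
  # blur moves photons around but conserves them away from the field edge
  simb <- single_granule(diameter = 400, psf_sigma = 80)
  expect_equal(sum(get_channel(simb$image)), 1000, tolerance = 0.01)
})

test_that("empty and crowded fields are handled explicitly", {
  p0 <- granule_field_params(field_shape = c(8, 16, 16),
                             voxel_size = c(60, 40, 40), n_granules = 0,
                             background_level = 5, seed = 1)
  sim0 <- generate_granule_image(p0)
  expect_equal(nrow(sim0$truth), 0)
  expect_true(all(get_channel(sim0$image) == 5))
  pc <- granule_field_params(field_shape = c(8, 16, 16),
                             voxel_size = c(60, 40, 40), n_granules = 40,
                             min_separation = 2000, seed = 1)
  expect_error(generate_granule_image(pc), "too crowded")
})

test_that("ground truth serializes losslessly", {
  sim <- single_granule()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back, sim$truth)
})

test_that("two-channel fields honour the partnered-count contract", {
  p <- granule_field_params(field_shape = c(16, 96, 96),
                            voxel_size = c(100, 100, 100),
                            min_separation = 1000, seed = 3)
  f <- generate_two_channel_field(p, n_ref = 40, n_target = 40,
                                  true_coloc_fraction = 0.5,
                                  jitter_sd = 50, render = FALSE)
  expect_equal(sum(f$truth_ref$has_partner), round(0.5 * 40))
  expect_equal(sum(!is.na(f$truth_target$partner_of)), 20)
  # fraction 1 with no jitter: every reference has a coincident target
  f1 <- generate_two_channel_field(p, n_ref = 15, n_target = 15,
                                   true_coloc_fraction = 1, jitter_sd = 0,
                                   render = FALSE)
  ax <- c("z_nm", "y_nm", "x_nm")
  ref <- as.matrix(f1$truth_ref[, ax])
  tar <- as.matrix(f1$truth_target[, ax])
  expect_equal(tar[order(f1$truth_target$partner_of), ], ref,
               ignore_attr = TRUE)
  # fraction 0: no partners
  f0 <- generate_two_channel_field(p, n_ref = 15, n_target = 15,
                                   true_coloc_fraction = 0, render = FALSE)
  expect_true(all(is.na(f0$truth_target$partner_of)))
  expect_error(
    generate_two_channel_field(p, n_ref = 20, n_target = 5,
                               true_coloc_fraction = 1, render = FALSE),
    "smaller than")
})

test_that("simulated FRAP traces follow the closed-form recovery model", {
  p <- frap_sim_params(I0 = 0.2, I1 = 0.5, tau = 10, n_prebleach = 3,
                       n_postbleach = 40, frame_interval = 1, noise_sd = 0)
  tr <- generate_frap_trace(p)$trace
  tb <- tr$time_s[tr$bleach_index]
  at10 <- which(tr$time_s - tb == 10)
  expect_equal(tr$roi[at10], 0.2 + 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  # full recovery limit
  pf <- frap_sim_params(I0 = 0, I1 = 1, tau = 2, n_postbleach = 200,
                        frame_interval = 1, noise_sd = 0)
  trf <- generate_frap_trace(pf)$trace
  expect_equal(tail(trf$roi, 1), 1, tolerance = 1e-12)
  # pre-bleach frames equal the reference before noise
  expect_equal(tr$roi[1:2], tr$reference[1:2])
})

test_that("intensity populations have the stated multiplicative structure", {
  pop <- generate_intensity_population(1000, c("1" = 1), n = 50,
                                       noise_cv = 0)
  expect_true(all(pop$intensity == 1000))
  expect_error(generate_intensity_population(1000, c("1" = 1), n = 0),
               "n must be")
  expect_error(generate_intensity_population(1000, c("1" = 0.5, "2" = 0.4),
                                             n = 10),
               "sum to 1")
  popn <- generate_intensity_population(1000, c("1" = 0.6, "2" = 0.4),
                                        n = 4000, noise_cv = 0.05, seed = 2)
  expect_equal(mean(popn$intensity / popn$copies), 1000, tolerance = 0.01)
})

test_that("polarity fields place granules by the posterior weight", {
  pf <- generate_polarity_field(c(40, 80), ap_axis = 2,
                                posterior_weight = 1, n_granules = 300,
                                voxel_size = c(100, 100), seed = 4)
  img <- get_channel(pf$image)
  expect_equal(sum(img[, 1:40]), 0)  # nothing anterior
  expect_equal(sum(img), 300)
  # symmetric placement has expectation 0 (loose Monte-Carlo band)
  pf5 <- generate_polarity_field(c(40, 80), ap_axis = 2,
                                 posterior_weight = 0.5, n_granules = 4000,
                                 voxel_size = c(100, 100), seed = 5)
  expect_lt(abs(pf5$true_displacement), 0.02)
  expect_error(generate_polarity_field(c(10, 10), posterior_weight = 1.2),
               "posterior_weight")
})

test_that("calibration ladders are linear in concentration", {
  lad <- generate_calibration_ladder(c(1e-6, 2e-6), response_slope = 1e9,
                                     noise_sd = 0)
  expect_equal(lad$table$mean_intensity, c(1000, 2000))
  expect_error(generate_calibration_ladder(c(1e-6, 1e-6), 1e9),
               "distinct")
})
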