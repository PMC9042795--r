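make_object_set <- function(pts, shape = c(20L, 100L, 100L),
                            voxel = c(100, 100, 100)) {
  object_set(pts, array(TRUE, shape), voxel)
}

test_that("observed fraction matches definition and brute force", {
  set.seed(1)
  a <- cbind(runif(50, 0, 2000), runif(50, 0, 10000), runif(50, 0, 10000))
  expect_equal(observed_coloc_fraction(a, a, 250), 1)
  b_far <- a + 5000
  expect_equal(observed_coloc_fraction(a, b_far, 250), 0)
  for (case in 1:5) {
    aa <- cbind(runif(60, 0, 2000), runif(60, 0, 8000), runif(60, 0, 8000))
    bb <- cbind(runif(60, 0, 2000), runif(60, 0, 8000), runif(60, 0, 8000))
    w <- runif(1, 200, 1500)
    expect_equal(observed_coloc_fraction(aa, bb, w),
                 oracle_coloc_fraction(aa, bb, w))
  }
  expect_error(observed_coloc_fraction(a[0, ], a, 250), "empty reference")
  expect_equal(observed_coloc_fraction(a, a[0, ], 250), 0)
  expect_error(observed_coloc_fraction(a, a, 0), "window")
})

test_that("observed fraction is monotone in the window and rigid-motion
           invariant", {
  set.seed(2)
  a <- cbind(runif(40, 0, 2000), runif(40, 0, 8000), runif(40, 0, 8000))
  b <- cbind(runif(40, 0, 2000), runif(40, 0, 8000), runif(40, 0, 8000))
  f <- vapply(c(100, 250, 500, 1000, 2000), function(w) {
    observed_coloc_fraction(a, b, w)
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
  shift <- c(123.4, -56.7, 89.1)
  expect_equal(observed_coloc_fraction(sweep(a, 2, shift, "+"),
                                       sweep(b, 2, shift, "+"), 250),
               observed_coloc_fraction(a, b, 250))
})

test_that("the randomization null is seeded, bounded and mask-confined", {
  set.seed(3)
  refs <- cbind(runif(30, 500, 1500), runif(30, 500, 9500),
                runif(30, 500, 9500))
  os <- make_object_set(refs)
  n1 <- randomized_null(os, n_target = 50, window_nm = 250, R = 20,
                        seed = 42)
  n2 <- randomized_null(os, n_target = 50, window_nm = 250, R = 20,
                        seed = 42)
  expect_identical(n1, n2)
  expect_length(n1, 20)
  # vanishing window: chance matches vanish
  n0 <- randomized_null(os, n_target = 50, window_nm = 1e-6, R = 10,
                        seed = 1)
  expect_true(all(n0 == 0))
  # mask fully covered by window balls: every null fraction is 1
  tiny <- object_set(matrix(c(100, 100), 1, 2),
                     array(TRUE, c(2L, 2L)), c(100, 100))
  nf <- randomized_null(tiny, n_target = 5, window_nm = 1000, R = 10,
                        seed = 1)
  expect_true(all(nf == 1))
  empty <- object_set(matrix(c(100, 100), 1, 2),
                      array(FALSE, c(2L, 2L)), c(100, 100))
  expect_error(randomized_null(empty, n_target = 5, window_nm = 100,
                               R = 2, seed = 1), "too small")
})

test_that("sparse-regime null mean matches the Poisson void probability", {
  set.seed(4)
  shape <- c(20L, 100L, 100L)  # 2 x 10 x 10 um at 100 nm voxels
  refs <- cbind(runif(150, 300, 1700), runif(150, 300, 9700),
                runif(150, 300, 9700))
  os <- make_object_set(refs, shape)
  n_target <- 300
  null <- randomized_null(os, n_target = n_target, window_nm = 250,
                          R = 200, seed = 7)
  v_window <- 4 / 3 * pi * 0.25^3          # um^3
  v_mask <- prod(shape) * 0.1^3            # um^3
  expected <- 1 - exp(-n_target / v_mask * v_window)
  mc_se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - expected), 3 * mc_se)
})

test_that("coloc frequency is observed minus null mean with diagnostics", {
  res <- coloc_frequency(0.8, c(0.2, 0.3, 0.4))
  expect_equal(res$coloc_frequency, 0.5)
  expect_equal(res$null_mean, 0.3)
  expect_equal(res$R, 3)
  expect_equal(res$exceedance, 0)
  res0 <- coloc_frequency(0.3, rep(0.3, 10))
  expect_equal(res0$coloc_frequency, 0)
})

test_that("true colocalization fractions are recovered on sparse fields", {
  p <- granule_field_params(field_shape = c(20L, 140L, 140L),
                            voxel_size = c(100, 100, 100),
                            diameter_mean = 400, diameter_sd = 0,
                            min_separation = 800, seed = 31)
  f <- generate_two_channel_field(p, n_ref = 200, n_target = 200,
                                  true_coloc_fraction = 0.5,
                                  jitter_sd = 50, render = FALSE)
  ax <- c("z_nm", "y_nm", "x_nm")
  ref <- object_set(as.matrix(f$truth_ref[, ax]),
                    array(TRUE, c(20L, 140L, 140L)), c(100, 100, 100))
  tar <- object_set(as.matrix(f$truth_target[, ax]),
                    array(TRUE, c(20L, 140L, 140L)), c(100, 100, 100))
  res <- coloc_analysis(ref, tar, window_nm = 250, R = 100, seed = 1)
  # 3 binomial SE around the constructed fraction
  expect_lt(abs(res$coloc_frequency - 0.5), 3 * sqrt(0.25 / 200) + 0.02)
})

test_that("crowding biases the frequency downward, never upward", {
  # dense field: chance colocalization is high
  p <- granule_field_params(field_shape = c(10L, 40L, 40L),
                            voxel_size = c(100, 100, 100),
                            diameter_mean = 300, diameter_sd = 0,
                            min_separation = 0, seed = 17)
  f <- generate_two_channel_field(p, n_ref = 150, n_target = 150,
                                  true_coloc_fraction = 0.5,
                                  jitter_sd = 50, render = FALSE)
  ax <- c("z_nm", "y_nm", "x_nm")
  ref <- object_set(as.matrix(f$truth_ref[, ax]),
                    array(TRUE, c(10L, 40L, 40L)), c(100, 100, 100))
  tar <- object_set(as.matrix(f$truth_target[, ax]),
                    array(TRUE, c(10L, 40L, 40L)), c(100, 100, 100))
  res <- coloc_analysis(ref, tar, window_nm = 250, R = 100, seed = 2)
  expect_gt(res$null_mean, 0.2)  # genuinely crowded regime
  expect_lt(res$coloc_frequency, 0.5)
})

test_that("uniform targets fall inside the null band at the stated rate", {
  set.seed(6)
  shape <- c(10L, 60L, 60L)
  covered <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    refs <- cbind(runif(60, 300, 700), runif(60, 300, 5700),
                  runif(60, 300, 5700))
    os <- object_set(refs, array(TRUE, shape), c(100, 100, 100))
    tars <- cbind(runif(80, 0, 1000), runif(80, 0, 6000),
                  runif(80, 0, 6000))
    obs <- observed_coloc_fraction(refs, tars, 250)
    null <- randomized_null(os, n_target = 80, window_nm = 250, R = 50,
                            seed = r)
    band <- quantile(null, c(0.025, 0.975))
    if (obs >= band[1] && obs <= band[2]) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.85)
})
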