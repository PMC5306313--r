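test_that("excess kurtosis matches the closed-form reference cases", {
  expect_equal(excess_kurtosis(1:5), -1.2, tolerance = 1e-12)
  # flat histogram is platykurtic, spiky one leptokurtic
  expect_lt(excess_kurtosis(rep(c(0, 1), 50)), 0)
  expect_gt(excess_kurtosis(c(rep(0, 99), 50)), 10)
})

test_that("excess kurtosis agrees with term-by-term evaluation on random samples", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:500, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 50)) + runif(1, -100, 100)
    k <- excess_kurtosis(x)
    o <- kurtosis_oracle(x)
    expect_lt(abs(k - o), 1e-12 * max(1, abs(o)))
  }
})

test_that("excess kurtosis is invariant under affine intensity rescaling", {
  set.seed(7)
  for (i in 1:20) {
    x <- rlnorm(sample(5:80, 1))
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    expect_equal(excess_kurtosis(a * x + runif(1, -10, 10)),
                 excess_kurtosis(x), tolerance = 1e-9)
  }
  expect_equal(excess_kurtosis(3 * c(2, 4, 1, 7, 5) + 7),
               excess_kurtosis(c(2, 4, 1, 7, 5)), tolerance = 1e-12)
})

test_that("excess kurtosis of large Gaussian samples is near zero", {
  set.seed(2024)
  k <- excess_kurtosis(rnorm(1e5))
  expect_lt(abs(k), 3 * sqrt(24 / 1e5))  # 3 analytic standard errors
  expect_lt(abs(k), 0.05)
})

test_that("degenerate histograms are rejected with classed conditions", {
  expect_error(excess_kurtosis(c(1, 2, 3)), class = "cttasurv_insufficient_pixels")
  expect_error(excess_kurtosis(rep(5, 10)), class = "cttasurv_degenerate_histogram")
})

test_that("LoG kernel sums to zero and is rotationally symmetric", {
  for (ssf in c(2, 3, 4, 5, 6)) {
    k <- log_kernel(ssf, 0.98)
    expect_lt(abs(sum(k)), 1e-8 * sum(abs(k)))
    expect_identical(dim(k)[1] %% 2L, 1L)        # odd support
    expect_equal(k, t(k), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))],
                 tolerance = 1e-12, ignore_attr = TRUE)  # 180-degree rotation
  }
})

test_that("scales finer than a pixel are refused", {
  expect_error(log_kernel(0.5, 0.98), class = "cttasurv_scale_too_fine")
  expect_error(log_filter(lesion_image(matrix(0, 20, 20), 2), 1),
               class = "cttasurv_scale_too_fine")
})

test_that("filter response to a constant image is numerically zero", {
  img <- lesion_image(matrix(250, 48, 48), 0.98)
  for (ssf in c(2, 4, 6))
    expect_lt(max(abs(log_filter(img, ssf)$pixels)), 1e-6 * 250)
})

test_that("adding a constant offset leaves the filtered image unchanged", {
  set.seed(3)
  px <- matrix(rnorm(48 * 48, 40, 15), 48, 48)
  f0 <- log_filter(lesion_image(px, 0.98), 4)$pixels
  f1 <- log_filter(lesion_image(px + 123.4, 0.98), 4)$pixels
  expect_equal(f0, f1, tolerance = 1e-9)
})

test_that("impulse response reproduces the kernel and matches dense convolution", {
  k <- log_kernel(2, 1)
  m <- attr(k, "half_width")
  n <- 2L * m + 15L
  px <- matrix(0, n, n); ctr <- (n + 1L) %/% 2L
  px[ctr, ctr] <- 1
  f <- log_filter(lesion_image(px, 1), 2)$pixels
  expect_equal(f[(ctr - m):(ctr + m), (ctr - m):(ctr + m)], unclass(k),
               tolerance = 1e-10, ignore_attr = TRUE)
  # random image, full-grid agreement with the quadruple-loop oracle
  set.seed(11)
  px2 <- matrix(rnorm(22 * 19), 22, 19)
  f2 <- log_filter(lesion_image(px2, 1), 2)$pixels
  expect_equal(f2, dense_conv_oracle(px2, k), tolerance = 1e-10)
})

test_that("auto-contour removes exactly the sub-threshold pixels", {
  px <- matrix(100, 10, 10)
  msk <- roi_mask(matrix(TRUE, 10, 10))
  img <- lesion_image(px, 1)
  expect_identical(auto_contour(msk, img)$mask, msk$mask)  # nothing below -50

  px[4, 7] <- -100
  img2 <- lesion_image(px, 1)
  ac <- auto_contour(msk, img2)
  expect_identical(ac$n_pixels, 99L)
  expect_false(ac$mask[4, 7])

  # idempotence
  expect_identical(auto_contour(ac, img2)$mask, ac$mask)

  # everything below threshold -> empty-ROI condition
  expect_error(auto_contour(msk, lesion_image(matrix(-900, 10, 10), 1)),
               class = "cttasurv_empty_roi")
})

test_that("gas pockets in phantoms are excluded pixel-for-pixel", {
  ph <- generate_phantom(phantom_spec(seed = 99, noise_sd_hu = 5,
    gas_pocket = list(center_px = c(30, 34), radius_px = 2, hu = -800)))
  below <- sum(ph$mask$mask & ph$image$pixels < -50)   # exhaustive scan
  expect_gt(below, 0)
  ac <- auto_contour(ph$mask, ph$image)
  expect_identical(ph$mask$n_pixels - ac$n_pixels, below)
})

test_that("texture profile control scale equals raw masked kurtosis", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  prof <- compute_texture_profile(ph$image, ph$mask, scales = c(0, 3))
  refined <- auto_contour(ph$mask, ph$image)
  expect_equal(prof$values[["k0"]],
               excess_kurtosis(ph$image$pixels[refined$mask]),
               tolerance = 1e-12)
  expect_identical(prof$n_pixels, refined$n_pixels)
})

test_that("constant lesions yield all-missing profiles instead of errors", {
  img <- lesion_image(matrix(40, 40, 40), 0.98)
  msk <- roi_mask(matrix(TRUE, 40, 40))
  prof <- compute_texture_profile(img, msk)
  expect_true(all(is.na(prof$values)))
  expect_length(prof$missing, length(SSF_SCALES))
})

test_that("mask erosion shrinks the ROI and congruence is enforced", {
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  er <- erode_mask(roi_mask(m), 1)
  expect_identical(er$n_pixels, sum(m[4:9, 4:9]))
  expect_error(
    compute_texture_profile(lesion_image(matrix(0, 5, 5), 1),
                            roi_mask(matrix(TRUE, 6, 6))),
    class = "cttasurv_shape_mismatch")
})

test_that("kurtosis at the matching scale falls as blob count rises", {
  k_at <- function(count, seed) {
    ph <- generate_phantom(phantom_spec(grid = 80, mask_radius_frac = 0.44,
      blob_count = count, blob_radius_mm = 3, blob_amplitude_hu = 100,
      noise_sd_hu = 8, seed = seed))
    compute_texture_profile(ph$image, ph$mask, scales = 3)$values[["k3"]]
  }
  counts <- c(3, 6, 12, 24, 48)
  ks <- unlist(lapply(1:10, function(s)
    vapply(counts, function(ct) k_at(ct, s * 100 + ct), numeric(1))))
  ct_vec <- rep(counts, 10)
  sp <- suppressWarnings(
    cor.test(ct_vec, ks, method = "spearman", alternative = "less"))
  expect_lt(sp$estimate, 0)
  expect_lt(sp$p.value, 0.01)
})
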