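# ACR QA: ROI geometry, SNR, integral uniformity, alignment plumbing.

vox <- c(250 / 64, 250 / 64, 10)
shape <- c(64, 64, 11)

test_that("ROI masks satisfy the geometric contract", {
  rois <- build_acr_rois(shape, vox)
  va <- prod(vox[1:2])
  # per-slice areas within one voxel area of the configured targets
  expect_lt(abs(sum(rois$signal_mask) / 5 * va - 400), va)
  expect_lt(abs(sum(rois$background_mask) / 9 * va - 182), va)
  expect_lt(abs(sum(rois$uniformity_mask) * va - 200 * 100), va)
  # pairwise disjoint
  expect_false(any(rois$signal_mask & rois$background_mask))
  expect_false(any(rois$signal_mask & rois$uniformity_mask))
  expect_false(any(rois$background_mask & rois$uniformity_mask))
  # signal/uniformity inside the cylinder, background outside
  r2 <- outer((((1:64) - 0.5) * vox[1] - 125)^2,
              (((1:64) - 0.5) * vox[2] - 125)^2, "+")
  inside <- array(r2 <= 95^2, dim = shape)
  expect_true(all(inside[rois$signal_mask]))
  expect_true(all(inside[rois$uniformity_mask]))
  expect_false(any(inside[rois$background_mask]))
  # slice placement (1-based, 6..10 signal / 2..10 background / 7 uniformity)
  per_slice <- apply(rois$signal_mask, 3, sum)
  expect_true(all(per_slice[6:10] > 0) && all(per_slice[-(6:10)] == 0))
  expect_equal(which(apply(rois$uniformity_mask, 3, sum) > 0), 7L)
})

test_that("zero requested area yields an empty mask; tiny grids error", {
  rois <- build_acr_rois(shape, vox,
                         acr_roi_config(signal_area_mm2 = 0))
  expect_equal(sum(rois$signal_mask), 0L)
  expect_error(build_acr_rois(c(8, 8, 11), c(250 / 8, 250 / 8, 10),
                              acr_roi_config(background_area_mm2 = 1e5)),
               "too small")
})

test_that("SNR matches its definition and the Rayleigh closed form", {
  # two-point background: sample SD of {3, 5} is sqrt(2) -> SNR 50/sqrt(2)
  blank <- array(FALSE, c(4, 4, 1))
  sig <- blank; sig[1:2, 1, 1] <- TRUE
  bg <- blank; bg[4, 3:4, 1] <- TRUE
  uni <- blank; uni[2:3, 2:3, 1] <- TRUE
  tiny_rois <- structure(list(signal_mask = sig, background_mask = bg,
                              uniformity_mask = uni,
                              voxel_size_mm = c(1, 1, 1)),
                         class = "acr_roi_set")
  img <- image_volume(array(0, c(4, 4, 1)))
  img$data[sig] <- 50
  img$data[bg] <- c(3, 5)
  expect_equal(compute_snr(img, tiny_rois), 50 / sqrt(2))
  # synthetic phantom at the full acquisition geometry (256 x 256, the
  # background ROI then has enough voxels for a stable SD): SNR within 5%
  # of S / rayleigh_sd(sigma) over 10 seeds
  rois_full <- build_acr_rois(c(256, 256, 11), c(250 / 256, 250 / 256, 10))
  snrs <- vapply(1:10, function(s) {
    ph <- gen_acr_phantom(acr_phantom_spec(signal_level = 100,
                                           noise_sigma = 2, seed = s))
    compute_snr(ph, rois_full)
  }, numeric(1))
  target <- 100 / rayleigh_sd(2)
  expect_lt(abs(mean(snrs) - target) / target, 0.05)
  # degenerate background
  rois <- build_acr_rois(shape, vox)
  flat <- image_volume(array(1, dim = shape), vox)
  expect_error(compute_snr(flat, rois), "degenerate background")
})

test_that("SNR is invariant under global intensity scaling", {
  rois <- build_acr_rois(shape, vox)
  ph <- gen_acr_phantom(acr_phantom_spec(grid_shape = shape,
                                         voxel_size_mm = vox, seed = 5))
  scaled <- image_volume(ph$data * 7.3, vox)
  expect_equal(compute_snr(scaled, rois), compute_snr(ph, rois),
               tolerance = 1e-12)
})

test_that("IU follows the nearest-rank percentile formula", {
  rois <- build_acr_rois(shape, vox)
  img <- image_volume(array(1, dim = shape), vox)
  expect_equal(compute_iu(img, rois), 100)
  # low = 80, high = 120 -> 100 * (1 - 40/200) = 80
  uni <- which(rois$uniformity_mask)
  img$data[uni] <- rep(c(80, 120), length.out = length(uni))
  expect_equal(compute_iu(img, rois), 80)
  # 1..1000 pattern: nearest rank gives low = 50th, high = 950th value
  n <- length(uni)
  vals <- seq_len(n)
  img$data[uni] <- vals
  lo <- sort(vals)[ceiling(0.05 * n)]
  hi <- sort(vals)[ceiling(0.95 * n)]
  expect_equal(compute_iu(img, rois), 100 * (1 - (hi - lo) / (hi + lo)))
  # scale invariance
  img2 <- image_volume(img$data * 3, vox)
  expect_equal(compute_iu(img2, rois), compute_iu(img, rois))
})

test_that("IU recovers the generator bias amplitude and is monotone", {
  rois <- build_acr_rois(shape, vox)
  amps <- c(0, 0.02, 0.05, 0.1, 0.2)
  ius <- vapply(amps, function(a) {
    ph <- gen_acr_phantom(acr_phantom_spec(
      grid_shape = shape, voxel_size_mm = vox, signal_level = 100,
      noise_sigma = 0.25, bias_amplitude = a, seed = 4))  # sigma << S
    compute_iu(ph, rois)
  }, numeric(1))
  expect_true(all(abs(ius - 100 * (1 - amps)) < 2))
  expect_true(all(diff(ius) < 0))
})

test_that("centre-of-mass alignment recovers integer shifts", {
  spec <- acr_phantom_spec(grid_shape = shape, voxel_size_mm = vox,
                           cylinder_radius_mm = 60, noise_sigma = 1, seed = 8)
  ref <- gen_acr_phantom(spec)
  aligned <- align_phantom(ref, ref)
  expect_equal(aligned$shift, c(0L, 0L, 0L))
  # apply (3, -2, 0) and expect the inverse back
  shifted <- array(0, dim = shape)
  shifted[4:64, 1:62, ] <- ref$data[1:61, 3:64, ]
  rec <- align_phantom(image_volume(shifted, vox), ref)
  expect_equal(rec$shift, c(-3L, 2L, 0L))
  expect_equal(rec$data[10:50, 10:50, ], ref$data[10:50, 10:50, ])
  # pure noise has no phantom
  set.seed(1)
  noise <- image_volume(array(abs(stats::rnorm(prod(shape))), dim = shape),
                        vox)
  expect_error(align_phantom(noise, ref), "no phantom")
})
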