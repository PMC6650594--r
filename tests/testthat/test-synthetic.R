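# Synthetic-data generators: closed-form limits, determinism, moment
# recovery.

test_that("phantom noiseless limit is exact and generation is deterministic", {
  spec <- acr_phantom_spec(grid_shape = c(64, 64, 11),
                           voxel_size_mm = c(250 / 64, 250 / 64, 10),
                           signal_level = 80, noise_sigma = 0,
                           bias_amplitude = 0, seed = 1)
  ph <- gen_acr_phantom(spec)
  r2 <- outer((((1:64) - 0.5) * 250 / 64 - 125)^2,
              (((1:64) - 0.5) * 250 / 64 - 125)^2, "+")
  inside <- r2 <= 95^2
  for (k in c(1, 6, 11)) {
    expect_true(all(ph$data[, , k][inside] == 80))
    expect_true(all(ph$data[, , k][!inside] == 0))
  }
  spec2 <- acr_phantom_spec(noise_sigma = 2, seed = 99)
  expect_identical(gen_acr_phantom(spec2)$data, gen_acr_phantom(spec2)$data)
})

test_that("phantom background noise follows Rayleigh statistics", {
  # sample SD of the background ROI over 10 seeds vs the closed form
  rois <- build_acr_rois(c(64, 64, 11), c(250 / 64, 250 / 64, 10))
  sds <- vapply(1:10, function(s) {
    ph <- gen_acr_phantom(acr_phantom_spec(
      grid_shape = c(64, 64, 11), voxel_size_mm = c(250 / 64, 250 / 64, 10),
      signal_level = 100, noise_sigma = 2, seed = s))
    stats::sd(ph$data[rois$background_mask])
  }, numeric(1))
  expect_lt(abs(mean(sds) - rayleigh_sd(2)) / rayleigh_sd(2), 0.1)
})

test_that("phantom spec rejects invalid parameters", {
  expect_error(acr_phantom_spec(signal_level = 0), "positive")
  expect_error(acr_phantom_spec(bias_amplitude = 1), "bias_amplitude")
  expect_error(acr_phantom_spec(noise_sigma = -1), "nonnegative")
  expect_error(acr_phantom_spec(cylinder_radius_mm = 200), "fit")
})

test_that("DWI generator matches the tensor-model closed forms", {
  iso <- uniform_tensor_field(1e-3 * diag(c(0.7, 0.7, 0.7)), c(2, 2, 1))
  sch <- default_scheme(n_b0 = 5, n_dir = 30, b = 1000)
  dwi <- gen_dwi_series(iso, 500, sch, noise_sigma = 0)
  expect_equal(dim(dwi$data), c(2, 2, 1, 35))
  # b = 0 -> exactly s0; any unit g on an isotropic tensor -> s0 e^-0.7
  expect_equal(as.vector(dwi$data[1, 1, 1, 1:5]), rep(500, 5))
  expect_equal(as.vector(dwi$data[2, 2, 1, 6:35]),
               rep(500 * exp(-0.7), 30), tolerance = 1e-12)
  # anisotropic tensor along the x gradient: g' D g = 1.7e-3
  ani <- uniform_tensor_field(1e-3 * diag(c(1.7, 0.2, 0.2)), c(1, 1, 1))
  sx <- diffusion_scheme(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  d2 <- gen_dwi_series(ani, 1000, sx, 0)
  expect_equal(d2$data[1, 1, 1, 2], 1000 * exp(-1.7), tolerance = 1e-12)
})

test_that("DWI Rician corruption matches the exact magnitude moments", {
  # exact Rician mean via numeric integration of the magnitude density;
  # independent of the generator's complex-channel construction
  rice_mean <- function(v, s) {
    dens <- function(r)
      (r / s^2) * exp(-(r^2 + v^2) / (2 * s^2) +
                        log(besselI(r * v / s^2, 0, TRUE)) + r * v / s^2)
    stats::integrate(function(r) r * dens(r), 0, v + 12 * s)$value
  }
  iso <- uniform_tensor_field(1e-3 * diag(3), c(20, 20, 10))
  sch <- diffusion_scheme(0, cbind(c(0, 0, 0)))
  s0 <- 100
  # at S/sigma = 5 the mean magnitude sits 2.02% above the clean signal
  # (the asymptotic sigma^2/2S); the generator must match the exact value
  dwi <- gen_dwi_series(iso, s0, sch, noise_sigma = 20, seed = 2)
  se <- 20 / sqrt(length(dwi$data))
  expect_lt(abs(mean(dwi$data) - rice_mean(100, 20)), 4 * se)
  # strictly inside the high-SNR regime the < 2% bias bound holds
  dwi6 <- gen_dwi_series(iso, 120, sch, noise_sigma = 20, seed = 3)
  expect_lt(abs(mean(dwi6$data) - 120) / 120, 0.02)
  clean <- gen_dwi_series(iso, s0, sch, noise_sigma = 0)
  expect_true(all(clean$data == s0))
})

test_that("rater label maps follow the confusion model", {
  truth <- label_map(array(rep(0:1, each = 5000), c(100, 100, 1)))
  idm <- diag(2)
  identical_raters <- gen_rater_labelmaps(truth, rater_model(idm, 3, seed = 1))
  for (r in identical_raters) expect_identical(r$data, truth$data)
  cm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  raters <- gen_rater_labelmaps(truth, rater_model(cm, 4, seed = 7))
  agree <- vapply(raters, function(r) mean(r$data == truth$data), numeric(1))
  expect_true(all(abs(agree - 0.9) < 0.01))
  expect_identical(gen_rater_labelmaps(truth, rater_model(cm, 0)), list())
  bad_truth <- label_map(array(5L, c(2, 2, 1)))
  expect_error(gen_rater_labelmaps(bad_truth, rater_model(cm, 1)), "outside")
})

test_that("rater model validates confusion matrices", {
  expect_error(rater_model(matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2), 1),
               "summing to 1")
  expect_error(rater_model(matrix(1, 2, 3), 1), "square")
})

test_that("multi-site panel hits its stated moments", {
  # zero variance components -> exact true values
  exact <- gen_multisite_panel(toy_panel_spec(inter = 0, intra = 0,
                                              n_scanners = 2, n_sessions = 3))
  expect_true(all(exact$value[exact$label == "a"] == 100))
  expect_true(all(exact$value[exact$label == "b"] == 5000))
  # intra-only, 200 sessions on one scanner: CV estimate 1.0 +/- 0.15
  spec <- toy_panel_spec(inter = 0, intra = 1, n_scanners = 1,
                         n_sessions = 200, seed = 3)
  tab <- build_repro_table(gen_multisite_panel(spec))
  expect_true(all(abs(tab$intra$cv_pct - 1) < 0.15))
  # determinism
  spec2 <- toy_panel_spec(seed = 11)
  expect_identical(gen_multisite_panel(spec2), gen_multisite_panel(spec2))
})

test_that("pooled CV converges to the intra CV when inter = 0", {
  # moment recovery at n = 500 sessions, tolerance 3 standard errors of the
  # sample SD: SE(CV) ~ CV / sqrt(2 (n - 1))
  spec <- toy_panel_spec(inter = 0, intra = 2, n_scanners = 1,
                         n_sessions = 500, seed = 21, labels = c(x = 10))
  tab <- build_repro_table(gen_multisite_panel(spec))
  se <- 2 / sqrt(2 * 499)
  expect_lt(abs(tab$inter$cv_pct - 2), 3 * se)
})

test_that("geometric brain volumes match analytic ellipsoid volumes", {
  sphere <- gen_geometric_brain(c(40, 40, 40),
    list(list(center_mm = c(20, 20, 20), semiaxes_mm = c(10, 10, 10),
              label = 1)))
  vol <- label_volumes(sphere)[["1"]]
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  expect_true(all(gen_geometric_brain(c(5, 5, 5), list())$data == 0L))
  two <- gen_geometric_brain(c(40, 40, 20),
    list(list(center_mm = c(10, 10, 10), semiaxes_mm = c(5, 5, 5), label = 1),
         list(center_mm = c(30, 30, 10), semiaxes_mm = c(5, 5, 5), label = 2)))
  one <- gen_geometric_brain(c(40, 40, 20),
    list(list(center_mm = c(10, 10, 10), semiaxes_mm = c(5, 5, 5), label = 1)))
  expect_equal(label_volumes(two)[["1"]], label_volumes(one)[["1"]])
  expect_error(gen_geometric_brain(c(10, 10, 10),
    list(list(center_mm = c(9, 5, 5), semiaxes_mm = c(3, 3, 3), label = 1))),
    "outside")
})
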