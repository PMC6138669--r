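# Shared fixture: a rank-3 spectral family, its camera and a fitted model.
local_recovery_model <- function(k = 3, seed = 1) {
  cam <- camera_model()
  checker <- make_color_checker(30, seed = seed, rank = 3)
  rgb <- render_rgb(checker, cam, bits = NULL)
  list(cam = cam,
       checker = checker,
       model = fit_hsei_model(checker, rgb, k = k))
}

test_that("PCA basis recovers an exact low-dimensional subspace", {
  set.seed(3)
  comps <- qr.Q(qr(matrix(rnorm(81 * 3), ncol = 3)))
  coefs <- matrix(rnorm(60), ncol = 3)
  lib <- spectra_matrix(0.5 + coefs %*% t(comps))
  basis <- fit_spectral_basis(lib, k = 5)
  expect_lt(max(basis$explained_variance[4:5]), 1e-20)
  rec <- basis_reconstruct(basis, basis_project(basis, lib))
  expect_lt(max(abs(unclass(rec) - unclass(lib))), 1e-10)
})

test_that("basis components are orthonormal with decreasing variance", {
  basis <- fit_spectral_basis(make_color_checker(30, seed = 2), k = 6)
  G <- basis$components %*% t(basis$components)
  expect_lt(max(abs(G - diag(6))), 1e-10)
  expect_true(all(diff(basis$explained_variance) <= 1e-12))
  # deterministic sign convention
  for (i in 1:6) {
    expect_gt(basis$components[i, which.max(abs(basis$components[i, ]))], 0)
  }
})

test_that("two-point PCA gives a component along the difference", {
  a <- make_color_checker(4, seed = 8)[1, ]
  b <- make_color_checker(4, seed = 8)[2, ]
  basis <- fit_spectral_basis(spectra_matrix(rbind(a, b)), k = 1)
  d <- (a - b) / sqrt(sum((a - b)^2))
  expect_lt(min(max(abs(basis$components[1, ] - d)),
                max(abs(basis$components[1, ] + d))), 1e-10)
})

test_that("basis fitting is permutation invariant and validates k", {
  lib <- make_color_checker(20, seed = 6)
  b1 <- fit_spectral_basis(lib, k = 4)
  set.seed(1)
  b2 <- fit_spectral_basis(spectra_matrix(unclass(lib)[sample(20), ]), k = 4)
  expect_equal(b1$components, b2$components, tolerance = 1e-9)
  expect_equal(b1$mean_spectrum, b2$mean_spectrum, tolerance = 1e-12)
  expect_error(fit_spectral_basis(lib, k = 20), "library size > k")
  expect_error(fit_spectral_basis(lib, k = 0), "library size > k")
})

test_that("training reconstruction error is non-increasing in k", {
  lib <- make_color_checker(30, seed = 9)
  errs <- vapply(1:8, function(k) {
    basis <- fit_spectral_basis(lib, k = k)
    rec <- basis_reconstruct(basis, basis_project(basis, lib))
    sqrt(mean((unclass(rec) - unclass(lib))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("transformation matrix recovers a known linear map", {
  set.seed(21)
  feats <- poly_expand3(matrix(runif(90), ncol = 3))
  K <- matrix(rnorm(20 * 4), nrow = 20)
  tm <- fit_transformation_matrix(feats, feats %*% K)
  expect_lt(max(abs(tm$matrix - t(K))), 1e-8)
  expect_lt(max(tm$residual_rmse), 1e-10)
  expect_error(fit_transformation_matrix(feats[1:10, ], (feats %*% K)[1:10, ]),
               ">= 20 patches")
  dup <- feats[rep(1, 25), ]
  expect_error(fit_transformation_matrix(dup, dup[, 1:2]), "rank-deficient")
})

test_that("render-estimate round trip recovers in-span spectra", {
  fx <- local_recovery_model()
  # training residual: truth is inside the model class
  expect_lt(max(fx$model$tmat$residual_rmse), 1e-8)
  test_spectra <- make_color_checker(100, seed = 77, rank = 3)
  est <- estimate_pixel_spectrum(render_rgb(test_spectra, fx$cam, bits = NULL),
                                 model = fx$model)
  rmse <- sqrt(mean((unclass(est) - unclass(test_spectra))^2))
  expect_lt(rmse, 1e-3)
})

test_that("a black pixel from a zero reflector estimates a near-zero spectrum", {
  # conical family of positive bumps whose span contains the zero spectrum
  wl <- hsei_wavelengths()
  comps <- cbind(exp(-0.5 * ((wl - 470) / 70)^2),
                 exp(-0.5 * ((wl - 555) / 70)^2),
                 exp(-0.5 * ((wl - 645) / 70)^2))
  set.seed(12)
  lib <- spectra_matrix(matrix(runif(90, 0.02, 0.35), ncol = 3) %*% t(comps))
  cam <- camera_model()
  model <- fit_hsei_model(lib, render_rgb(lib, cam, bits = NULL), k = 3)
  est <- estimate_pixel_spectrum(c(0, 0, 0), model = model)
  expect_lt(max(abs(est)), 1e-3)
})

test_that("pixel estimation is deterministic and checks dimensions", {
  fx <- local_recovery_model()
  e1 <- estimate_pixel_spectrum(c(120, 80, 60), model = fx$model)
  e2 <- estimate_pixel_spectrum(c(120, 80, 60), model = fx$model)
  expect_identical(unclass(e1), unclass(e2))
  broken <- fx$model
  broken$tmat$matrix <- broken$tmat$matrix[, 1:10]
  expect_error(estimate_pixel_spectrum(c(1, 2, 3), model = broken),
               "dimension mismatch")
  broken2 <- fx$model
  broken2$tmat$matrix <- rbind(broken2$tmat$matrix, 0)
  expect_error(estimate_pixel_spectrum(c(1, 2, 3), model = broken2),
               "dimension mismatch")
})

test_that("image estimation equals the per-pixel loop", {
  fx <- local_recovery_model()
  img <- render_rgb(make_endoscopic_scene("IPCL_IV", "nbi", c(64, 64),
                                          seed = 5), fx$cam)
  est <- estimate_pixel_spectrum(img, model = fx$model)
  set.seed(2)
  for (px in sample(64 * 64, 10)) {
    r <- ((px - 1) %% 64) + 1; c <- ((px - 1) %/% 64) + 1
    one <- estimate_pixel_spectrum(img[r, c, ], model = fx$model)
    expect_equal(unclass(est)[(c - 1) * 64 + r, ], as.numeric(one),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("ROI averaging counts pixels and matches per-pixel estimates", {
  fx <- local_recovery_model()
  img <- render_rgb(make_endoscopic_scene("IPCL_V1_SCC", "nbi", c(64, 64),
                                          seed = 6), fx$cam)
  avg <- roi_average_spectrum(img, c(3, 5, 10, 12), model = fx$model)
  expect_equal(attr(avg, "n_pixels"), 120)
  # definition check: mean of per-pixel estimates, exactly
  est <- estimate_pixel_spectrum(img[3:12, 5:16, , drop = FALSE],
                                 model = fx$model)
  expect_equal(as.numeric(avg), colMeans(unclass(est)), tolerance = 1e-14)
  # 1x1 ROI equals the single-pixel estimate
  one <- roi_average_spectrum(img, c(7, 9, 1, 1), model = fx$model)
  px <- estimate_pixel_spectrum(img[7, 9, ], model = fx$model)
  expect_equal(as.numeric(one), as.numeric(px), tolerance = 1e-14)
  # uniform image: average equals any pixel
  uni <- array(rep(c(100, 120, 90), each = 16 * 16), dim = c(16, 16, 3))
  u <- roi_average_spectrum(uni, c(1, 1, 16, 16), model = fx$model)
  upx <- estimate_pixel_spectrum(c(100, 120, 90), model = fx$model)
  expect_equal(as.numeric(u), as.numeric(upx), tolerance = 1e-12)
  expect_error(roi_average_spectrum(img, c(60, 60, 10, 10), model = fx$model),
               "outside")
})

test_that("estimates are clipped to [0, 1.2] with a clip count", {
  fx <- local_recovery_model()
  est <- estimate_pixel_spectrum(matrix(c(255, 0, 255, 0, 255, 0), ncol = 3),
                                 model = fx$model)
  expect_true(all(est >= 0 & est <= 1.2))
  expect_true(is.numeric(attr(est, "n_clipped")))
})
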