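#' Fit a PCA spectral basis
#'
#' Mean-centred principal component analysis of a spectral library. The
#' first `k` components, ordered by decreasing explained variance, form an
#' orthonormal basis for reconstructing smooth visible reflectance spectra
#' from a handful of coefficients. Signs are fixed deterministically (the
#' largest-magnitude element of each component is made positive) so
#' serialized bases are reproducible.
#'
#' @param library A spectra matrix (rows are library spectra).
#' @param k Number of components to keep (1 <= k < number of spectra).
#' @return An `hsei_basis`: `mean_spectrum`, `components` (k x n_wl,
#'   orthonormal rows), `explained_variance`, `wavelength`.
#' @examples
#' basis <- fit_spectral_basis(make_color_checker(30, seed = 1), k = 6)
#' @export
fit_spectral_basis <- function(library, k = 6) {
  m <- unclass(library)
  if (is.vector(m)) m <- matrix(m, nrow = 1)
  if (k < 1 || k >= nrow(m)) {
    stop("need library size > k >= 1 (got ", nrow(m), " spectra, k = ", k,
         ")", call. = FALSE)
  }
  wl <- spectra_grid(library)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-magnitude element of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(
    list(
      mean_spectrum = pc$center,
      components = comp,
      explained_variance = pc$sdev[seq_len(k)]^2,
      wavelength = wl
    ),
    class = "hsei_basis"
  )
}

#' Project spectra onto a basis / reconstruct from coefficients
#'
#' @param basis An `hsei_basis`.
#' @param spectra Spectra matrix or single spectrum vector.
#' @param coefficients n x k matrix (or length-k vector) of coefficients.
#' @return `basis_project()` returns an n x k coefficient matrix;
#'   `basis_reconstruct()` a spectra matrix.
#' @export
basis_project <- function(basis, spectra) {
  m <- if (is.vector(spectra)) matrix(spectra, nrow = 1) else unclass(spectra)
  check_same_grid(spectra_grid(spectra), basis$wavelength, "spectra and basis")
  sweep(m, 2, basis$mean_spectrum) %*% t(basis$components)
}

#' @rdname basis_project
#' @export
basis_reconstruct <- function(basis, coefficients) {
  co <- if (is.vector(coefficients)) matrix(coefficients, nrow = 1) else
    as.matrix(coefficients)
  stopifnot(ncol(co) == nrow(basis$components))
  m <- sweep(co %*% basis$components, 2, basis$mean_spectrum, "+")
  spectra_matrix(m, wavelength = basis$wavelength)
}

#' @export
print.hsei_basis <- function(x, ...) {
  cat(sprintf("<hsei_basis> k=%d components on %d wavelengths; var %s\n",
              nrow(x$components), length(x$mean_spectrum),
              paste(signif(x$explained_variance, 3), collapse = ", ")))
  invisible(x)
}

#' @method tidy hsei_basis
#' @export
tidy.hsei_basis <- function(x, ...) {
  k <- nrow(x$components)
  tibble::tibble(
    component = rep(seq_len(k), each = length(x$wavelength)),
    wavelength_nm = rep(x$wavelength, times = k),
    loading = as.vector(t(x$components))
  )
}

#' @method glance hsei_basis
#' @export
glance.hsei_basis <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$components),
    total_variance = sum(x$explained_variance),
    leading_share = x$explained_variance[1] / sum(x$explained_variance)
  )
}

#' Fit the RGB-feature to basis-coefficient transformation matrix
#'
#' The core of spectrum estimation: a least-squares linear map from the
#' 20-dimensional third-order RGB feature vector to the k basis
#' coefficients, fitted on the colour-checker patches.
#'
#' @param features n x 20 matrix of expanded (adapted) linear RGB features.
#' @param coefficients n x k matrix of basis projections of the measured
#'   patch spectra.
#' @return An `hsei_tmat`: `matrix` (k x 20), per-component residual RMSE.
#' @export
fit_transformation_matrix <- function(features, coefficients) {
  X <- as.matrix(features); Y <- as.matrix(coefficients)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) < 20) {
    stop("transformation matrix needs >= 20 patches (got ", nrow(X), ")",
         call. = FALSE)
  }
  coef <- ls_solve(X, Y)
  resid <- X %*% coef - Y
  structure(
    list(
      matrix = t(coef),
      feature_order = poly3_feature_order,
      residual_rmse = sqrt(colMeans(resid^2)),
      n_patches = nrow(X)
    ),
    class = "hsei_tmat"
  )
}

#' @export
print.hsei_tmat <- function(x, ...) {
  cat(sprintf("<hsei_tmat> %d x %d, fitted on %d patches\n",
              nrow(x$matrix), ncol(x$matrix), x$n_patches))
  invisible(x)
}

#' Fit the full spectrum-estimation model from a checker
#'
#' Convenience wrapper chaining the pieces: fits the PCA basis on a
#' spectral library, renders/receives the checker's camera RGB, applies
#' chromatic adaptation, expands features and fits the transformation
#' matrix.
#'
#' @param checker_spectra Spectra matrix of measured checker reflectances.
#' @param camera_rgb_8bit n x 3 matrix of the camera's 8-bit RGB for the
#'   same patches (or continuous 0--255 values).
#' @param library Spectral library for the basis; defaults to the checker
#'   itself.
#' @param k Basis dimension.
#' @param src_white,dst_white Whites for chromatic adaptation (camera scene
#'   illuminant vs target illuminant).
#' @return An `hsei_model`: list with `calibration` (adaptation + feature
#'   machinery), `tmat`, `basis`.
#' @export
fit_hsei_model <- function(checker_spectra, camera_rgb_8bit,
                           library = checker_spectra, k = 6,
                           src_white = c(100, 100, 100),
                           dst_white = src_white) {
  basis <- fit_spectral_basis(library, k = k)
  check_same_grid(spectra_grid(checker_spectra), basis$wavelength,
                  "checker and basis")
  coefs <- basis_project(basis, checker_spectra)
  calib <- fit_color_transform(srgb_decode(camera_rgb_8bit), coefs,
                               src_white = src_white, dst_white = dst_white)
  tmat <- structure(
    list(matrix = t(calib$coefficients),
         feature_order = poly3_feature_order,
         residual_rmse = calib$residual_rmse,
         n_patches = calib$n_patches),
    class = "hsei_tmat"
  )
  structure(list(calibration = calib, tmat = tmat, basis = basis),
            class = "hsei_model")
}

#' @export
print.hsei_model <- function(x, ...) {
  cat("<hsei_model>\n  ")
  print(x$basis)
  cat("  ")
  print(x$tmat)
  invisible(x)
}

#' Estimate the reflectance spectrum of pixels
#'
#' The estimation chain for one pixel (or many): sRGB decode, chromatic
#' adaptation, third-order feature expansion, transformation matrix to
#' basis coefficients, then mean + sum(coefficient x component). Estimates
#' are clipped to \[0, 1.2\]; the number of clipped samples is attached as
#' attribute `n_clipped` (a non-zero count flags calibration failure
#' rather than silently saturating at 1).
#'
#' @param rgb_8bit Length-3 RGB triple, n x 3 matrix, or h x w x 3 array,
#'   on the 0--255 scale.
#' @param model An `hsei_model` from [fit_hsei_model()] (or pass
#'   `calibration`, `tmat`, `basis` individually).
#' @param calibration,tmat,basis Individual fitted pieces (overridden by
#'   `model` when given).
#' @return A spectra matrix (one row per pixel; arrays are flattened
#'   row-major by pixel with attribute `image_dim`), clipped to \[0, 1.2\].
#' @export
estimate_pixel_spectrum <- function(rgb_8bit, model = NULL,
                                    calibration = model$calibration,
                                    tmat = model$tmat,
                                    basis = model$basis) {
  if (is.null(calibration) || is.null(tmat) || is.null(basis)) {
    stop("need a fitted model (calibration, tmat, basis)", call. = FALSE)
  }
  if (ncol(tmat$matrix) != 20L) {
    stop("dimension mismatch: transformation matrix has ",
         ncol(tmat$matrix), " feature columns, expected 20", call. = FALSE)
  }
  if (nrow(tmat$matrix) != nrow(basis$components)) {
    stop("dimension mismatch: transformation matrix maps to ",
         nrow(tmat$matrix), " coefficients but the basis has k = ",
         nrow(basis$components), call. = FALSE)
  }
  img_dim <- NULL
  if (is.array(rgb_8bit) && length(dim(rgb_8bit)) == 3) {
    d <- dim(rgb_8bit)
    stopifnot(d[3] == 3)
    img_dim <- d[1:2]
    m <- matrix(rgb_8bit, nrow = d[1] * d[2], ncol = 3)
  } else if (is.matrix(rgb_8bit)) {
    stopifnot(ncol(rgb_8bit) == 3)
    m <- rgb_8bit
  } else {
    stopifnot(length(rgb_8bit) == 3)
    m <- matrix(as.numeric(rgb_8bit), ncol = 3)
  }
  lin <- srgb_decode(m)
  adapted <- lin %*% t(calibration$adaptation_matrix_rgb)
  coefs <- poly_expand3(adapted) %*% t(tmat$matrix)
  est <- unclass(basis_reconstruct(basis, coefs))
  n_clip <- sum(est < 0) + sum(est > 1.2)
  est <- pmin(pmax(est, 0), 1.2)
  out <- spectra_matrix(est, wavelength = basis$wavelength)
  attr(out, "n_clipped") <- n_clip
  attr(out, "image_dim") <- img_dim
  out
}

#' Average estimated spectrum over a rectangular ROI
#'
#' Estimates the spectrum of every pixel inside a region of interest and
#' returns their arithmetic mean, recording how many pixels contributed
#' (for the conventional 50 x 50 patient ROI this is 2500).
#'
#' @param image h x w x 3 RGB array (0--255).
#' @param roi Rectangle `c(row0, col0, height, width)` (1-based, inclusive
#'   origin).
#' @param model Fitted `hsei_model` (or pass pieces via `...`).
#' @param ... Passed to [estimate_pixel_spectrum()].
#' @return One-row spectra matrix with attribute `n_pixels`.
#' @export
roi_average_spectrum <- function(image, roi, model = NULL, ...) {
  stopifnot(length(dim(image)) == 3, length(roi) == 4)
  r0 <- roi[1]; c0 <- roi[2]; hh <- roi[3]; ww <- roi[4]
  d <- dim(image)
  if (r0 < 1 || c0 < 1 || hh < 1 || ww < 1 ||
      r0 + hh - 1 > d[1] || c0 + ww - 1 > d[2]) {
    stop("roi [", paste(roi, collapse = ", "), "] lies outside the ",
         d[1], "x", d[2], " image", call. = FALSE)
  }
  sub <- image[r0:(r0 + hh - 1), c0:(c0 + ww - 1), , drop = FALSE]
  est <- estimate_pixel_spectrum(sub, model = model, ...)
  avg <- colMeans(unclass(est))
  out <- spectra_matrix(avg, wavelength = spectra_grid(est), ids = "roi_mean")
  attr(out, "n_pixels") <- nrow(est)
  out
}
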