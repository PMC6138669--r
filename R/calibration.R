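# Frozen monomial ordering of the third-order feature expansion. Serialized
# with every fitted model so coefficient files remain portable.
poly3_feature_order <- c(
  "1", "R", "G", "B",
  "R2", "G2", "B2", "RG", "RB", "GB",
  "R3", "G3", "B3", "R2G", "R2B", "G2R", "G2B", "B2R", "B2G", "RGB"
)

#' Third-order polynomial feature expansion of linear RGB
#'
#' Expands linear RGB triples into all 20 monomials of total degree <= 3
#' (the C(3+3,3) = 20 terms: constant, linear, quadratic and cubic), in the
#' fixed documented order given by `poly3_feature_order`.
#'
#' @param rgb Length-3 numeric, or an n x 3 matrix of linear RGB rows.
#' @return Length-20 vector, or n x 20 matrix, with named columns.
#' @examples
#' poly_expand3(c(0, 0, 0))[1] # 1
#' @export
poly_expand3 <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(as.numeric(rgb), ncol = 3)
  stopifnot(ncol(m) == 3, all(is.finite(m)))
  R <- m[, 1]; G <- m[, 2]; B <- m[, 3]
  out <- cbind(
    1, R, G, B,
    R^2, G^2, B^2, R * G, R * B, G * B,
    R^3, G^3, B^3, R^2 * G, R^2 * B, G^2 * R, G^2 * B, B^2 * R, B^2 * G,
    R * G * B
  )
  colnames(out) <- poly3_feature_order
  if (!is.matrix(rgb)) out[1, ] else out
}

# Least squares with pseudo-inverse fallback for near-singular designs.
# Errors (rather than silently regularising) when the design is genuinely
# rank-deficient, because a deficient checker cannot identify the map.
ls_solve <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank-deficient (rank ", qx$rank, " < ",
         ncol(X), "): calibration needs >= 20 patches in general position",
         call. = FALSE)
  }
  kappa_x <- kappa(X)
  if (is.finite(kappa_x) && kappa_x > 1e12) {
    # near-singular: pseudo-inverse is numerically safer than qr.coef
    return(MASS::ginv(X) %*% Y)
  }
  qr.coef(qx, Y)
}

#' Fit the colour-correction model
#'
#' Fits the colour relationship between a camera and a spectrophotometer:
#' a chromatic adaptation between the two white points followed by an
#' independent third-order polynomial regression per output channel, from
#' expanded linear camera RGB to the target values (XYZ tristimulus triples
#' or spectral-basis coefficients; both share the same expansion).
#'
#' Chromatic adaptation is applied to the camera RGB (a Bradford transform
#' expressed in linear sRGB space) before the polynomial expansion; when
#' `src_white` equals `dst_white` it is the identity.
#'
#' @param camera_rgbs n x 3 matrix of linear camera RGB values (one row per
#'   checker patch, in \[0,1\]).
#' @param targets n x p matrix of target values (p = 3 for XYZ,
#'   p = k for basis coefficients).
#' @param src_white,dst_white XYZ whites of the camera scene illuminant and
#'   of the target (spectrophotometer) illuminant. Defaults give an
#'   identity adaptation.
#' @return An `hsei_calibration` object: adaptation matrix and whites,
#'   coefficient matrix (20 x p), the frozen feature order, and the
#'   training residual RMSE per output channel.
#' @examples
#' checker <- make_color_checker(30, seed = 1)
#' cam <- camera_model()
#' rgb <- srgb_decode(render_rgb(checker, cam, bits = NULL))
#' fit <- fit_color_transform(rgb, xyz_from_spectrum(checker))
#' @export
fit_color_transform <- function(camera_rgbs, targets,
                                src_white = c(100, 100, 100),
                                dst_white = src_white) {
  camera_rgbs <- as.matrix(camera_rgbs)
  targets <- as.matrix(targets)
  stopifnot(ncol(camera_rgbs) == 3, nrow(camera_rgbs) == nrow(targets))
  if (nrow(camera_rgbs) < 20) {
    stop("calibration needs >= 20 patches: the 20-term third-order ",
         "expansion is otherwise rank-deficient", call. = FALSE)
  }
  A <- chromatic_adapt_matrix(src_white, dst_white)
  A_rgb <- srgb_xyz_inv %*% A %*% srgb_xyz
  adapted <- camera_rgbs %*% t(A_rgb)
  X <- poly_expand3(adapted)
  coef <- ls_solve(X, targets)
  resid <- X %*% coef - targets
  structure(
    list(
      adaptation_matrix = A,
      adaptation_matrix_rgb = A_rgb,
      src_white = as.numeric(src_white),
      dst_white = as.numeric(dst_white),
      coefficients = coef,
      feature_order = poly3_feature_order,
      residual_rmse = sqrt(colMeans(resid^2)),
      n_patches = nrow(camera_rgbs)
    ),
    class = "hsei_calibration"
  )
}

# Linear sRGB <-> XYZ (D65 reference, Y of white = 100).
srgb_xyz <- 100 * matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
srgb_xyz_inv <- solve(srgb_xyz)

#' Apply a fitted colour-correction model
#'
#' @param object An `hsei_calibration` fit.
#' @param rgb Linear RGB triple or n x 3 matrix.
#' @param ... Unused.
#' @return Predicted targets (vector or n x p matrix).
#' @export
predict.hsei_calibration <- function(object, rgb, ...) {
  m <- if (is.matrix(rgb)) rgb else matrix(as.numeric(rgb), ncol = 3)
  adapted <- m %*% t(object$adaptation_matrix_rgb)
  out <- poly_expand3(adapted) %*% object$coefficients
  if (!is.matrix(rgb)) drop(out) else out
}

#' @export
print.hsei_calibration <- function(x, ...) {
  cat(sprintf(
    "<hsei_calibration> %d patches, %d outputs, residual RMSE %s\n",
    x$n_patches, ncol(x$coefficients),
    paste(signif(x$residual_rmse, 3), collapse = ", ")))
  invisible(x)
}

#' @method tidy hsei_calibration
#' @export
tidy.hsei_calibration <- function(x, ...) {
  co <- x$coefficients
  outs <- colnames(co)
  if (is.null(outs)) outs <- sprintf("target_%d", seq_len(ncol(co)))
  tibble::tibble(
    term = rep(x$feature_order, times = ncol(co)),
    output = rep(outs, each = nrow(co)),
    estimate = as.vector(co)
  )
}

#' @method glance hsei_calibration
#' @export
glance.hsei_calibration <- function(x, ...) {
  tibble::tibble(
    n_patches = x$n_patches,
    n_outputs = ncol(x$coefficients),
    residual_rmse = sqrt(mean(x$residual_rmse^2))
  )
}
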