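#' sRGB transfer functions
#'
#' `srgb_decode()` maps 8-bit sRGB-encoded values (0--255) to linear
#' reflectance-proportional values in \[0, 1\] with the standard piecewise
#' IEC 61966-2-1 electro-optical transfer function; `srgb_encode()` is its
#' inverse (returning values on the 0--255 scale, unrounded unless
#' `bits = 8`). Both accept scalars, vectors or arrays and preserve shape.
#'
#' @param x Encoded values on the 0--255 scale (`srgb_decode`) or linear
#'   values in \[0, 1\] (`srgb_encode`).
#' @param bits If `8`, `srgb_encode()` rounds to integers; `NULL` leaves
#'   the encoded values continuous (used for noise-free round trips).
#' @return Numeric object of the same shape as `x`.
#' @examples
#' srgb_decode(c(0, 255)) # 0, 1
#' srgb_encode(srgb_decode(55)) # 55
#' @export
srgb_decode <- function(x) {
  stopifnot(is.numeric(x))
  v <- x / 255
  out <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  out[] <- pmin(pmax(out, 0), 1)
  attributes(out) <- attributes(x)
  out
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(x, bits = NULL) {
  stopifnot(is.numeric(x))
  v <- pmin(pmax(x, 0), 1)
  out <- ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055) * 255
  if (identical(bits, 8)) out <- round(out)
  attributes(out) <- attributes(x)
  out
}

# CIE 1931 2-degree colour-matching functions, analytic multi-lobe
# piecewise-Gaussian fit (max abs error ~1e-2 relative to the tables,
# smooth and exactly reproducible from constants).
piecewise_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 observer colour-matching functions
#'
#' Analytic approximation of the 2-degree standard observer evaluated on a
#' wavelength grid. Returns a matrix with columns `x`, `y`, `z`.
#'
#' @param wavelength Wavelength grid in nm.
#' @return Numeric matrix `length(wavelength)` x 3.
#' @export
cie_cmf <- function(wavelength = hsei_wavelengths()) {
  xbar <- 1.056 * piecewise_gauss(wavelength, 599.8, 37.9, 31.0) +
    0.362 * piecewise_gauss(wavelength, 442.0, 16.0, 26.7) -
    0.065 * piecewise_gauss(wavelength, 501.1, 20.4, 26.2)
  ybar <- 0.821 * piecewise_gauss(wavelength, 568.8, 46.9, 40.5) +
    0.286 * piecewise_gauss(wavelength, 530.9, 16.3, 31.1)
  zbar <- 1.217 * piecewise_gauss(wavelength, 437.0, 11.8, 36.0) +
    0.681 * piecewise_gauss(wavelength, 459.0, 26.0, 13.8)
  cbind(x = xbar, y = ybar, z = zbar)
}

#' Standard illuminants on the package grid
#'
#' `illuminant_flat()` is an equal-energy spectrum (the package's stand-in
#' for a broadband endoscope lamp); `illuminant_daylight()` is a
#' daylight-like 6504 K Planck blackbody spectrum, normalised to unit
#' mean, used as a genuinely different white for checker measurement so
#' chromatic adaptation is exercised.
#'
#' @param wavelength Wavelength grid in nm.
#' @return Numeric vector of relative spectral power (unit mean).
#' @export
illuminant_flat <- function(wavelength = hsei_wavelengths()) {
  rep(1, length(wavelength))
}

#' @rdname illuminant_flat
#' @param temp_K Blackbody temperature in kelvin.
#' @export
illuminant_daylight <- function(wavelength = hsei_wavelengths(),
                                temp_K = 6504) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kb <- 1.380649e-23
  lam <- wavelength * 1e-9
  p <- 1 / (lam^5 * (exp(h * c0 / (lam * kb * temp_K)) - 1))
  p / mean(p)
}

#' XYZ tristimulus values of a reflectance spectrum
#'
#' X, Y, Z = k * sum(reflectance * illuminant * CMF), with the constant k
#' chosen so a perfect (unit) reflector has Y = 100 under the given
#' illuminant.
#'
#' @param spectrum Reflectance vector on `wavelength`, or a spectra matrix
#'   (one row per spectrum).
#' @param illuminant Spectral power distribution on the same grid.
#' @param cmf Observer colour-matching functions, matrix with columns x,y,z.
#' @param wavelength Grid for `spectrum` when it is a bare vector.
#' @return Numeric vector `c(X, Y, Z)`, or an n x 3 matrix for a spectra
#'   matrix input.
#' @examples
#' xyz_from_spectrum(rep(1, 81))[2] # Y = 100
#' @export
xyz_from_spectrum <- function(spectrum,
                              illuminant = illuminant_flat(wavelength),
                              cmf = cie_cmf(wavelength),
                              wavelength = hsei_wavelengths()) {
  if (inherits(spectrum, "hsei_spectra")) {
    wavelength <- spectra_grid(spectrum)
    m <- unclass(spectrum)
  } else if (is.matrix(spectrum)) {
    m <- spectrum
  } else {
    m <- matrix(spectrum, nrow = 1)
  }
  if (ncol(m) != length(wavelength)) {
    stop("wavelength grid mismatch between spectrum and grid", call. = FALSE)
  }
  if (length(illuminant) != length(wavelength) ||
      nrow(cmf) != length(wavelength)) {
    stop("wavelength grid mismatch between spectrum, illuminant and CMFs",
         call. = FALSE)
  }
  k <- 100 / sum(illuminant * cmf[, "y"])
  xyz <- k * (m %*% (illuminant * cmf))
  colnames(xyz) <- c("X", "Y", "Z")
  if (nrow(xyz) == 1) drop(xyz) else xyz
}

# Bradford sharpened cone-response matrix and its inverse.
bradford_M <- matrix(c(
   0.8951,  0.2664, -0.1614,
  -0.7502,  1.7135,  0.0367,
   0.0389, -0.0685,  1.0296
), nrow = 3, byrow = TRUE)

#' Chromatic adaptation between white points
#'
#' Linear von-Kries-style adaptation in the Bradford sharpened cone space:
#' cone responses are scaled by the ratio of destination to source white
#' responses, so the source white maps exactly to the destination white.
#' `chromatic_adapt_matrix()` returns the 3x3 XYZ-to-XYZ map;
#' `chromatic_adapt()` applies it to one XYZ triple or to rows of a matrix.
#'
#' @param xyz XYZ triple (length 3) or n x 3 matrix.
#' @param src_white,dst_white XYZ of the source and destination whites
#'   (positive Y).
#' @return Adapted XYZ with the shape of `xyz`; the matrix function returns
#'   a 3x3 matrix.
#' @export
chromatic_adapt_matrix <- function(src_white, dst_white) {
  src_white <- as.numeric(src_white); dst_white <- as.numeric(dst_white)
  stopifnot(length(src_white) == 3, length(dst_white) == 3)
  if (src_white[2] <= 0 || dst_white[2] <= 0) {
    stop("white points must have positive Y", call. = FALSE)
  }
  cs <- as.numeric(bradford_M %*% src_white)
  cd <- as.numeric(bradford_M %*% dst_white)
  if (any(abs(cs) < 1e-12)) stop("degenerate source white", call. = FALSE)
  solve(bradford_M) %*% diag(cd / cs) %*% bradford_M
}

#' @rdname chromatic_adapt_matrix
#' @export
chromatic_adapt <- function(xyz, src_white, dst_white) {
  A <- chromatic_adapt_matrix(src_white, dst_white)
  if (is.matrix(xyz)) {
    out <- xyz %*% t(A)
    colnames(out) <- c("X", "Y", "Z")
    out
  } else {
    as.numeric(A %*% as.numeric(xyz))
  }
}
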