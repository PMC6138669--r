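# Local seeded evaluation: restores the caller's RNG stream afterwards so
# fixture generation is reproducible without disturbing outer code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic endoscope camera model
#'
#' A simple trichromatic camera: three non-negative Gaussian spectral
#' sensitivity curves on the package wavelength grid, a scene illuminant,
#' and sRGB output encoding. Exposure is normalised per channel so a
#' perfect (unit) reflector renders to RGB (255, 255, 255).
#'
#' @param wavelength Wavelength grid (nm).
#' @param illuminant Scene illuminant on the grid; default equal-energy,
#'   the package's stand-in for a broadband endoscope lamp.
#' @param centers,widths Per-channel Gaussian centre/width (nm) for the
#'   R, G, B sensitivities.
#' @return An object of class `hsei_camera`: list with `sensitivities`
#'   (n x 3 matrix), `illuminant`, `wavelength`, `white_point` (XYZ of the
#'   illuminant) and `encoding = "srgb"`.
#' @export
camera_model <- function(wavelength = hsei_wavelengths(),
                         illuminant = illuminant_flat(wavelength),
                         centers = c(610, 540, 465),
                         widths = c(45, 40, 35)) {
  stopifnot(length(illuminant) == length(wavelength),
            all(illuminant >= 0), length(centers) == 3, length(widths) == 3)
  sens <- vapply(1:3, function(ch) {
    exp(-0.5 * ((wavelength - centers[ch]) / widths[ch])^2)
  }, numeric(length(wavelength)))
  colnames(sens) <- c("R", "G", "B")
  structure(
    list(
      sensitivities = sens,
      illuminant = illuminant,
      wavelength = wavelength,
      white_point = xyz_from_spectrum(rep(1, length(wavelength)),
                                      illuminant = illuminant,
                                      wavelength = wavelength),
      encoding = "srgb"
    ),
    class = "hsei_camera"
  )
}

#' @export
print.hsei_camera <- function(x, ...) {
  cat(sprintf("<hsei_camera> %d wavelengths, white point XYZ = (%.1f, %.1f, %.1f)\n",
              length(x$wavelength), x$white_point[1], x$white_point[2],
              x$white_point[3]))
  invisible(x)
}

# Linear camera response of spectra (rows) under a camera: each channel is
# sum(reflectance * illuminant * sensitivity), scaled so unit reflectance
# gives exactly 1.0 per channel.
linear_response <- function(spectra, camera) {
  m <- if (inherits(spectra, "hsei_spectra")) unclass(spectra) else spectra
  if (is.vector(m)) m <- matrix(m, nrow = 1)
  check_same_grid(spectra_grid(spectra), camera$wavelength,
                  "scene and camera")
  w <- camera$sensitivities * camera$illuminant
  norm <- colSums(w)
  out <- sweep(m %*% w, 2, norm, "/")
  colnames(out) <- c("R", "G", "B")
  out
}

#' Render reflectance spectra through a camera
#'
#' Forward imaging model: per pixel the linear channel value is
#' sum(reflectance x illuminant x sensitivity), normalised so a unit
#' reflector maps to 1.0 per channel, then sRGB-encoded to the 0--255
#' scale. With `bits = 8` (default) values are rounded to integers as a
#' real camera would; `bits = NULL` keeps them continuous, which is used
#' by noise-free round-trip checks.
#'
#' @param scene An `hsei_scene`, a spectra matrix, or a reflectance array
#'   (h x w x n_wavelength).
#' @param camera An [camera_model()] on the same wavelength grid.
#' @param bits `8` or `NULL`, see above.
#' @return For a scene/array input an h x w x 3 array; for a spectra matrix
#'   an n x 3 matrix. Values on the 0--255 scale.
#' @examples
#' cam <- camera_model()
#' render_rgb(spectra_matrix(rep(1, 81)), cam) # 255 255 255
#' @export
render_rgb <- function(scene, camera, bits = 8) {
  if (inherits(scene, "hsei_scene")) {
    refl <- scene$reflectance
    check_same_grid(scene$wavelength, camera$wavelength, "scene and camera")
  } else if (is.array(scene) && length(dim(scene)) == 3) {
    refl <- scene
  } else {
    lin <- linear_response(scene, camera)
    return(srgb_encode(lin, bits = bits))
  }
  d <- dim(refl)
  if (d[3] != length(camera$wavelength)) {
    stop("wavelength grid mismatch between scene and camera", call. = FALSE)
  }
  flat <- matrix(refl, nrow = d[1] * d[2], ncol = d[3])
  lin <- linear_response(spectra_matrix(flat, wavelength = camera$wavelength),
                         camera)
  out <- array(srgb_encode(lin, bits = bits), dim = c(d[1], d[2], 3))
  out
}
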