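# All matrices are serialized row-major with explicit dimensions, and the
# polynomial feature order is written out so coefficient files remain
# self-describing.

mat_to_json <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), data = as.vector(t(m)))
}

mat_from_json <- function(x) {
  matrix(unlist(x$data), nrow = x$nrow, ncol = x$ncol, byrow = TRUE)
}

#' Serialize and restore a fitted spectrum-estimation model
#'
#' The full `hsei_model` (chromatic adaptation, polynomial coefficients,
#' transformation matrix, PCA basis and wavelength grid) round-trips
#' through a single JSON file.
#'
#' @param model An `hsei_model`.
#' @param path JSON file path.
#' @return `write_hsei_model()` returns `path` invisibly;
#'   `read_hsei_model()` the restored model.
#' @export
write_hsei_model <- function(model, path) {
  stopifnot(inherits(model, "hsei_model"))
  cal <- model$calibration
  obj <- list(
    format = "hsei_model",
    version = 1L,
    calibration = list(
      adaptation_matrix = mat_to_json(cal$adaptation_matrix),
      adaptation_matrix_rgb = mat_to_json(cal$adaptation_matrix_rgb),
      src_white = cal$src_white,
      dst_white = cal$dst_white,
      coefficients = mat_to_json(cal$coefficients),
      feature_order = cal$feature_order,
      residual_rmse = as.numeric(cal$residual_rmse),
      n_patches = cal$n_patches
    ),
    tmat = list(
      matrix = mat_to_json(model$tmat$matrix),
      feature_order = model$tmat$feature_order,
      residual_rmse = as.numeric(model$tmat$residual_rmse),
      n_patches = model$tmat$n_patches
    ),
    basis = list(
      mean_spectrum = as.numeric(model$basis$mean_spectrum),
      components = mat_to_json(model$basis$components),
      explained_variance = as.numeric(model$basis$explained_variance),
      wavelength = as.numeric(model$basis$wavelength)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hsei_model
#' @export
read_hsei_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hsei_model")) {
    stop("not an hsei model file: ", path, call. = FALSE)
  }
  cal <- obj$calibration
  calibration <- structure(
    list(
      adaptation_matrix = mat_from_json(cal$adaptation_matrix),
      adaptation_matrix_rgb = mat_from_json(cal$adaptation_matrix_rgb),
      src_white = as.numeric(cal$src_white),
      dst_white = as.numeric(cal$dst_white),
      coefficients = mat_from_json(cal$coefficients),
      feature_order = as.character(cal$feature_order),
      residual_rmse = as.numeric(cal$residual_rmse),
      n_patches = as.integer(cal$n_patches)
    ),
    class = "hsei_calibration"
  )
  tmat <- structure(
    list(
      matrix = mat_from_json(obj$tmat$matrix),
      feature_order = as.character(obj$tmat$feature_order),
      residual_rmse = as.numeric(obj$tmat$residual_rmse),
      n_patches = as.integer(obj$tmat$n_patches)
    ),
    class = "hsei_tmat"
  )
  basis <- structure(
    list(
      mean_spectrum = as.numeric(obj$basis$mean_spectrum),
      components = mat_from_json(obj$basis$components),
      explained_variance = as.numeric(obj$basis$explained_variance),
      wavelength = as.numeric(obj$basis$wavelength)
    ),
    class = "hsei_basis"
  )
  if (ncol(tmat$matrix) != 20L || nrow(tmat$matrix) != nrow(basis$components)) {
    stop("corrupt model file: transformation matrix is ",
         nrow(tmat$matrix), "x", ncol(tmat$matrix),
         " but the basis has k = ", nrow(basis$components),
         " components and 20 features are expected", call. = FALSE)
  }
  structure(list(calibration = calibration, tmat = tmat, basis = basis),
            class = "hsei_model")
}

#' Serialize and restore triangle regions
#'
#' @param regions An `hsei_regions` set.
#' @param path JSON file path.
#' @return Path (write) or restored `hsei_regions` (read).
#' @export
write_regions_json <- function(regions, path) {
  obj <- lapply(unclass(regions), function(r) {
    list(stage = r$stage, vertices = mat_to_json(r$vertices))
  })
  jsonlite::write_json(list(format = "hsei_regions", regions = obj), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_json
#' @export
read_regions_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hsei_regions")) {
    stop("not an hsei regions file: ", path, call. = FALSE)
  }
  regs <- obj$regions
  out <- lapply(names(regs), function(st) {
    v <- mat_from_json(regs[[st]]$vertices)
    triangle_region(v[1, ], v[2, ], v[3, ], stage = regs[[st]]$stage)
  })
  names(out) <- names(regs)
  structure(out, class = "hsei_regions")
}

#' Export and import recorded coordinates as CSV
#'
#' Columns `row`, `col`, 0-based, row-major sorted — the machine-readable
#' replacement for a hand-kept coordinate notepad.
#'
#' @param coords An `hsei_coords` tibble.
#' @param path CSV path.
#' @return Path (write) or tibble (read).
#' @export
write_coordinates_csv <- function(coords, path) {
  readr::write_csv(coords[, c("row", "col")], path)
  invisible(path)
}

#' @rdname write_coordinates_csv
#' @export
read_coordinates_csv <- function(path) {
  readr::read_csv(path, col_types = "ii")
}

#' Spectral cube container
#'
#' A full-image spectral cube (h x w x n_wavelength reflectance array) is
#' written as a flat little-endian float64 binary file plus a JSON header
#' recording shape, wavelength grid and element order (row, col,
#' wavelength; last index fastest).
#'
#' @param cube Numeric 3-d array.
#' @param prefix Path prefix; writes `<prefix>.json` and `<prefix>.bin`.
#' @param wavelength Wavelength grid.
#' @return Prefix (write) or a list `cube`, `wavelength` (read).
#' @export
write_spectral_cube <- function(cube, prefix,
                                wavelength = hsei_wavelengths()) {
  stopifnot(length(dim(cube)) == 3, dim(cube)[3] == length(wavelength))
  d <- dim(cube)
  header <- list(format = "hsei_cube", version = 1L, shape = d,
                 order = "row,col,wavelength (wavelength fastest)",
                 dtype = "float64le", wavelength = wavelength)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- aperm(cube, c(3, 2, 1)) # wavelength fastest, then col, then row
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(flat), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_spectral_cube
#' @export
read_spectral_cube <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
  if (!identical(header$format, "hsei_cube")) {
    stop("not an hsei cube: ", prefix, call. = FALSE)
  }
  d <- as.integer(header$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  cube <- aperm(array(flat, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  list(cube = cube, wavelength = as.numeric(header$wavelength))
}

#' Write and read an 8-bit RGB image as PNG
#'
#' @param image h x w x 3 array on the 0--255 scale.
#' @param path PNG path.
#' @return Path (write) or an h x w x 3 array in 0--255 (read).
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}
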