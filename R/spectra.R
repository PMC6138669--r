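#' Visible wavelength grid
#'
#' The shared sampling grid for every spectral quantity in the package:
#' reflectance spectra, illuminants, camera sensitivities and observer
#' colour-matching functions all live on the same vector of wavelengths.
#' The default covers the visible range 380--780 nm at 5 nm steps
#' (81 samples).
#'
#' @param from,to Range endpoints in nanometres.
#' @param by Step in nanometres.
#' @return Numeric vector of wavelengths (nm).
#' @examples
#' length(hsei_wavelengths()) # 81
#' @export
hsei_wavelengths <- function(from = 380, to = 780, by = 5) {
  stopifnot(from < to, by > 0)
  seq(from, to, by = by)
}

#' Spectra collections as matrices and tibbles
#'
#' Internally a collection of reflectance spectra is a numeric matrix with
#' one row per spectrum and one column per wavelength (an attribute stores
#' the grid). `spectra_matrix()` validates and tags such a matrix;
#' `spectra_to_tibble()` / `tibble_to_spectra()` convert to and from the
#' long tibble form (`id`, `wavelength_nm`, `reflectance`) used for
#' plotting and CSV export.
#'
#' @param x Numeric matrix (spectra in rows) or a single numeric vector.
#' @param wavelength Wavelength grid; defaults to [hsei_wavelengths()].
#' @param ids Optional character ids, one per spectrum.
#' @return `spectra_matrix()` returns the tagged matrix; `spectra_to_tibble()`
#'   a long tibble; `tibble_to_spectra()` a tagged matrix.
#' @export
spectra_matrix <- function(x, wavelength = hsei_wavelengths(), ids = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) != length(wavelength)) {
    stop("spectra have ", ncol(x), " samples but the wavelength grid has ",
         length(wavelength), call. = FALSE)
  }
  if (!is.null(ids)) rownames(x) <- ids
  attr(x, "wavelength") <- wavelength
  class(x) <- c("hsei_spectra", "matrix", "array")
  x
}

#' @rdname spectra_matrix
#' @export
spectra_to_tibble <- function(x) {
  wl <- spectra_grid(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(x)))
  tibble::tibble(
    id = rep(ids, each = length(wl)),
    wavelength_nm = rep(wl, times = nrow(x)),
    reflectance = as.vector(t(unclass(x)))
  )
}

#' @rdname spectra_matrix
#' @param tbl Long tibble with columns `id`, `wavelength_nm`, `reflectance`.
#' @export
tibble_to_spectra <- function(tbl) {
  stopifnot(all(c("id", "wavelength_nm", "reflectance") %in% names(tbl)))
  wide <- tidyr::pivot_wider(tbl, names_from = "wavelength_nm",
                             values_from = "reflectance")
  m <- as.matrix(wide[setdiff(names(wide), "id")])
  spectra_matrix(m, wavelength = as.numeric(colnames(m)), ids = wide$id)
}

spectra_grid <- function(x) {
  wl <- attr(x, "wavelength")
  if (is.null(wl)) wl <- hsei_wavelengths()
  wl
}

check_same_grid <- function(a, b, what = "curves") {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9)) {
    stop("wavelength grid mismatch between ", what, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hsei_spectra <- function(x, ...) {
  wl <- spectra_grid(x)
  cat(sprintf("<hsei_spectra> %d spectra, %d wavelengths (%g-%g nm)\n",
              nrow(x), length(wl), min(wl), max(wl)))
  invisible(x)
}

#' Read and write spectra tables as CSV
#'
#' The on-disk convention for spectral tables (colour checkers, spectral
#' libraries, exported ROI spectra) is a wide CSV: a `wavelength_nm` column
#' followed by one column per spectrum.
#'
#' @param x A spectra matrix from [spectra_matrix()].
#' @param path File path.
#' @return `read_spectra_csv()` returns a spectra matrix;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  wl <- spectra_grid(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("patch_%03d", seq_len(nrow(x)))
  out <- tibble::as_tibble(t(unclass(x)), .name_repair = "minimal")
  names(out) <- ids
  out <- dplyr::bind_cols(tibble::tibble(wavelength_nm = wl), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("wavelength_nm" %in% names(tbl))
  wl <- tbl$wavelength_nm
  m <- t(as.matrix(tbl[setdiff(names(tbl), "wavelength_nm")]))
  spectra_matrix(m, wavelength = wl, ids = rownames(m))
}

#' Plot a collection of reflectance spectra
#'
#' @param object A spectra matrix.
#' @param ... Unused.
#' @return A ggplot object (reflectance vs wavelength, one line per spectrum).
#' @method autoplot hsei_spectra
#' @export
autoplot.hsei_spectra <- function(object, ...) {
  spectra_to_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavelength_nm, .data$reflectance,
                                 colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}
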