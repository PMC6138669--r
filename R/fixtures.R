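# Smooth spectral component family shared by all fixtures. Three fixed
# Gaussian-bump shapes (overall lightness, blue-red tilt, a narrow
# green-band feature near the 530 nm haemoglobin absorption) keep every
# generated tissue spectrum inside a low-dimensional smooth subspace, which
# is what makes PCA reduction of the library effective.
fixture_components <- function(wavelength = hsei_wavelengths()) {
  g <- function(mu, s) exp(-0.5 * ((wavelength - mu) / s)^2)
  comps <- cbind(
    lightness = g(550, 140),
    tilt = g(660, 70) - g(450, 70),
    green_band = g(530, 25)
  )
  sweep(comps, 2, sqrt(colSums(comps^2)), "/")
}

stage_sets <- list(
  white_light = c("normal", "dysplasia", "dysplasia_ECA", "ECA"),
  lugol = c("normal", "dysplasia", "dysplasia_ECA", "ECA"),
  nbi = c("normal", "IPCL_IV", "IPCL_V1_HGD", "IPCL_V1_SCC", "IPCL_V3_SCC")
)

# Mean reflectivity level per stage and modality. White light: reflectivity
# decreases with severity (lesions are darker red than surrounding mucosa).
# Lugol: normal mucosa stains dark brown, neoplastic areas stay unstained
# and bright, so reflectivity increases with severity. NBI: capillary
# proliferation darkens the mucosa with increasing IPCL grade.
stage_levels <- list(
  white_light = c(normal = 0.72, dysplasia = 0.58, dysplasia_ECA = 0.45,
                  ECA = 0.32),
  lugol = c(normal = 0.18, dysplasia = 0.32, dysplasia_ECA = 0.46,
            ECA = 0.62),
  nbi = c(normal = 0.62, IPCL_IV = 0.52, IPCL_V1_HGD = 0.43,
          IPCL_V1_SCC = 0.34, IPCL_V3_SCC = 0.25)
)

check_stage_modality <- function(stage, modality) {
  modality <- match.arg(modality, names(stage_sets))
  if (!stage %in% stage_sets[[modality]]) {
    stop("unknown stage '", stage, "' for modality '", modality, "'",
         call. = FALSE)
  }
  modality
}

# Deterministic mean spectrum for a stage/modality (no noise): level plus
# fixed shape terms from the component family, so all class means share a
# 3-dimensional affine span.
stage_mean_spectrum <- function(stage, modality,
                                wavelength = hsei_wavelengths()) {
  modality <- check_stage_modality(stage, modality)
  comps <- fixture_components(wavelength)
  level <- stage_levels[[modality]][[stage]]
  sev <- match(stage, stage_sets[[modality]]) - 1
  mu <- level +
    0.35 * comps[, "lightness"] +
    0.30 * comps[, "tilt"] -
    0.10 * sev * comps[, "green_band"]
  pmin(pmax(mu, 0.02), 0.98)
}

#' Synthetic tissue reflectance spectra
#'
#' Draws reflectance spectra for an oesophageal tissue class under a given
#' imaging modality. Class means follow the expected clinical ordering:
#' under white light, mean reflectivity strictly decreases from normal
#' mucosa through dysplasia and dysplasia-ECA to ECA; under Lugol staining
#' it strictly increases with severity (unstained neoplasia is bright);
#' under NBI the four IPCL grades are separated in mean, darkening with
#' grade. Each draw adds i.i.d. Gaussian noise (sd `noise`) to the smooth
#' class mean and clips to \[0, 1\].
#'
#' @param stage Stage label; one of `normal`, `dysplasia`, `dysplasia_ECA`,
#'   `ECA` (white light / Lugol) or `normal`, `IPCL_IV`, `IPCL_V1_HGD`,
#'   `IPCL_V1_SCC`, `IPCL_V3_SCC` (NBI).
#' @param modality `"white_light"`, `"lugol"` or `"nbi"`.
#' @param seed Integer seed (draws are reproducible).
#' @param n Number of spectra to draw.
#' @param noise Per-sample noise standard deviation.
#' @param wavelength Wavelength grid.
#' @return A spectra matrix with `n` rows.
#' @examples
#' s <- make_tissue_spectrum("ECA", "white_light", seed = 1)
#' @export
make_tissue_spectrum <- function(stage, modality = "white_light", seed = 1,
                                 n = 1, noise = 0.01,
                                 wavelength = hsei_wavelengths()) {
  mu <- stage_mean_spectrum(stage, modality, wavelength)
  with_seed(seed, {
    eps <- matrix(rnorm(n * length(wavelength), sd = noise), nrow = n)
    m <- sweep(eps, 2, mu, "+")
    m <- pmin(pmax(m, 0), 1)
    spectra_matrix(m, wavelength = wavelength,
                   ids = sprintf("%s_%s_%03d", modality, stage, seq_len(n)))
  })
}

#' Synthetic colour-checker spectra
#'
#' Generates a set of smooth, mutually distinct reflectance spectra to play
#' the role of a physical colour checker in calibration. With
#' `rank = NULL` each patch is an independent mixture of random Gaussian
#' bumps (a rich, high-rank set); with integer `rank` the patches are drawn
#' from the package's fixed `rank`-dimensional smooth component family,
#' which is the configuration used to validate exact spectral recovery.
#'
#' @param n_patches Number of patches (>= 4; calibration itself needs
#'   >= 20).
#' @param seed Integer seed.
#' @param rank `NULL` for free smooth spectra, or an integer 1--3 to draw
#'   from the fixed component family.
#' @param wavelength Wavelength grid.
#' @return A spectra matrix with `n_patches` rows named `patch_###`.
#' @examples
#' checker <- make_color_checker(30, seed = 1)
#' @export
make_color_checker <- function(n_patches = 30, seed = 1, rank = NULL,
                               wavelength = hsei_wavelengths()) {
  if (n_patches < 4) {
    stop("n_patches must be >= 4: fewer patches leave the calibration ",
         "regression underdetermined", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(rank)) {
      m <- t(vapply(seq_len(n_patches), function(i) {
        nb <- sample(2:4, 1)
        mu <- runif(nb, 400, 760)
        s <- runif(nb, 30, 120)
        a <- runif(nb, -0.35, 0.45)
        sp <- 0.45 + colSums(a * t(vapply(seq_len(nb), function(b) {
          exp(-0.5 * ((wavelength - mu[b]) / s[b])^2)
        }, numeric(length(wavelength)))))
        pmin(pmax(sp, 0.02), 0.98)
      }, numeric(length(wavelength))))
    } else {
      stopifnot(rank >= 1, rank <= 3)
      comps <- fixture_components(wavelength)[, seq_len(rank), drop = FALSE]
      # coefficient box scaled so patches stay strictly inside [0, 1]:
      # clipping would break the exact low-rank structure
      lim <- 0.45 / (rank * apply(abs(comps), 2, max))
      coefs <- sapply(seq_len(rank), function(j) {
        runif(n_patches, -lim[j], lim[j])
      })
      m <- 0.5 + coefs %*% t(comps)
    }
    spectra_matrix(m, wavelength = wavelength,
                   ids = sprintf("patch_%03d", seq_len(n_patches)))
  })
}

#' Synthetic endoscopic scene with ground-truth spectra
#'
#' Builds a per-pixel reflectance field for one tissue stage and modality:
#' the stage's mean spectrum, modulated by a smooth multiplicative
#' illumination/texture field plus small per-pixel noise. For NBI scenes of
#' non-normal stages, curvilinear IPCL-like vessel strokes (seeded
#' self-avoiding random walks, width 1--3 px) are stamped with darker
#' spectra and recorded in `vessel_mask`.
#'
#' @param stage,modality As in [make_tissue_spectrum()].
#' @param size Image size, `c(rows, cols)`, each >= 64.
#' @param seed Integer seed.
#' @param n_strokes Range of vessel stroke counts for NBI scenes.
#' @param wavelength Wavelength grid.
#' @return An `hsei_scene`: list with `reflectance` (h x w x n_wl array in
#'   \[0,1\]), `vessel_mask` (logical h x w), `stage`, `modality`,
#'   `wavelength`, `seed`.
#' @examples
#' sc <- make_endoscopic_scene("IPCL_V3_SCC", "nbi", size = c(64, 64), seed = 7)
#' sum(sc$vessel_mask) > 0
#' @export
make_endoscopic_scene <- function(stage, modality = "nbi",
                                  size = c(128, 128), seed = 1,
                                  n_strokes = c(5, 20),
                                  wavelength = hsei_wavelengths()) {
  stopifnot(length(size) == 2, all(size >= 64))
  modality <- check_stage_modality(stage, modality)
  h <- size[1]; w <- size[2]
  mu <- stage_mean_spectrum(stage, modality, wavelength)
  with_seed(seed, {
    # smooth multiplicative field in about [0.9, 1.1]
    ph <- runif(4, 0, 2 * pi)
    fr <- runif(4, 1, 3)
    rows <- seq_len(h) / h; cols <- seq_len(w) / w
    field <- 1 +
      0.05 * outer(sin(2 * pi * fr[1] * rows + ph[1]),
                   cos(2 * pi * fr[2] * cols + ph[2])) +
      0.05 * outer(cos(2 * pi * fr[3] * rows + ph[3]),
                   sin(2 * pi * fr[4] * cols + ph[4]))
    gain <- field + matrix(rnorm(h * w, sd = 0.01), h, w)

    mask <- matrix(FALSE, h, w)
    if (modality == "nbi" && stage != "normal") {
      ns <- sample(seq(n_strokes[1], n_strokes[2]), 1)
      for (s in seq_len(ns)) {
        mask <- mask | vessel_stroke(h, w)
      }
    }
    refl <- array(0, dim = c(h, w, length(wavelength)))
    vessel_gain <- 0.35 # vessels darker than mucosa, same texture field
    g <- ifelse(mask, vessel_gain * gain, gain)
    for (k in seq_along(wavelength)) {
      refl[, , k] <- pmin(pmax(g * mu[k], 0), 1)
    }
    structure(
      list(reflectance = refl, vessel_mask = mask, stage = stage,
           modality = modality, wavelength = wavelength, seed = seed),
      class = "hsei_scene"
    )
  })
}

# One self-avoiding random-walk stroke, stamped at width 1-3 px.
vessel_stroke <- function(h, w) {
  mask <- matrix(FALSE, h, w)
  len <- sample(30:80, 1)
  width <- sample(1:3, 1)
  r <- sample(seq(8, h - 8), 1)
  c <- sample(seq(8, w - 8), 1)
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  d <- sample(8, 1)
  visited <- matrix(FALSE, h, w)
  path <- matrix(NA_integer_, len, 2)
  npath <- 0
  for (step in seq_len(len)) {
    visited[r, c] <- TRUE
    npath <- npath + 1
    path[npath, ] <- c(r, c)
    # momentum: prefer continuing straight, small turns allowed
    cand <- ((d - 1) + c(0, -1, 1, -2, 2)) %% 8 + 1
    moved <- FALSE
    for (dd in cand) {
      nr <- r + dirs[dd, 1]; nc <- c + dirs[dd, 2]
      if (nr >= 2 && nr <= h - 1 && nc >= 2 && nc <= w - 1 &&
          !visited[nr, nc]) {
        r <- nr; c <- nc; d <- dd; moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  path <- path[seq_len(npath), , drop = FALSE]
  off <- seq(0, width - 1) - (width - 1) %/% 2
  for (i in seq_len(nrow(path))) {
    rr <- pmin(pmax(path[i, 1] + off, 1), h)
    cc <- pmin(pmax(path[i, 2] + off, 1), w)
    mask[rr, cc] <- TRUE
  }
  mask
}

#' @export
print.hsei_scene <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hsei_scene> %dx%d px, stage=%s, modality=%s, %d vessel px\n",
              d[1], d[2], x$stage, x$modality, sum(x$vessel_mask)))
  invisible(x)
}
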