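#' Convert an RGB image to 8-bit grayscale
#'
#' Standard luma weights 0.299 R + 0.587 G + 0.114 B applied to 8-bit
#' channels, rounded to the nearest integer.
#'
#' @param image h x w x 3 array on the 0--255 scale.
#' @return h x w integer-valued matrix in 0--255.
#' @export
to_grayscale <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  d <- dim(image)
  ch <- function(k) matrix(image[, , k], d[1], d[2])
  round_half_up(0.299 * ch(1) + 0.587 * ch(2) + 0.114 * ch(3))
}

# round() in R rounds half to even; the 8-bit image chain uses the
# conventional round-half-up so 127.5 -> 128.
round_half_up <- function(x) floor(x + 0.5)

#' Min-max contrast enhancement
#'
#' Linear rescaling of a grayscale image so the minimum maps to 0 and the
#' maximum to 255: `(pixel - min) / (max - min) * 255`, rounded half-up at
#' the 8-bit boundary (internal math in floating point).
#'
#' @param gray Grayscale matrix.
#' @return Rescaled matrix of integers in 0--255.
#' @examples
#' enhance_contrast(matrix(c(10, 20, 30, 10), 2)) # 0, 128, 255
#' @export
enhance_contrast <- function(gray) {
  stopifnot(is.matrix(gray))
  lo <- min(gray); hi <- max(gray)
  if (hi == lo) {
    stop("constant image: zero dynamic range, contrast rescaling undefined",
         call. = FALSE)
  }
  round_half_up((gray - lo) / (hi - lo) * 255)
}

#' Otsu threshold and binarization
#'
#' `otsu_threshold()` picks the 8-bit threshold maximising the
#' between-class variance of the grayscale histogram (first maximum on
#' ties); `binarize()` returns the logical foreground mask
#' `gray > threshold`.
#'
#' @param gray Grayscale matrix with values in 0--255.
#' @return `otsu_threshold()` an integer in 0--254; `binarize()` a logical
#'   matrix with the chosen threshold attached as attribute `threshold`.
#' @export
otsu_threshold <- function(gray) {
  h <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  n <- sum(h)
  p <- h / n
  levels <- 0:255
  omega <- cumsum(p)                # class-0 probability up to t
  mu <- cumsum(p * levels)          # partial first moment
  mu_t <- mu[256]
  t_all <- 1:255                    # candidate thresholds 0..254
  w0 <- omega[t_all]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_all][valid])^2 /
    (w0[valid] * w1[valid])
  which.max(sigma_b) - 1L
}

#' @rdname otsu_threshold
#' @export
binarize <- function(gray) {
  t <- otsu_threshold(gray)
  out <- gray > t
  attr(out, "threshold") <- t
  out
}

#' Logical complement of a binary image
#'
#' IPCL vessels are dark in NBI frames, so after binarization the mask is
#' inverted to make the vessels foreground before thinning.
#'
#' @param binary Logical matrix.
#' @return Logical matrix, the complement.
#' @export
invert_binary <- function(binary) {
  stopifnot(is.logical(binary))
  out <- !binary
  attr(out, "threshold") <- NULL
  out
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# One parallel Guo-Hall subiteration (iter = 0 or 1), vectorized over the
# whole image via shifted copies of the 8-neighbourhood.
guo_hall_subiter <- function(img, iter) {
  p2 <- shift_mat(img, 1, 0)   # N  (neighbour above)
  p3 <- shift_mat(img, 1, -1)  # NE
  p4 <- shift_mat(img, 0, -1)  # E
  p5 <- shift_mat(img, -1, -1) # SE
  p6 <- shift_mat(img, -1, 0)  # S
  p7 <- shift_mat(img, -1, 1)  # SW
  p8 <- shift_mat(img, 0, 1)   # W
  p9 <- shift_mat(img, 1, 1)   # NW
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
    (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(N1, N2)
  m <- if (iter == 0) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
  del <- img & (C == 1) & (N >= 2) & (N <= 3) & !m
  img & !del
}

#' Guo--Hall thinning
#'
#' Parallel two-subiteration Guo--Hall skeletonization, iterated until no
#' pixel changes. The skeleton is a subset of the input foreground and
#' preserves the 8-connectivity of each component; 1-pixel-wide curves are
#' fixed points.
#'
#' @param binary Logical matrix (foreground = TRUE).
#' @param max_iter Safety cap on full iterations.
#' @return Logical matrix, the skeleton.
#' @export
guo_hall_thin <- function(binary, max_iter = 1000L) {
  stopifnot(is.logical(binary))
  img <- binary
  attr(img, "threshold") <- NULL
  for (i in seq_len(max_iter)) {
    prev <- img
    img <- guo_hall_subiter(img, 0L)
    img <- guo_hall_subiter(img, 1L)
    if (identical(img, prev)) break
  }
  img
}

#' Label and circle skeleton components
#'
#' 8-connected component labelling of a binary skeleton (via a pixel
#' adjacency graph), dropping components smaller than `min_size`, with a
#' per-component bounding box and an outline overlay for visual QC.
#'
#' @param skeleton Logical matrix.
#' @param min_size Minimum component size in pixels (smaller components are
#'   treated as salt noise and dropped).
#' @return A list: `components` tibble (`component`, `n_pixels`,
#'   `row_min`, `row_max`, `col_min`, `col_max`), `labels` integer matrix
#'   (0 = background), `pixels` tibble (`component`, `row`, `col`), and
#'   `overlay` (h x w x 3 array: skeleton white, bounding boxes red).
#' @export
circle_regions <- function(skeleton, min_size = 5L) {
  stopifnot(is.logical(skeleton))
  h <- nrow(skeleton); w <- ncol(skeleton)
  idx <- which(skeleton)
  labels <- matrix(0L, h, w)
  comp_tbl <- tibble::tibble(component = integer(), n_pixels = integer(),
                             row_min = integer(), row_max = integer(),
                             col_min = integer(), col_max = integer())
  pix_tbl <- tibble::tibble(component = integer(), row = integer(),
                            col = integer())
  if (length(idx) > 0) {
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    # edges between 8-neighbouring foreground pixels
    offs <- cbind(dr = c(0L, 1L, 1L, 1L), dc = c(1L, -1L, 0L, 1L))
    edges <- NULL
    pos <- matrix(0L, h, w); pos[idx] <- seq_along(idx)
    for (o in seq_len(nrow(offs))) {
      nr <- rows + offs[o, 1]; nc <- cols + offs[o, 2]
      ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
      ok[ok] <- skeleton[cbind(nr[ok], nc[ok])]
      if (any(ok)) {
        edges <- rbind(edges, cbind(pos[cbind(rows[ok], cols[ok])],
                                    pos[cbind(nr[ok], nc[ok])]))
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    sizes <- tabulate(memb)
    keep <- which(sizes >= min_size)
    relab <- integer(length(sizes))
    # stable ids: order components by first (row-major) pixel occurrence
    if (length(keep) > 0) {
      first_px <- vapply(keep, function(cmp) {
        min((cols[memb == cmp] - 1L) * h + rows[memb == cmp])
      }, integer(1))
      keep <- keep[order(first_px)]
      relab[keep] <- seq_along(keep)
      lab_px <- relab[memb]
      sel <- lab_px > 0
      labels[idx[sel]] <- lab_px[sel]
      pix_tbl <- tibble::tibble(component = lab_px[sel], row = rows[sel],
                                col = cols[sel]) |>
        dplyr::arrange(.data$component, .data$row, .data$col)
      comp_tbl <- pix_tbl |>
        dplyr::group_by(.data$component) |>
        dplyr::summarise(n_pixels = dplyr::n(),
                         row_min = min(.data$row), row_max = max(.data$row),
                         col_min = min(.data$col), col_max = max(.data$col),
                         .groups = "drop")
    }
  }
  overlay <- array(0, dim = c(h, w, 3))
  overlay[, , 1][skeleton] <- 255
  overlay[, , 2][skeleton] <- 255
  overlay[, , 3][skeleton] <- 255
  if (nrow(comp_tbl) > 0) {
    for (i in seq_len(nrow(comp_tbl))) {
      r0 <- max(1, comp_tbl$row_min[i] - 1); r1 <- min(h, comp_tbl$row_max[i] + 1)
      c0 <- max(1, comp_tbl$col_min[i] - 1); c1 <- min(w, comp_tbl$col_max[i] + 1)
      overlay[r0, c0:c1, 1] <- 255; overlay[r1, c0:c1, 1] <- 255
      overlay[r0:r1, c0, 1] <- 255; overlay[r0:r1, c1, 1] <- 255
      overlay[r0, c0:c1, 2:3] <- 0; overlay[r1, c0:c1, 2:3] <- 0
      overlay[r0:r1, c0, 2:3] <- 0; overlay[r0:r1, c1, 2:3] <- 0
    }
  }
  list(components = comp_tbl, labels = labels, pixels = pix_tbl,
       overlay = overlay)
}

#' Record IPCL skeleton pixel coordinates
#'
#' Samples up to `budget` coordinates from the thinned skeleton (the
#' conventional experiment records 1000 points per frame). When the
#' skeleton has at least `budget` pixels, a uniform seeded sample without
#' replacement of exactly `budget` points is taken; otherwise all pixels
#' are returned with a warning. Coordinates are exported in row-major
#' sorted order, 0-based.
#'
#' @param skeleton Logical matrix from [guo_hall_thin()].
#' @param budget Maximum number of coordinates.
#' @param seed Integer seed for the sample.
#' @return A tibble of class `hsei_coords` with columns `row`, `col`
#'   (0-based) and attributes `image_dim`, `budget`, `seed`,
#'   `n_skeleton_pixels`.
#' @export
record_coordinates <- function(skeleton, budget = 1000L, seed = 1L) {
  stopifnot(is.logical(skeleton), budget >= 1)
  idx <- which(skeleton)
  if (length(idx) == 0) {
    stop("empty skeleton: no IPCL coordinates to record", call. = FALSE)
  }
  if (length(idx) >= budget) {
    idx <- with_seed(seed, sample(idx, budget))
  } else {
    warning("skeleton has only ", length(idx), " pixels, below the budget ",
            budget, "; recording all of them", call. = FALSE)
  }
  h <- nrow(skeleton)
  rows <- ((idx - 1L) %% h)          # 0-based
  cols <- ((idx - 1L) %/% h)
  ord <- order(rows, cols)
  out <- tibble::tibble(row = rows[ord], col = cols[ord])
  attr(out, "image_dim") <- dim(skeleton)
  attr(out, "budget") <- as.integer(budget)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_skeleton_pixels") <- sum(skeleton)
  class(out) <- c("hsei_coords", class(out))
  out
}

#' Run the full IPCL segmentation pipeline
#'
#' Chains the automatic circling steps on an NBI frame: grayscale, min-max
#' contrast enhancement, Otsu binarization, inversion (vessels are dark),
#' Guo--Hall thinning, component circling and coordinate recording.
#'
#' @param image h x w x 3 RGB array (0--255).
#' @param min_size Component size filter.
#' @param budget,seed Passed to [record_coordinates()].
#' @param keep_stages Keep every intermediate image for audit.
#' @return A list: `skeleton`, `regions` (from [circle_regions()]),
#'   `coordinates` (an `hsei_coords` tibble), `threshold`, and (if
#'   requested) `stages`.
#' @export
segment_ipcl <- function(image, min_size = 5L, budget = 1000L, seed = 1L,
                         keep_stages = FALSE) {
  gray <- to_grayscale(image)
  enh <- enhance_contrast(gray)
  bin <- binarize(enh)
  inv <- invert_binary(bin)
  skel <- guo_hall_thin(inv)
  regions <- circle_regions(skel, min_size = min_size)
  kept <- regions$labels > 0
  coords <- record_coordinates(kept, budget = budget, seed = seed)
  out <- list(skeleton = skel, regions = regions, coordinates = coords,
              threshold = attr(bin, "threshold"))
  if (keep_stages) {
    out$stages <- list(gray = gray, enhanced = enh, binary = bin,
                       inverted = inv)
  }
  out
}
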