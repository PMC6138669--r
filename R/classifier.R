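# Severity-descending test order for stage assignment: most severe first,
# so a point in an overlap is assigned the more severe stage.
ipcl_stage_order <- c("IPCL_V3_SCC", "IPCL_V1_SCC", "IPCL_V1_HGD", "IPCL_IV")

#' Fit the principal-component score chart
#'
#' Mean-centred PCA of a set of reflectance spectra; every spectrum is
#' mapped to its first and second principal-component scores (FPC, SPC),
#' the axes of the staging chart. Component signs are fixed
#' deterministically as in [fit_spectral_basis()].
#'
#' @param spectra Spectra matrix (>= 3 spectra).
#' @param labels Optional stage label per spectrum, carried into the score
#'   tibble.
#' @return An `hsei_score_chart`: `basis` (an `hsei_basis` with k = 2) and
#'   `scores`, a tibble with columns `fpc`, `spc` (and `stage` if labels
#'   were given).
#' @export
fit_score_chart <- function(spectra, labels = NULL) {
  m <- unclass(spectra)
  if (is.vector(m)) m <- matrix(m, nrow = 1)
  if (nrow(m) < 3) {
    stop("need >= 3 spectra to fit a score chart", call. = FALSE)
  }
  basis <- fit_spectral_basis(spectra, k = 2)
  sc <- basis_project(basis, spectra)
  scores <- tibble::tibble(fpc = sc[, 1], spc = sc[, 2])
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(scores))
    scores$stage <- labels
  }
  structure(list(basis = basis, scores = scores),
            class = "hsei_score_chart")
}

#' Project spectra onto a fitted score chart
#'
#' @param chart An `hsei_score_chart`.
#' @param spectra Spectra matrix.
#' @return Tibble with columns `fpc`, `spc`.
#' @export
score_spectra <- function(chart, spectra) {
  sc <- basis_project(chart$basis, spectra)
  tibble::tibble(fpc = sc[, 1], spc = sc[, 2])
}

#' @export
print.hsei_score_chart <- function(x, ...) {
  cat(sprintf("<hsei_score_chart> %d scored spectra\n", nrow(x$scores)))
  invisible(x)
}

#' @method tidy hsei_score_chart
#' @export
tidy.hsei_score_chart <- function(x, ...) x$scores

#' Patient-level principal-component score
#'
#' Averages the per-pixel scores of a patient's sampled spectra into one
#' (FPC, SPC) testing point. Because projection is linear this equals the
#' score of the mean spectrum; both are computed and checked to agree.
#'
#' @param spectra Spectra matrix of the patient's sampled pixels (>= 1).
#' @param chart Fitted `hsei_score_chart`.
#' @return One-row tibble `fpc`, `spc` with attribute `n_spectra`.
#' @export
patient_score <- function(spectra, chart) {
  m <- unclass(spectra)
  if (is.vector(m)) m <- matrix(m, nrow = 1)
  if (nrow(m) == 0) stop("no spectra to score", call. = FALSE)
  per_pixel <- score_spectra(chart, spectra)
  mean_of_scores <- colMeans(as.matrix(per_pixel))
  score_of_mean <- basis_project(
    chart$basis, spectra_matrix(colMeans(m),
                                wavelength = spectra_grid(spectra)))
  stopifnot(max(abs(mean_of_scores - as.numeric(score_of_mean))) < 1e-8)
  out <- tibble::tibble(fpc = mean_of_scores[1], spc = mean_of_scores[2])
  attr(out, "n_spectra") <- nrow(m)
  out
}

#' Triangle area in score space
#'
#' Area of the triangle A, B, C as half the absolute determinant of the
#' edge vectors AB and AC.
#'
#' @param A,B,C Length-2 numeric points `(fpc, spc)`.
#' @return Non-negative area (score units squared).
#' @examples
#' triangle_area(c(0, 0), c(1, 0), c(0, 1)) # 0.5
#' @export
triangle_area <- function(A, B, C) {
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C)
  stopifnot(length(A) == 2, length(B) == 2, length(C) == 2,
            all(is.finite(c(A, B, C))))
  0.5 * abs((B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2]))
}

#' Triangle region for one stage
#'
#' @param A,B,C Vertices `(fpc, spc)`.
#' @param stage Stage label.
#' @return An `hsei_triangle`: list with `vertices` (3 x 2 matrix), `stage`,
#'   `area`.
#' @export
triangle_region <- function(A, B, C, stage = NA_character_) {
  area <- triangle_area(A, B, C)
  if (area <= 0) {
    stop("degenerate triangle (area 0) for stage ", stage, call. = FALSE)
  }
  v <- rbind(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C))
  colnames(v) <- c("fpc", "spc")
  structure(list(vertices = v, stage = stage, area = area),
            class = "hsei_triangle")
}

#' Area-sum point-in-triangle test
#'
#' A testing point X lies inside (or on the edge of) triangle ABC exactly
#' when the three sub-triangle areas XAB, XBC and XAC sum to the area of
#' ABC; strictly outside, the sum strictly exceeds it. Floating-point
#' equality is replaced by a relative tolerance: the point is inside when
#' `XAB + XBC + XAC <= area(ABC) * (1 + rel_tol)`.
#'
#' @param X Length-2 point `(fpc, spc)`.
#' @param triangle An `hsei_triangle` (non-degenerate).
#' @param rel_tol Relative tolerance on the area equality.
#' @return Logical.
#' @export
point_in_triangle <- function(X, triangle, rel_tol = 1e-9) {
  stopifnot(inherits(triangle, "hsei_triangle"))
  v <- triangle$vertices
  if (triangle$area <= 0) stop("degenerate triangle", call. = FALSE)
  s <- triangle_area(X, v[1, ], v[2, ]) +
    triangle_area(X, v[2, ], v[3, ]) +
    triangle_area(X, v[1, ], v[3, ])
  s <= triangle$area * (1 + rel_tol)
}

#' Maximum-area triangle of a score cloud
#'
#' Finds the three input points forming the triangle of maximum area.
#' Since the maximising vertices must be extreme points, the search is
#' restricted to the convex hull and is exhaustive over hull triples; ties
#' are broken lexicographically on the sorted vertex coordinates, making
#' the result deterministic.
#'
#' @param points n x 2 matrix or tibble with columns `fpc`, `spc`
#'   (>= 3 non-collinear points).
#' @param stage Stage label for the resulting region.
#' @return An `hsei_triangle`.
#' @export
max_area_triangle <- function(points, stage = NA_character_) {
  m <- score_points_matrix(points)
  if (nrow(m) < 3) stop("need >= 3 points", call. = FALSE)
  hull <- unique(grDevices::chull(m[, 1], m[, 2]))
  hm <- m[hull, , drop = FALSE]
  nh <- nrow(hm)
  if (nh < 3) stop("all points are collinear: no triangle exists",
                   call. = FALSE)
  best_area <- -1
  best_key <- NULL
  best <- NULL
  for (i in 1:(nh - 2)) for (j in (i + 1):(nh - 1)) for (k in (j + 1):nh) {
    a <- triangle_area(hm[i, ], hm[j, ], hm[k, ])
    vm <- rbind(hm[i, ], hm[j, ], hm[k, ])
    key <- as.vector(t(vm[order(vm[, 1], vm[, 2]), ]))
    if (a > best_area + 1e-12 ||
        (abs(a - best_area) <= 1e-12 && !is.null(best_key) &&
         lex_less(key, best_key))) {
      best_area <- max(a, best_area)
      best_key <- key
      best <- vm
    }
  }
  if (best_area <= 0) stop("all points are collinear: no triangle exists",
                           call. = FALSE)
  triangle_region(best[1, ], best[2, ], best[3, ], stage = stage)
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(abs(d) > 1e-12)
  length(nz) > 0 && d[nz[1]] < 0
}

score_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("fpc", "spc") %in% names(points)))
    m <- cbind(points$fpc, points$spc)
  } else {
    m <- as.matrix(points)
  }
  stopifnot(ncol(m) == 2, all(is.finite(m)))
  m
}

#' Fit per-stage triangle regions
#'
#' For each stage in the labelled score cloud, fits the maximum-area
#' triangle of that stage's points (or accepts manually chosen vertices).
#'
#' @param scores Tibble with columns `fpc`, `spc`, `stage`.
#' @param stages Stage test order; defaults to severity-descending
#'   IPCL order (V3 SCC, V1 SCC, V1 HGD, IV).
#' @param manual Optional named list `stage -> 3 x 2 vertex matrix`
#'   overriding the automatic search for those stages.
#' @return An `hsei_regions`: named list of `hsei_triangle` in test order.
#' @export
fit_triangle_regions <- function(scores, stages = ipcl_stage_order,
                                 manual = NULL) {
  stopifnot(all(c("fpc", "spc", "stage") %in% names(scores)))
  regions <- lapply(stages, function(st) {
    if (!is.null(manual[[st]])) {
      v <- manual[[st]]
      return(triangle_region(v[1, ], v[2, ], v[3, ], stage = st))
    }
    pts <- dplyr::filter(scores, .data$stage == st)
    if (nrow(pts) < 3) {
      stop("stage ", st, " has fewer than 3 score points", call. = FALSE)
    }
    max_area_triangle(pts, stage = st)
  })
  names(regions) <- stages
  structure(regions, class = "hsei_regions")
}

#' @export
print.hsei_regions <- function(x, ...) {
  cat("<hsei_regions>\n")
  for (r in x) {
    cat(sprintf("  %-12s area %.4f\n", r$stage, r$area))
  }
  invisible(x)
}

#' @method tidy hsei_regions
#' @export
tidy.hsei_regions <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(r) {
    tibble::tibble(stage = r$stage, vertex = c("A", "B", "C"),
                   fpc = r$vertices[, 1], spc = r$vertices[, 2])
  })
}

#' Assign a stage to testing points
#'
#' Tests each point against the triangle regions in severity-descending
#' order (IPCL-V3 SCC, IPCL-V1 SCC, IPCL-V1 HGD, IPCL-IV); the first
#' region containing the point wins. A point contained in no region is
#' `"undetected"`.
#'
#' @param points Tibble/matrix of testing points (`fpc`, `spc`), one row
#'   per patient.
#' @param regions An `hsei_regions` set.
#' @param rel_tol Tolerance for [point_in_triangle()].
#' @return Tibble: `fpc`, `spc`, `stage` (label or `"undetected"`), plus
#'   one logical membership column `in_<stage>` per region.
#' @export
classify_point <- function(points, regions, rel_tol = 1e-9) {
  if (length(regions) == 0) stop("empty region set", call. = FALSE)
  m <- score_points_matrix(points)
  memb <- vapply(regions, function(r) {
    apply(m, 1, function(p) point_in_triangle(p, r, rel_tol = rel_tol))
  }, logical(nrow(m)))
  memb <- matrix(memb, nrow = nrow(m),
                 dimnames = list(NULL, names(regions)))
  stage <- apply(memb, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) "undetected" else names(regions)[hit[1]]
  })
  out <- tibble::tibble(fpc = m[, 1], spc = m[, 2], stage = stage)
  memb_tbl <- tibble::as_tibble(memb, .name_repair = "minimal")
  names(memb_tbl) <- paste0("in_", names(regions))
  dplyr::bind_cols(out, memb_tbl)
}

#' Per-stage sensitivity and specificity
#'
#' One-vs-rest diagnostic metrics: for each stage, sensitivity
#' TP / (TP + FN) and specificity TN / (TN + FP). An `"undetected"`
#' prediction counts as negative for every stage.
#'
#' @param predictions Character vector of predicted stages (or a tibble
#'   from [classify_point()], whose `stage` column is used).
#' @param truth Character vector of true stage labels, same length.
#' @param stages Stages to report; defaults to the IPCL test order.
#' @return Tibble: `stage`, `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_stages <- function(predictions, truth, stages = ipcl_stage_order) {
  if (is.data.frame(predictions)) predictions <- predictions$stage
  if (length(predictions) != length(truth)) {
    stop("predictions and truth have different lengths (",
         length(predictions), " vs ", length(truth), ")", call. = FALSE)
  }
  bad <- setdiff(unique(truth), stages)
  if (length(bad) > 0) {
    stop("unknown truth labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(stages, function(st) {
    tp <- sum(predictions == st & truth == st)
    fn <- sum(predictions != st & truth == st)
    fp <- sum(predictions == st & truth != st)
    tn <- sum(predictions != st & truth != st)
    tibble::tibble(
      stage = st, tp = tp, fn = fn, tn = tn, fp = fp,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  })
}

#' Plot a score chart with optional triangle regions
#'
#' @param object An `hsei_score_chart`.
#' @param regions Optional `hsei_regions` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsei_score_chart
#' @export
autoplot.hsei_score_chart <- function(object, regions = NULL, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$fpc, .data$spc))
  if ("stage" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage))
  } else {
    p <- p + ggplot2::geom_point()
  }
  if (!is.null(regions)) {
    tri <- tidy(regions)
    p <- p + ggplot2::geom_polygon(
      data = tri,
      ggplot2::aes(.data$fpc, .data$spc, group = .data$stage,
                   colour = .data$stage),
      fill = NA, linewidth = 0.4)
  }
  p + ggplot2::labs(x = "first principal-component score (FPC)",
                    y = "second principal-component score (SPC)") +
    ggplot2::theme_minimal()
}
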