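make_disjoint_regions <- function() {
  tri <- function(cx, cy, s = 1) {
    rbind(c(cx - s, cy - s / 2), c(cx + s, cy - s / 2), c(cx, cy + s))
  }
  centers <- list(IPCL_V3_SCC = c(0, 0), IPCL_V1_SCC = c(6, 0),
                  IPCL_V1_HGD = c(0, 6), IPCL_IV = c(6, 6))
  out <- lapply(names(centers), function(st) {
    v <- tri(centers[[st]][1], centers[[st]][2])
    triangle_region(v[1, ], v[2, ], v[3, ], stage = st)
  })
  names(out) <- names(centers)
  structure(out, class = "hsei_regions")
}

test_that("score chart separates constructed clusters and is well-formed", {
  wl <- hsei_wavelengths()
  bump1 <- exp(-0.5 * ((wl - 450) / 50)^2)
  bump2 <- exp(-0.5 * ((wl - 650) / 50)^2)
  set.seed(4)
  a <- t(replicate(20, 0.3 + 0.4 * bump1 + rnorm(81, sd = 0.005)))
  b <- t(replicate(20, 0.3 + 0.4 * bump2 + rnorm(81, sd = 0.005)))
  chart <- fit_score_chart(spectra_matrix(rbind(a, b)),
                           labels = rep(c("a", "b"), each = 20))
  sc <- chart$scores
  gap <- min(sc$fpc[sc$stage == levels(factor(sc$stage))[1]]) -
    max(sc$fpc[sc$stage != levels(factor(sc$stage))[1]])
  expect_true(abs(mean(sc$fpc[sc$stage == "a"]) -
                    mean(sc$fpc[sc$stage == "b"])) >
                4 * (sd(sc$fpc[sc$stage == "a"]) + sd(sc$fpc[sc$stage == "b"])))
  # score covariance diagonal with decreasing variance
  cv <- stats::cov(cbind(sc$fpc, sc$spc))
  expect_lt(abs(cv[1, 2]), 1e-10)
  expect_gte(cv[1, 1], cv[2, 2])
})

test_that("rank-1 spectra have zero second-component scores", {
  wl <- hsei_wavelengths()
  base <- 0.4 + 0.3 * exp(-0.5 * ((wl - 550) / 80)^2)
  lib <- spectra_matrix(t(sapply(seq(0.5, 1.5, length.out = 10),
                                 function(a) a * base)))
  chart <- fit_score_chart(lib)
  expect_lt(max(abs(chart$scores$spc)), 1e-8)
  expect_error(fit_score_chart(lib[1:2, ]), ">= 3 spectra")
})

test_that("triangle area halves the absolute cross product", {
  expect_equal(triangle_area(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  expect_equal(triangle_area(c(0, 0), c(1, 1), c(2, 2)), 0)
  set.seed(17)
  for (i in 1:200) {
    A <- runif(2, -5, 5); B <- runif(2, -5, 5); C <- runif(2, -5, 5)
    expect_equal(triangle_area(A, B, C), shoelace_area(A, B, C),
                 tolerance = 1e-12)
  }
})

test_that("area-sum membership matches the barycentric oracle", {
  A <- c(-1, -0.5); B <- c(2, 0); C <- c(0.5, 1.8)
  T <- triangle_region(A, B, C, "x")
  centroid <- (A + B + C) / 3
  expect_true(point_in_triangle(centroid, T))
  expect_true(point_in_triangle(A, T)) # boundary (vertex) counts as inside
  expect_true(point_in_triangle((A + B) / 2, T)) # edge midpoint
  set.seed(23)
  # random points land in the 1e-9 relative tolerance band with
  # probability ~0, so decisions must agree everywhere
  agree <- vapply(1:10000, function(i) {
    X <- runif(2, -2, 3)
    identical(point_in_triangle(X, T), barycentric_inside(X, A, B, C))
  }, logical(1))
  expect_true(all(agree))
  expect_error(triangle_region(c(0, 0), c(1, 1), c(2, 2), "x"), "degenerate")
})

test_that("maximum-area triangle equals exhaustive search", {
  m3 <- rbind(c(0, 0), c(2, 0), c(1, 1.5))
  t3 <- max_area_triangle(m3, "s")
  expect_equal(sort(unname(t3$vertices[, 1])), sort(m3[, 1]))
  set.seed(29)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    m <- cbind(runif(n, -3, 3), runif(n, -3, 3))
    tri <- max_area_triangle(m)
    expect_equal(tri$area, brute_max_triangle_area(m), tolerance = 1e-12)
  }
  # square corners plus interior points: max area is half the square
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2),
              cbind(runif(10, 0.3, 1.7), runif(10, 0.3, 1.7)))
  expect_equal(max_area_triangle(sq)$area, 2)
  expect_error(max_area_triangle(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("stage assignment tests regions in severity order", {
  regs <- make_disjoint_regions()
  pred <- classify_point(tibble::tibble(fpc = c(0, 6, 0, 6, 20),
                                        spc = c(0, 0, 6, 6, 20)), regs)
  expect_equal(pred$stage, c("IPCL_V3_SCC", "IPCL_V1_SCC", "IPCL_V1_HGD",
                             "IPCL_IV", "undetected"))
  # overlapping V3 and V1 triangles: severity-first order wins
  v <- rbind(c(-1, -1), c(1, -1), c(0, 1))
  over <- structure(list(
    IPCL_V3_SCC = triangle_region(v[1, ], v[2, ], v[3, ], "IPCL_V3_SCC"),
    IPCL_V1_SCC = triangle_region(v[1, ] + 0.1, v[2, ] + 0.1, v[3, ] + 0.1,
                                  "IPCL_V1_SCC")
  ), class = "hsei_regions")
  both <- classify_point(tibble::tibble(fpc = 0.05, spc = 0), over)
  expect_true(both$in_IPCL_V3_SCC && both$in_IPCL_V1_SCC)
  expect_equal(both$stage, "IPCL_V3_SCC")
  expect_error(classify_point(tibble::tibble(fpc = 0, spc = 0),
                              structure(list(), class = "hsei_regions")),
               "empty region set")
})

test_that("patient score averages per-pixel scores linearly", {
  lib <- make_color_checker(30, seed = 14)
  chart <- fit_score_chart(lib)
  one <- patient_score(lib[1, , drop = FALSE], chart)
  expect_equal(as.numeric(one), as.numeric(chart$scores[1, c("fpc", "spc")]),
               tolerance = 1e-10)
  many <- make_tissue_spectrum("ECA", "white_light", seed = 2, n = 50)
  ps <- patient_score(many, chart)
  manual <- colMeans(as.matrix(score_spectra(chart, many)))
  expect_equal(as.numeric(ps), as.numeric(manual), tolerance = 1e-10)
  expect_equal(attr(ps, "n_spectra"), 50)
})

test_that("sensitivity and specificity match a hand-built confusion table", {
  truth <- rep(c("IPCL_V3_SCC", "IPCL_V1_SCC", "IPCL_V1_HGD", "IPCL_IV"),
               each = 5)
  perfect <- evaluate_stages(truth, truth)
  expect_true(all(perfect$sensitivity == 1) && all(perfect$specificity == 1))
  none <- evaluate_stages(rep("undetected", 20), truth)
  expect_true(all(none$sensitivity == 0) && all(none$specificity == 1))
  # hand-built 20-case table: V3 gets 3/5 right, 1 -> V1_SCC, 1 undetected;
  # V1_SCC perfect; V1_HGD 2/5 right, 3 -> IV; IV 4/5 right, 1 -> V3
  pred <- c("IPCL_V3_SCC", "IPCL_V3_SCC", "IPCL_V3_SCC", "IPCL_V1_SCC",
            "undetected",
            rep("IPCL_V1_SCC", 5),
            "IPCL_V1_HGD", "IPCL_V1_HGD", "IPCL_IV", "IPCL_IV", "IPCL_IV",
            rep("IPCL_IV", 4), "IPCL_V3_SCC")
  ev <- evaluate_stages(pred, truth)
  expect_equal(ev$sensitivity, c(3 / 5, 5 / 5, 2 / 5, 4 / 5))
  expect_equal(ev$specificity, c(14 / 15, 14 / 15, 15 / 15, 12 / 15))
  expect_error(evaluate_stages(pred[1:10], truth), "different lengths")
  expect_error(evaluate_stages(pred, rep("bogus", 20)), "unknown truth")
})

test_that("disjoint class triangles give perfect recovery; overlap degrades it", {
  regs <- make_disjoint_regions()
  set.seed(101)
  n <- 200
  pts <- NULL; truth <- NULL
  for (st in names(regs)) {
    v <- regs[[st]]$vertices
    pts <- rbind(pts, runif_triangle(n, v[1, ], v[2, ], v[3, ]))
    truth <- c(truth, rep(st, n))
  }
  pred <- classify_point(pts, regs)
  ev <- evaluate_stages(pred, truth)
  expect_true(all(ev$sensitivity == 1))
  expect_true(all(ev$specificity == 1))

  # V1_SCC triangle shifted to overlap a fraction f of the V3 triangle's
  # area: V3 keeps priority, so V1_SCC points falling in the overlap are
  # absorbed by V3 and V1_SCC sensitivity drops by about f
  base <- rbind(c(0, 0), c(2, 0), c(0, 2))
  f <- 0.25
  # scaled copy of the triangle occupying area fraction f, inside base
  s <- sqrt(f)
  v3 <- triangle_region(c(0, 0), c(2 * s, 0), c(0, 2 * s), "IPCL_V3_SCC")
  v1 <- triangle_region(base[1, ], base[2, ], base[3, ], "IPCL_V1_SCC")
  regs2 <- structure(list(IPCL_V3_SCC = v3, IPCL_V1_SCC = v1),
                     class = "hsei_regions")
  set.seed(55)
  m <- 500
  pts2 <- runif_triangle(m, base[1, ], base[2, ], base[3, ])
  pred2 <- classify_point(pts2, regs2)
  sens <- mean(pred2$stage == "IPCL_V1_SCC")
  expect_lt(abs((1 - sens) - f), 3 * sqrt(f * (1 - f) / m) + 0.01)
})
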