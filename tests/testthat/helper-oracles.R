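# Independent oracles used across the suite. Each is deliberately written
# by a different route than the package implementation it checks.

# Single Guo-Hall subiteration as a plain per-pixel loop over a padded
# image, reading the 8-neighbourhood explicitly (reference for the
# vectorised implementation).
ref_guo_hall_subiter <- function(img, iter) {
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  out <- img
  for (i in 2:(h + 1)) {
    for (j in 2:(w + 1)) {
      if (!pad[i, j]) next
      p2 <- pad[i - 1, j];     p3 <- pad[i - 1, j + 1]
      p4 <- pad[i, j + 1];     p5 <- pad[i + 1, j + 1]
      p6 <- pad[i + 1, j];     p7 <- pad[i + 1, j - 1]
      p8 <- pad[i, j - 1];     p9 <- pad[i - 1, j - 1]
      C <- sum((!p2 && (p3 || p4)), (!p4 && (p5 || p6)),
               (!p6 && (p7 || p8)), (!p8 && (p9 || p2)))
      N1 <- sum((p9 || p2), (p3 || p4), (p5 || p6), (p7 || p8))
      N2 <- sum((p2 || p3), (p4 || p5), (p6 || p7), (p8 || p9))
      N <- min(N1, N2)
      m <- if (iter == 0) ((p6 || p7 || !p9) && p8) else
        ((p2 || p3 || !p5) && p4)
      if (C == 1 && N >= 2 && N <= 3 && !m) out[i - 1, j - 1] <- FALSE
    }
  }
  out
}

ref_guo_hall_thin <- function(img, max_iter = 500) {
  for (it in seq_len(max_iter)) {
    prev <- img
    img <- ref_guo_hall_subiter(img, 0)
    img <- ref_guo_hall_subiter(img, 1)
    if (identical(img, prev)) break
  }
  img
}

# BFS flood-fill 8-connected labelling (oracle for the graph-based
# labelling in circle_regions).
bfs_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      px <- queue[1]; queue <- queue[-1]
      r <- ((px - 1L) %% h) + 1L
      c <- ((px - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        nr <- r + dr; nc <- c + dc
        if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
            mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- cur
          queue <- c(queue, (nc - 1L) * h + nr)
        }
      }
    }
  }
  lab
}

# Brute-force Otsu: direct class means and probabilities per threshold.
brute_otsu <- function(gray) {
  g <- as.integer(gray)
  best_t <- 0L; best_s <- -Inf
  for (t in 0:254) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(g)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# Shoelace triangle area.
shoelace_area <- function(A, B, C) {
  0.5 * abs(A[1] * (B[2] - C[2]) + B[1] * (C[2] - A[2]) +
              C[1] * (A[2] - B[2]))
}

# Sign-based barycentric point-in-triangle (boundary inclusive).
barycentric_inside <- function(X, A, B, C) {
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  d1 <- cross(A, B, X); d2 <- cross(B, C, X); d3 <- cross(C, A, X)
  has_neg <- (d1 < 0) || (d2 < 0) || (d3 < 0)
  has_pos <- (d1 > 0) || (d2 > 0) || (d3 > 0)
  !(has_neg && has_pos)
}

# Exhaustive O(n^3) maximum triangle area.
brute_max_triangle_area <- function(m) {
  n <- nrow(m)
  best <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    best <- max(best, shoelace_area(m[i, ], m[j, ], m[k, ]))
  }
  best
}

# Chebyshev-1 dilation used for the 1-px recovery tolerance.
dilate3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc]
  }
  out
}

# Random thick blob (dilated random walk), for thinning property tests.
random_blob <- function(h, w, len = 40) {
  mask <- matrix(FALSE, h, w)
  r <- sample(5:(h - 4), 1); c <- sample(5:(w - 4), 1)
  for (i in seq_len(len)) {
    mask[r, c] <- TRUE
    r <- min(max(r + sample(-1:1, 1), 3), h - 2)
    c <- min(max(c + sample(-1:1, 1), 3), w - 2)
  }
  dilate3(mask)
}

# Uniform sample inside a triangle.
runif_triangle <- function(n, A, B, C) {
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  x <- (1 - r1) * A[1] + r1 * (1 - r2) * B[1] + r1 * r2 * C[1]
  y <- (1 - r1) * A[2] + r1 * (1 - r2) * B[2] + r1 * r2 * C[2]
  cbind(x, y)
}
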