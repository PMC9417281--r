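# Shared fixture builders. Everything is generated in code at test time.

# Hexagon-majority / rod-minority ensemble matching the well-dispersed
# distinct-shape scenario (38 + 5 particles, sizes 64.5 +- 3.0 and
# 49.0 +- 1.1 nm, aspect ratios ~1.03 and ~1.76).
distinct_class_spec <- function(n_hex = 38L, n_rod = 5L) {
  tibble::tibble(
    label = c("hex", "rod"), n = c(n_hex, n_rod),
    shape_family = c("hexagon", "rod"),
    size_mean = c(64.5, 49.0), size_sd = c(3.0, 1.1),
    ar_mean = c(1.03, 1.76), ar_sd = c(0.02, 0.05)
  )
}

distinct_scene <- function(seed = 1L, n_hex = 38L, n_rod = 5L,
                           dim = c(512L, 512L)) {
  make_ensemble(distinct_class_spec(n_hex, n_rod), dim = dim,
                pixel_size = 2, noise_sd = 0.02, seed = seed)
}

# Two-component Gaussian mixture in log-Hu feature space, anchored to the
# ellipse manifold at the continuum scenario's aspect-ratio scale
# (AR 1.12 +- 0.05 and 1.25 +- 0.08, weights 0.57 / 0.43).
loghu_component <- function(ar, ar_sd, rho = 0.9) {
  h2 <- ((ar - 1 / ar) / (4 * pi))^2
  h1 <- (ar + 1 / ar) / (4 * pi)
  s2 <- (2 / log(10)) * (1 + 1 / ar^2) / (ar - 1 / ar) * ar_sd
  s1 <- (1 / log(10)) * (1 - 1 / ar^2) / (ar + 1 / ar) * ar_sd
  list(mu = c(log10(h1), log10(h2)),
       S = matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2L))
}

# stratified draw (exact 0.57 / 0.43 composition) of n feature vectors;
# returns features X, truth labels z
gen_loghu_mixture <- function(seed, n = 500L, w1 = 0.57,
                              ar1 = 1.12, sd1 = 0.05,
                              ar2 = 1.25, sd2 = 0.08) {
  p1 <- loghu_component(ar1, sd1)
  p2 <- loghu_component(ar2, sd2)
  withr::with_seed(as.integer(seed), {
    n1 <- round(w1 * n)
    z <- sample(c(rep(1L, n1), rep(2L, n - n1)))
    E <- matrix(stats::rnorm(2L * n), n, 2L)
    X <- matrix(NA_real_, n, 2L)
    X[z == 1L, ] <- sweep(E[z == 1L, , drop = FALSE] %*% chol(p1$S), 2L,
                          p1$mu, "+")
    X[z == 2L, ] <- sweep(E[z == 2L, , drop = FALSE] %*% chol(p2$S), 2L,
                          p2$mu, "+")
  })
  colnames(X) <- c("logH1", "logH2")
  list(X = X, z = z)
}

# per-point aspect ratio from log-Hu features via the eigenvalue map
ar_from_features <- function(X) {
  H1 <- 10^X[, 1L]; H2 <- 10^X[, 2L]
  s <- sqrt(pmin(H2, H1^2))
  sqrt((H1 + s) / (H1 - s))
}

# random convex polygon: convex hull of k uniform points, as a contour
random_convex_polygon <- function(k = 12L) {
  repeat {
    pts <- cbind(stats::runif(k), stats::runif(k))
    h <- grDevices::chull(pts)
    if (length(h) >= 4L) return(as_contour(pts[h, ]))
  }
}

# regular-polygon approximation of an ellipse with semi-axes a, b
ellipse_contour <- function(a, b, n = 512L, theta = 0, center = c(0, 0)) {
  t <- 2 * pi * (0:(n - 1L)) / n
  xy <- cbind(a * cos(t), b * sin(t))
  out <- as_contour(xy)
  if (theta != 0) out <- rotate_contour(out, theta, center = c(0, 0))
  shift_contour(out, center[1L], center[2L])
}

# brute-force sliding overlap used as the FFT-scan oracle
brute_overlap_scan <- function(ring, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  idx <- which(ring > 0, arr.ind = TRUE)
  nring <- nrow(idx)
  for (dy in 0:(nr - 1L)) for (dx in 0:(nc - 1L)) {
    ry <- ((idx[, 1L] - 1L + dy) %% nr) + 1L
    rx <- ((idx[, 2L] - 1L + dx) %% nc) + 1L
    out[dy + 1L, dx + 1L] <- sum(mask[cbind(ry, rx)]) / nring
  }
  out
}

expect_all_close <- function(x, y, tol) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max deviation %.3g < %.3g", max(abs(x - y)),
                              tol))
}
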