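test_that("polygon moments match closed-form oracles", {
  sq <- as_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  m <- polygon_moments(sq)
  expect_equal(m$raw[["m00"]], 1)
  expect_equal(unname(m$centroid), c(0.5, 0.5))
  expect_equal(m$central[["mu20"]], 1 / 12)
  expect_equal(m$central[["mu02"]], 1 / 12)
  expect_equal(m$central[["mu11"]], 0)
  expect_equal(m$raw[["m30"]], 1 / 4) # int x^3 over the unit square

  # translation invariance of central moments is exact
  m2 <- polygon_moments(shift_contour(sq, 17, -3))
  expect_equal(m2$central, m$central, tolerance = 1e-9)

  # 512-gon disk: mu20 = pi r^4 / 4 = m00^2 / (4 pi)
  disk <- ellipse_contour(3, 3, n = 512L)
  md <- polygon_moments(disk)
  expect_equal(md$central[["mu20"]], md$raw[["m00"]]^2 / (4 * pi),
               tolerance = 1e-3)
  expect_error(polygon_moments(as_contour(rbind(c(0, 0), c(1, 0),
                                                c(2, 0.0001)))), NA)
})

test_that("Hu features match analytic circle and ellipse values", {
  disk <- ellipse_contour(1 / sqrt(pi), 1 / sqrt(pi), n = 512L)
  h <- hu_features(disk)
  expect_equal(h$H[["H1"]], 1 / (2 * pi), tolerance = 1e-3)
  expect_lt(h$H[["H2"]], 1e-8)

  b <- sqrt(1 / (2 * pi)); a <- 2 * b # unit-area 2:1 ellipse
  el <- ellipse_contour(a, b, n = 512L)
  he <- hu_features(el)
  expect_equal(he$H[["H1"]], 5 / (8 * pi), tolerance = 1e-3)
  expect_equal(he$H[["H2"]], 9 / (64 * pi^2), tolerance = 1e-3)
  expect_true(all(is.finite(hu_features(disk)$logH)))
  # higher invariants available behind the n_hu flag
  h7 <- hu_features(el, n_hu = 7L)
  expect_length(h7$H, 7L)
  expect_lt(abs(h7$H[["H3"]]), 1e-8) # ellipse has no third-order asymmetry
})

test_that("shape eigenvalues follow the unit-area semi-axis convention", {
  eig <- shape_eigenvalues(1 / (2 * pi), 0)
  expect_equal(unname(eig), rep(1 / sqrt(pi), 2L), tolerance = 1e-12)
  e2 <- shape_eigenvalues(5 / (8 * pi), 9 / (64 * pi^2))
  expect_equal(e2[["eta1"]], sqrt(2 / pi), tolerance = 1e-12) # a = 2b
  expect_equal(e2[["eta1"]] / e2[["eta2"]], 2, tolerance = 1e-12)
  expect_gte(e2[["eta1"]], e2[["eta2"]])
  expect_error(shape_eigenvalues(0.1, 0.1^2 * 1.1), "realizable")
  expect_error(shape_eigenvalues(-1, 0), "H1")
})

test_that("effective diameter follows the equal-area-circle convention", {
  expect_equal(effective_diameter(pi, 1), 2)
  expect_equal(effective_diameter(1e4, 0.57), 2 * sqrt(1e4 / pi) * 0.57,
               tolerance = 1e-12)
  expect_equal(effective_diameter(1e4, 0.57), 64.3, tolerance = 1e-2)
  expect_error(effective_diameter(-1), "area")
})

test_that("a rendered hexagon recovers its generator truth diameter", {
  hx <- shift_contour(make_contour("hexagon", size = 64.5 / 2), 64, 64)
  sc <- render_scene(list(hx), dim = c(128L, 128L), noise_sd = 0)
  d <- shape_descriptors(extract_contours(binarize(sc$image), 50),
                         pixel_size = 2)
  expect_equal(d$d_eff_nm, 64.5, tolerance = 0.5 / 64.5)
})

test_that("principal orientation tracks rotations and flags isotropy", {
  b <- sqrt(1 / (2 * pi)); a <- 2 * b
  el <- ellipse_contour(a, b, n = 512L)
  expect_equal(as.numeric(principal_orientation(el)), 0, tolerance = 1e-6)
  ro <- principal_orientation(rotate_contour(el, 0.7))
  expect_equal(as.numeric(ro), 0.7, tolerance = 1e-3)
  circ <- principal_orientation(ellipse_contour(1, 1, n = 512L))
  expect_true(attr(circ, "isotropic"))
  expect_identical(as.numeric(circ), 0)
})

test_that("Hu features are invariant under similarity transforms", {
  withr::with_seed(41, {
    worst <- 0
    for (i in 1:50) {
      p <- resample_contour(random_convex_polygon(12L), 256L)
      h0 <- hu_features(p)$H
      q <- shift_contour(
        scale_contour(rotate_contour(p, stats::runif(1, 0, 2 * pi)),
                      stats::runif(1, 0.2, 5)),
        stats::runif(1, -50, 50), stats::runif(1, -50, 50))
      h1 <- hu_features(q)$H
      worst <- max(worst, abs(h1[["H1"]] / h0[["H1"]] - 1))
      if (h0[["H2"]] > 1e-8) {
        worst <- max(worst, abs(h1[["H2"]] / h0[["H2"]] - 1))
      }
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("ellipses land on the general-ellipse curve with exact ratios", {
  for (r in c(1, 1.25, 1.5, 1.75, 2, 3)) {
    b <- sqrt(1 / (pi * r)); a <- r * b
    h <- hu_features(ellipse_contour(a, b, n = 512L))$H
    eig <- shape_eigenvalues(h[["H1"]], h[["H2"]])
    expect_equal(eig[["eta1"]] / eig[["eta2"]], r, tolerance = 1e-2)
    expect_equal(eig[["eta2"]], 1 / (pi * eig[["eta1"]]), tolerance = 1e-2)
  }
})

test_that("descriptor aspect ratio is monotone in generator aspect ratio", {
  ars <- c(1.05, 1.2, 1.4, 1.8, 2.5)
  got <- vapply(ars, function(r) {
    shape_descriptors(make_contour("hexagon", size = 30,
                                   aspect_ratio = r))$aspect_ratio
  }, numeric(1L))
  expect_true(all(diff(got) > 0))
})

test_that("descriptor error shrinks monotonically with vertex count", {
  errs <- vapply(c(32L, 64L, 128L, 256L), function(n) {
    h <- hu_features(ellipse_contour(1 / sqrt(pi), 1 / sqrt(pi), n = n),
                     min_points = n) # do not auto-resample upwards
    abs(h$H[["H1"]] - 1 / (2 * pi))
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
})

test_that("the descriptor table is tidy and complete", {
  cs <- list(make_contour("hexagon", size = 30),
             make_contour("rod", size = 20, aspect_ratio = 1.8))
  d <- shape_descriptors(cs, pixel_size = 0.5)
  expect_s3_class(d, "tbl_df")
  expect_identical(nrow(d), 2L)
  expect_true(all(c("particle_id", "area_px", "d_eff_nm", "H1", "H2",
                    "logH1", "logH2", "eta1", "eta2", "aspect_ratio",
                    "orientation", "isotropic", "centroid_x",
                    "centroid_y") %in% names(d)))
  expect_true(all(d$eta1 >= d$eta2))
})
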