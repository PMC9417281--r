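test_that("the DoG sign mask is empty on constant images", {
  bd <- compute_binary_dog(gray_image(matrix(0.7, 64L, 64L)), sigma = 2)
  expect_false(any(bd$mask))
  expect_true(all(abs(bd$dog) < 1e-9))
})

test_that("the DoG response changes sign exactly at a dark step edge", {
  img <- matrix(0.8, 64L, 96L)
  img[, 37:60] <- 0.2 # dark band: the "particle" side
  bd <- compute_binary_dog(gray_image(img), sigma = 2, magnitude_floor = 0)
  # particle-sign response starts at the edge, on the dark side only
  expect_true(all(bd$mask[20:44, 37:42]))
  expect_false(any(bd$mask[20:44, 30:36]))
  on_cols <- which(apply(bd$mask[20:44, , drop = FALSE], 2L, any))
  expect_identical(min(on_cols), 37L) # transition localized at the edge
  expect_error(compute_binary_dog(gray_image(img), sigma = -1), "sigma")
  expect_error(compute_binary_dog(gray_image(img), sigma = 1, ratio = 0.5),
               "ratio")
})

test_that("the mask traces a rendered particle's boundary", {
  disk <- shift_contour(make_contour("ellipse", size = 32), 64, 64)
  sc <- render_scene(list(disk), dim = c(128L, 128L), noise_sd = 0)
  bd <- compute_binary_dog(sc$image, sigma = 1.6)
  # truth boundary samples all fall within the 1-px fitting tolerance of
  # the mask (the sign transition sits within half a pixel of the edge)
  tol_mask <- EBImage::dilate(bd$mask * 1L, EBImage::makeBrush(3L, "box")) > 0
  pts <- resample_contour(disk, 200L)
  cov <- mean(tol_mask[cbind(round(pts[, 2L]), round(pts[, 1L]))])
  expect_gte(cov, 0.95)
})

test_that("contour averaging reproduces a hexagon from rotated copies", {
  hx <- make_contour("hexagon", size = 40)
  withr::with_seed(71, {
    copies <- lapply(stats::runif(12L, 0, 2 * pi), function(th) {
      rotate_contour(hx, th)
    })
  })
  tpl <- average_contour(copies, class_label = "hex")
  expect_identical(tpl$source_count, 12L)
  expect_equal(contour_area(tpl$contour), 1, tolerance = 1e-3)
  # compare to the canonical truth after the same normalization + alignment
  truth <- resample_contour(rotate_contour(
    normalize_contour(hx),
    -as.numeric(principal_orientation(hx)), center = c(0, 0)), 256L)
  z <- complex(real = tpl$contour[, 1L], imaginary = tpl$contour[, 2L])
  w <- complex(real = truth[, 1L], imaginary = truth[, 2L])
  corr <- stats::fft(stats::fft(z) * Conj(stats::fft(w)),
                     inverse = TRUE) / length(z)
  s <- which.max(Mod(corr))
  za <- c(z[s:length(z)], z[seq_len(s - 1L)]) * exp(-1i * Arg(corr[s]))
  expect_lt(max(Mod(za - w)), 1e-2)
})

test_that("averaging suppresses independent boundary noise", {
  hx <- make_contour("hexagon", size = 40)
  noisy <- lapply(1:50, function(i) {
    make_contour("hexagon", size = 40, radial_noise = 0.03, rng = 7000 + i,
                 convex_only = FALSE,
                 orientation = withr::with_seed(i, stats::runif(1, 0, pi)))
  })
  tpl <- average_contour(noisy, class_label = "hex")
  ref <- average_contour(list(hx))
  z <- complex(real = tpl$contour[, 1L], imaginary = tpl$contour[, 2L])
  w <- complex(real = ref$contour[, 1L], imaginary = ref$contour[, 2L])
  corr <- stats::fft(stats::fft(z) * Conj(stats::fft(w)),
                     inverse = TRUE) / length(z)
  s <- which.max(Mod(corr))
  za <- c(z[s:length(z)], z[seq_len(s - 1L)]) * exp(-1i * Arg(corr[s]))
  # mean radial error ~ noise / sqrt(N): 3% / sqrt(50) << 1%
  expect_lt(mean(Mod(za - w)) / mean(Mod(w)), 0.01)
})

test_that("single-contour averaging returns its smoothed resampling", {
  hx <- make_contour("hexagon", size = 25, orientation = 0.5)
  tpl <- average_contour(list(hx), M = 128L)
  expect_identical(nrow(tpl$contour), 128L)
  expect_equal(contour_area(tpl$contour), 1, tolerance = 1e-3)
  expect_identical(tpl$source_count, 1L)
  expect_error(average_contour(list()), "at least one")
})

test_that("template symmetry order is detected", {
  expect_identical(contour_symmetry_order(make_contour("hexagon", size = 20,
                                                       aspect_ratio = 1.02)),
                   6L)
  expect_identical(contour_symmetry_order(make_contour("rod", size = 20,
                                                       aspect_ratio = 1.8)),
                   2L)
  expect_identical(contour_symmetry_order(make_contour("rounded_cube",
                                                       size = 20)), 4L)
})

test_that("the FFT overlap scan equals brute force exactly", {
  withr::with_seed(73, {
    for (i in 1:5) {
      ring <- matrix(stats::runif(64 * 64) < 0.05, 64L, 64L)
      mask <- matrix(stats::runif(64 * 64) < 0.4, 64L, 64L)
      if (!any(ring)) ring[20, 20] <- TRUE
      fast <- fft_overlap_scan(ring, mask)
      slow <- brute_overlap_scan(ring, mask)
      expect_lt(max(abs(fast - slow)), 1e-9)
    }
  })
  # trivial cases
  solid <- matrix(TRUE, 32L, 32L)
  ring <- matrix(FALSE, 32L, 32L); ring[10:14, 10:14] <- TRUE
  expect_equal(max(fft_overlap_scan(ring, solid)), 1)
  expect_true(all(fft_overlap_scan(ring, matrix(FALSE, 32L, 32L)) == 0))
})

test_that("an isolated particle is fitted at its true pose", {
  hx <- shift_contour(make_contour("hexagon", size = 30, orientation = 0.4),
                      60, 70)
  sc <- render_scene(list(hx), dim = c(128L, 128L), noise_sd = 0.02,
                     seed = 3)
  bd <- compute_binary_dog(sc$image, sigma = 1.5)
  tpl <- average_contour(list(make_contour("hexagon", size = 30)),
                         class_label = "hex")
  f <- fit_templates(bd, tpl)
  expect_identical(nrow(f), 1L)
  expect_lt(sqrt((f$tx - 60)^2 + (f$ty - 70)^2), 1.5)
  expect_gte(f$score, 0.95)
  expect_gte(polygon_iou(f$contour[[1L]], hx), 0.8)
})

test_that("touching particles are separated into exactly two fits", {
  h1 <- shift_contour(make_contour("hexagon", size = 30), 48, 64)
  h2 <- shift_contour(make_contour("hexagon", size = 30,
                                   orientation = 0.5), 77.3, 64)
  sc <- render_scene(list(h1, h2), dim = c(128L, 160L), noise_sd = 0.02,
                     seed = 4, allow_overlap = TRUE)
  bd <- compute_binary_dog(sc$image, sigma = 1.5)
  tpl <- average_contour(list(make_contour("hexagon", size = 30)),
                         class_label = "hex")
  f <- fit_templates(bd, tpl)
  expect_identical(nrow(f), 2L)
  ious <- vapply(f$contour, function(fc) {
    max(polygon_iou(fc, h1), polygon_iou(fc, h2))
  }, numeric(1L))
  expect_true(all(ious >= 0.8))
})

test_that("a mismatched template finds nothing at a strict threshold", {
  withr::with_seed(74, {
    hexes <- lapply(1:3, function(i) {
      shift_contour(make_contour("hexagon", size = 28),
                    40 + (i - 1) * 45, 50)
    })
  })
  sc <- render_scene(hexes, dim = c(100L, 176L), noise_sd = 0.02, seed = 5)
  bd <- compute_binary_dog(sc$image, sigma = 1.4)
  rod <- average_contour(list(make_contour("rod", size = 28,
                                           aspect_ratio = 1.76)),
                         class_label = "rod")
  f <- fit_templates(bd, rod, score_min = 0.9)
  expect_identical(nrow(f), 0L)
})

test_that("image noise never improves the attained fit quality", {
  hx <- shift_contour(make_contour("hexagon", size = 30), 64, 64)
  tpl <- average_contour(list(make_contour("hexagon", size = 30)))
  scores <- vapply(c(0.01, 0.05, 0.1, 0.16), function(ns) {
    sc <- render_scene(list(hx), dim = c(128L, 128L), noise_sd = ns,
                       seed = 8)
    bd <- compute_binary_dog(sc$image, sigma = 1.5)
    f <- fit_templates(bd, tpl, score_min = 0.5)
    if (nrow(f) == 0L) 0 else mean(f$score)
  }, numeric(1L))
  expect_true(all(diff(scores) <= 0.01))
})

test_that("degenerate fitting inputs are rejected or benign", {
  tpl <- average_contour(list(make_contour("hexagon", size = 20)))
  expect_identical(nrow(fit_templates(matrix(FALSE, 64L, 64L), tpl,
                                      base_area_px = 300)), 0L)
  expect_error(fit_templates(matrix(TRUE, 64L, 64L), tpl,
                             base_area_px = 300, scales = c(-1, 1)),
               "degenerate")
})
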