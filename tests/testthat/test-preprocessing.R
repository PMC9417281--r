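test_that("denoising has the right fixed points and attenuation", {
  const <- gray_image(matrix(0.5, 64L, 64L))
  out <- denoise(const, "fourier_lowpass", cutoff = 0.2)
  expect_equal(out$pixels, const$pixels, tolerance = 1e-12)

  # checkerboard at Nyquist, cutoff below it: amplitude crushed > 100x
  chk <- outer(1:64, 1:64, function(i, j) 0.1 * (-1)^(i + j))
  img <- gray_image(0.5 + chk)
  den <- denoise(img, "fourier_lowpass", cutoff = 0.2)
  amp0 <- abs(stats::fft(img$pixels)[33, 33]) # Nyquist-Nyquist coefficient
  amp1 <- abs(stats::fft(den$pixels)[33, 33])
  expect_gt(amp0 / max(amp1, 1e-300), 100)
  # total intensity preserved (DC untouched)
  expect_equal(sum(den$pixels), sum(img$pixels), tolerance = 1e-3 * 0.1)

  expect_error(denoise(img, "fourier_lowpass", cutoff = 0.7), "Nyquist")
  expect_error(denoise(img, "gaussian", cutoff = -1), "cutoff")
})

test_that("denoising a noiseless scene leaves extraction unchanged", {
  sc <- make_ensemble(
    tibble::tibble(label = "hex", n = 6L, shape_family = "hexagon",
                   size_mean = 28, size_sd = 2, ar_mean = 1.05, ar_sd = 0.03),
    dim = c(256L, 256L), noise_sd = 0, seed = 12)
  raw <- extract_contours(binarize(sc$image), 50)
  den <- extract_contours(binarize(denoise(sc$image, "gaussian", 1)), 50)
  expect_length(den, length(raw))
  cen_r <- t(vapply(raw, contour_centroid, numeric(2L)))
  cen_d <- t(vapply(den, contour_centroid, numeric(2L)))
  expect_lt(max(abs(cen_r - cen_d)), 0.5)
})

test_that("binarization resolves polarity and fills internal structure", {
  disk <- shift_contour(make_contour("ellipse", size = 30), 40, 40)
  bf <- render_scene(list(disk), dim = c(80L, 80L), noise_sd = 0)
  mask <- binarize(bf$image)$mask
  expect_true(mask[40, 40])
  expect_false(mask[5, 5])

  # dark-field core-shell particle: one solid component, no interior holes
  cs <- render_scene(list(disk), dim = c(80L, 80L), modality = "dark_field",
                     core_shell = TRUE, noise_sd = 0.01, seed = 3)
  m2 <- binarize(cs$image)$mask
  lab <- EBImage::bwlabel(m2 * 1L)
  expect_identical(max(lab), 1L)
  filled <- EBImage::fillHull(m2 * 1L) > 0
  expect_identical(sum(filled), sum(m2)) # already hole-free

  # degenerate threshold flags and warns
  expect_warning(b <- binarize(gray_image(matrix(0.5, 10L, 10L))),
                 "all-foreground or all-background")
  expect_true(attr(b, "degenerate"))
})

test_that("otsu matches the exhaustive inter-class-variance maximizer", {
  withr::with_seed(17, {
    px <- c(stats::rnorm(3000, 0.3, 0.05), stats::rnorm(2000, 0.7, 0.05))
    img <- matrix(px[1:4900], 70L, 70L)
  })
  lv <- seq(min(img), max(img), length.out = 256L)
  bcv <- vapply(lv[-c(1L, 256L)], function(t) {
    g1 <- img[img <= t]; g2 <- img[img > t]
    length(g1) * length(g2) * (mean(g1) - mean(g2))^2
  }, numeric(1L))
  best <- lv[-c(1L, 256L)][which.max(bcv)]
  b <- binarize(gray_image(img), "otsu", fill_holes = FALSE)
  # recover the implied threshold as the gap between the two classes
  thr_est <- (max(img[b$mask]) + min(img[!b$mask])) / 2
  expect_lt(abs(thr_est - best), diff(range(img)) / 64)
})

test_that("contour extraction counts, excludes borders, measures area", {
  m <- matrix(FALSE, 120L, 120L)
  m[10:30, 10:30] <- TRUE
  m[60:80, 20:40] <- TRUE
  m[40:60, 70:90] <- TRUE
  expect_length(extract_contours(m, 20), 3L)
  m2 <- m; m2[1:15, 100:120] <- TRUE # touches the border
  cc <- extract_contours(m2, 20)
  expect_length(cc, 3L)

  disk <- shift_contour(make_contour("ellipse", size = 100), 64, 64)
  sc <- render_scene(list(disk), dim = c(128L, 128L), noise_sd = 0)
  dc <- extract_contours(binarize(sc$image), 50)
  expect_equal(contour_area(dc[[1L]]), pi * 50^2, tolerance = 0.02)

  expect_identical(extract_contours(matrix(FALSE, 10L, 10L)), list())
})

test_that("all extracted contours are CCW, including on mirrored images", {
  sc <- make_ensemble(
    tibble::tibble(label = "x", n = 4L, shape_family = "rod",
                   size_mean = 26, size_sd = 1, ar_mean = 1.6, ar_sd = 0.1),
    dim = c(200L, 200L), noise_sd = 0.01, seed = 14)
  cc <- extract_contours(binarize(sc$image), 50)
  expect_true(all(vapply(cc, function(ci) {
    nanoshape:::shoelace_area(ci) > 0
  }, logical(1L))))
  flipped <- gray_image(sc$image$pixels[, ncol(sc$image$pixels):1],
                        sc$image$pixel_size, sc$image$modality)
  cf <- extract_contours(binarize(flipped), 50)
  expect_length(cf, length(cc))
  expect_true(all(vapply(cf, function(ci) {
    nanoshape:::shoelace_area(ci) > 0
  }, logical(1L))))
})

test_that("triage partitions contours exhaustively and correctly", {
  hex <- make_contour("hexagon", size = 30)
  t <- seq(-acos(-0.9), acos(-0.9), length.out = 80L)
  right <- cbind(9 + 10 * cos(t), 10 * sin(t))
  dumb <- as_contour(rbind(right,
                           cbind(-right[, 1L], right[, 2L])[80:1, ]))
  speck <- scale_contour(make_contour("ellipse", size = 4), 1, 1)
  tri <- triage(list(hex, dumb, speck), solidity_min = 0.95,
                size_bounds = c(20, Inf))
  expect_length(tri$isolated, 1L)
  expect_length(tri$aggregated, 1L)
  expect_length(tri$rejected, 1L)
  expect_identical(length(tri$isolated) + length(tri$aggregated) +
                     length(tri$rejected), 3L)
  expect_lt(contour_solidity(dumb), 0.95) # the analytic discriminator
})
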