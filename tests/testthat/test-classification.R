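test_that("a single-component fit reduces to the closed-form MLE", {
  withr::with_seed(51, X <- matrix(stats::rnorm(200), 100L, 2L))
  m <- fit_gmm(X, 1L, seed = 1)
  expect_equal(as.numeric(m$means), colMeans(X), tolerance = 1e-8)
  expect_equal(m$covariances[[1L]], stats::cov(X) * 99 / 100,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m$weights, 1)
})

test_that("well-separated clusters yield an effectively hard classification", {
  withr::with_seed(52, {
    X <- rbind(matrix(stats::rnorm(300, 0, 1), ncol = 2L),
               matrix(stats::rnorm(200, 10, 1), ncol = 2L))
  })
  m <- fit_gmm(X, 2L, seed = 3)
  cl <- soft_assign(m, X)
  expect_gt(mean(apply(cl$responsibilities, 1L, max) > 0.99), 0.99)
  expect_equal(sum(cl$class_totals), nrow(X), tolerance = 1e-8)
  expect_true(all(abs(rowSums(cl$responsibilities) - 1) < 1e-10))
})

test_that("fits are bit-reproducible under a fixed seed", {
  withr::with_seed(53, X <- matrix(stats::rnorm(300), 150L, 2L))
  a <- fit_gmm(X, 3L, seed = 11)
  b <- fit_gmm(X, 3L, seed = 11)
  expect_identical(a$means, b$means)
  expect_identical(a$loglik, b$loglik)
})

test_that("EM log-likelihood is non-decreasing along every trace", {
  withr::with_seed(54, {
    for (i in 1:5) {
      X <- rbind(matrix(stats::rnorm(120, 0, 1), ncol = 2L),
                 matrix(stats::rnorm(120, 2.5, 1.3), ncol = 2L))
      m <- fit_gmm(X, 2L, seed = i, n_restarts = 2L)
      expect_true(all(diff(m$loglik_trace) > -1e-8 * abs(m$loglik)))
    }
  })
})

test_that("the fitted likelihood matches an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(55, {
    X <- rbind(matrix(stats::rnorm(200, 0, 1), ncol = 2L),
               matrix(stats::rnorm(200, 4, 1.5), ncol = 2L))
  })
  ours <- fit_gmm(X, 2L, seed = 2, n_restarts = 10L, tol = 1e-10)
  ref <- mclust::Mclust(X, G = 2L, modelNames = "VVV", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("class-count selection finds no structure in a single Gaussian", {
  withr::with_seed(56, X <- matrix(stats::rnorm(400), 200L, 2L))
  expect_identical(select_classes(X, K_max = 5L, seed = 7)$K, 1L)
  expect_identical(select_classes(X, K_max = 5L, criterion = "bic",
                                  seed = 7)$K, 1L)
  expect_identical(select_classes(X, K_max = 5L, criterion = "weight_prune",
                                  prune_weight = 0.25, seed = 7)$K, 1L)
})

test_that("the class count reduces to two for distinct shape families", {
  # descriptors straight from the generator (no rendering): 38 + 5
  withr::with_seed(57, {
    cs <- c(
      lapply(1:38, function(i) make_contour(
        "hexagon", size = stats::rnorm(1, 64.5, 3),
        aspect_ratio = sample_aspect_ratio(1, 1.03, 0.02),
        orientation = stats::runif(1, -pi / 2, pi / 2))),
      lapply(1:5, function(i) make_contour(
        "rod", size = stats::rnorm(1, 49, 1.1),
        aspect_ratio = sample_aspect_ratio(1, 1.76, 0.05),
        orientation = stats::runif(1, -pi / 2, pi / 2))))
  })
  d <- shape_descriptors(cs)
  cl <- classify_shapes(d, K_max = 5L, seed = 1)
  expect_identical(ncol(cl$responsibilities), 2L)
})

test_that("overlapping two-component structure is still detected by BIC", {
  hits <- vapply(1:10, function(s) {
    g <- gen_loghu_mixture(600 + s, n = 500L)
    select_classes(g$X, K_max = 4L, criterion = "bic", seed = s,
                   n_restarts = 3L)$K == 2L
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("soft assignment behaves correctly in limit and symmetric cases", {
  m <- structure(list(
    K = 2L, weights = c(0.5, 0.5),
    means = rbind(c(0, 0), c(100, 0)),
    covariances = list(diag(2L), diag(2L)),
    loglik = 0, bic = 0, n_iter = 1L, seed = 1L, n = 2L, d = 2L,
    feature_names = NULL), class = "gmm_model")
  cl <- soft_assign(m, rbind(c(0, 0), c(100, 0)))
  expect_equal(max(cl$responsibilities[1L, ]), 1, tolerance = 1e-10)
  mid <- soft_assign(m, rbind(c(50, 0)))
  expect_equal(as.numeric(mid$responsibilities), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("distinct ensembles reduce soft assignment to hard labels", {
  withr::with_seed(58, {
    cs <- c(
      lapply(1:30, function(i) make_contour(
        "hexagon", size = 40, aspect_ratio = sample_aspect_ratio(1, 1.03,
                                                                 0.02))),
      lapply(1:8, function(i) make_contour(
        "rod", size = 30, aspect_ratio = sample_aspect_ratio(1, 1.76,
                                                             0.05))))
  })
  d <- shape_descriptors(cs)
  cl <- classify_shapes(d, K_max = 4L, seed = 2)
  expect_true(all(pmin(cl$responsibilities[, 1L],
                       1 - cl$responsibilities[, 1L]) < 1e-3))
})

test_that("class summaries are exact weighted statistics", {
  cl <- structure(list(
    responsibilities = rbind(c(1, 0), c(1, 0), c(0, 1)),
    class_totals = c(2, 1), fractions = c(2 / 3, 1 / 3),
    hard_labels = c(1L, 1L, 2L), model = NULL),
    class = "shape_classification")
  d <- tibble::tibble(d_eff_nm = c(10, 12, 20),
                      aspect_ratio = c(1.1, 1.2, 1.5))
  s <- class_summary(cl, d)
  expect_equal(s$sigma, c(2, 1))
  expect_equal(s$fraction, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(s$diam_mean, c(11, 20))

  # uniform responsibilities: both class means equal the global mean
  cu <- cl
  cu$responsibilities <- matrix(0.5, 3L, 2L)
  su <- class_summary(cu, d)
  expect_equal(su$diam_mean, rep(mean(d$d_eff_nm), 2L))
  expect_equal(su$ar_mean, rep(mean(d$aspect_ratio), 2L))
})

test_that("responsibility weighting recovers overlapping class parameters", {
  # contour-level analogue of the dense continuum scenario (truth AR
  # means 1.12 / 1.25 at n = 482)
  withr::with_seed(59, {
    n <- 482L; n1 <- round(0.57 * n)
    z <- sample(c(rep(1L, n1), rep(2L, n - n1)))
    ar <- ifelse(z == 1L, sample_aspect_ratio(n, 1.12, 0.05),
                 sample_aspect_ratio(n, 1.25, 0.08))
    dnm <- stats::rnorm(n, 11.8, 0.8)
    seeds <- sample.int(2^31 - 1, n)
    cs <- lapply(seq_len(n), function(i) {
      make_contour("ellipse", size = dnm[i] / 0.2, aspect_ratio = ar[i],
                   orientation = stats::runif(1, -pi / 2, pi / 2),
                   radial_noise = 0.01, rng = seeds[i], n_points = 128L,
                   convex_only = FALSE)
    })
  })
  d <- shape_descriptors(cs, pixel_size = 0.2)
  m <- fit_gmm(as.matrix(d[, c("logH1", "logH2")]), 2L, seed = 4,
               n_restarts = 5L)
  cl <- soft_assign(m, as.matrix(d[, c("logH1", "logH2")]))
  s <- class_summary(cl, d)
  got <- sort(s$ar_mean)
  expect_equal(got[1L], mean(ar[z == 1L]), tolerance = 0.03 / 1.12)
  expect_equal(got[2L], mean(ar[z == 2L]), tolerance = 0.03 / 1.25)
})

test_that("summaries and tidiers are consistently ordered and conserved", {
  g <- gen_loghu_mixture(61, n = 300L)
  cl <- classify_shapes(
    tibble::tibble(logH1 = g$X[, 1L], logH2 = g$X[, 2L],
                   d_eff_nm = 12, aspect_ratio = ar_from_features(g$X)),
    K_max = 3L, seed = 5)
  s <- class_summary(cl, tibble::tibble(
    d_eff_nm = rep(12, 300L), aspect_ratio = ar_from_features(g$X)))
  expect_true(all(diff(s$sigma) <= 0)) # majority class first
  expect_equal(sum(s$sigma), 300, tolerance = 1e-6)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)

  td <- tidy(cl)
  expect_identical(nrow(td), 300L)
  expect_true(all(abs(rowSums(as.matrix(
    td[, grep("^r_", names(td))])) - 1) < 1e-9))
  gl <- glance(cl)
  expect_identical(gl$n, 300L)
  tm <- tidy(cl$model)
  expect_identical(nrow(tm), ncol(cl$responsibilities))
  expect_equal(sum(tm$weight), 1, tolerance = 1e-9)
})

test_that("degenerate fits are rejected or pruned, never silent nonsense", {
  X <- matrix(stats::rnorm(8), 4L, 2L)
  expect_error(fit_gmm(X, 2L), "too few")
  # duplicated points force component collapse handling
  withr::with_seed(62, {
    X2 <- rbind(matrix(stats::rnorm(100), 50L, 2L),
                matrix(0.001 * stats::rnorm(100), 50L, 2L))
  })
  m <- fit_gmm(X2, 3L, seed = 1, n_restarts = 2L)
  expect_true(all(is.finite(m$loglik_trace)))
})
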