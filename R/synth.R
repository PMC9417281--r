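#' Render a synthetic micrograph-like scene from particle contours
#'
#' Emulates nanometer-resolution TEM contrast, which is dominated by
#' projected specimen thickness: each particle contributes a smooth dome
#' profile (spherical-cap function of the interior distance transform), so
#' the intensity inside a particle is a smooth valley (bright field) or hill
#' (dark field) and the sign structure of its Laplacian matches real
#' thickness contrast. This is deliberately not a physical image simulation
#' (no lens aberrations, no dynamical scattering) — only the contrast
#' structure the analysis pipeline relies on.
#'
#' @param contours list of contours positioned in image coordinates.
#' @param dim image size, `c(rows, cols)`.
#' @param modality `"bright_field"` (particles dark) or `"dark_field"`.
#' @param background `"constant"`, `"gradient"`, or `"fluctuating"`
#'   (low-order 2-D polynomial plus band-limited noise; stresses
#'   thresholding the way dense quantum-dot micrographs do).
#' @param bg_level mean background intensity.
#' @param depth peak thickness-contrast amplitude per particle.
#' @param bg_amplitude amplitude of background structure (gradient or
#'   fluctuation), as an intensity offset.
#' @param noise_sd additive Gaussian pixel noise sd (>= 0).
#' @param dome_amplitude relative amplitude of the dome (curvature) term on
#'   top of the unit slab thickness.
#' @param psf_sigma Gaussian point-spread blur applied to the projected
#'   thickness, px. Placing the blur on the sharp slab edge puts the
#'   half-amplitude intensity level exactly at the true particle boundary,
#'   so contour extraction by mid-level thresholding is unbiased.
#' @param core_shell if `TRUE`, each particle gets a brighter inner core
#'   (dark field) emulating core-shell internal contrast.
#' @param pixel_size nm per pixel for the output image.
#' @param allow_overlap permit touching/overlapping contours (aggregate
#'   scenes); otherwise overlapping particle masks are an error.
#' @param allow_border permit contours extending beyond the image; they are
#'   clipped and flagged in the truth table.
#' @param labels optional per-particle class labels kept as truth.
#' @param params optional per-particle truth tibble (one row per contour).
#' @param seed integer RNG seed; the scene is bit-identical for equal inputs.
#' @return object of class `synthetic_scene`: list with `image`
#'   (a [gray_image()]), `truth_contours`, `truth_labels`, `truth_params`
#'   (tibble incl. `border_clipped`), and `seed`.
#' @export
render_scene <- function(contours, dim = c(256L, 256L),
                         modality = c("bright_field", "dark_field"),
                         background = c("constant", "gradient", "fluctuating"),
                         bg_level = 0.75, depth = 0.45, bg_amplitude = 0.1,
                         noise_sd = 0, dome_amplitude = 0.3, psf_sigma = 0.7,
                         core_shell = FALSE, pixel_size = 1,
                         allow_overlap = FALSE, allow_border = FALSE,
                         labels = NULL, params = NULL, seed = 1L) {
  modality <- match.arg(modality)
  background <- match.arg(background)
  if (is_contour(contours)) contours <- list(contours)
  stopifnot(noise_sd >= 0, length(contours) >= 0)
  nr <- dim[1L]; nc <- dim[2L]

  border_clipped <- vapply(contours, function(cc) {
    any(cc[, 1L] < 1 | cc[, 1L] > nc | cc[, 2L] < 1 | cc[, 2L] > nr)
  }, logical(1L))
  if (any(border_clipped) && !allow_border) {
    stop("contour(s) extend beyond the image; set allow_border = TRUE ",
         "to render them clipped")
  }

  thickness <- matrix(0, nr, nc)
  occupancy <- matrix(0L, nr, nc)
  for (cc in contours) {
    td <- particle_thickness(cc, nr, nc, dome_amplitude = dome_amplitude,
                             core_shell = core_shell)
    thickness <- thickness + td$h
    occupancy <- occupancy + td$mask
  }
  if (!allow_overlap && any(occupancy > 1L)) {
    stop("contours overlap; set allow_overlap = TRUE for aggregate scenes")
  }
  if (psf_sigma > 0) thickness <- EBImage::gblur(thickness, sigma = psf_sigma)

  withr::with_seed(as.integer(seed), {
    bg <- matrix(bg_level, nr, nc)
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc - 0.5
    ys <- matrix(rep(seq_len(nr), nc), nr, nc) / nr - 0.5
    if (background == "gradient") {
      bg <- bg + bg_amplitude * (xs + ys)
    } else if (background == "fluctuating") {
      co <- stats::rnorm(5L)
      poly <- co[1L] * xs + co[2L] * ys + co[3L] * xs * ys +
        co[4L] * (xs^2 - 1 / 12) + co[5L] * (ys^2 - 1 / 12)
      bl <- band_limited_noise(nr, nc, cutoff = 0.03)
      bg <- bg + bg_amplitude * (poly / max(abs(poly)) + bl)
    }
    img <- if (modality == "bright_field") bg - depth * thickness
           else bg + depth * thickness
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                          nr, nc)
  })

  tp <- params %||% tibble::tibble(particle_id = seq_along(contours))
  tp$border_clipped <- border_clipped
  structure(list(
    image = gray_image(img, pixel_size = pixel_size, modality = modality),
    truth_contours = contours,
    truth_labels = labels %||% rep(NA_character_, length(contours)),
    truth_params = tp,
    seed = as.integer(seed)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d particles, seed %d\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              length(x$truth_contours), x$seed))
  invisible(x)
}

# Rasterize one particle: binary mask + thickness profile. The profile is
# a unit slab (platelet-like particles have flat tops) plus a dome term
# (spherical-cap function of the interior distance transform) that gives
# the interior the definite Laplacian sign real thickness contrast shows.
# The sharp slab edge is later blurred by the scene PSF, which places the
# half-amplitude intensity level exactly at the true boundary — so
# threshold-based contour extraction is unbiased.
particle_thickness <- function(contour, nr, nc, dome_amplitude = 0.3,
                               core_shell = FALSE) {
  h <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  x0 <- max(1L, floor(min(contour[, 1L])) - 1L)
  x1 <- min(nc, ceiling(max(contour[, 1L])) + 1L)
  y0 <- max(1L, floor(min(contour[, 2L])) - 1L)
  y1 <- min(nr, ceiling(max(contour[, 2L])) + 1L)
  if (x0 > x1 || y0 > y1) return(list(h = h, mask = mask))
  gx <- x0:x1; gy <- y0:y1
  pts_x <- rep(gx, each = length(gy))
  pts_y <- rep(gy, times = length(gx))
  inside <- pracma::inpolygon(pts_x, pts_y, contour[, 1L], contour[, 2L])
  sub <- matrix(0, length(gy), length(gx))
  sub[cbind(match(pts_y, gy), match(pts_x, gx))] <- as.numeric(inside)
  if (!any(sub > 0)) return(list(h = h, mask = mask))
  d <- EBImage::distmap(sub)
  R <- max(d)
  dome <- if (R > 0) sqrt(pmax(d * (2 * R - d), 0)) / R else sub
  prof <- sub + dome_amplitude * dome
  if (core_shell) {
    # brighter core: extra dome over the inner half of the particle
    core <- pmax(d - R / 2, 0)
    Rc <- max(core)
    if (Rc > 0) prof <- prof + 0.8 * sqrt(pmax(core * (2 * Rc - core), 0)) / Rc
  }
  h[gy, gx] <- h[gy, gx] + prof
  mask[gy, gx] <- mask[gy, gx] + (sub > 0)
  list(h = h, mask = mask)
}

#' Sample particle aspect ratios
#'
#' Aspect ratios are strictly greater than 1: a real particle is never
#' perfectly isotropic, and an atom of exact-AR-1 particles would be a
#' sampling artifact (their eigenvalue gap H2 is identically zero, which no
#' measured contour exhibits). The elongation excess AR - 1 is drawn
#' log-normal with the requested mean and standard deviation, matching a
#' normal AR distribution closely for small relative sd.
#'
#' @param n number of draws.
#' @param mean,sd target mean and sd of the aspect ratio (mean > 1 for a
#'   spread; `sd = 0` returns `mean` exactly).
#' @return numeric vector of aspect ratios > 1 (or exactly `mean`).
#' @export
sample_aspect_ratio <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 1), n))
  m <- max(mean - 1, 1e-6)
  sdlog2 <- log(1 + (sd / m)^2)
  1 + stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# isotropic band-limited unit-variance noise field (radial FFT low-pass)
band_limited_noise <- function(nr, nc, cutoff = 0.03) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  W <- stats::fft(w)
  fy <- ifelse(0:(nr - 1L) <= nr %/% 2, 0:(nr - 1L), 0:(nr - 1L) - nr) / nr
  fx <- ifelse(0:(nc - 1L) <= nc %/% 2, 0:(nc - 1L), 0:(nc - 1L) - nc) / nc
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  W[rad > cutoff] <- 0
  out <- Re(stats::fft(W, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

#' Generate a seeded particle ensemble scene
#'
#' Draws per-class particle parameters (size and aspect-ratio normal
#' distributions), places the particles without contact by rejection
#' sampling, renders the scene and returns it together with the ground-truth
#' table, so parameter recovery by the analysis pipeline can be tested
#' directly against the generator.
#'
#' @param class_spec tibble/data.frame with one row per shape class:
#'   columns `label`, `n`, `shape_family`, `size_mean`, `size_sd` (nm),
#'   `ar_mean`, `ar_sd`; optional `corner_rounding`, `radial_noise`.
#' @param dim image size `c(rows, cols)` in px.
#' @param pixel_size nm per pixel (sizes in `class_spec` are nm).
#' @param margin minimum gap between particle boundaries and to the image
#'   border, px.
#' @param seed integer seed; scenes are bit-identical under equal inputs.
#' @param max_tries placement attempts per particle before erroring.
#' @inheritParams render_scene
#' @return a `synthetic_scene`; `truth_params` holds per-particle family,
#'   label, size (nm), aspect ratio, orientation and center.
#' @export
make_ensemble <- function(class_spec, dim = c(512L, 512L), pixel_size = 1,
                          modality = "bright_field", background = "constant",
                          noise_sd = 0.02, margin = 4, seed = 1L,
                          max_tries = 5000L, ...) {
  cs <- tibble::as_tibble(class_spec)
  stopifnot(all(c("label", "n", "shape_family", "size_mean", "size_sd",
                  "ar_mean", "ar_sd") %in% names(cs)), all(cs$n >= 1))
  nr <- dim[1L]; nc <- dim[2L]

  draws <- withr::with_seed(as.integer(seed), {
    per <- purrr::pmap(cs, function(label, n, shape_family, size_mean,
                                    size_sd, ar_mean, ar_sd, ...) {
      extra <- list(...)
      tibble::tibble(
        label = label, shape_family = shape_family,
        size_nm = pmax(stats::rnorm(n, size_mean, size_sd), size_mean / 4),
        aspect_ratio = sample_aspect_ratio(n, ar_mean, ar_sd),
        orientation = stats::runif(n, -pi / 2, pi / 2),
        corner_rounding = extra$corner_rounding %||% NA_real_,
        radial_noise = extra$radial_noise %||% 0
      )
    })
    tab <- dplyr::bind_rows(per)
    # shuffle so classes interleave spatially
    tab <- tab[sample.int(nrow(tab)), ]
    tab$particle_id <- seq_len(nrow(tab))
    tab$noise_seed <- sample.int(.Machine$integer.max, nrow(tab))

    # rejection-sample particle centers with pairwise clearance
    rad_px <- tab$size_nm / 2 / pixel_size * sqrt(tab$aspect_ratio)
    cx <- cy <- numeric(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        px <- stats::runif(1, 1 + rad_px[i] + margin, nc - rad_px[i] - margin)
        py <- stats::runif(1, 1 + rad_px[i] + margin, nr - rad_px[i] - margin)
        if (i == 1L || all(sqrt((cx[seq_len(i - 1L)] - px)^2 +
                                (cy[seq_len(i - 1L)] - py)^2) >
                           rad_px[seq_len(i - 1L)] + rad_px[i] + margin)) {
          cx[i] <- px; cy[i] <- py; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", nrow(tab), " particles in a ",
                    nr, "x", nc, " image; enlarge the image or reduce n")
    }
    tab$center_x <- cx; tab$center_y <- cy
    tab
  })

  contours <- purrr::pmap(draws, function(label, shape_family, size_nm,
                                          aspect_ratio, orientation,
                                          corner_rounding, radial_noise,
                                          particle_id, noise_seed,
                                          center_x, center_y) {
    cc <- make_contour(shape_family, size = size_nm / pixel_size,
                       aspect_ratio = aspect_ratio,
                       corner_rounding = if (is.na(corner_rounding)) NULL
                                         else corner_rounding,
                       orientation = orientation,
                       radial_noise = radial_noise,
                       convex_only = radial_noise == 0,
                       rng = noise_seed)
    cc <- shift_contour(cc, center_x, center_y)
    attr(cc, "id") <- particle_id
    cc
  })

  render_scene(contours, dim = dim, modality = modality,
               background = background, noise_sd = noise_sd,
               pixel_size = pixel_size, labels = draws$label,
               params = draws, seed = as.integer(seed) + 1L, ...)
}

#' Generate a scene with isolated and aggregated particle groups
#'
#' Builds the standard validation scene for aggregate separation: isolated
#' hexagons and rods plus three group types — a *touching* pair (boundary
#' contact), a *connected* pair (slight overlap) and a 3-particle
#' *aggregate* clump. Particles and groups are placed on a jittered grid so
#' every configuration fits without unintended contact; full ground truth
#' is retained.
#'
#' @param seed integer seed.
#' @param n_isolated_hex,n_isolated_rod isolated particle counts.
#' @param size_nm hexagon equal-area diameter (rods are drawn at 0.76 of
#'   it, mirroring a smaller rod-shaped minority class).
#' @param pixel_size nm per pixel.
#' @param cell grid cell size, px; the image is sized to fit all slots.
#' @param noise_sd additive intensity noise sd.
#' @return a `synthetic_scene`; `truth_params$group` marks `"isolated"`,
#'   `"touching"`, `"connected"`, `"aggregate"`.
#' @export
make_aggregate_scene <- function(seed = 1L, n_isolated_hex = 9L,
                                 n_isolated_rod = 4L, size_nm = 30,
                                 pixel_size = 1, cell = 80L,
                                 noise_sd = 0.02) {
  n_groups <- 3L
  n_slots <- n_isolated_hex + n_isolated_rod + n_groups
  side <- ceiling(sqrt(n_slots))
  dim <- c(side * cell, side * cell)
  rod_size <- 0.76 * size_nm

  withr::with_seed(as.integer(seed), {
    slots <- sample(seq_len(side^2), n_slots)
    slot_xy <- cbind(((slots - 1L) %% side + 0.5) * cell +
                       stats::runif(n_slots, -6, 6),
                     ((slots - 1L) %/% side + 0.5) * cell +
                       stats::runif(n_slots, -6, 6))
    kinds <- c(rep("hex", n_isolated_hex), rep("rod", n_isolated_rod),
               "touching", "connected", "aggregate")
    mk <- function(kind, ar = NULL) {
      fam <- if (kind == "rod") "rod" else "hexagon"
      make_contour(fam, size = if (kind == "rod") rod_size else size_nm,
                   aspect_ratio = ar %||%
                     (if (kind == "rod") sample_aspect_ratio(1, 1.76, 0.05)
                      else sample_aspect_ratio(1, 1.03, 0.02)),
                   orientation = stats::runif(1, -pi / 2, pi / 2))
    }
    contours <- list(); labels <- character(); groups <- character()
    for (i in seq_len(n_slots)) {
      k <- kinds[i]; cx <- slot_xy[i, 1L]; cy <- slot_xy[i, 2L]
      if (k %in% c("hex", "rod")) {
        contours <- c(contours, list(shift_contour(mk(k), cx, cy)))
        labels <- c(labels, k); groups <- c(groups, "isolated")
      } else {
        r <- size_nm / pixel_size / 2
        gap <- switch(k, touching = 2 * r * 0.985, connected = 2 * r * 0.92,
                      aggregate = 2 * r * 0.95)
        th0 <- stats::runif(1, 0, 2 * pi)
        n_in_group <- if (k == "aggregate") 3L else 2L
        for (j in seq_len(n_in_group)) {
          ang <- th0 + (j - 1L) * 2 * pi / n_in_group
          off <- if (n_in_group == 2L) (j - 1.5) * gap else gap / sqrt(3) * 1.05
          px <- if (n_in_group == 2L) cx + off * cos(th0) else
            cx + off * cos(ang)
          py <- if (n_in_group == 2L) cy + off * sin(th0) else
            cy + off * sin(ang)
          contours <- c(contours, list(shift_contour(mk("hex"), px, py)))
          labels <- c(labels, "hex"); groups <- c(groups, k)
        }
      }
    }
  })
  params <- tibble::tibble(particle_id = seq_along(contours),
                           label = labels, group = groups)
  for (i in seq_along(contours)) attr(contours[[i]], "id") <- i
  render_scene(contours, dim = dim, noise_sd = noise_sd,
               pixel_size = pixel_size, allow_overlap = TRUE,
               labels = labels, params = params,
               seed = as.integer(seed) + 1L)
}

#' Write / read a synthetic scene (TIFF image + JSON truth)
#'
#' @param scene a `synthetic_scene`.
#' @param prefix path prefix; writes `<prefix>.tif` and `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
write_scene <- function(scene, prefix) {
  stopifnot(inherits(scene, "synthetic_scene"))
  write_micrograph(scene$image, paste0(prefix, ".tif"))
  truth <- list(
    pixel_size = scene$image$pixel_size,
    modality = scene$image$modality,
    seed = scene$seed,
    labels = scene$truth_labels,
    params = scene$truth_params,
    contours = purrr::map(scene$truth_contours, function(cc) {
      list(id = attr(cc, "id"), x = unname(cc[, 1L]), y = unname(cc[, 2L]))
    })
  )
  jsonlite::write_json(truth, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  truth <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- read_micrograph(paste0(prefix, ".tif"),
                         pixel_size = truth$pixel_size,
                         modality = truth$modality)
  contours <- purrr::map(seq_len(nrow(truth$contours)), function(i) {
    as_contour(cbind(truth$contours$x[[i]], truth$contours$y[[i]]),
               id = truth$contours$id[[i]])
  })
  structure(list(image = img, truth_contours = contours,
                 truth_labels = truth$labels,
                 truth_params = tibble::as_tibble(truth$params),
                 seed = truth$seed),
            class = "synthetic_scene")
}
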