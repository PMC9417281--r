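#' Generate a parametric convex particle contour
#'
#' Produces the convex shape families used to emulate typical nanoparticle
#' projections: hexagonal platelets, rounded rods, ellipses, rounded cubes
#' (squares in projection) and general regular polygons. Each family is built
#' from an isotropic base shape (second-moment tensor proportional to the
#' identity, guaranteed by the base shape's n-fold symmetry, n >= 3), then
#' stretched anisotropically. Because the base is isotropic, the stretch
#' factor maps *exactly* onto the inertia-eigenvalue aspect ratio
#' eta1/eta2 recovered by [shape_descriptors()], so generator truth and
#' descriptor output are directly comparable.
#'
#' `size` follows the effective-diameter convention: the diameter of the
#' circle with the same enclosed area, so the enclosed area is
#' `pi * (size/2)^2` (exact by final rescaling).
#'
#' @param shape_family one of `"hexagon"`, `"rod"`, `"ellipse"`,
#'   `"rounded_cube"`, `"polygon"`.
#' @param size equal-area-circle diameter, in pixels (or nm if you work in
#'   calibrated units throughout).
#' @param aspect_ratio inertia aspect ratio >= 1.
#' @param corner_rounding fraction 0..1 of the inradius used as the corner
#'   fillet radius; `NULL` picks a per-family default (hexagon 0.15,
#'   rod 0.6, rounded_cube 0.3, polygon 0.1). Ignored for ellipses.
#' @param orientation major-axis angle, radians.
#' @param n_points number of boundary vertices returned.
#' @param n_sides number of sides for `shape_family = "polygon"`.
#' @param radial_noise sd of i.i.d. relative radial perturbation (fraction of
#'   local radius), applied before smoothing; models irregular particles.
#' @param smooth_noise harmonic cutoff used to smooth radial noise into a
#'   plausible irregular boundary.
#' @param convex_only reject parameter combinations that produce a
#'   non-convex contour.
#' @param rng integer seed used for `radial_noise` draws (ignored when
#'   `radial_noise = 0`).
#' @return a [as_contour()] object with `n_points` vertices, exactly the
#'   requested enclosed area, CCW-oriented.
#' @examples
#' h <- make_contour("hexagon", size = 60)
#' contour_area(h) / (pi * 30^2) # 1
#' @export
make_contour <- function(shape_family = c("hexagon", "rod", "ellipse",
                                          "rounded_cube", "polygon"),
                         size, aspect_ratio = 1, corner_rounding = NULL,
                         orientation = 0, n_points = 256L, n_sides = 5L,
                         radial_noise = 0, smooth_noise = 12L,
                         convex_only = TRUE, rng = NULL) {
  shape_family <- match.arg(shape_family)
  if (size <= 0) stop("size must be > 0")
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (radial_noise < 0) stop("radial_noise must be >= 0")
  if (convex_only && radial_noise > 0.1) {
    stop("radial_noise > 0.1 can produce non-convex contours; ",
         "set convex_only = FALSE to allow this")
  }

  base <- switch(shape_family,
    ellipse      = regular_base(180L, 1),           # rounding 1 => circle
    hexagon      = regular_base(6L, corner_rounding %||% 0.15),
    rod          = regular_base(4L, corner_rounding %||% 0.6),
    rounded_cube = regular_base(4L, corner_rounding %||% 0.3),
    polygon      = regular_base(as.integer(n_sides), corner_rounding %||% 0.1)
  )

  xy <- unclass(resample_contour(base, n_points))

  if (radial_noise > 0) {
    if (is.null(rng)) stop("radial_noise > 0 requires an explicit rng seed")
    r <- sqrt(rowSums(xy^2))
    pert <- withr::with_seed(as.integer(rng),
                             stats::rnorm(nrow(xy), 0, radial_noise))
    # band-limit the perturbation so the boundary stays particle-like
    p <- stats::fft(pert)
    k <- c(0:(length(p) %/% 2), -((length(p) - length(p) %/% 2 - 1L):1L))
    p[abs(k) > smooth_noise] <- 0
    pert <- Re(stats::fft(p, inverse = TRUE)) / length(p)
    xy <- xy * (1 + pert)
  }

  # anisotropic stretch: isotropic base => eta1/eta2 == aspect_ratio exactly
  xy[, 1L] <- xy[, 1L] * sqrt(aspect_ratio)
  xy[, 2L] <- xy[, 2L] / sqrt(aspect_ratio)

  out <- as_contour(xy)
  if (convex_only && !is_convex_contour(out, tol = 1e-7)) {
    stop("requested parameters produce a non-convex contour under ",
         "convex_only = TRUE")
  }
  if (orientation != 0) out <- rotate_contour(out, orientation,
                                              center = c(0, 0))
  target_area <- pi * (size / 2)^2
  s <- sqrt(target_area / contour_area(out))
  out <- scale_contour(out, s, s, center = c(0, 0))
  attr(out, "shape_family") <- shape_family
  out
}

# Regular n-gon with circular corner fillets, circumradius ~1, centered at
# the origin. rounding = fillet radius as a fraction of the inradius;
# rounding 1 gives the inscribed circle. n >= 3; returns a dense contour.
regular_base <- function(n, rounding) {
  stopifnot(n >= 3L)
  rounding <- min(max(rounding, 0), 1)
  r_in <- cos(pi / n)
  rho <- rounding * r_in
  # vertices of the sharp polygon
  ang <- 2 * pi * (0:(n - 1L)) / n
  V <- cbind(cos(ang), sin(ang))
  # fillet arc centers sit on the vertex bisector at distance rho / cos(pi/n)
  # from the origin-side, i.e. at radius (1 - rho / cos(pi/n)) * |V|
  cfac <- 1 - rho / cos(pi / n)
  C <- V * cfac
  pts <- list()
  half <- pi / n
  for (k in seq_len(n)) {
    if (rho > 0) {
      # fillet arc spans the two edge-normal directions ang[k] +/- pi/n;
      # straight edge segments arise implicitly between consecutive arcs
      th <- seq(ang[k] - half, ang[k] + half, length.out = 24L)
      pts[[length(pts) + 1L]] <- cbind(C[k, 1L] + rho * cos(th),
                                       C[k, 2L] + rho * sin(th))
    } else {
      pts[[length(pts) + 1L]] <- V[k, , drop = FALSE]
    }
  }
  as_contour(do.call(rbind, pts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
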