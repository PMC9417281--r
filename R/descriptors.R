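#' Exact area moments of a polygonal contour
#'
#' Raw geometric moments \eqn{m_{pq} = \iint x^p y^q \, dA} over the filled
#' contour, evaluated in closed form from the vertices by Green's theorem
#' (no rasterization), plus the translation-invariant central moments
#' \eqn{\mu_{pq}}. Exact polygon integration makes the downstream Hu-moment
#' invariance properties hold to numerical precision, independent of image
#' resolution.
#'
#' @param contour a [as_contour()] object (simple, CCW).
#' @param max_order highest total order p + q (default 3, enough for all
#'   seven Hu invariants).
#' @return a list with `raw` and `central` named numeric vectors
#'   (`m00`, `m10`, ..., `mu20`, ...), and `centroid`.
#' @references closed-form polygon moments follow the standard
#'   Green's-theorem reduction of the area integral to an edge sum.
#' @export
polygon_moments <- function(contour, max_order = 3L) {
  xy <- unclass(contour)
  if (shoelace_area(xy) <= 0) stop("contour must have positive area (CCW)")
  x <- xy[, 1L]; y <- xy[, 2L]
  xp <- c(x[-1L], x[1L]); yp <- c(y[-1L], y[1L]) # successor vertices
  cr <- x * yp - xp * y

  raw <- c()
  for (p in 0:max_order) for (q in 0:(max_order - p)) {
    s <- 0
    for (k in 0:p) for (l in 0:q) {
      s <- s + choose(k + l, l) * choose(p + q - k - l, q - l) *
        sum(cr * x^(p - k) * xp^k * y^(q - l) * yp^l)
    }
    m <- s / ((p + q + 2) * (p + q + 1) * choose(p + q, p))
    raw[sprintf("m%d%d", p, q)] <- m
  }
  a <- raw[["m00"]]
  if (a <= 0) stop("degenerate contour: zero area")
  cx <- raw[["m10"]] / a
  cy <- raw[["m01"]] / a

  central <- c()
  for (p in 0:max_order) for (q in 0:(max_order - p)) {
    mu <- 0
    for (i in 0:p) for (j in 0:q) {
      mu <- mu + choose(p, i) * choose(q, j) * (-cx)^(p - i) * (-cy)^(q - j) *
        raw[[sprintf("m%d%d", i, j)]]
    }
    central[sprintf("mu%d%d", p, q)] <- mu
  }
  list(raw = raw, central = central, centroid = c(x = cx, y = cy))
}

#' Hu moment invariants of a contour
#'
#' Computes the first `n_hu` Hu invariants from scale-normalized central
#' moments of the filled contour; by construction they are independent of the
#' contour's position, orientation and overall size. For the convex particle
#' shapes this package targets, the first two (`H1`, `H2`) carry the shape
#' information: `H1` is the trace and `H2` the squared eigenvalue gap of the
#' normalized second-moment (inertia) tensor.
#'
#' The classification feature is `log10(H + eps)` with `eps = 1e-12`:
#' circularly symmetric shapes have H2 exactly 0 and the log feature must
#' stay finite.
#'
#' @param contour a contour; resampled to at least `min_points` equally
#'   spaced boundary points before integration.
#' @param n_hu number of Hu invariants, 2..7.
#' @param eps floor added inside the log.
#' @param min_points minimum boundary sampling.
#' @return named list: `H` (length `n_hu`), `logH`, plus the normalized
#'   second-order moments `nu20`, `nu02`, `nu11`.
#' @export
hu_features <- function(contour, n_hu = 2L, eps = 1e-12, min_points = 256L) {
  stopifnot(n_hu >= 2L, n_hu <= 7L)
  if (nrow(contour) < min_points) contour <- resample_contour(contour, min_points)
  mom <- polygon_moments(contour, max_order = if (n_hu > 2L) 3L else 2L)
  mu <- mom$central
  a <- mom$raw[["m00"]]
  nu <- function(p, q) mu[[sprintf("mu%d%d", p, q)]] / a^(1 + (p + q) / 2)
  n20 <- nu(2, 0); n02 <- nu(0, 2); n11 <- nu(1, 1)
  H <- c(H1 = n20 + n02,
         H2 = (n20 - n02)^2 + 4 * n11^2)
  if (n_hu > 2L) {
    n30 <- nu(3, 0); n03 <- nu(0, 3); n21 <- nu(2, 1); n12 <- nu(1, 2)
    H <- c(H,
      H3 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
      H4 = (n30 + n12)^2 + (n21 + n03)^2,
      H5 = (n30 - 3 * n12) * (n30 + n12) *
             ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
           (3 * n21 - n03) * (n21 + n03) *
             (3 * (n30 + n12)^2 - (n21 + n03)^2),
      H6 = (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
           4 * n11 * (n30 + n12) * (n21 + n03),
      H7 = (3 * n21 - n03) * (n30 + n12) *
             ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
           (n30 - 3 * n12) * (n21 + n03) *
             (3 * (n30 + n12)^2 - (n21 + n03)^2)
    )[1:n_hu]
  }
  H2f <- max(H[["H2"]], 0) # exact symmetry can give tiny negative roundoff
  H[["H2"]] <- H2f
  list(H = H, logH = log10(abs(H) + eps),
       nu20 = n20, nu02 = n02, nu11 = n11)
}

#' Shape eigenvalues (semi-axis lengths) from the first two Hu moments
#'
#' The two principal moments of inertia of the unit-area filled contour are
#' \eqn{\lambda_{1,2} = (H_1 \pm \sqrt{H_2})/2}. The returned values
#' \eqn{\eta_{1,2} = 2\sqrt{\lambda_{1,2}}} are scaled so that for an ellipse
#' of unit area they equal the semi-major and semi-minor axes; for any
#' unit-area ellipse the pair then satisfies \eqn{\pi\,\eta_1\eta_2 = 1}.
#' Their ratio \eqn{\eta_1/\eta_2 \ge 1} is the aspect ratio.
#'
#' @param H1,H2 first two Hu invariants (H1 > 0, 0 <= H2 <= H1^2).
#' @return named numeric: `eta1 >= eta2 > 0`.
#' @examples
#' shape_eigenvalues(1 / (2 * pi), 0) # circle: both 1/sqrt(pi)
#' @export
shape_eigenvalues <- function(H1, H2) {
  if (any(H1 <= 0)) stop("H1 must be > 0")
  if (any(H2 < 0)) stop("H2 must be >= 0")
  if (any(H2 > H1^2 * (1 + 1e-12))) {
    stop("H1^2 < H2: not realizable as a shape's inertia tensor")
  }
  s <- sqrt(pmin(H2, H1^2))
  lam1 <- (H1 + s) / 2
  lam2 <- (H1 - s) / 2
  c(eta1 = 2 * sqrt(lam1), eta2 = 2 * sqrt(lam2))
}

#' Effective diameter from enclosed area
#'
#' Standard equal-area-circle metrology convention:
#' \eqn{d = 2\sqrt{A/\pi}\cdot s} with `s` the pixel size.
#'
#' @param area_px enclosed area in px^2.
#' @param pixel_size calibration in nm per pixel.
#' @return diameter in nm.
#' @export
effective_diameter <- function(area_px, pixel_size = 1) {
  if (any(area_px <= 0)) stop("area must be > 0")
  2 * sqrt(area_px / pi) * pixel_size
}

#' Principal orientation of a contour
#'
#' Angle of the major principal axis of the second-moment (inertia) tensor,
#' in radians, mapped to (-pi/2, pi/2]. Shapes that are isotropic at second
#' order (H2 below `iso_floor`) have undefined orientation: 0 is returned
#' with attribute `isotropic = TRUE`.
#'
#' @param contour a contour.
#' @param iso_floor H2 threshold below which orientation is undefined.
#' @return angle in radians with logical attribute `isotropic`.
#' @export
principal_orientation <- function(contour, iso_floor = 1e-10) {
  mom <- polygon_moments(contour, max_order = 2L)
  mu <- mom$central
  a <- mom$raw[["m00"]]
  n20 <- mu[["mu20"]] / a^2; n02 <- mu[["mu02"]] / a^2
  n11 <- mu[["mu11"]] / a^2
  h2 <- (n20 - n02)^2 + 4 * n11^2
  if (h2 < iso_floor) {
    return(structure(0, isotropic = TRUE))
  }
  th <- 0.5 * atan2(2 * n11, n20 - n02)
  if (th <= -pi / 2) th <- th + pi
  if (th > pi / 2) th <- th - pi
  structure(th, isotropic = FALSE)
}

#' Per-particle shape descriptor table
#'
#' Applies the full descriptor pipeline to a list of contours and returns one
#' tidy row per particle: Hu features and their logs, the shape eigenvalues
#' `eta1 >= eta2`, aspect ratio `eta1/eta2`, effective diameter in nm,
#' principal orientation, and centroid.
#'
#' @param contours list of contours (or a single contour).
#' @param pixel_size nm per pixel.
#' @param n_hu number of Hu invariants to report (default 2, the
#'   classification feature set).
#' @param min_points boundary resampling floor passed to [hu_features()].
#' @return a tibble with one row per contour.
#' @export
shape_descriptors <- function(contours, pixel_size = 1, n_hu = 2L,
                              min_points = 256L) {
  if (is_contour(contours)) contours <- list(contours)
  rows <- purrr::imap(contours, function(cnt, i) {
    id <- attr(cnt, "id") %||% i
    hf <- hu_features(cnt, n_hu = n_hu, min_points = min_points)
    eig <- shape_eigenvalues(hf$H[["H1"]], hf$H[["H2"]])
    area <- attr(cnt, "area_px") %||% contour_area(cnt)
    ori <- principal_orientation(cnt)
    cen <- contour_centroid(cnt)
    out <- tibble::tibble(
      particle_id = as.integer(id),
      area_px = area,
      d_eff_nm = effective_diameter(area, pixel_size),
      eta1 = eig[["eta1"]], eta2 = eig[["eta2"]],
      aspect_ratio = eig[["eta1"]] / eig[["eta2"]],
      orientation = as.numeric(ori),
      isotropic = isTRUE(attr(ori, "isotropic")),
      centroid_x = cen[["x"]], centroid_y = cen[["y"]]
    )
    hu <- c(as.list(hf$H), as.list(stats::setNames(hf$logH,
                                                   paste0("log", names(hf$H)))))
    dplyr::bind_cols(out, tibble::as_tibble(hu))
  })
  dplyr::bind_rows(rows)
}
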