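#' Construct a particle contour
#'
#' A contour is a closed, simple polygon stored as an open vertex sequence
#' (the closing edge from the last to the first vertex is implicit). Vertices
#' are in floating-point pixel units, `x` = column, `y` = row, origin at the
#' top-left pixel center. On construction the vertex order is normalized to
#' counter-clockwise, i.e. positive shoelace area.
#'
#' @param xy numeric matrix with two columns (x, y) and at least 3 rows.
#' @param id optional particle identifier kept as an attribute.
#' @return an object of class `contour`: the vertex matrix with columns
#'   named `x`, `y`.
#' @export
as_contour <- function(xy, id = NULL) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("a contour needs exactly two coordinate columns")
  if (nrow(xy) < 3L) stop("a contour needs at least 3 vertices")
  if (!all(is.finite(xy))) stop("contour coordinates must be finite")
  # drop a duplicated closing vertex if present
  if (isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], check.attributes = FALSE))) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  colnames(xy) <- c("x", "y")
  if (shoelace_area(xy) < 0) xy <- xy[nrow(xy):1L, , drop = FALSE]
  if (shoelace_area(xy) <= 0) stop("degenerate contour: non-positive area")
  structure(xy, class = c("contour", "matrix", "array"), id = id)
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, area %.4g px^2\n",
              nrow(x), contour_area(x)))
  invisible(x)
}

is_contour <- function(x) inherits(x, "contour")

# signed shoelace area; > 0 for the package's CCW convention
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Enclosed area of a contour
#' @param contour a `contour`
#' @return area in squared pixel units (always positive)
#' @export
contour_area <- function(contour) abs(shoelace_area(contour))

#' Contour perimeter
#' @param contour a `contour`
#' @return perimeter in pixel units
#' @export
contour_perimeter <- function(contour) {
  d <- diff(rbind(contour, contour[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a contour
#' @param contour a `contour`
#' @return length-2 numeric (x, y)
#' @export
contour_centroid <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Affine helpers for contours
#'
#' Rigid and affine maps applied to contour vertices. `rotate_contour`
#' rotates about the centroid unless `center` is given; `scale_contour`
#' scales about the centroid.
#'
#' @param contour a `contour`
#' @param dx,dy translation in pixels
#' @param theta rotation angle in radians (mathematically positive)
#' @param sx,sy scale factors
#' @param center optional (x, y) to rotate/scale about
#' @return a transformed `contour`
#' @name contour_transforms
NULL

#' @rdname contour_transforms
#' @export
shift_contour <- function(contour, dx, dy) {
  out <- contour
  out[, 1L] <- out[, 1L] + dx
  out[, 2L] <- out[, 2L] + dy
  out
}

#' @rdname contour_transforms
#' @export
rotate_contour <- function(contour, theta, center = NULL) {
  if (is.null(center)) center <- contour_centroid(contour)
  xy <- sweep(unclass(contour), 2L, center)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  out <- sweep(xy %*% t(R), 2L, center, "+")
  as_contour(out, id = attr(contour, "id"))
}

#' @rdname contour_transforms
#' @export
scale_contour <- function(contour, sx, sy = sx, center = NULL) {
  if (is.null(center)) center <- contour_centroid(contour)
  xy <- sweep(unclass(contour), 2L, center)
  xy[, 1L] <- xy[, 1L] * sx
  xy[, 2L] <- xy[, 2L] * sy
  out <- sweep(xy, 2L, center, "+")
  as_contour(out, id = attr(contour, "id"))
}

#' Resample a contour to equally spaced arc-length points
#'
#' Linear interpolation along the closed polygon boundary. Used before moment
#' computation (moments are exact polygon integrals, but a common vertex
#' density makes invariance checks sharp) and before contour averaging.
#'
#' @param contour a `contour`
#' @param n number of output vertices
#' @return a `contour` with `n` vertices
#' @export
resample_contour <- function(contour, n = 256L) {
  xy <- rbind(unclass(contour), unclass(contour)[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  xi <- stats::approx(s, xy[, 1L], xout = target, ties = "ordered")$y
  yi <- stats::approx(s, xy[, 2L], xout = target, ties = "ordered")$y
  as_contour(cbind(xi, yi), id = attr(contour, "id"))
}

#' Scale a contour to unit enclosed area, centered at the origin
#' @param contour a `contour`
#' @return a unit-area `contour` with centroid (0, 0)
#' @export
normalize_contour <- function(contour) {
  cen <- contour_centroid(contour)
  xy <- sweep(unclass(contour), 2L, cen)
  a <- abs(shoelace_area(xy))
  as_contour(xy / sqrt(a), id = attr(contour, "id"))
}

#' Symmetric Hausdorff distance between two contours
#'
#' Vertex-to-vertex distance; both contours should be resampled densely
#' for a tight estimate of the true boundary Hausdorff distance.
#' @param a,b contours
#' @return numeric distance in the contours' units
#' @export
hausdorff_distance <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}

# convexity check via sign of consecutive cross products (tolerates tiny
# numerical concavity relative to the contour scale)
is_convex_contour <- function(contour, tol = 1e-9) {
  xy <- unclass(contour)
  n <- nrow(xy)
  p <- xy[c(n, 1:(n - 1L)), ]
  q <- xy
  r <- xy[c(2:n, 1L), ]
  cr <- (q[, 1L] - p[, 1L]) * (r[, 2L] - q[, 2L]) -
        (q[, 2L] - p[, 2L]) * (r[, 1L] - q[, 1L])
  scale2 <- max(abs(cr))
  all(cr >= -tol * max(scale2, .Machine$double.eps))
}

#' Smooth a closed contour by truncating its Fourier series
#'
#' The boundary is treated as a complex-valued periodic signal
#' z = x + iy; harmonics above `cutoff` are removed.
#'
#' @param contour a `contour`
#' @param cutoff highest harmonic retained (>= 1)
#' @return a smoothed `contour` with the same number of vertices
#' @export
fourier_smooth_contour <- function(contour, cutoff = 32L) {
  stopifnot(cutoff >= 1L)
  z <- complex(real = contour[, 1L], imaginary = contour[, 2L])
  n <- length(z)
  Z <- stats::fft(z)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1L)) # frequency index per bin
  Z[abs(k) > cutoff] <- 0
  zs <- stats::fft(Z, inverse = TRUE) / n
  as_contour(cbind(Re(zs), Im(zs)), id = attr(contour, "id"))
}

#' Solidity of a contour
#'
#' Enclosed area divided by the area of the convex hull of the vertices;
#' close to 1 for convex particles, markedly below 1 for fused/aggregated
#' blobs.
#' @param contour a `contour`
#' @return solidity in (0, 1]
#' @export
contour_solidity <- function(contour) {
  h <- grDevices::chull(contour[, 1L], contour[, 2L])
  hull <- unclass(contour)[h, , drop = FALSE]
  min(1, contour_area(contour) / abs(shoelace_area(hull)))
}
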