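#' Responsibility-weighted contour density map
#'
#' The classic per-class diagnostic: all contours are scale- and
#' orientation-matched (unit area, principal axis horizontal, residual
#' n-fold symmetry resolved by angular cross-correlation against the
#' running class mean) and overlaid as thin rings, each weighted by the
#' particle's responsibility for the class. Well-defined shape classes give
#' extremely tight rings; a continuum of non-distinct shapes gives a
#' visibly diffuse band.
#'
#' @param contours list of contours.
#' @param descriptors matching [shape_descriptors()] tibble (for
#'   orientations).
#' @param responsibilities numeric vector, the class's responsibility
#'   column (one entry per contour).
#' @param grid_size output grid resolution (cells per side).
#' @param extent half-width of the normalized coordinate window.
#' @param class_label stored on the result.
#' @return object of class `density_map`: `grid` (grid_size x grid_size),
#'   `class_label`, `total_weight` (= sum of responsibilities accumulated),
#'   `extent`. Each contour deposits exactly its responsibility, spread
#'   uniformly over its ring cells.
#' @export
density_map <- function(contours, descriptors, responsibilities,
                        grid_size = 128L, extent = 1.25,
                        class_label = NULL) {
  stopifnot(length(contours) == nrow(descriptors),
            length(responsibilities) == length(contours))
  grid <- matrix(0, grid_size, grid_size)
  if (sum(responsibilities) <= 0) {
    warning("class has zero total responsibility; empty density map")
    return(structure(list(grid = grid, class_label = class_label,
                          total_weight = 0, extent = extent),
                     class = "density_map"))
  }
  ref <- NULL
  ord <- order(responsibilities, decreasing = TRUE) # align to clearest first
  for (i in ord) {
    w <- responsibilities[i]
    cc <- normalize_contour(contours[[i]])
    if (!descriptors$isotropic[i]) {
      cc <- rotate_contour(cc, -descriptors$orientation[i], center = c(0, 0))
    }
    cc <- resample_contour(cc, 256L)
    z <- complex(real = cc[, 1L], imaginary = cc[, 2L])
    if (is.null(ref)) {
      ref <- z
      za <- z
    } else {
      za <- align_complex_contour(z, ref)
      # running weighted mean keeps symmetric families phase-locked
      ref <- ref + w * za / sum(responsibilities)
    }
    # rasterize ring into the grid, depositing exactly w in total
    gx <- floor((Re(za) + extent) / (2 * extent) * grid_size) + 1L
    gy <- floor((Im(za) + extent) / (2 * extent) * grid_size) + 1L
    keep <- gx >= 1L & gx <= grid_size & gy >= 1L & gy <= grid_size
    if (!any(keep)) next
    cells <- unique(cbind(gy[keep], gx[keep]))
    grid[cells] <- grid[cells] + w / nrow(cells)
  }
  structure(list(grid = grid, class_label = class_label,
                 total_weight = sum(responsibilities), extent = extent),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> '%s': %dx%d grid, total weight %.2f\n",
              x$class_label %||% "?", nrow(x$grid), ncol(x$grid),
              x$total_weight))
  invisible(x)
}

#' Shape-eigenvalue scatter data with overlay curves
#'
#' Per-particle (eta1, eta2) points plus the two reference overlays: the
#' aspect-ratio isolines eta2 = eta1 / AR and the general-ellipse curve
#' eta2 = 1 / (pi * eta1), on which every perfect ellipse lies regardless
#' of aspect ratio. Deviation from the ellipse curve measures how
#' non-elliptical the particle shapes are.
#'
#' @param descriptors a [shape_descriptors()] tibble.
#' @param responsibilities optional N x K responsibility matrix (columns
#'   are appended as `r_1`, ...).
#' @param ar_isolines aspect ratios for the isoline overlay.
#' @return a tibble of points with attributes `isolines` and
#'   `ellipse_curve` (tibbles ready to plot).
#' @export
eigenvalue_scatter_data <- function(descriptors, responsibilities = NULL,
                                    ar_isolines = c(1, 1.25, 1.5, 2, 3)) {
  pts <- dplyr::select(descriptors, dplyr::any_of(
    c("particle_id", "eta1", "eta2", "aspect_ratio", "d_eff_nm")))
  if (!is.null(responsibilities)) {
    pts <- dplyr::bind_cols(pts, tibble::as_tibble(responsibilities))
  }
  e1 <- seq(max(min(pts$eta1) * 0.9, 0.3), max(pts$eta1) * 1.1,
            length.out = 200L)
  iso <- purrr::map_dfr(ar_isolines, function(a) {
    tibble::tibble(ar = a, eta1 = e1, eta2 = e1 / a)
  })
  curve <- tibble::tibble(eta1 = e1, eta2 = 1 / (pi * e1))
  attr(pts, "isolines") <- iso
  attr(pts, "ellipse_curve") <- curve
  pts
}

#' Class-weighted effective-diameter histogram data
#'
#' Stacked per-bin responsibility weights per class; total accumulated
#' weight equals the particle count, so class mixing is visible bin by bin.
#'
#' @param descriptors a [shape_descriptors()] tibble.
#' @param responsibilities N x K responsibility matrix.
#' @param bins number of bins (or a vector of break points).
#' @return a tibble: `bin_lo`, `bin_hi`, `bin_mid`, `class`, `weight`.
#' @export
diameter_histogram_data <- function(descriptors, responsibilities,
                                    bins = 30L) {
  resp <- as.matrix(responsibilities)
  stopifnot(nrow(resp) == nrow(descriptors), length(bins) >= 1L)
  d <- descriptors$d_eff_nm
  breaks <- if (length(bins) == 1L) {
    seq(min(d) - 1e-9, max(d) + 1e-9, length.out = bins + 1L)
  } else bins
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  purrr::map_dfr(seq_len(ncol(resp)), function(k) {
    w <- vapply(seq_len(length(breaks) - 1L),
                function(b) sum(resp[bin == b, k]), numeric(1L))
    tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                   bin_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                   class = k, weight = w)
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contour density map
#' @param object a [density_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  g <- object$grid
  ex <- object$extent
  n <- nrow(g)
  df <- tibble::tibble(
    x = rep(seq(-ex, ex, length.out = n), each = n),
    y = rep(seq(-ex, ex, length.out = n), times = n),
    density = as.vector(g)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$class_label,
                  x = "normalized x", y = "normalized y",
                  fill = "weight") +
    ggplot2::theme_minimal()
}

#' Eigenvalue scatter plot with AR isolines and the general-ellipse curve
#'
#' @param descriptors a [shape_descriptors()] tibble.
#' @param classification optional [soft_assign()] result; two-class
#'   results are colored by responsibility mixing (magenta-cyan).
#' @param ar_isolines aspect ratios drawn as solid isolines.
#' @return a ggplot.
#' @export
plot_eigenvalues <- function(descriptors, classification = NULL,
                             ar_isolines = c(1, 1.25, 1.5, 2, 3)) {
  resp <- if (!is.null(classification)) classification$responsibilities
  pts <- eigenvalue_scatter_data(descriptors, resp, ar_isolines)
  iso <- attr(pts, "isolines")
  curve <- attr(pts, "ellipse_curve")
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$eta1, y = .data$eta2)) +
    ggplot2::geom_line(data = iso,
                       ggplot2::aes(group = .data$ar), color = "grey60") +
    ggplot2::geom_line(data = curve, linetype = "dashed", color = "grey30")
  p <- if (!is.null(resp) && ncol(resp) == 2L) {
    mix <- grDevices::rgb(pts$r_1, 1 - pts$r_1, 1 - 0 * pts$r_1)
    p + ggplot2::geom_point(color = mix, size = 1.6)
  } else {
    p + ggplot2::geom_point(size = 1.6, color = "steelblue")
  }
  p + ggplot2::coord_cartesian(ylim = c(0, max(pts$eta1) * 0.8)) +
    ggplot2::labs(x = expression(eta[1]), y = expression(eta[2])) +
    ggplot2::theme_classic()
}

#' Stacked class-colored effective-diameter distribution
#' @param descriptors a [shape_descriptors()] tibble.
#' @param classification a [soft_assign()] result.
#' @param bins histogram bin count.
#' @return a ggplot.
#' @export
plot_diameters <- function(descriptors, classification, bins = 30L) {
  h <- diameter_histogram_data(descriptors,
                               classification$responsibilities, bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$weight,
                                  fill = factor(.data$class))) +
    ggplot2::geom_col(width = h$bin_hi[1L] - h$bin_lo[1L]) +
    ggplot2::scale_fill_manual(values = c("magenta3", "cyan3", "orange",
                                          "green4", "purple")) +
    ggplot2::labs(x = "effective diameter (nm)", y = "weighted count",
                  fill = "class") +
    ggplot2::theme_classic()
}
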