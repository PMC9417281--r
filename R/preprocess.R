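#' Denoise a micrograph
#'
#' Either an isotropic Fourier low-pass (all spatial frequencies above
#' `cutoff`, in cycles per pixel, removed; the DC term is untouched so total
#' intensity is preserved exactly) or a Gaussian blur of width `cutoff`
#' (interpreted as sigma in pixels).
#'
#' @param image a [gray_image()].
#' @param method `"fourier_lowpass"` or `"gaussian"`.
#' @param cutoff spatial frequency in cycles/px (must be <= 0.5, the
#'   Nyquist limit) for the Fourier filter; sigma in px for the Gaussian.
#' @return a denoised `gray_image` of the same shape.
#' @export
denoise <- function(image, method = c("fourier_lowpass", "gaussian"),
                    cutoff = 0.15) {
  stopifnot(inherits(image, "gray_image"))
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be > 0")
  px <- image$pixels
  out <- if (method == "fourier_lowpass") {
    if (cutoff > 0.5) stop("cutoff beyond the Nyquist frequency (0.5 cycles/px)")
    nr <- nrow(px); nc <- ncol(px)
    FW <- stats::fft(px)
    fy <- ifelse(0:(nr - 1L) <= nr %/% 2, 0:(nr - 1L), 0:(nr - 1L) - nr) / nr
    fx <- ifelse(0:(nc - 1L) <= nc %/% 2, 0:(nc - 1L), 0:(nc - 1L) - nc) / nc
    rad <- sqrt(outer(fy^2, fx^2, "+"))
    FW[rad > cutoff] <- 0
    Re(stats::fft(FW, inverse = TRUE)) / (nr * nc)
  } else {
    EBImage::gblur(px, sigma = cutoff)
  }
  gray_image(out, pixel_size = image$pixel_size, modality = image$modality)
}

#' Threshold a micrograph into a binary particle mask
#'
#' Separates particles from background by intensity thresholding, resolving
#' contrast polarity from the image's modality (bright-field particles are
#' darker than background, dark-field brighter). Interior holes are filled
#' so particles with internal contrast (e.g. core-shell structure) come out
#' as solid components.
#'
#' @param image a [gray_image()].
#' @param threshold_method `"otsu"` (inter-class-variance maximizer on a
#'   256-bin histogram), `"fixed"` (explicit `value` on the image's
#'   intensity scale), or `"adaptive"` (local mean over a Gaussian window of
#'   sigma `value` px, default 1/8 of the smaller image side).
#' @param value threshold intensity (fixed) or window sigma (adaptive).
#' @param fill_holes fill interior holes of each component.
#' @return object of class `binary_image`: list with logical `mask`
#'   (TRUE = particle), `pixel_size`, `modality`; attribute `degenerate` is
#'   TRUE (with a warning) when the mask is all-foreground/all-background.
#' @export
binarize <- function(image, threshold_method = c("otsu", "fixed", "adaptive"),
                     value = NULL, fill_holes = TRUE) {
  stopifnot(inherits(image, "gray_image"))
  threshold_method <- match.arg(threshold_method)
  px <- image$pixels
  rng <- range(px)
  dark_particles <- image$modality == "bright_field"

  if (threshold_method == "adaptive") {
    sigma <- value %||% (min(dim(px)) / 8)
    local_mean <- EBImage::gblur(px, sigma = sigma)
    fg <- if (dark_particles) px < local_mean else px > local_mean
  } else {
    thr <- switch(threshold_method,
      otsu = {
        if (rng[2L] > rng[1L]) {
          scaled <- (px - rng[1L]) / (rng[2L] - rng[1L])
          t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                               levels = 256L)
          rng[1L] + t01 * (rng[2L] - rng[1L])
        } else rng[1L]
      },
      fixed = {
        if (is.null(value)) stop("fixed thresholding needs a value")
        if (value < rng[1L] || value > rng[2L])
          stop("fixed threshold outside the image intensity range")
        value
      }
    )
    fg <- if (dark_particles) px < thr else px > thr
  }

  mask <- matrix(fg, nrow(px), ncol(px))
  if (fill_holes) mask <- EBImage::fillHull(mask * 1L) > 0
  degenerate <- all(mask) || !any(mask)
  if (degenerate) warning("binarization produced an all-foreground or ",
                          "all-background mask")
  structure(list(mask = mask, pixel_size = image$pixel_size,
                 modality = image$modality),
            class = "binary_image", degenerate = degenerate)
}

#' Extract closed particle contours from a binary mask
#'
#' Connected foreground components are labelled and their outer boundaries
#' traced (Moore neighborhood following); components touching the image
#' border are excluded (their shape is unmeasurable), as are components
#' below `min_area`. Each traced boundary passes through boundary pixel
#' centers, which under-measures the enclosed area by about half a pixel of
#' perimeter; contours are therefore rescaled uniformly about their centroid
#' so the polygon area equals the component's pixel count, an unbiased area
#' measure for compact shapes.
#'
#' @param binary a [binarize()] result (or a logical matrix).
#' @param min_area minimum component area in px^2.
#' @return list of [as_contour()] objects, each carrying attributes
#'   `id` (component label) and `area_px` (pixel-count area). An empty list
#'   is a valid result.
#' @export
extract_contours <- function(binary, min_area = 20) {
  mask <- if (inherits(binary, "binary_image")) binary$mask else binary
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n == 0L) return(list())
  nr <- nrow(lab); nc <- ncol(lab)
  border_labels <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- setdiff(which(areas >= min_area), border_labels)
  if (length(keep) == 0L) return(list())
  tr <- EBImage::ocontour(lab)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    oc <- tr[[k]]
    # ocontour returns 0-based (row, col); convert to (x, y) 1-based
    cc <- as_contour(cbind(oc[, 2L] + 1, oc[, 1L] + 1), id = k)
    s <- sqrt(areas[k] / contour_area(cc))
    cc <- scale_contour(cc, s, s)
    attr(cc, "area_px") <- areas[k]
    out[[i]] <- cc
  }
  out
}

#' Triage contours into isolated particles, aggregates and debris
#'
#' Isolated convex particles have solidity (area / convex-hull area) near
#' 1; fused or aggregated blobs are markedly less solid or larger than any
#' plausible single particle, and sub-threshold specks are debris. Every
#' input contour lands in exactly one bucket.
#'
#' @param contours list of contours.
#' @param solidity_min minimum solidity for an isolated particle.
#' @param size_bounds `c(min, max)` acceptable single-particle area, px^2.
#' @return list with elements `isolated`, `aggregated`, `rejected`.
#' @export
triage <- function(contours, solidity_min = 0.95,
                   size_bounds = c(20, Inf)) {
  stopifnot(solidity_min > 0, solidity_min <= 1, length(size_bounds) == 2L)
  iso <- agg <- rej <- list()
  for (cc in contours) {
    a <- attr(cc, "area_px") %||% contour_area(cc)
    if (a < size_bounds[1L]) {
      rej <- c(rej, list(cc))
    } else if (a <= size_bounds[2L] && contour_solidity(cc) >= solidity_min) {
      iso <- c(iso, list(cc))
    } else {
      agg <- c(agg, list(cc))
    }
  }
  list(isolated = iso, aggregated = agg, rejected = rej)
}
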