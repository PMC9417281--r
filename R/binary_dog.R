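#' Sign-of-curvature binarization (binary difference-of-Gaussians)
#'
#' At nanometer resolution, thickness contrast makes particle interiors
#' regions where the intensity Laplacian has definite sign. The
#' difference-of-Gaussians operator \eqn{G(\sigma) - G(\rho\sigma)}
#' approximates the (negated, scaled) Laplacian; thresholding its sign
#' yields a mask that covers particle interiors and edges while the narrow
#' gaps between touching particles flip sign — which is what lets template
#' fitting separate aggregates. Bright-field particles are intensity
#' valleys, so the particle-interior sign is negative; dark-field inverts.
#'
#' @param image a [gray_image()].
#' @param sigma inner Gaussian width in px (> 0). A good default is 5% of
#'   the median isolated-particle diameter, which the pipeline computes for
#'   you ([run_aggregates()]).
#' @param ratio outer/inner sigma ratio (> 1); 1.6 approximates the
#'   Laplacian-of-Gaussian.
#' @param magnitude_floor responses weaker than `magnitude_floor` times the
#'   image-wide median absolute DoG response are not counted, whatever
#'   their sign: in signal-free background the sign of the (band-passed)
#'   noise is a fair coin, while particle edges respond far above the noise
#'   scale. Set to 0 for the pure sign map.
#' @param fill_holes fill enclosed holes of the thresholded mask. Off by
#'   default, and deliberately so for fitting: the informative structure is
#'   the strong edge band plus the white creases separating touching
#'   particles; filling seals the crease junctions inside multi-particle
#'   clumps and invites "bridge" fits straddling two particles.
#' @return object of class `binary_dog`: logical `mask` (TRUE where the DoG
#'   response has the particle-interior sign), `anti_mask` (TRUE where it
#'   has the strong *opposite* sign — the white creases separating touching
#'   particles), `dog` (the raw response), `sigma`, `ratio`, `tau`,
#'   `modality`.
#' @export
compute_binary_dog <- function(image, sigma, ratio = 1.6,
                               magnitude_floor = 3, fill_holes = FALSE) {
  stopifnot(inherits(image, "gray_image"), sigma > 0, ratio > 1)
  px <- image$pixels
  dog <- EBImage::gblur(px, sigma = sigma) -
         EBImage::gblur(px, sigma = ratio * sigma)
  tau <- magnitude_floor * stats::median(abs(dog))
  mask <- if (image$modality == "bright_field") dog < -tau else dog > tau
  mask <- matrix(mask, nrow(px), ncol(px))
  anti <- if (image$modality == "bright_field") dog > tau else dog < -tau
  if (fill_holes && any(mask)) mask <- EBImage::fillHull(mask * 1L) > 0
  structure(list(mask = mask, anti_mask = matrix(anti, nrow(px), ncol(px)),
                 dog = dog, sigma = sigma, ratio = ratio, tau = tau,
                 modality = image$modality),
            class = "binary_dog")
}

#' @export
print.binary_dog <- function(x, ...) {
  cat(sprintf("<binary_dog> %d x %d px, sigma %.2f, ratio %.2f, %.1f%% set\n",
              nrow(x$mask), ncol(x$mask), x$sigma, x$ratio,
              100 * mean(x$mask)))
  invisible(x)
}

#' Average a set of same-class contours into a shape template
#'
#' Each contour is scaled to unit area, centered, rotated to canonical
#' principal orientation and resampled to `M` equal arc-length points.
#' Residual alignment (start-point phase and any n-fold symmetry ambiguity)
#' is resolved by maximal angular cross-correlation against the first
#' contour, treating the boundary as a complex signal z = x + iy: for every
#' cyclic shift the optimal residual rotation is available in closed form,
#' so the global (shift, rotation) optimum is found exactly. The pointwise
#' mean is then Fourier low-passed at `fourier_cutoff` harmonics and
#' renormalized to unit area.
#'
#' @param contours non-empty list of contours of one shape class.
#' @param M number of template boundary points.
#' @param fourier_cutoff highest harmonic retained in the smoothed mean.
#' @param class_label label stored on the template.
#' @return object of class `shape_template`: unit-area `contour` (M points,
#'   canonical orientation), `class_label`, `source_count`.
#' @export
average_contour <- function(contours, M = 256L, fourier_cutoff = 32L,
                            class_label = NULL) {
  if (length(contours) == 0L) stop("need at least one contour to average")
  canon <- purrr::map(contours, function(cc) {
    cc <- normalize_contour(cc)
    ori <- principal_orientation(cc)
    if (!isTRUE(attr(ori, "isotropic"))) {
      cc <- rotate_contour(cc, -as.numeric(ori), center = c(0, 0))
    }
    resample_contour(cc, M)
  })
  zs <- purrr::map(canon, function(cc) {
    complex(real = cc[, 1L], imaginary = cc[, 2L])
  })
  ref <- zs[[1L]]
  aligned <- purrr::map(zs, align_complex_contour, ref = ref)
  zbar <- Reduce(`+`, aligned) / length(aligned)
  mean_c <- fourier_smooth_contour(as_contour(cbind(Re(zbar), Im(zbar))),
                                   cutoff = fourier_cutoff)
  mean_c <- normalize_contour(mean_c)
  structure(list(contour = mean_c, class_label = class_label,
                 source_count = length(contours),
                 area_px = stats::median(vapply(contours, function(cc) {
                   attr(cc, "area_px") %||% contour_area(cc)
                 }, numeric(1L)))),
            class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("<shape_template> '%s': %d points from %d contours\n",
              x$class_label %||% "?", nrow(x$contour), x$source_count))
  invisible(x)
}

#' Rotational symmetry order of a contour
#'
#' Largest m in 2..`max_order` such that rotating the (unit-area, centered)
#' contour by 2*pi/m reproduces it, judged by the residual after the best
#' cyclic re-parameterization; 1 if no symmetry is found. Used to reduce
#' the rotation search range in template fitting.
#'
#' @param contour a contour.
#' @param max_order highest order tested.
#' @param tol mean-residual tolerance relative to the contour's RMS radius.
#' @return integer symmetry order.
#' @export
contour_symmetry_order <- function(contour, max_order = 8L, tol = 0.04) {
  cc <- resample_contour(normalize_contour(contour), 256L)
  z <- complex(real = cc[, 1L], imaginary = cc[, 2L])
  scale <- sqrt(mean(Mod(z)^2))
  n <- length(z)
  fz <- stats::fft(z)
  for (m in max_order:2) {
    zr <- z * exp(2i * pi / m)
    # best cyclic shift without any compensating rotation
    corr <- stats::fft(stats::fft(zr) * Conj(fz), inverse = TRUE) / n
    s <- which.max(Re(corr))
    zs <- if (s == 1L) zr else c(zr[s:n], zr[seq_len(s - 1L)])
    if (sqrt(mean(Mod(zs - z)^2)) < tol * scale) return(m)
  }
  1L
}

# align complex boundary z to ref over cyclic shift + global rotation:
# maximize Re(conj(phase) * corr_s); optimal phase has modulus 1, so pick
# the shift with max |corr_s| and rotate by -Arg(corr_s).
align_complex_contour <- function(z, ref) {
  n <- length(z)
  # corr_s = sum_j z_{j+s} * Conj(ref_j) for all s, via FFT
  corr <- stats::fft(stats::fft(z) * Conj(stats::fft(ref)), inverse = TRUE) / n
  s <- which.max(Mod(corr))
  zc <- if (s == 1L) z else c(z[s:n], z[seq_len(s - 1L)])
  zc * exp(-1i * Arg(corr[s]))
}

#' Overlap of a contour ring with a mask, for every translation at once
#'
#' Computes \eqn{score(t) = |ring \cap mask_{shifted}| / |ring|} for every
#' integer translation via the convolution theorem: one FFT
#' cross-correlation replaces the full sliding scan, and the result equals
#' the brute-force overlap everywhere (the correlation is rounded to the
#' underlying integer counts, so FFT roundoff cannot leak in). Translations
#' are circular; callers pad the mask if wrap-around matters.
#'
#' @param ring_mask logical/0-1 matrix, the rasterized contour ring placed
#'   anywhere in an array of the same size as `bdog_mask`.
#' @param bdog_mask logical/0-1 matrix, the binary DoG (or any) mask.
#' @return numeric matrix of scores in \[0, 1\]; entry `[i, j]` is the score
#'   for shifting the ring by `(i-1, j-1)` rows/cols (circularly).
#' @export
fft_overlap_scan <- function(ring_mask, bdog_mask) {
  R <- ring_mask * 1; Mm <- bdog_mask * 1
  if (!all(dim(R) == dim(Mm))) stop("ring and mask arrays must match in size")
  nring <- sum(R)
  if (nring == 0) return(matrix(0, nrow(R), ncol(R)))
  corr <- stats::fft(Conj(stats::fft(R)) * stats::fft(Mm), inverse = TRUE) /
    length(R)
  pmin(pmax(round(Re(corr)) / nring, 0), 1)
}

#' Fit affine-transformed shape templates to a binary DoG mask
#'
#' The workhorse for identifying touching/connected/aggregated particles.
#' Each template (unit area) is scaled to the expected particle area and
#' placed under a grid of affine poses — rotation, per-axis scale, skew,
#' each within bounds — and for every pose the translation dimension is
#' solved exactly and exhaustively by [fft_overlap_scan()]. A pose's score
#' is the fraction of its rasterized contour ring covered by the mask; an
#' optimal fit has its ring entirely within the mask.
#'
#' Acceptance is greedy with region claiming: candidates are ordered by
#' score (ties broken toward larger fitted area, so a full-size fit beats a
#' shrunken one inside the same blob), and each accepted fit removes its
#' interior from the working mask before the remaining candidates are
#' rescored. This suppresses both duplicate poses and spurious small fits
#' inside already-claimed aggregate interiors.
#'
#' @param bdog a [compute_binary_dog()] result (or logical mask matrix).
#' @param templates list of [average_contour()] templates (or a single one).
#' @param base_area_px expected single-particle area in px^2; template
#'   scale 1 corresponds to this area. `NULL` (default) uses each
#'   template's own source median area, so each shape class is searched at
#'   its own size.
#' @param rotations rotation grid, radians. `NULL` (default) builds a
#'   `rot_step` grid over one rotational-symmetry period of each template
#'   (a 6-fold template only needs 0..60 degrees).
#' @param rot_step rotation grid step, radians, used when `rotations` is
#'   `NULL`.
#' @param scales per-axis scale grid applied as `s_x`, `s_y` (all pairs).
#' @param skews shear grid (x-shear coefficient).
#' @param score_min minimum acceptable ring-coverage score, in (0, 1].
#' @param max_fits cap on the number of accepted fits.
#' @param ring_width rasterized ring width, px.
#' @param mask_open radius of a morphological opening applied to the mask
#'   before fitting; removes the isolated-pixel sign noise a flat noisy
#'   background produces while leaving solid particle interiors intact.
#' @param mask_dilate tolerance dilation of the working mask, px
#'   (Chebyshev radius). The sign mask ends exactly at the particle edge,
#'   so a correctly scaled ring straddles it; dilating by the ring
#'   half-width admits the true pose without admitting grossly inflated
#'   ones.
#' @param scale_penalty prior penalty per unit
#'   `|ln s_x| + |ln s_y| + |skew|` in the candidate-ranking functional
#'   (see Details); expresses that particles are near the expected size.
#' @param crease_penalty evidence penalty per opposite-sign (crease) pixel
#'   inside the fitted contour. A correct fit never contains a separating
#'   crease; a fit bridging two touching particles does, which is what
#'   makes this term the decisive discriminator inside aggregates. Only
#'   available when `bdog` is a full [compute_binary_dog()] result.
#' @param suppress_iou maximum filled-area IoU allowed between accepted
#'   fits.
#' @return a tibble, one row per accepted fit: `template_label`, `tx`,
#'   `ty` (fitted centroid, px), `rotation`, `s_x`, `s_y`, `skew`, `score`,
#'   and a `contour` list-column with the fitted contour.
#' @export
fit_templates <- function(bdog, templates, base_area_px = NULL,
                          rotations = NULL, rot_step = 3 * pi / 180,
                          scales = c(0.9, 1, 1.1),
                          skews = 0,
                          score_min = 0.75, max_fits = Inf, ring_width = 2,
                          mask_open = 0, mask_dilate = 1,
                          scale_penalty = 0.2, crease_penalty = 2,
                          suppress_iou = 0.2) {
  mask <- if (inherits(bdog, "binary_dog")) bdog$mask else bdog
  anti <- if (inherits(bdog, "binary_dog")) bdog$anti_mask else NULL
  if (inherits(templates, "shape_template")) templates <- list(templates)
  stopifnot(length(templates) >= 1L, score_min > 0, score_min <= 1)
  areas <- vapply(templates, function(tpl) {
    a <- base_area_px %||% tpl$area_px
    if (is.null(a) || !is.finite(a) || a <= 0) {
      stop("no base area: supply base_area_px or templates with area_px")
    }
    a
  }, numeric(1L))
  if ((!is.null(rotations) && any(!is.finite(rotations))) ||
      any(!is.finite(c(scales, skews))) ||
      any(scales <= 0)) stop("degenerate affine search bounds")
  nr <- nrow(mask); nc <- ncol(mask)
  empty <- tibble::tibble(template_label = character(), tx = numeric(),
                          ty = numeric(), rotation = numeric(),
                          s_x = numeric(), s_y = numeric(), skew = numeric(),
                          score = numeric(), contour = list())
  if (!any(mask)) return(empty)
  if (mask_open > 0) {
    # opening removes the salt-and-pepper sign noise of flat background
    # while leaving solid particle interiors intact
    br <- EBImage::makeBrush(2L * mask_open + 1L, "box")
    mask <- EBImage::dilate(EBImage::erode(mask * 1, br), br) > 0
  }
  if (mask_dilate > 0) {
    mask <- EBImage::dilate(mask * 1,
                            EBImage::makeBrush(2L * mask_dilate + 1L,
                                               "box")) > 0
  }
  if (!any(mask)) return(empty)
  fftM <- stats::fft(mask * 1)
  rot_grids <- purrr::map(templates, function(tpl) {
    if (!is.null(rotations)) return(rotations)
    m <- contour_symmetry_order(tpl$contour)
    period <- 2 * pi / max(m, 1L)
    seq(0, period - 1e-9, by = rot_step)
  })

  # phase 1: exhaustive pose grid; translation solved by FFT scan.
  # Candidates are recorded as lightweight pose rows.
  hits_list <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    base <- unclass(tpl$contour) * sqrt(areas[ti])
    # dense boundary samples computed once; affine maps keep them dense
    per <- sum(sqrt(rowSums(diff(rbind(base, base[1L, ]))^2)))
    dense_base <- unclass(resample_contour(as_contour(base),
                                           max(ceiling(per / 0.3), 64L)))
    for (rot in rot_grids[[ti]]) for (sx in scales) for (sy in scales)
      for (sk in skews) {
        A <- pose_matrix(rot, sx, sy, sk)
        ring <- rasterize_ring(dense_base %*% t(A), nr, nc,
                               width = ring_width)
        if (is.null(ring)) next
        nring <- nrow(ring$yx0)
        corr <- stats::fft(Conj(stats::fft(ring$arr)) * fftM,
                           inverse = TRUE) / (nr * nc)
        score_map <- pmin(pmax(round(Re(corr)) / nring, 0), 1)
        # invalidate translations that would wrap the ring around the array
        rh <- max(ring$yx0[, 1L]); rw <- max(ring$yx0[, 2L])
        if (rh > 1L) score_map[nr - seq_len(rh - 1L) + 1L, ] <- 0
        if (rw > 1L) score_map[, nc - seq_len(rw - 1L) + 1L] <- 0
        hits <- find_peaks(score_map, score_min,
                           r_sup = 0.5 * sqrt(areas[ti] / pi),
                           max_peaks = 8L)
        for (h in seq_len(nrow(hits))) {
          hits_list[[length(hits_list) + 1L]] <-
            c(ti, rot, sx, sy, sk, hits[h, 1L] - 1, hits[h, 2L] - 1,
              hits[h, 3L],
              ring$centroid[1L] + hits[h, 2L] - 1,  # tx
              ring$centroid[2L] + hits[h, 1L] - 1,  # ty
              nring)
        }
      }
  }
  if (length(hits_list) == 0L) return(empty)
  H <- do.call(rbind, hits_list)
  colnames(H) <- c("ti", "rot", "sx", "sy", "sk", "dy", "dx", "score0",
                   "tx", "ty", "nring")

  # phase 2: thin near-duplicates, keeping the best per (template, 4px cell).
  # Ranking is by signed boundary evidence: covered ring pixels minus
  # uncovered ones. Unlike raw precision it compares across template sizes
  # (a full-size ring explaining the whole edge band beats a smaller
  # template's ring hiding inside thick black) and across scales (an
  # inflated ring accumulates uncovered pixels fast), with a mild
  # scale/skew prior on top.
  cand_eff <- function(score, nring, sx, sy, sk) {
    nring * (2 * score - 1 -
               scale_penalty * (abs(log(sx)) + abs(log(sy)) + abs(sk)))
  }
  eff0 <- cand_eff(H[, "score0"], H[, "nring"], H[, "sx"], H[, "sy"],
                   H[, "sk"])
  key <- sprintf("%d_%d_%d", H[, "ti"], round(H[, "tx"] / 4),
                 round(H[, "ty"] / 4))
  ord <- order(eff0, decreasing = TRUE)
  H <- H[ord[!duplicated(key[ord])], , drop = FALSE]
  if (nrow(H) > 300L) H <- H[seq_len(300L), , drop = FALSE]

  # phase 3: rebuild geometry for the surviving candidates only
  bases <- purrr::map(seq_along(templates), function(ti) {
    base <- unclass(templates[[ti]]$contour) * sqrt(areas[ti])
    per <- sum(sqrt(rowSums(diff(rbind(base, base[1L, ]))^2)))
    list(base = base,
         dense = unclass(resample_contour(as_contour(base),
                                          max(ceiling(per / 0.3), 64L))))
  })
  cand <- purrr::map(seq_len(nrow(H)), function(i) {
    r <- H[i, ]
    tpl <- templates[[r[["ti"]]]]
    A <- pose_matrix(r[["rot"]], r[["sx"]], r[["sy"]], r[["sk"]])
    poly <- bases[[r[["ti"]]]]$base %*% t(A)
    ring <- rasterize_ring(bases[[r[["ti"]]]]$dense %*% t(A), nr, nc,
                           width = ring_width)
    cc <- list(template = r[["ti"]],
               label = tpl$class_label %||% as.character(r[["ti"]]),
               rot = r[["rot"]], sx = r[["sx"]], sy = r[["sy"]],
               sk = r[["sk"]],
               score0 = r[["score0"]], tx = r[["tx"]], ty = r[["ty"]],
               ring_yx = cbind(ring$yx0[, 1L] + r[["dy"]],
                               ring$yx0[, 2L] + r[["dx"]]),
               poly = poly)
    cc$anti_n <- if (is.null(anti)) 0 else {
      # count creases in the deep interior only: a bridge fit straddling
      # two particles has the separating crease near its center, while a
      # correct fit of a slightly overlapping particle has only shallow
      # fringe from the overlap lens near its boundary
      fp <- fitted_polygon(cc)
      sum(anti[fill_polygon_idx(scale_polygon(fp, 0.7), nr, nc)])
    }
    cc
  })

  # greedy acceptance with mask claiming
  work <- mask
  accepted <- list()
  cand_score <- vapply(cand, function(cc) ring_score(cc$ring_yx, work, nr, nc),
                       numeric(1L))
  cand_area <- vapply(cand, function(cc) abs(shoelace_area(cc$poly)),
                      numeric(1L))
  cand_nring <- vapply(cand, function(cc) nrow(cc$ring_yx), numeric(1L))
  cand_sc_pen <- vapply(cand, function(cc) {
    scale_penalty * (abs(log(cc$sx)) + abs(log(cc$sy)) + abs(cc$sk))
  }, numeric(1L))
  cand_anti <- vapply(cand, function(cc) cc$anti_n, numeric(1L))
  alive <- rep(TRUE, length(cand))
  while (length(accepted) < max_fits && any(alive)) {
    alive[alive] <- cand_score[alive] >= score_min
    if (!any(alive)) break
    eff <- ifelse(alive,
                  cand_nring * (2 * cand_score - 1 - cand_sc_pen) -
                    crease_penalty * cand_anti, -Inf)
    best <- which(eff == max(eff))
    best <- best[which.max(cand_area[best])]
    cc <- cand[[best]]
    alive[best] <- FALSE
    fitted <- fitted_polygon(cc)
    # overlap suppression against already accepted fits
    clash <- any(vapply(accepted, function(a) {
      polygon_iou(fitted, a$fitted) > suppress_iou
    }, logical(1L)))
    if (clash) next
    accepted[[length(accepted) + 1L]] <-
      list(cand = cc, fitted = fitted, score = cand_score[best])
    # claim: clear the fitted interior (shrunk by the ring width) and rescore
    shrink <- max(1 - ring_width / sqrt(cand_area[best] / pi), 0.5)
    claim <- fill_polygon_idx(scale_polygon(fitted, shrink), nr, nc)
    if (length(claim)) work[claim] <- FALSE
    for (i in which(alive)) {
      cand_score[i] <- ring_score(cand[[i]]$ring_yx, work, nr, nc)
    }
  }

  if (length(accepted) == 0L) return(empty)
  dplyr::bind_rows(purrr::map(accepted, function(a) {
    cc <- a$cand
    tibble::tibble(template_label = cc$label, tx = cc$tx, ty = cc$ty,
                   rotation = cc$rot, s_x = cc$sx, s_y = cc$sy,
                   skew = cc$sk, score = a$score,
                   contour = list(as_contour(a$fitted)))
  }))
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# affine pose: rotation after anisotropic scaling with x-shear
pose_matrix <- function(rot, sx, sy, sk) {
  rot_mat(rot) %*% matrix(c(sx, 0, sk * sy, sy), 2L, 2L)
}

# Rasterize a closed polygon boundary (centered near origin, already
# densely sampled) as a ~width px ring in an nr x nc array anchored at the
# top-left; returns the array, the ring pixel (row, col) list at zero
# shift, and the polygon centroid position within the array.
rasterize_ring <- function(dense, nr, nc, width = 2) {
  # shift so the ring sits tight against the top-left corner
  offx <- 1 - floor(min(dense[, 1L])); offy <- 1 - floor(min(dense[, 2L]))
  xs <- dense[, 1L] + offx; ys <- dense[, 2L] + offy
  if (max(xs) + 1 > nc || max(ys) + 1 > nr) return(NULL) # ring larger than image
  px <- c(floor(xs), floor(xs) + 1L, floor(xs), floor(xs) + 1L)
  py <- c(floor(ys), floor(ys), floor(ys) + 1L, floor(ys) + 1L)
  if (width > 2) { # widen by one more pixel ring
    px <- c(px, floor(xs) - 1L, floor(xs), floor(xs) + 2L)
    py <- c(py, floor(ys), floor(ys) - 1L, floor(ys))
  }
  keep <- px >= 1L & px <= nc & py >= 1L & py <= nr
  yx <- unique(cbind(py[keep], px[keep]))
  arr <- matrix(0, nr, nc)
  arr[yx] <- 1
  cen <- contour_centroid(as_contour(cbind(xs, ys)))
  list(arr = arr, idx = which(arr > 0), yx0 = yx,
       centroid = c(cen[["x"]], cen[["y"]]))
}

# score of a ring (list of (row, col) at current shift) against a mask,
# with circular wrapping to match the FFT scan convention
ring_score <- function(yx, mask, nr, nc) {
  ry <- ((yx[, 1L] - 1L) %% nr) + 1L
  rx <- ((yx[, 2L] - 1L) %% nc) + 1L
  mean(mask[cbind(ry, rx)])
}

fitted_polygon <- function(cc) {
  # candidate polygon in absolute image coordinates
  p <- cc$poly
  cen_now <- contour_centroid(as_contour(p))
  sweep(p, 2L, c(cc$tx, cc$ty) - c(cen_now[["x"]], cen_now[["y"]]), "+")
}

scale_polygon <- function(poly, s) {
  cen <- contour_centroid(as_contour(poly))
  sweep(sweep(poly, 2L, c(cen[["x"]], cen[["y"]])) * s, 2L,
        c(cen[["x"]], cen[["y"]]), "+")
}

# linear indices of pixels inside a polygon
fill_polygon_idx <- function(poly, nr, nc) {
  x0 <- max(1L, floor(min(poly[, 1L]))); x1 <- min(nc, ceiling(max(poly[, 1L])))
  y0 <- max(1L, floor(min(poly[, 2L]))); y1 <- min(nr, ceiling(max(poly[, 2L])))
  if (x0 > x1 || y0 > y1) return(integer(0))
  gx <- x0:x1; gy <- y0:y1
  pts_x <- rep(gx, each = length(gy)); pts_y <- rep(gy, times = length(gx))
  inside <- pracma::inpolygon(pts_x, pts_y, poly[, 1L], poly[, 2L])
  (pts_x[inside] - 1L) * nr + pts_y[inside]
}

#' Filled-area intersection-over-union of two polygons
#' @param a,b polygons (contours or 2-column matrices) in a shared
#'   coordinate frame.
#' @param resolution rasterization step, px.
#' @return IoU in \[0, 1\].
#' @export
polygon_iou <- function(a, b, resolution = 1) {
  a <- unclass(a); b <- unclass(b)
  if (min(a[, 1L]) > max(b[, 1L]) || min(b[, 1L]) > max(a[, 1L]) ||
      min(a[, 2L]) > max(b[, 2L]) || min(b[, 2L]) > max(a[, 2L])) {
    return(0) # disjoint bounding boxes
  }
  # decimate dense boundaries: rasterized IoU is insensitive to vertex count
  if (nrow(a) > 64L) a <- a[round(seq(1L, nrow(a), length.out = 65L))[-65L], ]
  if (nrow(b) > 64L) b <- b[round(seq(1L, nrow(b), length.out = 65L))[-65L], ]
  x0 <- floor(min(a[, 1L], b[, 1L])); x1 <- ceiling(max(a[, 1L], b[, 1L]))
  y0 <- floor(min(a[, 2L], b[, 2L])); y1 <- ceiling(max(a[, 2L], b[, 2L]))
  gx <- seq(x0, x1, by = resolution); gy <- seq(y0, y1, by = resolution)
  pts_x <- rep(gx, each = length(gy)); pts_y <- rep(gy, times = length(gx))
  ina <- pracma::inpolygon(pts_x, pts_y, a[, 1L], a[, 2L])
  inb <- pracma::inpolygon(pts_x, pts_y, b[, 1L], b[, 2L])
  un <- sum(ina | inb)
  if (un == 0L) return(0)
  sum(ina & inb) / un
}

# peak picking on a score map: iteratively take the max >= thresh and
# suppress a disc of radius r_sup around it
find_peaks <- function(score_map, thresh, r_sup, max_peaks = 8L) {
  out <- matrix(numeric(0), 0L, 3L)
  sm <- score_map
  nr <- nrow(sm); nc <- ncol(sm)
  for (i in seq_len(max_peaks)) {
    m <- max(sm)
    if (m < thresh) break
    ij <- which(sm == m, arr.ind = TRUE)[1L, ]
    out <- rbind(out, c(ij[1L], ij[2L], m))
    y0 <- max(1L, ij[1L] - ceiling(r_sup)); y1 <- min(nr, ij[1L] + ceiling(r_sup))
    x0 <- max(1L, ij[2L] - ceiling(r_sup)); x1 <- min(nc, ij[2L] + ceiling(r_sup))
    sm[y0:y1, x0:x1] <- -Inf
  }
  out
}
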