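#' Assemble and validate a run configuration
#'
#' Central parameter record for the staged pipeline. All physical
#' parameters are validated up front; the configuration is serialized
#' verbatim into the output directory for provenance on every run.
#'
#' @param input path to a TIFF/PNG micrograph (optional when an image object
#'   is passed to the run functions directly).
#' @param pixel_size nm per pixel.
#' @param modality `"bright_field"` or `"dark_field"`.
#' @param denoise_method `"fourier_lowpass"`, `"gaussian"`, or `"none"`.
#' @param denoise_cutoff cutoff for [denoise()].
#' @param threshold_method passed to [binarize()].
#' @param threshold_value passed to [binarize()].
#' @param min_area minimum component area, px^2.
#' @param solidity_min isolated/aggregated triage threshold.
#' @param size_max maximum single-particle area, px^2 (Inf = no cap).
#' @param n_hu number of Hu invariants used as features.
#' @param K_max largest class count considered.
#' @param criterion class-count selection criterion, see [select_classes()].
#' @param prune_weight minimum retained component weight.
#' @param dog_sigma_frac binary-DoG inner sigma as a fraction of the median
#'   isolated-particle diameter.
#' @param dog_ratio DoG outer/inner sigma ratio.
#' @param fit_score_min minimum template-fit score.
#' @param fit_scales,fit_skews,fit_rot_step_deg affine search grid.
#' @param seed integer master seed for all stochastic steps.
#' @param out_dir output directory (`NULL` = return results only).
#' @return a validated `run_config` list.
#' @export
run_config <- function(input = NULL, pixel_size = 1,
                       modality = c("bright_field", "dark_field"),
                       denoise_method = "gaussian", denoise_cutoff = 1.5,
                       threshold_method = "otsu", threshold_value = NULL,
                       min_area = 50, solidity_min = 0.95, size_max = Inf,
                       n_hu = 2L, K_max = 5L, criterion = "icl",
                       prune_weight = 0.01,
                       dog_sigma_frac = 0.05, dog_ratio = 1.6,
                       fit_score_min = 0.75,
                       fit_scales = c(0.9, 1, 1.1),
                       fit_skews = 0, fit_rot_step_deg = 3,
                       seed = 1L, out_dir = NULL) {
  modality <- match.arg(modality)
  cfg <- list(input = input, pixel_size = pixel_size, modality = modality,
              denoise_method = denoise_method,
              denoise_cutoff = denoise_cutoff,
              threshold_method = threshold_method,
              threshold_value = threshold_value,
              min_area = min_area, solidity_min = solidity_min,
              size_max = size_max, n_hu = as.integer(n_hu),
              K_max = as.integer(K_max), criterion = criterion,
              prune_weight = prune_weight,
              dog_sigma_frac = dog_sigma_frac, dog_ratio = dog_ratio,
              fit_score_min = fit_score_min, fit_scales = fit_scales,
              fit_skews = fit_skews, fit_rot_step_deg = fit_rot_step_deg,
              seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  pos <- c("pixel_size", "denoise_cutoff", "min_area", "solidity_min",
           "dog_sigma_frac", "dog_ratio", "fit_score_min")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0))) {
      stop("config field '", f, "' must be positive")
    }
  }
  if (cfg$solidity_min > 1 || cfg$fit_score_min > 1) {
    stop("solidity_min and fit_score_min must be <= 1")
  }
  if (cfg$K_max < 1L) stop("K_max must be >= 1")
  if (!cfg$denoise_method %in% c("fourier_lowpass", "gaussian", "none")) {
    stop("unknown denoise_method")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_config_provenance <- function(cfg, dir) {
  y <- cfg
  y$size_max <- if (is.infinite(y$size_max)) ".inf" else y$size_max
  yaml::write_yaml(y[!vapply(y, is.null, logical(1L))],
                   file.path(dir, "config.yaml"))
}

#' Run the isolated-particle analysis pipeline
#'
#' Executes preprocess -> descriptors -> soft classification -> summary on
#' one micrograph: denoise, binarize, extract contours, triage; compute the
#' log-Hu descriptor table for isolated particles; select the class count
#' and soft-assign; summarize per class. Aggregated contours are routed to
#' a manifest for [run_aggregates()]. With an `out_dir` in the config, all
#' stage outputs are written as plain CSV/YAML, and identical config + seed
#' gives byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param image optional [gray_image()] or `synthetic_scene` (overrides
#'   `config$input`).
#' @return an `analysis_result` list: `image`, `binary`, `triaged`,
#'   `descriptors`, `classification`, `summary`, `config`.
#' @export
run_analyze <- function(config, image = NULL) {
  stopifnot(inherits(config, "run_config"))
  img <- resolve_image(config, image)
  den <- if (config$denoise_method == "none") img else {
    denoise(img, config$denoise_method, config$denoise_cutoff)
  }
  bin <- binarize(den, config$threshold_method, config$threshold_value)
  contours <- extract_contours(bin, min_area = config$min_area)
  tri <- triage(contours, solidity_min = config$solidity_min,
                size_bounds = c(config$min_area, config$size_max))

  n_iso <- length(tri$isolated)
  if (n_iso == 0L) {
    desc <- shape_descriptors(list(), pixel_size = config$pixel_size)
    classification <- NULL
    summary <- tibble::tibble(k = integer(), sigma = numeric(),
                              fraction = numeric(), diam_mean = numeric(),
                              diam_sd = numeric(), ar_mean = numeric(),
                              ar_sd = numeric())
  } else {
    desc <- shape_descriptors(tri$isolated, pixel_size = config$pixel_size,
                              n_hu = config$n_hu)
    feature_cols <- paste0("logH", seq_len(config$n_hu))
    K_cap <- min(config$K_max,
                 max(1L, (n_iso - 1L) %/% config$n_hu))
    classification <- classify_shapes(desc, feature_cols = feature_cols,
                                      K_max = K_cap,
                                      criterion = config$criterion,
                                      prune_weight = config$prune_weight,
                                      seed = config$seed)
    summary <- class_summary(classification, desc)
  }

  res <- structure(list(image = den, binary = bin, triaged = tri,
                        descriptors = desc, classification = classification,
                        summary = summary, config = config),
                   class = "analysis_result")
  if (!is.null(config$out_dir)) write_analysis(res, config$out_dir)
  res
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf(paste0("<analysis_result> %d isolated / %d aggregated / ",
                     "%d rejected contours; K = %s\n"),
              length(x$triaged$isolated), length(x$triaged$aggregated),
              length(x$triaged$rejected),
              if (is.null(x$classification)) "-" else
                ncol(x$classification$responsibilities)))
  invisible(x)
}

resolve_image <- function(config, image) {
  if (inherits(image, "synthetic_scene")) return(image$image)
  if (inherits(image, "gray_image")) return(image)
  if (is.null(config$input)) stop("no input image: set config$input or pass one")
  if (!file.exists(config$input)) stop("input not readable: ", config$input)
  read_micrograph(config$input, pixel_size = config$pixel_size,
                  modality = config$modality)
}

write_analysis <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_contours_csv(res$triaged$isolated,
                     file.path(dir, "contours_isolated.csv"))
  write_contours_csv(res$triaged$aggregated,
                     file.path(dir, "contours_aggregated.csv"))
  readr::write_csv(res$descriptors, file.path(dir, "descriptors.csv"))
  if (!is.null(res$classification)) {
    readr::write_csv(tidy(res$classification),
                     file.path(dir, "responsibilities.csv"))
  }
  readr::write_csv(res$summary, file.path(dir, "summary.csv"))
  write_config_provenance(res$config, dir)
  invisible(dir)
}

#' Write / read contour vertex tables (one row per vertex)
#' @param contours list of contours.
#' @param path CSV path with columns `particle_id`, `x`, `y`.
#' @return the path (write) or a list of contours (read), invisibly for
#'   write.
#' @export
write_contours_csv <- function(contours, path) {
  df <- purrr::imap_dfr(contours, function(cc, i) {
    tibble::tibble(particle_id = attr(cc, "id") %||% i,
                   x = unname(cc[, 1L]), y = unname(cc[, 2L]))
  })
  if (nrow(df) == 0L) df <- tibble::tibble(particle_id = integer(),
                                           x = numeric(), y = numeric())
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0L) return(list())
  purrr::map(split(df, df$particle_id), function(d) {
    as_contour(cbind(d$x, d$y), id = d$particle_id[1L])
  }) |> unname()
}

#' Write / read a shape template as JSON
#' @param template a [average_contour()] result.
#' @param path JSON path.
#' @return path (write) / `shape_template` (read).
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "shape_template"))
  jsonlite::write_json(list(class_label = template$class_label,
                            source_count = template$source_count,
                            x = unname(template$contour[, 1L]),
                            y = unname(template$contour[, 2L])),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(contour = as_contour(cbind(j$x, j$y)),
                 class_label = j$class_label,
                 source_count = j$source_count),
            class = "shape_template")
}

#' Identify particles in aggregated regions by binary-DoG template fitting
#'
#' Builds one averaged shape template per class from the isolated-particle
#' classification (or takes user-supplied templates), computes the binary
#' DoG of the micrograph (inner sigma = `dog_sigma_frac` of the median
#' isolated-particle diameter), and fits affine-transformed templates
#' inside each aggregated region. The whole-sample summary is recomputed
#' with the fitted particles included.
#'
#' @param config a [run_config()].
#' @param analysis a [run_analyze()] result for the same image.
#' @param templates optional list of [average_contour()] templates; by
#'   default they are built from the isolated particles' hard classes.
#' @param min_class_count smallest hard-class size used to build a
#'   template.
#' @return list with `fits` (tibble as in [fit_templates()], coordinates in
#'   the full image frame), `templates`, `merged_descriptors`,
#'   `merged_summary` (per class: isolated + fitted counts).
#' @export
run_aggregates <- function(config, analysis, templates = NULL,
                           min_class_count = 3L) {
  stopifnot(inherits(config, "run_config"),
            inherits(analysis, "analysis_result"))
  iso <- analysis$triaged$isolated
  if (is.null(templates)) {
    if (is.null(analysis$classification)) {
      stop("no isolated-particle classification available; ",
           "run run_analyze() first or supply templates")
    }
    hard <- analysis$classification$hard_labels
    templates <- purrr::compact(purrr::map(sort(unique(hard)), function(k) {
      members <- iso[hard == k]
      if (length(members) < min_class_count) return(NULL)
      average_contour(members, class_label = as.character(k))
    }))
  }
  if (length(templates) == 0L) stop("no usable shape templates")

  med_diam_px <- stats::median(sqrt(analysis$descriptors$area_px / pi)) * 2
  base_area_px <- stats::median(analysis$descriptors$area_px)
  bdog <- compute_binary_dog(analysis$image,
                             sigma = config$dog_sigma_frac * med_diam_px,
                             ratio = config$dog_ratio)
  rot_step <- config$fit_rot_step_deg * pi / 180
  agg <- analysis$triaged$aggregated
  fits <- purrr::map_dfr(agg, function(cc) {
    pad <- ceiling(med_diam_px * 0.75)
    nr <- nrow(bdog$mask); nc <- ncol(bdog$mask)
    x0 <- max(1L, floor(min(cc[, 1L])) - pad)
    x1 <- min(nc, ceiling(max(cc[, 1L])) + pad)
    y0 <- max(1L, floor(min(cc[, 2L])) - pad)
    y1 <- min(nr, ceiling(max(cc[, 2L])) + pad)
    sub <- structure(list(mask = bdog$mask[y0:y1, x0:x1],
                          anti_mask = bdog$anti_mask[y0:y1, x0:x1],
                          sigma = bdog$sigma, ratio = bdog$ratio,
                          tau = bdog$tau, modality = bdog$modality),
                     class = "binary_dog")
    n_expect <- ceiling((attr(cc, "area_px") %||% contour_area(cc)) /
                          base_area_px) + 1L
    f <- fit_templates(sub, templates,
                       rot_step = rot_step,
                       scales = config$fit_scales,
                       skews = config$fit_skews,
                       score_min = config$fit_score_min,
                       max_fits = n_expect)
    if (nrow(f) == 0L) return(f)
    f$tx <- f$tx + x0 - 1L
    f$ty <- f$ty + y0 - 1L
    f$contour <- purrr::map2(f$contour, seq_len(nrow(f)), function(p, i) {
      shift_contour(p, x0 - 1L, y0 - 1L)
    })
    f
  })

  merged_desc <- analysis$descriptors
  merged_desc$source <- if (nrow(merged_desc)) "isolated" else character(0)
  merged_desc$class_label <- if (nrow(merged_desc)) {
    as.character(analysis$classification$hard_labels)
  } else character(0)
  if (nrow(fits) > 0L) {
    fd <- shape_descriptors(fits$contour, pixel_size = config$pixel_size)
    fd$particle_id <- max(merged_desc$particle_id, 0L) + seq_len(nrow(fd))
    fd$source <- "aggregate_fit"
    fd$class_label <- fits$template_label
    merged_desc <- dplyr::bind_rows(merged_desc, fd)
  }
  merged_summary <- merged_desc |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(n = dplyr::n(),
                     diam_mean = mean(.data$d_eff_nm),
                     diam_sd = stats::sd(.data$d_eff_nm),
                     ar_mean = mean(.data$aspect_ratio),
                     ar_sd = stats::sd(.data$aspect_ratio),
                     .groups = "drop")

  out <- list(fits = fits, templates = templates, binary_dog = bdog,
              merged_descriptors = merged_desc,
              merged_summary = merged_summary)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(dplyr::select(fits, -"contour"),
                     file.path(config$out_dir, "aggregate_fits.csv"))
    write_contours_csv(fits$contour,
                       file.path(config$out_dir, "contours_fitted.csv"))
    readr::write_csv(merged_summary,
                     file.path(config$out_dir, "summary_merged.csv"))
    for (i in seq_along(templates)) {
      write_template(templates[[i]],
                     file.path(config$out_dir,
                               sprintf("template_%s.json",
                                       templates[[i]]$class_label %||% i)))
    }
  }
  out
}

#' Pooled multi-image analysis
#'
#' Runs preprocessing and descriptors per image, pools the descriptor
#' tables (per-image provenance retained in the `image_id` column), then
#' fits a single mixture classification to the pooled feature set.
#'
#' @param config a [run_config()] (shared stage parameters).
#' @param inputs character vector of image paths, or a list of
#'   `gray_image`/`synthetic_scene` objects.
#' @param pixel_sizes optional per-image calibrations; must all be equal
#'   unless `allow_mixed_pixel_size = TRUE`.
#' @param allow_mixed_pixel_size permit pooling across calibrations.
#' @return list: `descriptors` (pooled, with `image_id`),
#'   `classification`, `summary`, `per_image` (list of triage results).
#' @export
run_batch <- function(config, inputs, pixel_sizes = NULL,
                      allow_mixed_pixel_size = FALSE) {
  stopifnot(inherits(config, "run_config"), length(inputs) >= 1L)
  ps <- pixel_sizes %||% rep(config$pixel_size, length(inputs))
  if (length(unique(ps)) > 1L && !allow_mixed_pixel_size) {
    stop("images have different pixel sizes; set allow_mixed_pixel_size ",
         "= TRUE to pool anyway")
  }
  per <- purrr::imap(as.list(inputs), function(inp, i) {
    cfg_i <- config
    cfg_i$pixel_size <- ps[[i]]
    cfg_i$out_dir <- NULL
    img <- if (is.character(inp)) {
      read_micrograph(inp, pixel_size = ps[[i]], modality = config$modality)
    } else resolve_image(cfg_i, inp)
    den <- if (config$denoise_method == "none") img else {
      denoise(img, config$denoise_method, config$denoise_cutoff)
    }
    bin <- binarize(den, config$threshold_method, config$threshold_value)
    tri <- triage(extract_contours(bin, min_area = config$min_area),
                  solidity_min = config$solidity_min,
                  size_bounds = c(config$min_area, config$size_max))
    desc <- shape_descriptors(tri$isolated, pixel_size = ps[[i]],
                              n_hu = config$n_hu)
    if (nrow(desc)) desc$image_id <- i
    list(triaged = tri, descriptors = desc)
  })
  pooled <- dplyr::bind_rows(purrr::map(per, "descriptors"))
  if (nrow(pooled) == 0L) {
    return(list(descriptors = pooled, classification = NULL,
                summary = NULL, per_image = per))
  }
  feature_cols <- paste0("logH", seq_len(config$n_hu))
  K_cap <- min(config$K_max, max(1L, (nrow(pooled) - 1L) %/% config$n_hu))
  classification <- classify_shapes(pooled, feature_cols = feature_cols,
                                    K_max = K_cap,
                                    criterion = config$criterion,
                                    prune_weight = config$prune_weight,
                                    seed = config$seed)
  list(descriptors = pooled, classification = classification,
       summary = class_summary(classification, pooled), per_image = per)
}
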