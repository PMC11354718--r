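#' Run the full lesion-assessment pipeline
#'
#' Chains the stages end to end: field solve (when the lesion is generated
#' from the field or a threshold estimate is requested), synthetic view
#' rendering (or user images), calibration, segmentation, 2-D metrics,
#' similarity volumetry, and threshold estimation by area matching plus
#' boundary sampling. Writes per-slice metric rows, the EFT summary, the
#' depth profile, overlay PNGs, and a run manifest into `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param config A `pfa_scene` (default [default_scene()]).
#' @param lesion_spec List describing the lesion to generate:
#'   `list(type = "field_superlevel", threshold = 240)` or
#'   `list(type = "half_ellipsoid", a = , b = , c = )` or
#'   `list(type = "peanut", a = , b = , c = , offset = )`.
#' @param images Optional list with paths `top`, `cut` and calibration /
#'   top-line metadata, bypassing the synthetic renderer.
#' @param voltage Applied voltage, V (default: the recipe amplitude).
#' @param spacing Solver grid spacing, mm (default: config value).
#' @param render A [render_spec()] for the synthetic views.
#' @param top_threshold,cut_threshold Segmentation brightness thresholds.
#' @param n_slices Depth samples for the volumetry.
#' @param estimate_eft Run threshold estimation (needs a field solve).
#' @param solution Optional precomputed `pfa_field` to reuse.
#' @return List with `metrics` (one-row data frame), `eft` (data frame),
#'   `volume`, `solution`, `files`.
#' @export
run_full_pipeline <- function(out_dir, config = default_scene(),
                              lesion_spec = list(type = "field_superlevel",
                                                 threshold = 240),
                              images = NULL, voltage = NULL, spacing = NULL,
                              render = render_spec(),
                              top_threshold = 120, cut_threshold = 120,
                              n_slices = 101, estimate_eft = TRUE,
                              solution = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(voltage)) voltage <- config$recipe$amplitude
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  need_field <- estimate_eft ||
    (is.null(images) && identical(lesion_spec$type, "field_superlevel"))
  if (need_field && is.null(solution)) {
    note("solving field: %g V, spacing %g mm",
         voltage, if (is.null(spacing)) config$solver$spacing else spacing)
    mm <- rasterize_materials(config, spacing = spacing)
    solution <- solve_potential(mm, voltage)
    note("solver done: %d iterations, residual %.2e",
         solution$iterations, solution$residual)
  }

  # --- inputs: synthetic render or user images -----------------------------
  if (is.null(images)) {
    lesion <- switch(lesion_spec$type,
      field_superlevel = make_field_lesion(solution, lesion_spec$threshold),
      half_ellipsoid = make_parametric_lesion("half_ellipsoid",
        a = lesion_spec$a, b = lesion_spec$b, c = lesion_spec$c),
      peanut = make_parametric_lesion("peanut", a = lesion_spec$a,
        b = lesion_spec$b, c = lesion_spec$c, offset = lesion_spec$offset),
      stop(sprintf("unknown lesion type '%s'", lesion_spec$type), call. = FALSE))
    rv <- render_views(lesion, render, out_dir)
    truth <- rv$truth
    top_img_path <- rv$top
    cut_img_path <- rv$cut
    cal_top <- calibrate(truth$scale_bar$points_px[1, ],
                         truth$scale_bar$points_px[2, ],
                         truth$scale_bar$length_mm)
    cal_cut <- calibrate(truth$scale_bar$points_px_cut[1, ],
                         truth$scale_bar$points_px_cut[2, ],
                         truth$scale_bar$length_mm)
    top_line_px <- truth$cut$top_line_px
    marks_px <- truth$electrode_marks_px
  } else {
    truth <- NULL
    top_img_path <- images$top
    cut_img_path <- images$cut
    cal_top <- calibrate(images$scale_points[1, ], images$scale_points[2, ],
                         images$scale_mm)
    cal_cut <- if (!is.null(images$scale_points_cut)) {
      calibrate(images$scale_points_cut[1, ], images$scale_points_cut[2, ],
                images$scale_mm)
    } else cal_top
    top_line_px <- images$top_line_px
    marks_px <- images$electrode_marks_px
  }

  # --- segmentation + 2-D metrics ------------------------------------------
  note("segmenting views (thresholds %d / %d)", top_threshold, cut_threshold)
  top_img <- read_lesion_image(top_img_path)
  cut_img <- read_lesion_image(cut_img_path)
  top_mask <- segment_stained(top_img, top_threshold, cal_top, "top")
  cut_mask <- segment_stained(cut_img, cut_threshold, cal_cut, "cut")
  if (top_mask$empty || cut_mask$empty) {
    stop("segmentation produced an empty mask; check thresholds", call. = FALSE)
  }
  area_top <- measure_area(top_mask)
  lw <- measure_length_width(top_mask)
  if (is.null(top_line_px)) {
    stop("no top cut line available for the cut view", call. = FALSE)
  }
  poly <- trace_cut_polygon(cut_mask, top_line_px)
  depth <- measure_depth(poly)
  profile <- width_ratio_profile(poly, n_slices = n_slices)
  vol <- similarity_volume(area_top, profile)

  metrics <- data.frame(
    area_mm2 = area_top, length_mm = lw[["length"]], width_mm = lw[["width"]],
    depth_mm = depth, volume_mm3 = vol$volume,
    amplitude_V = config$recipe$amplitude,
    phase_duration_us = config$recipe$phase_duration,
    frequency_Hz = config$recipe$frequency,
    pulse_count = config$recipe$pulse_count)

  # --- threshold estimation -------------------------------------------------
  eft_df <- NULL
  overlay_path <- NULL
  if (estimate_eft) {
    plane <- slice_field(solution, "z", min(solution$z[solution$z > 0]))
    est_area <- eft_by_area_match(area_top, plane)
    ests <- list(est_area)
    if (!is.null(marks_px)) {
      reg <- register_lesion(top_mask, marks_px, config)
      m <- top_mask$mask
      cl <- grDevices::contourLines(seq_len(ncol(m)), seq_len(nrow(m)),
                                    t(m * 1), levels = 0.5)
      lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
      bnd_px <- cbind(cl[[which.max(lens)]]$x, cl[[which.max(lens)]]$y)
      bnd_scene <- transform_points(reg, bnd_px)
      inside <- bnd_scene[, 1] >= min(plane$u) & bnd_scene[, 1] <= max(plane$u) &
        bnd_scene[, 2] >= min(plane$v) & bnd_scene[, 2] <= max(plane$v)
      if (mean(inside) > 0.95) {
        ests <- c(ests, list(eft_by_boundary_quantile(bnd_scene[inside, ], plane)))
      } else {
        note("boundary method skipped: %.0f%% of vertices outside the plane",
             100 * mean(!inside))
      }
    }
    eft_df <- data.frame(
      method = vapply(ests, function(e) e$method, character(1)),
      eft_V_per_cm = vapply(ests, function(e) e$threshold, numeric(1)),
      residual = vapply(ests, function(e) e$residual %||% NA_real_, numeric(1)),
      flag = vapply(ests, function(e) e$flag, character(1)),
      applied_voltage_V = voltage)
    overlay_path <- file.path(out_dir, "overlay_top.png")
    render_overlay(top_img, top_mask, plane, est_area$threshold,
                   cal_top, overlay_path)
  }

  # --- outputs --------------------------------------------------------------
  files <- list(metrics = file.path(out_dir, "metrics.csv"),
                profile = file.path(out_dir, "depth_profile.csv"),
                eft = if (!is.null(eft_df)) file.path(out_dir, "eft.csv"),
                overlay = overlay_path,
                manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(metrics, files$metrics, row.names = FALSE, quote = FALSE)
  write_profile_csv(vol, files$profile)
  if (!is.null(eft_df)) {
    utils::write.csv(eft_df, files$eft, row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    command = "run_full_pipeline",
    package_version = as.character(utils::packageVersion("pfalesion")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = scene_to_list(config),
    lesion_spec = lesion_spec,
    voltage = voltage,
    spacing = spacing %||% config$solver$spacing,
    seeds = if (is.null(images)) render$seed else NULL,
    thresholds = list(top = top_threshold, cut = cut_threshold),
    n_slices = n_slices,
    input_digests = as.list(tools::md5sum(c(top_img_path, cut_img_path))),
    warnings = c(if (isTRUE(vol$capped)) "width ratios capped",
                 character(0)),
    log = log_lines)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(metrics = metrics, eft = eft_df, volume = vol, truth = truth,
       solution = solution, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# top image + segmented boundary (red) + field isoline at the estimated
# threshold (blue), composited in image pixel space
render_overlay <- function(top_img, top_mask, plane, level, cal, path) {
  lum <- luma_rec601(top_img) / 255
  img <- array(0, dim = c(nrow(lum), ncol(lum), 3))
  for (ch in 1:3) img[, , ch] <- lum
  m <- top_mask$mask
  cl <- grDevices::contourLines(seq_len(ncol(m)), seq_len(nrow(m)),
                                t(m * 1), levels = 0.5)
  for (cc in cl) img <- draw_polyline(img, cc$x, cc$y, c(1, 0.1, 0.1))
  iso <- extract_isolines(plane, level)
  mpp <- cal$mm_per_pixel
  cx <- (ncol(lum) + 1) / 2
  cy <- (nrow(lum) + 1) / 2
  for (cc in iso$contours) {
    img <- draw_polyline(img, cc$x / mpp + cx, cc$y / mpp + cy, c(0.2, 0.4, 1))
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Per-condition summary of a metrics table
#'
#' Groups the per-slice metric rows by the given keys and reports n, mean,
#' and SEM for every numeric metric column, the form in which bench
#' conditions are compared. SEM for a single-row group is flagged
#' undefined.
#'
#' @param metrics Data frame of per-slice rows (e.g. stacked
#'   [run_full_pipeline()] `metrics`).
#' @param group_keys Character vector of grouping column names.
#' @return Data frame with one row per group x metric: `n`, `mean`, `sem`,
#'   `sem_defined`.
#' @export
export_condition_summary <- function(metrics, group_keys) {
  miss <- setdiff(group_keys, names(metrics))
  if (length(miss) > 0) {
    stop(sprintf("grouping key(s) not in table: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  value_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                        group_keys)
  groups <- split(metrics, metrics[group_keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    do.call(rbind, lapply(value_cols, function(cl) {
      n <- nrow(g)
      cbind(g[1, group_keys, drop = FALSE],
            data.frame(metric = cl, n = n, mean = mean(g[[cl]]),
                       sem = if (n > 1) stats::sd(g[[cl]]) / sqrt(n) else 0,
                       sem_defined = n > 1))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
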