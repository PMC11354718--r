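#' Register a top-view lesion image to the scene frame
#'
#' Computes the rigid transform (rotation + translation, scale from the
#' image calibration) that carries image mm-coordinates into scene
#' coordinates, using the two electrode marks visible in the top view: the
#' mark midpoint maps to the scene origin and the mark axis to the scene
#' electrode axis (x).
#'
#' @param top_mask A calibrated `pfa_mask` (supplies `mm_per_pixel`).
#' @param electrode_marks 2 x 2 matrix of mark pixel coordinates
#'   (rows = marks, columns = x, y); mark 1 is electrode A (positive x).
#' @param scene A `pfa_scene`.
#' @return A `pfa_registration`: `rotation` (2 x 2), `translation`,
#'   `mm_per_pixel`, and `residual` (difference between the mark separation
#'   and the scene electrode center distance, mm).
#' @export
register_lesion <- function(top_mask, electrode_marks, scene) {
  mpp <- top_mask$calibration$mm_per_pixel
  marks_mm <- as.matrix(electrode_marks) * mpp
  sep <- sqrt(sum((marks_mm[1, ] - marks_mm[2, ])^2))
  if (sep < 1) {
    stop(sprintf("electrode marks only %.2f mm apart; cannot orient (need >= 1 mm)",
                 sep), call. = FALSE)
  }
  g <- scene$geometry
  scene_sep <- g$electrode_gap + g$electrode_diameter
  mid <- (marks_mm[1, ] + marks_mm[2, ]) / 2
  dir <- (marks_mm[1, ] - marks_mm[2, ]) / sep  # image direction of +x axis
  # rotate image so 'dir' maps onto (1, 0)
  rot <- rbind(c(dir[1], dir[2]), c(-dir[2], dir[1]))
  structure(list(rotation = rot, translation = -as.vector(rot %*% mid),
                 mm_per_pixel = mpp, residual = abs(sep - scene_sep),
                 angle_deg = atan2(dir[2], dir[1]) * 180 / pi),
            class = "pfa_registration")
}

#' Apply a registration to image points
#'
#' @param registration A `pfa_registration`.
#' @param points n x 2 matrix of image pixel coordinates.
#' @return n x 2 matrix of scene coordinates, mm.
#' @export
transform_points <- function(registration, points) {
  pts_mm <- as.matrix(points) * registration$mm_per_pixel
  out <- t(registration$rotation %*% t(pts_mm) + registration$translation)
  colnames(out) <- c("x", "y")
  out
}

#' Lethal-threshold estimate by area matching
#'
#' Finds the field level whose superlevel area on the comparison plane
#' equals the measured lesion area: the operational reading of comparing the
#' electroporated area between simulation and experiment. Exploits the
#' strict monotonicity of [superlevel_area()] in the level via bisection on
#' the bracket `[1 V/cm, plane maximum]`.
#'
#' @param lesion_area Measured lesion area, mm^2 (`> 0`).
#' @param plane A `pfa_plane` (conventionally the slab top surface for
#'   top-view lesions).
#' @param tol_rel Relative area mismatch at convergence (default 0.005).
#' @param max_iter Bisection cap (default 60).
#' @return A `pfa_eft`: `threshold` (V/cm), `method = "area_match"`,
#'   `residual` (relative area mismatch), `iterations`, and `flag`
#'   (`"ok"`, `"below_range"` when the lesion is larger than the area at the
#'   minimum bracket, or `"plateau"`).
#' @export
eft_by_area_match <- function(lesion_area, plane, tol_rel = 0.005, max_iter = 60) {
  if (lesion_area <= 0) stop("lesion_area must be > 0", call. = FALSE)
  lo <- 1
  hi <- max(plane$e)
  if (hi <= lo) stop("field plane has no dynamic range above 1 V/cm", call. = FALSE)
  a_lo <- superlevel_area(plane, lo)
  if (lesion_area > a_lo) {
    return(structure(list(threshold = lo, method = "area_match",
                          residual = abs(a_lo - lesion_area) / lesion_area,
                          iterations = 0L, flag = "below_range",
                          applied_voltage = NA_real_),
                     class = "pfa_eft"))
  }
  it <- 0L
  mid <- (lo + hi) / 2
  resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    a <- superlevel_area(plane, mid)
    resid <- abs(a - lesion_area) / lesion_area
    if (resid <= tol_rel) break
    if (a > lesion_area) lo <- mid else hi <- mid
  }
  flag <- if (resid <= tol_rel) "ok" else "plateau"
  structure(list(threshold = mid, method = "area_match", residual = resid,
                 iterations = it, flag = flag, applied_voltage = NA_real_),
            class = "pfa_eft")
}

#' Lethal-threshold estimate by boundary field sampling
#'
#' Implements the "external edge" reading of the threshold: the lesion edge
#' marks the minimum field that still produced the effect. Samples |E| at
#' the registered lesion-boundary vertices by bilinear interpolation and
#' returns the requested quantile (default median; quantile 0 is the
#' literal minimum-field reading), with the IQR as a registration-quality
#' diagnostic.
#'
#' @param boundary n x 2 matrix of boundary vertices in scene mm
#'   coordinates (plane frame).
#' @param plane A `pfa_plane`.
#' @param quantile Quantile in `[0, 1]` (default 0.5).
#' @return A `pfa_eft` with `threshold`, `method = "boundary_quantile"`,
#'   `quantile`, `iqr`, and `n_vertices`.
#' @export
eft_by_boundary_quantile <- function(boundary, plane, quantile = 0.5) {
  if (quantile < 0 || quantile > 1) stop("quantile must be in [0, 1]", call. = FALSE)
  boundary <- as.matrix(boundary)
  vals <- bilinear_sample(plane, boundary[, 1], boundary[, 2])
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    stop(sprintf("boundary vertices outside the field domain: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  structure(list(threshold = unname(stats::quantile(vals, quantile)),
                 method = "boundary_quantile", quantile = quantile,
                 iqr = unname(stats::IQR(vals)), n_vertices = nrow(boundary),
                 flag = "ok"),
            class = "pfa_eft")
}

#' @export
print.pfa_eft <- function(x, ...) {
  cat(sprintf("EFT estimate: %.1f V/cm [%s]", x$threshold, x$method))
  if (x$method == "boundary_quantile") {
    cat(sprintf(" (q = %.2f, IQR %.1f)", x$quantile, x$iqr))
  } else {
    cat(sprintf(" (area mismatch %.2f%%)", 100 * x$residual))
  }
  cat(sprintf(" flag: %s\n", x$flag))
  invisible(x)
}

#' Summarize threshold estimates across slices
#'
#' Per-condition, per-method mean and SEM of the estimated thresholds. With
#' a single estimate in a group the SEM is undefined and flagged.
#'
#' @param estimates List of `pfa_eft` objects, or a data frame with columns
#'   `threshold` and `method` (optionally `condition`).
#' @param condition Optional character vector of condition labels, recycled
#'   against the estimates.
#' @return Data frame with `condition`, `method`, `n`,
#'   `eft_mean_V_per_cm`, `eft_sem_V_per_cm`, `sem_defined`.
#' @export
eft_batch_report <- function(estimates, condition = NULL) {
  if (is.data.frame(estimates)) {
    df <- estimates
    if (is.null(df$condition)) df$condition <- "all"
  } else {
    if (length(estimates) < 1) stop("need at least one estimate", call. = FALSE)
    df <- data.frame(
      threshold = vapply(estimates, function(e) e$threshold, numeric(1)),
      method = vapply(estimates, function(e) e$method, character(1)),
      condition = if (is.null(condition)) "all" else
        rep_len(condition, length(estimates)))
  }
  groups <- split(df, list(df$condition, df$method), drop = TRUE)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(condition = g$condition[1], method = g$method[1], n = n,
               eft_mean_V_per_cm = mean(g$threshold),
               eft_sem_V_per_cm = if (n > 1) stats::sd(g$threshold) / sqrt(n) else 0,
               sem_defined = n > 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$method), , drop = FALSE]
}
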