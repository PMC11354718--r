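#' Trace the lesion polygon on a cut-view image
#'
#' Builds the cut-view lesion polygon from either user-supplied boundary
#' vertices (interactive-style path: `vertices` given in pixel coordinates)
#' or automatically from the segmentation mask: the mask boundary is
#' polygonized by marching squares, simplified (Ramer-Douglas-Peucker), and
#' clipped to the tissue side of the top cut line. The depth axis is the
#' perpendicular bisector of the top cut line, oriented into the tissue.
#'
#' @param cut_mask A `pfa_mask` from the cut view.
#' @param top_line_points 2 x 2 matrix (rows = the two top-line points,
#'   columns = pixel x, y): where the cut plane meets the slice surface.
#' @param vertices Optional n x 2 matrix of user-picked boundary pixels; when
#'   given, the mask is not polygonized.
#' @param simplify_tol_px Simplification tolerance in pixels (default 1).
#' @return A `pfa_cut_polygon`: `vertices` (mm, cut-plane coordinates),
#'   `top_line` (2 x 2, mm), `depth_origin` (top-line midpoint, mm),
#'   `depth_dir` (unit vector into the tissue), `mm_per_pixel`.
#' @export
trace_cut_polygon <- function(cut_mask, top_line_points, vertices = NULL,
                              simplify_tol_px = 1) {
  mpp <- cut_mask$calibration$mm_per_pixel
  tl <- top_line_points * mpp
  if (sqrt(sum((tl[1, ] - tl[2, ])^2)) <= 0) {
    stop("zero-length top cut line", call. = FALSE)
  }

  if (is.null(vertices)) {
    if (!any(cut_mask$mask)) stop("cannot trace an empty mask", call. = FALSE)
    m <- cut_mask$mask
    # contour in pixel coords: x = col, y = row
    cl <- grDevices::contourLines(seq_len(ncol(m)), seq_len(nrow(m)),
                                  t(m * 1), levels = 0.5)
    if (length(cl) == 0) stop("mask boundary polygonization failed", call. = FALSE)
    lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
    cc <- cl[[which.max(lens)]]
    poly_px <- cbind(cc$x, cc$y)
    poly_px <- rdp_simplify(poly_px, simplify_tol_px)
    # drop duplicated closing vertex if present
    if (nrow(poly_px) > 1 && all(poly_px[1, ] == poly_px[nrow(poly_px), ])) {
      poly_px <- poly_px[-nrow(poly_px), , drop = FALSE]
    }
  } else {
    poly_px <- as.matrix(vertices)
  }
  poly <- poly_px * mpp

  # tissue side: the side of the top line holding the polygon centroid
  u <- (tl[2, ] - tl[1, ]) / sqrt(sum((tl[2, ] - tl[1, ])^2))
  n_dir <- c(-u[2], u[1])
  cen <- polygon_centroid(poly)
  side <- sum((cen - tl[1, ]) * n_dir)
  if (side < 0) n_dir <- -n_dir
  poly <- clip_halfplane(poly, tl[1, ], n_dir)
  if (nrow(poly) < 3) stop("polygon degenerate after clipping to the top line",
                           call. = FALSE)

  bad <- polygon_self_intersection(poly)
  if (!is.null(bad)) {
    stop(sprintf("polygon self-intersects after simplification (edges %d and %d)",
                 bad[1], bad[2]), call. = FALSE)
  }

  structure(list(vertices = data.frame(x = poly[, 1], y = poly[, 2]),
                 top_line = tl,
                 depth_origin = (tl[1, ] + tl[2, ]) / 2,
                 depth_dir = n_dir, mm_per_pixel = mpp),
            class = "pfa_cut_polygon")
}

#' Construct a cut polygon directly from mm coordinates
#'
#' Convenience constructor used by the synthetic generator and by tests,
#' bypassing the image path.
#'
#' @param vertices n x 2 matrix, mm.
#' @param top_line 2 x 2 matrix, mm.
#' @return A `pfa_cut_polygon`.
#' @export
cut_polygon <- function(vertices, top_line) {
  vertices <- as.matrix(vertices)
  top_line <- as.matrix(top_line)
  u <- top_line[2, ] - top_line[1, ]
  L <- sqrt(sum(u^2))
  if (L == 0) stop("zero-length top cut line", call. = FALSE)
  u <- u / L
  n_dir <- c(-u[2], u[1])
  cen <- polygon_centroid(vertices)
  if (sum((cen - top_line[1, ]) * n_dir) < 0) n_dir <- -n_dir
  structure(list(vertices = data.frame(x = vertices[, 1], y = vertices[, 2]),
                 top_line = top_line,
                 depth_origin = (top_line[1, ] + top_line[2, ]) / 2,
                 depth_dir = n_dir, mm_per_pixel = NA_real_),
            class = "pfa_cut_polygon")
}

#' Lesion depth from the cut polygon
#'
#' Maximum distance from the top cut line to any polygon vertex, measured
#' along the depth-axis direction (the perpendicular bisector of the top
#' line, pointing into the tissue).
#'
#' @param polygon A `pfa_cut_polygon`.
#' @return Depth in mm.
#' @export
measure_depth <- function(polygon) {
  v <- as.matrix(polygon$vertices)
  proj <- (v[, 1] - polygon$top_line[1, 1]) * polygon$depth_dir[1] +
    (v[, 2] - polygon$top_line[1, 2]) * polygon$depth_dir[2]
  max(0, max(proj))
}

#' Write polygon vertices as CSV
#'
#' Columns `x_mm`, `y_mm` in cut-plane coordinates.
#'
#' @param polygon A `pfa_cut_polygon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon_csv <- function(polygon, path) {
  utils::write.csv(data.frame(x_mm = polygon$vertices$x,
                              y_mm = polygon$vertices$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
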