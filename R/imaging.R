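#' Read a lesion photograph
#'
#' Reads an 8-bit PNG or JPG photograph into a numeric array scaled 0-255,
#' oriented with the image origin at the top-left corner, x to the right
#' (columns) and y down (rows). PNGs are read with \pkg{png}; other formats
#' go through \pkg{EBImage}.
#'
#' @param path Image path.
#' @return Numeric array `[row, col]` (grayscale) or `[row, col, channel]`.
#' @export
read_lesion_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    ei <- EBImage::readImage(path)
    dat <- EBImage::imageData(ei)
    img <- if (length(dim(dat)) == 2) t(dat) else aperm(dat, c(2, 1, 3))
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  img * 255
}

#' Rec. 601 luma of an image
#'
#' `0.299 R + 0.587 G + 0.114 B` on the 0-255 scale; grayscale images pass
#' through unchanged.
#'
#' @param img Array from [read_lesion_image()].
#' @return Matrix `[row, col]` of luma values, 0-255.
#' @export
luma_rec601 <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Two-point image calibration
#'
#' Derives the physical pixel pitch from two reference points a known
#' distance apart (typically the endpoints of a scale bar in the
#' photograph).
#'
#' @param point_a,point_b Pixel coordinates `c(x, y)`.
#' @param known_distance_mm Physical distance between the points, mm.
#' @return An `pfa_calibration` list with `mm_per_pixel` and the inputs.
#' @export
calibrate <- function(point_a, point_b, known_distance_mm) {
  px_dist <- sqrt(sum((point_a - point_b)^2))
  if (px_dist == 0) stop("calibration points coincide", call. = FALSE)
  if (px_dist < 5) {
    stop(sprintf("calibration points only %.2f px apart (need >= 5 px)", px_dist),
         call. = FALSE)
  }
  if (known_distance_mm <= 0) stop("known distance must be > 0", call. = FALSE)
  structure(list(point_a = point_a, point_b = point_b,
                 known_distance_mm = known_distance_mm,
                 mm_per_pixel = known_distance_mm / px_dist),
            class = "pfa_calibration")
}

#' Segment the stained lesion by brightness threshold
#'
#' Marks as stained every pixel whose Rec. 601 luma falls below the
#' brightness threshold, then keeps the largest connected component and
#' fills its holes (stray dye specks and glare holes otherwise corrupt the
#' pixel count). An empty result is returned with a warning flag rather than
#' an error so batch runs proceed.
#'
#' @param img Image array (or luma matrix) on the 0-255 scale.
#' @param threshold Brightness threshold in `[0, 255]`; default 120.
#' @param calibration A [calibrate()] result.
#' @param view `"top"` or `"cut"`, recorded on the mask.
#' @param cleanup Keep largest component and fill holes (default `TRUE`;
#'   disable to get the raw thresholded pixel set).
#' @return A `pfa_mask`: logical matrix `mask` `[row, col]`, the threshold,
#'   the calibration, the view tag, and `empty` flag.
#' @export
segment_stained <- function(img, threshold = 120, calibration, view = c("top", "cut"),
                            cleanup = TRUE) {
  view <- match.arg(view)
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]", call. = FALSE)
  lum <- luma_rec601(img)
  raw <- lum < threshold
  mask <- raw
  if (any(raw) && cleanup) {
    lab <- EBImage::bwlabel(raw * 1)
    counts <- tabulate(as.integer(lab))
    mask <- lab == which.max(counts)
    mask <- EBImage::fillHull(mask * 1) > 0
  }
  structure(list(mask = mask, threshold = threshold, calibration = calibration,
                 view = view, empty = !any(mask)),
            class = "pfa_mask")
}

#' Stained area of a mask
#'
#' Pixel count times the pixel area: the mask pixel is modeled as a unit
#' square with no sub-pixel boundary correction.
#'
#' @param mask A `pfa_mask`.
#' @return Area in mm^2.
#' @export
measure_area <- function(mask) {
  sum(mask$mask) * mask$calibration$mm_per_pixel^2
}

# Convex hull of the solid pixel region (pixels as unit squares): hull of
# the centers, then the Minkowski corners of its vertices, hulled again.
mask_solid_hull <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cx <- idx[, 2]; cy <- idx[, 1]  # x = col, y = row
  h1 <- grDevices::chull(cx, cy)
  vx <- cx[h1]; vy <- cy[h1]
  corners_x <- c(vx - 0.5, vx + 0.5, vx - 0.5, vx + 0.5)
  corners_y <- c(vy - 0.5, vy - 0.5, vy + 0.5, vy + 0.5)
  h2 <- grDevices::chull(corners_x, corners_y)
  cbind(x = corners_x[h2], y = corners_y[h2])
}

#' Lesion length and width
#'
#' Length is the maximum Feret (caliper) diameter of the stained region with
#' pixels treated as unit squares; width is the maximum extent perpendicular
#' to the length axis. These operational definitions are fixed so numbers
#' are comparable across runs.
#'
#' @param mask A nonempty `pfa_mask`.
#' @return Named numeric `c(length, width)` in mm, with `length >= width`
#'   by convention.
#' @export
measure_length_width <- function(mask) {
  if (!any(mask$mask)) stop("undefined metric: empty mask", call. = FALSE)
  hull <- mask_solid_hull(mask$mask)
  n <- nrow(hull)
  d2 <- outer(hull[, 1], hull[, 1], `-`)^2 + outer(hull[, 2], hull[, 2], `-`)^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  len_px <- sqrt(max(d2))
  u <- (hull[ij[2], ] - hull[ij[1], ]) / len_px
  perp <- c(-u[2], u[1])
  proj <- hull[, 1] * perp[1] + hull[, 2] * perp[2]
  wid_px <- max(proj) - min(proj)
  mpp <- mask$calibration$mm_per_pixel
  out <- sort(c(len_px, wid_px), decreasing = TRUE) * mpp
  c(length = out[1], width = out[2])
}

#' Write a mask PNG
#'
#' White stained region on black background, for inspection.
#'
#' @param mask A `pfa_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}
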