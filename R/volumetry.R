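#' Width-ratio depth profile of a cut polygon
#'
#' For each depth `z` on a uniform grid from the surface (`z = 0`) to the
#' lesion depth `d`, computes the chord of the cut polygon at depth `z`
#' parallel to the top cut line and forms the ratio
#' `r(z) = chord(z) / top-line length`. For non-convex cross-sections the
#' chord is the total covered interval length (sum of sub-chords); the
#' single-interval alternative is available via `chord_mode = "single"`.
#' Ratios slightly above 1 (digitization noise at the surface) are capped at
#' `r_cap` with a warning flag.
#'
#' @param polygon A `pfa_cut_polygon`.
#' @param n_slices Number of depth samples including both endpoints
#'   (`>= 2`); default 101.
#' @param r_cap Ratio cap (default 1.05).
#' @param chord_mode `"total"` (default) or `"single"`.
#' @return A `pfa_depth_profile`: data frame `z_mm`, `ratio`, plus
#'   attributes `depth`, `top_line_length`, `capped`.
#' @export
width_ratio_profile <- function(polygon, n_slices = 101, r_cap = 1.05,
                                chord_mode = c("total", "single")) {
  chord_mode <- match.arg(chord_mode)
  if (n_slices < 2) stop("n_slices must be >= 2", call. = FALSE)
  tl <- polygon$top_line
  L0 <- sqrt(sum((tl[2, ] - tl[1, ])^2))
  if (L0 <= 0) stop("zero-length top cut line", call. = FALSE)
  u <- (tl[2, ] - tl[1, ]) / L0
  n_dir <- polygon$depth_dir
  v <- as.matrix(polygon$vertices)
  s <- (v[, 1] - polygon$depth_origin[1]) * u[1] +
    (v[, 2] - polygon$depth_origin[2]) * u[2]
  t <- (v[, 1] - polygon$depth_origin[1]) * n_dir[1] +
    (v[, 2] - polygon$depth_origin[2]) * n_dir[2]
  d <- measure_depth(polygon)
  z <- seq(0, d, length.out = n_slices)
  # chords are evaluated a hair inside [0, d]: the surface chord sits exactly
  # on the clip line and flat-bottomed lesions have their terminal chord as a
  # boundary-coincident edge, both of which a strict scanline would miss
  eps <- d * 1e-9
  z_eval <- pmin(pmax(z, eps), d - eps)
  chord <- vapply(z_eval, function(zi) polygon_chord(s, t, zi, chord_mode),
                  numeric(1))
  r <- chord / L0
  capped <- any(r > r_cap)
  if (capped) {
    warning(sprintf("width ratios up to %.3f capped at %.2f", max(r), r_cap))
  }
  r <- pmin(r, r_cap)
  structure(data.frame(z_mm = z, ratio = r),
            depth = d, top_line_length = L0, capped = capped,
            chord_mode = chord_mode,
            class = c("pfa_depth_profile", "data.frame"))
}

#' Similarity-scaled lesion volume
#'
#' Under the similarity assumption the lesion cross-section at depth `z` is
#' a scaled copy of the surface lesion, so its area is the squared width
#' ratio times the top-view area, `A(z) = r(z)^2 A_top`, and the volume is
#' `V = integral_0^d A(z) dz`, evaluated with the trapezoidal rule on the
#' uniform depth grid of the profile.
#'
#' @param area_top Top-view lesion area, mm^2 (`>= 0`).
#' @param profile A `pfa_depth_profile`.
#' @return A `pfa_volume`: `volume` (mm^3), `n_slices`, the profile with an
#'   `area_mm2` column, and the similarity-assumption audit flags.
#' @export
similarity_volume <- function(area_top, profile) {
  if (area_top < 0) stop("area_top must be >= 0", call. = FALSE)
  if (nrow(profile) < 2) stop("need at least 2 depth samples", call. = FALSE)
  z <- profile$z_mm
  a <- profile$ratio^2 * area_top
  vol <- pracma::trapz(z, a)
  out <- data.frame(z_mm = z, ratio = profile$ratio, area_mm2 = a)
  structure(list(volume = vol, n_slices = nrow(profile), profile = out,
                 area_top = area_top,
                 capped = isTRUE(attr(profile, "capped")),
                 similarity_assumed = TRUE),
            class = "pfa_volume")
}

#' @export
print.pfa_volume <- function(x, ...) {
  cat(sprintf("similarity volume: %.3f mm^3 (A_top %.3f mm^2, depth %.3f mm, %d slices)\n",
              x$volume, x$area_top, max(x$profile$z_mm), x$n_slices))
  invisible(x)
}

#' Quantify how well the similarity assumption holds for a field
#'
#' The volume estimator assumes lesion cross-sections at depth are
#' geometrically similar scaled copies of the surface lesion. For a solved
#' field this diagnostic extracts the superlevel contour at a set of depths,
#' normalizes each contour by its centroid and its width along the electrode
#' axis, and reports the mean Jaccard distance (symmetric-difference area
#' over union area) of the normalized shapes against the shallowest one:
#' 0 means exactly self-similar, 1 totally dissimilar.
#'
#' @param solution A `pfa_field`.
#' @param level Field level, V/cm.
#' @param depths Depths (mm, `> 0` into the slab) at which to compare;
#'   default: five uniform depths over the superlevel set's depth extent.
#' @param grid_n Rasterization resolution for the shape comparison.
#' @return List with `mean_discrepancy`, per-depth `discrepancy`, `depths`,
#'   and `skipped` (depths with no contour).
#' @export
validate_similarity_assumption <- function(solution, level, depths = NULL,
                                           grid_n = 128) {
  if (is.null(depths)) {
    slab_k <- which(solution$z > 0)
    has <- vapply(slab_k, function(k) any(solution$e_vcm[, , k] >= level), logical(1))
    if (!any(has)) stop("superlevel set empty at every depth", call. = FALSE)
    zmax <- max(solution$z[slab_k[has]])
    depths <- seq(solution$z[slab_k[1]], zmax * 0.9, length.out = 5)
  }
  norm_shape <- function(depth) {
    pl <- slice_field(solution, "z", depth)
    iso <- extract_isolines(pl, level)
    closed <- Filter(function(cc) isTRUE(attr(cc, "closed")), iso$contours)
    if (length(closed) == 0 && length(iso$contours) > 0) closed <- iso$contours
    if (length(closed) == 0) return(NULL)
    areas <- vapply(closed, function(cc) polygon_area(cc$x, cc$y), numeric(1))
    cc <- closed[[which.max(areas)]]
    w <- max(cc$x) - min(cc$x)  # width along the electrode axis (x)
    if (w <= 0) return(NULL)
    cen <- polygon_centroid(cbind(cc$x, cc$y))
    cbind((cc$x - cen[1]) / w, (cc$y - cen[2]) / w)
  }
  shapes <- lapply(depths, norm_shape)
  skipped <- depths[vapply(shapes, is.null, logical(1))]
  keep <- !vapply(shapes, is.null, logical(1))
  shapes <- shapes[keep]
  if (length(shapes) < 2) {
    stop("need contours at >= 2 depths for a similarity diagnostic", call. = FALSE)
  }
  gx <- seq(-0.75, 0.75, length.out = grid_n)
  gpts <- expand.grid(x = gx, y = gx)
  rasters <- lapply(shapes, function(s) points_in_polygon(gpts$x, gpts$y, s))
  ref <- rasters[[1]]
  disc <- vapply(rasters[-1], function(m) {
    un <- sum(ref | m)
    if (un == 0) return(0)
    sum(xor(ref, m)) / un
  }, numeric(1))
  list(mean_discrepancy = mean(disc), discrepancy = disc,
       depths = depths[keep][-1], skipped = skipped)
}

#' Write a depth profile as CSV
#'
#' Columns `z_mm`, `ratio`, `area_mm2`.
#'
#' @param volume A `pfa_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(volume, path) {
  utils::write.csv(volume$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
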