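#' Extract a 2-D field plane from a solution
#'
#' Slices the |E| (and potential) arrays on an axis-aligned plane by linear
#' interpolation between the two bracketing cell-center layers. The returned
#' plane keeps the native in-plane resolution.
#'
#' Plane coordinates: a `z` plane has `u = x`, `v = y` (the top-view frame);
#' a `y` plane has `u = x`, `v = z` (the cut-view frame through the
#' electrodes when `offset = 0`); an `x` plane has `u = y`, `v = z`.
#'
#' @param solution A `pfa_field`.
#' @param axis `"z"`, `"y"` or `"x"`: the axis normal to the plane.
#' @param offset Plane position along that axis, mm. Must lie within the
#'   cell-center range of the grid.
#' @return A `pfa_plane`: `u`, `v` coordinate vectors (mm), matrices `e`
#'   (V/cm) and `phi` (V), the plane spec, and the spacing `h`.
#' @export
slice_field <- function(solution, axis = c("z", "y", "x"), offset = 0) {
  axis <- match.arg(axis)
  ax_i <- match(axis, c("x", "y", "z"))
  coords <- solution[[axis]]
  if (offset < min(coords) || offset > max(coords)) {
    stop(sprintf("plane %s = %g mm lies outside the grid range [%g, %g]",
                 axis, offset, min(coords), max(coords)), call. = FALSE)
  }
  k <- findInterval(offset, coords, rightmost.closed = TRUE)
  k <- min(max(k, 1), length(coords) - 1)
  w <- (offset - coords[k]) / (coords[k + 1] - coords[k])
  take <- function(arr, i) {
    sel <- list(TRUE, TRUE, TRUE)
    sel[[ax_i]] <- i
    m <- do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
    dd <- dim(m)
    matrix(m, nrow = dd[setdiff(1:3, ax_i)[1]], ncol = dd[setdiff(1:3, ax_i)[2]])
  }
  interp <- function(arr) (1 - w) * take(arr, k) + w * take(arr, k + 1)
  uv <- switch(axis,
    z = list(u = solution$x, v = solution$y),
    y = list(u = solution$x, v = solution$z),
    x = list(u = solution$y, v = solution$z))
  structure(list(u = uv$u, v = uv$v, e = interp(solution$e_vcm),
                 phi = interp(solution$potential),
                 axis = axis, offset = offset, h = solution$h),
            class = "pfa_plane")
}

#' Extract |E| isolines from a field plane
#'
#' Marching-squares contours with linear interpolation (via
#' [grDevices::contourLines()]) at the requested field levels. Levels above
#' the plane maximum simply yield no contours.
#'
#' @param plane A `pfa_plane`.
#' @param levels Field levels in V/cm, all strictly positive.
#' @return A `pfa_isolines` object: list with `levels` and `contours`, the
#'   latter a list of data frames (`x`, `y` in plane mm coordinates) each
#'   carrying attributes `level` and `closed`.
#' @export
extract_isolines <- function(plane, levels) {
  if (any(levels <= 0)) stop("isoline levels must be strictly positive", call. = FALSE)
  cl <- withCallingHandlers(
    grDevices::contourLines(plane$u, plane$v, plane$e, levels = levels),
    warning = function(w) {
      # a constant plane legitimately has no contours; not worth a warning
      if (grepl("all z values are equal", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  contours <- lapply(cl, function(cc) {
    closed <- isTRUE(all.equal(c(cc$x[1], cc$y[1]),
                               c(cc$x[length(cc$x)], cc$y[length(cc$y)])))
    structure(data.frame(x = cc$x, y = cc$y),
              level = cc$level, closed = closed)
  })
  structure(list(axis = plane$axis, offset = plane$offset,
                 levels = levels, contours = contours),
            class = "pfa_isolines")
}

# Exact superlevel area of the piecewise-linear interpolant on a triangle
# with vertex values v1 <= v2 <= v3 and area A: fraction of {f >= L}.
tri_superlevel_fraction <- function(v1, v2, v3, L) {
  frac <- numeric(length(v1))
  full <- L <= v1
  none <- L >= v3
  frac[full] <- 1
  mid_hi <- !full & !none & L >= v2
  if (any(mid_hi)) {
    d <- (v3 - v1) * (v3 - v2)
    frac[mid_hi] <- ifelse(d[mid_hi] > 0, (v3[mid_hi] - L)^2 / d[mid_hi], 0)
  }
  mid_lo <- !full & !none & L < v2
  if (any(mid_lo)) {
    d <- (v2 - v1) * (v3 - v1)
    frac[mid_lo] <- ifelse(d[mid_lo] > 0,
                           1 - (L - v1[mid_lo])^2 / d[mid_lo], 1)
  }
  frac
}

#' Area of the field superlevel set on a plane
#'
#' Area (mm^2) of the region where |E| meets or exceeds `level`, computed by
#' cell counting with fractional boundary cells: each grid cell is split
#' into four triangles (cell corners plus their mean at the center) on which
#' the linear interpolant's superlevel area is exact and in closed form. The
#' result is non-increasing in `level` by construction.
#'
#' @param plane A `pfa_plane` (or any list with `u`, `v`, `e`).
#' @param level Field level, V/cm, `> 0`.
#' @return Area in mm^2; 0 when the level exceeds the plane maximum and the
#'   full interpolation-domain area when it is below the minimum.
#' @export
superlevel_area <- function(plane, level) {
  if (level <= 0) stop("level must be > 0", call. = FALSE)
  e <- plane$e
  nu <- nrow(e); nv <- ncol(e)
  a <- e[-nu, -nv]; b <- e[-1, -nv]; c <- e[-1, -1]; d <- e[-nu, -1]
  ctr <- (a + b + c + d) / 4
  du <- diff(plane$u); dv <- diff(plane$v)
  cell_area <- outer(du, dv)
  tri_area <- as.vector(cell_area) / 4
  total <- 0
  for (pair in list(cbind(as.vector(a), as.vector(b)),
                    cbind(as.vector(b), as.vector(c)),
                    cbind(as.vector(c), as.vector(d)),
                    cbind(as.vector(d), as.vector(a)))) {
    p <- pair[, 1]; q <- pair[, 2]; r <- as.vector(ctr)
    v1 <- pmin(p, q, r); v3 <- pmax(p, q, r); v2 <- p + q + r - v1 - v3
    total <- total + sum(tri_area * tri_superlevel_fraction(v1, v2, v3, level))
  }
  total
}

# Bilinear interpolation of a plane field at arbitrary (x, y) points (mm).
# Returns NA outside the cell-center domain.
bilinear_sample <- function(plane, px, py) {
  u <- plane$u; v <- plane$v; e <- plane$e
  i <- findInterval(px, u)
  j <- findInterval(py, v)
  # points exactly on the upper edges still get the last cell
  i[px == u[length(u)]] <- length(u) - 1
  j[py == v[length(v)]] <- length(v) - 1
  ok <- i >= 1 & i < length(u) & j >= 1 & j < length(v)
  out <- rep(NA_real_, length(px))
  ii <- i[ok]; jj <- j[ok]
  tx <- (px[ok] - u[ii]) / (u[ii + 1] - u[ii])
  ty <- (py[ok] - v[jj]) / (v[jj + 1] - v[jj])
  f00 <- e[cbind(ii, jj)]; f10 <- e[cbind(ii + 1, jj)]
  f01 <- e[cbind(ii, jj + 1)]; f11 <- e[cbind(ii + 1, jj + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
  out
}

#' Export a field plane as CSV
#'
#' Long-format table with columns `x_mm`, `y_mm`, `E_V_per_cm` (plane
#' coordinates `u`, `v`).
#'
#' @param plane A `pfa_plane`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plane_csv <- function(plane, path) {
  df <- data.frame(x_mm = rep(plane$u, times = length(plane$v)),
                   y_mm = rep(plane$v, each = length(plane$u)),
                   E_V_per_cm = as.vector(plane$e))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a volumetric field as plain text
#'
#' Self-describing container: a JSON header (axis coordinates in mm, units,
#' dims) plus a flat CSV of values in column-major order.
#'
#' @param solution A `pfa_field`.
#' @param path_prefix Files `<prefix>_header.json` and `<prefix>_values.csv`
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_field_volume <- function(solution, path_prefix) {
  header <- list(dims = solution$dims, order = "column-major x,y,z",
                 x_mm = solution$x, y_mm = solution$y, z_mm = solution$z,
                 units = list(potential = "V", e = "V/cm"),
                 applied_voltage = solution$applied_voltage)
  hp <- paste0(path_prefix, "_header.json")
  vp <- paste0(path_prefix, "_values.csv")
  jsonlite::write_json(header, hp, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(potential_V = as.vector(solution$potential),
                              E_V_per_cm = as.vector(solution$e_vcm)),
                   vp, row.names = FALSE, quote = FALSE)
  invisible(c(hp, vp))
}

#' Render a field plane heatmap PNG with isoline overlays
#'
#' Writes an RGB PNG of |E| over the plane with optional isolines burned in,
#' for quick visual inspection of the field pattern around the electrode
#' pair.
#'
#' @param plane A `pfa_plane`.
#' @param path Output PNG path.
#' @param levels Optional isoline levels (V/cm) to overlay in white.
#' @param px_per_cell Integer upsampling factor.
#' @return `path`, invisibly.
#' @export
render_plane_png <- function(plane, path, levels = NULL, px_per_cell = 2) {
  e <- plane$e
  lo <- min(e); hi <- max(e)
  sc <- if (hi > lo) (e - lo) / (hi - lo) else e * 0
  pal <- grDevices::hcl.colors(256, "viridis")
  rgbm <- grDevices::col2rgb(pal[pmin(255, floor(sc * 255)) + 1]) / 255
  nu <- nrow(e); nv <- ncol(e)
  img <- array(0, dim = c(nv, nu, 3))  # row = v (down), col = u
  for (ch in 1:3) img[, , ch] <- t(matrix(rgbm[ch, ], nu, nv))[nv:1, ]
  if (px_per_cell > 1) {
    img <- img[rep(seq_len(nv), each = px_per_cell),
               rep(seq_len(nu), each = px_per_cell), , drop = FALSE]
  }
  if (!is.null(levels)) {
    iso <- extract_isolines(plane, levels)
    for (cc in iso$contours) {
      pxy <- mm_to_px(cc$x, cc$y, plane, px_per_cell)
      img <- draw_polyline(img, pxy$col, pxy$row, c(1, 1, 1))
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

# map plane mm coords to (row, col) in the rendered heatmap raster
mm_to_px <- function(x, y, plane, px_per_cell) {
  du <- plane$u[2] - plane$u[1]; dv <- plane$v[2] - plane$v[1]
  col <- ((x - plane$u[1]) / du + 0.5) * px_per_cell
  nv <- length(plane$v)
  row <- ((plane$v[nv] - y) / dv + 0.5) * px_per_cell
  list(row = row, col = col)
}

# densely sample each segment and set pixels; good enough for overlays
draw_polyline <- function(img, cols, rows, rgb) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  for (s in seq_len(length(cols) - 1)) {
    n <- max(2, ceiling(max(abs(cols[s + 1] - cols[s]),
                            abs(rows[s + 1] - rows[s])) * 2))
    cs <- round(seq(cols[s], cols[s + 1], length.out = n))
    rs <- round(seq(rows[s], rows[s + 1], length.out = n))
    keep <- cs >= 1 & cs <= nc & rs >= 1 & rs <= nr
    for (ch in 1:3) img[cbind(rs[keep], cs[keep], ch)] <- rgb[ch]
  }
  img
}
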