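# run code under a local, restored RNG state so renders are reproducible
# without disturbing the caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_ellipse <- function(a, b, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = a * cos(th), y = b * sin(th))
}

#' Construct a parametric ground-truth lesion
#'
#' Parametric lesion solids emulating the stained shapes seen on treated
#' tuber slices: a half-ellipsoid (semi-axes `a`, `b` in the surface plane,
#' `c` in depth), or a "peanut" (the union of two overlapping
#' half-ellipsoids with centers offset along x). Half-ellipsoid truth
#' metrics are closed-form (`A_top = pi a b`, depth `c`,
#' `V = (2/3) pi a b c`); peanut truth is computed by voxel brute force,
#' never by the similarity estimator under test.
#'
#' @param kind `"half_ellipsoid"` or `"peanut"`.
#' @param a,b,c Semi-axes, mm (x, y at the surface; c into depth).
#' @param offset Center-to-center lobe offset along x for the peanut, mm
#'   (0 degenerates to a single half-ellipsoid).
#' @param voxel Voxel pitch for brute-force truth, mm (default 0.05).
#' @param max_depth Maximum admissible depth (slab height), mm.
#' @return A `pfa_lesion`: truth metrics, membership predicates
#'   `inside_top(x, y)` and `inside_cut(x, z)` (mm, scene frame), truth
#'   polygons, and the lateral/depth extent.
#' @export
make_parametric_lesion <- function(kind = c("half_ellipsoid", "peanut"),
                                   a = 4, b = 3, c = 2, offset = 2,
                                   voxel = 0.05, max_depth = 20) {
  kind <- match.arg(kind)
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (c > max_depth) {
    stop(sprintf("non-physical lesion: depth %g mm exceeds slab height %g mm",
                 c, max_depth), call. = FALSE)
  }
  if (kind == "half_ellipsoid") {
    truth <- list(area_top = pi * a * b, depth = c, volume = 2 / 3 * pi * a * b * c)
    inside_top <- function(x, y) (x / a)^2 + (y / b)^2 <= 1
    inside_cut <- function(x, z) z >= 0 & (x / a)^2 + (z / c)^2 <= 1
    half_x <- a
    top_poly <- sample_ellipse(a, b)
    th <- seq(0, pi, length.out = 91)
    cut_poly <- cbind(x = a * cos(th), y = c * sin(th))  # depth positive down
  } else {
    x1 <- -offset / 2; x2 <- offset / 2
    inside_top <- function(x, y) {
      ((x - x1) / a)^2 + (y / b)^2 <= 1 | ((x - x2) / a)^2 + (y / b)^2 <= 1
    }
    inside_cut <- function(x, z) {
      z >= 0 & (((x - x1) / a)^2 + (z / c)^2 <= 1 |
                  ((x - x2) / a)^2 + (z / c)^2 <= 1)
    }
    half_x <- a + offset / 2
    # voxel brute force truth
    gx <- seq(-half_x, half_x, by = voxel)
    gy <- seq(-b, b, by = voxel)
    gz <- seq(0, c, by = voxel) + voxel / 2
    top <- outer(gx, gy, function(x, y) inside_top(x, y))
    vol_count <- 0
    for (z in gz) {
      sc <- sqrt(pmax(0, 1 - (z / c)^2))
      if (sc == 0) next
      lay <- outer(gx, gy, function(x, y) {
        ((x - x1) / a)^2 + (y / b)^2 <= sc^2 | ((x - x2) / a)^2 + (y / b)^2 <= sc^2
      })
      vol_count <- vol_count + sum(lay)
    }
    truth <- list(area_top = sum(top) * voxel^2, depth = c,
                  volume = vol_count * voxel^3)
    th <- seq(0, 2 * pi, length.out = 181)[-181]
    top_poly <- NULL
    cut_poly <- NULL
  }
  structure(list(kind = kind,
                 params = list(a = a, b = b, c = c,
                               offset = if (kind == "peanut") offset else NULL),
                 truth = truth, inside_top = inside_top, inside_cut = inside_cut,
                 top_poly = top_poly, cut_poly = cut_poly,
                 extent = list(half_x = half_x, half_y = b, depth = c)),
            class = "pfa_lesion")
}

#' Construct a lesion as a field superlevel set
#'
#' The ground-truth lesion predicted by a solved field: the 3-D set of slab
#' voxels where |E| meets or exceeds the lethal threshold. Truth metrics are
#' obtained by voxel counting at the solver resolution; the top mask is the
#' shallowest slab layer and the cut section is the mid-electrode vertical
#' plane (y = 0).
#'
#' @param solution A `pfa_field`.
#' @param threshold Lethal field threshold, V/cm; must lie within the field
#'   range so the superlevel set is nonempty.
#' @return A `pfa_lesion` with `generator = "field_superlevel"`, the
#'   generating `threshold`, voxel-truth metrics, and membership predicates
#'   backed by nearest-voxel lookup.
#' @export
make_field_lesion <- function(solution, threshold) {
  if (threshold > max(solution$e_vcm)) {
    stop(sprintf("threshold %g V/cm exceeds the field maximum %.1f V/cm",
                 threshold, max(solution$e_vcm)), call. = FALSE)
  }
  slab_k <- which(solution$z > 0)
  if (length(slab_k) == 0) stop("solution grid has no slab layers", call. = FALSE)
  vox <- solution$e_vcm[, , slab_k, drop = FALSE] >= threshold
  lab <- solution$material_map$label[, , slab_k, drop = FALSE]
  vox <- vox & lab == 2L
  if (!any(vox)) stop("empty superlevel set inside the slab", call. = FALSE)
  h <- solution$h
  zs <- solution$z[slab_k]
  top_mask <- vox[, , 1]
  jmid <- which.min(abs(solution$y))
  cut_mask <- vox[, jmid, ]  # x by z
  occupied <- which(vox, arr.ind = TRUE)
  depth <- max(zs[occupied[, 3]]) + h / 2
  truth <- list(area_top = sum(top_mask) * h^2,
                depth = depth,
                volume = sum(vox) * h^3)
  x <- solution$x; y <- solution$y
  inside_top <- function(px, py) {
    i <- round((px - x[1]) / h) + 1
    j <- round((py - y[1]) / h) + 1
    ok <- i >= 1 & i <= length(x) & j >= 1 & j <= length(y)
    out <- rep(FALSE, length(px))
    out[ok] <- top_mask[cbind(i[ok], j[ok])]
    out
  }
  inside_cut <- function(px, pz) {
    i <- round((px - x[1]) / h) + 1
    k <- round((pz - zs[1]) / h) + 1
    ok <- i >= 1 & i <= length(x) & k >= 1 & k <= length(zs) & pz >= 0
    out <- rep(FALSE, length(px))
    out[ok] <- cut_mask[cbind(i[ok], k[ok])]
    out
  }
  occ_x <- range(x[occupied[, 1]])
  occ_y <- range(y[occupied[, 2]])
  structure(list(kind = "field_superlevel", generator = "field_superlevel",
                 threshold = threshold,
                 params = list(threshold = threshold,
                               applied_voltage = solution$applied_voltage),
                 truth = truth, inside_top = inside_top, inside_cut = inside_cut,
                 top_poly = NULL, cut_poly = NULL,
                 extent = list(half_x = max(abs(occ_x)) + h,
                               half_y = max(abs(occ_y)) + h,
                               depth = depth)),
            class = "pfa_lesion")
}

#' Rendering specification for synthetic views
#'
#' Parameters of the synthetic photograph renderer: dark stained lesion on a
#' light tuber background, a linear illumination gradient, Gaussian sensor
#' noise, a burned-in scale bar, and electrode marks. The seed fixes the
#' output byte-exactly.
#'
#' @param mm_per_pixel Pixel pitch, mm (default 0.05, a close-up slice
#'   photograph scale).
#' @param background_luma,lesion_luma 8-bit luma values of tuber background
#'   and stained lesion.
#' @param gradient_amplitude Peak-to-center amplitude of the linear
#'   illumination gradient, luma units.
#' @param noise_sigma Gaussian noise standard deviation, luma units.
#' @param scale_bar_mm Scale-bar length, mm.
#' @param electrode_marks_mm 2 x 2 matrix of electrode mark scene
#'   coordinates (mm), default the bench electrode centers at x = +/- 1.
#' @param rotation_deg In-plane rotation of the scene within the image.
#' @param margin_mm Canvas margin around the lesion extent.
#' @param canvas_mm Optional fixed canvas width/height (mm); the render
#'   errors out if the lesion does not fit.
#' @param seed Integer RNG seed for the noise field.
#' @return A `pfa_render_spec` list.
#' @export
render_spec <- function(mm_per_pixel = 0.05, background_luma = 220,
                        lesion_luma = 40, gradient_amplitude = 10,
                        noise_sigma = 8, scale_bar_mm = 10,
                        electrode_marks_mm = rbind(c(1, 0), c(-1, 0)),
                        rotation_deg = 0, margin_mm = 2, canvas_mm = NULL,
                        seed = 1) {
  stopifnot(background_luma >= 0, background_luma <= 255,
            lesion_luma >= 0, lesion_luma <= 255, noise_sigma >= 0)
  structure(list(mm_per_pixel = mm_per_pixel, background_luma = background_luma,
                 lesion_luma = lesion_luma,
                 gradient_amplitude = gradient_amplitude,
                 noise_sigma = noise_sigma, scale_bar_mm = scale_bar_mm,
                 electrode_marks_mm = electrode_marks_mm,
                 rotation_deg = rotation_deg, margin_mm = margin_mm,
                 canvas_mm = canvas_mm, seed = seed),
            class = "pfa_render_spec")
}

# one grayscale canvas -> finished 8-bit image matrix with gradient + noise
finish_canvas <- function(lum, spec, seed_offset) {
  nc <- ncol(lum); nr <- nrow(lum)
  ramp <- matrix(rep((2 * (seq_len(nc) / nc) - 1) * spec$gradient_amplitude,
                     each = nr), nr, nc)
  lum <- lum + ramp
  if (spec$noise_sigma > 0) {
    lum <- lum + with_local_seed(spec$seed + seed_offset,
                                 matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma),
                                        nr, nc))
  }
  round(pmin(pmax(lum, 0), 255))
}

burn_disk <- function(lum, cx, cy, r_px, value) {
  nr <- nrow(lum); nc <- ncol(lum)
  xr <- max(1, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
  yr <- max(1, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
  for (x in xr) for (y in yr) {
    if ((x - cx)^2 + (y - cy)^2 <= r_px^2) lum[y, x] <- value
  }
  lum
}

#' Render synthetic top and cut views of a lesion
#'
#' Produces 8-bit RGB PNGs of the two orthogonal views plus a JSON truth
#' sidecar holding every ground-truth value and the render transform, so the
#' full measurement pipeline can be validated against known answers.
#'
#' The top view maps scene (x, y) mm onto the canvas (optionally rotated);
#' the cut view shows the (x, z) plane with the slice surface at a known
#' row and depth increasing downward. Both carry a burned-in scale bar; the
#' top view carries electrode marks.
#'
#' @param lesion A `pfa_lesion`.
#' @param spec A [render_spec()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for `\<stem\>_top.png`, `\<stem\>_cut.png`,
#'   `\<stem\>_truth.json`.
#' @return List with `top`, `cut`, `truth_path` file paths and the `truth`
#'   sidecar contents, invisibly usable by the pipeline.
#' @export
render_views <- function(lesion, spec = render_spec(), dir, basename = "lesion") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpp <- spec$mm_per_pixel
  ext <- lesion$extent
  bar_gap_mm <- 1.5
  half_w <- max(ext$half_x, ext$half_y) + spec$margin_mm
  if (!is.null(spec$canvas_mm)) {
    if (spec$canvas_mm / 2 < max(ext$half_x, ext$half_y)) {
      stop("lesion exceeds the requested canvas", call. = FALSE)
    }
    half_w <- spec$canvas_mm / 2
  }
  half_w <- max(half_w, spec$scale_bar_mm / 2 + 1)
  npx <- 2 * ceiling(half_w / mpp) + 1
  n_bar_rows <- ceiling((bar_gap_mm + 0.5) / mpp)
  nr <- npx + n_bar_rows
  th <- spec$rotation_deg * pi / 180
  # pixel centers -> scene mm (scene origin at canvas center, rotation th)
  px_x <- (seq_len(npx) - (npx + 1) / 2) * mpp
  px_y <- (seq_len(npx) - (npx + 1) / 2) * mpp
  xm <- matrix(rep(px_x, each = npx), npx, npx)   # row = y, col = x
  ym <- matrix(rep(px_y, times = npx), npx, npx)
  sx <- cos(th) * xm + sin(th) * ym
  sy <- -sin(th) * xm + cos(th) * ym

  lum_top <- matrix(spec$background_luma, nr, npx)
  inside <- matrix(lesion$inside_top(as.vector(sx), as.vector(sy)), npx, npx)
  lum_top[seq_len(npx), ][inside] <- spec$lesion_luma

  # scale bar along the bottom margin
  bar_row <- npx + ceiling(bar_gap_mm / mpp)
  bar_px <- round(spec$scale_bar_mm / mpp)
  bar_c0 <- round((npx - bar_px) / 2)
  lum_top[bar_row + (-1:1), bar_c0:(bar_c0 + bar_px)] <- 0
  scale_points <- rbind(c(bar_c0, bar_row), c(bar_c0 + bar_px, bar_row))

  # electrode marks (scene mm -> px)
  marks_px <- NULL
  for (i in seq_len(nrow(spec$electrode_marks_mm))) {
    p <- spec$electrode_marks_mm[i, ]
    ix <- cos(th) * p[1] - sin(th) * p[2]
    iy <- sin(th) * p[1] + cos(th) * p[2]
    col <- ix / mpp + (npx + 1) / 2
    row <- iy / mpp + (npx + 1) / 2
    lum_top <- burn_disk(lum_top, col, row, 2, 0)
    marks_px <- rbind(marks_px, c(col, row))
  }
  lum_top <- finish_canvas(lum_top, spec, seed_offset = 0)

  # cut view: x across, z down from the surface row
  surface_row <- ceiling(spec$margin_mm / mpp)
  nz <- ceiling((ext$depth + 1) / mpp)
  nr_cut <- surface_row + nz + n_bar_rows
  lum_cut <- matrix(spec$background_luma, nr_cut, npx)
  zc <- (seq_len(nz) - 0.5) * mpp
  xm2 <- matrix(rep(px_x, each = nz), nz, npx)
  zm2 <- matrix(rep(zc, times = npx), nz, npx)
  inside_c <- matrix(lesion$inside_cut(as.vector(xm2), as.vector(zm2)), nz, npx)
  block <- lum_cut[surface_row + seq_len(nz), ]
  block[inside_c] <- spec$lesion_luma
  lum_cut[surface_row + seq_len(nz), ] <- block
  bar_row_c <- surface_row + nz + ceiling(bar_gap_mm / mpp)
  lum_cut[bar_row_c + (-1:1), bar_c0:(bar_c0 + bar_px)] <- 0
  scale_points_cut <- rbind(c(bar_c0, bar_row_c), c(bar_c0 + bar_px, bar_row_c))
  # top-line endpoints: lesion x-extent in the first tissue row
  srow <- which(inside_c[1, ])
  top_line_px <- if (length(srow) >= 2) {
    rbind(c(min(srow), surface_row + 0.5), c(max(srow), surface_row + 0.5))
  } else NULL
  lum_cut <- finish_canvas(lum_cut, spec, seed_offset = 1)

  to_rgb <- function(lum) {
    arr <- array(0, dim = c(nrow(lum), ncol(lum), 3))
    for (ch in 1:3) arr[, , ch] <- lum / 255
    arr
  }
  top_path <- file.path(dir, paste0(basename, "_top.png"))
  cut_path <- file.path(dir, paste0(basename, "_cut.png"))
  truth_path <- file.path(dir, paste0(basename, "_truth.json"))
  png::writePNG(to_rgb(lum_top), top_path)
  png::writePNG(to_rgb(lum_cut), cut_path)

  truth <- list(kind = lesion$kind, params = lesion$params,
                truth = lesion$truth,
                mm_per_pixel = mpp, rotation_deg = spec$rotation_deg,
                background_luma = spec$background_luma,
                lesion_luma = spec$lesion_luma,
                gradient_amplitude = spec$gradient_amplitude,
                noise_sigma = spec$noise_sigma, seed = spec$seed,
                canvas_px = c(nr, npx),
                scene_center_px = c((npx + 1) / 2, (npx + 1) / 2),
                scale_bar = list(points_px = scale_points,
                                 points_px_cut = scale_points_cut,
                                 length_mm = spec$scale_bar_mm),
                electrode_marks_px = marks_px,
                cut = list(surface_row_px = surface_row,
                           top_line_px = top_line_px))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(top = top_path, cut = cut_path, truth_path = truth_path, truth = truth)
}
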