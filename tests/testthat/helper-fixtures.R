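# Shared fixtures: all built in code at test time.

# Small bench scene for fast 3-D solves (coarse grid, tight domain).
small_scene <- function(spacing = 0.2, half = 4, depth = 4, ...) {
  scene_config(solver = list(spacing = spacing, lateral_half_extent = half,
                             slab_depth_extent = depth),
               ...)
}

# Hand-built homogeneous material map with two parallel cylinder electrodes
# along z (single z layer => the planar two-wire problem). Uses the same
# half-cell inflation convention as the package rasterizer.
twowire_map <- function(h, L = 40, a = 0.315, D = 2.0, sigma0 = 1) {
  n <- 2 * floor((L / 2) / h) + 1
  x <- (seq_len(n) - (n + 1) / 2) * h
  a_eff <- a + h / 2
  mask <- array(0L, dim = c(n, n, 1))
  mask[, , 1][outer((x - D / 2)^2, x^2, `+`) <= a_eff^2] <- 1L
  mask[, , 1][outer((x + D / 2)^2, x^2, `+`) <= a_eff^2] <- 2L
  list(sigma = array(sigma0, dim = c(n, n, 1)), dirichlet_mask = mask,
       label = array(1L, dim = c(n, n, 1)),
       x = x, y = x, z = 0, h = h, dims = c(n, n, 1L),
       config = list(solver = list(tolerance = 1e-8, max_iterations = 50000)))
}

# Closed-form |E| at the midpoint between two parallel wire electrodes
# (radius a, center distance D, voltage difference V across them), V/cm.
twowire_midpoint_field <- function(V, a, D) {
  s <- sqrt((D / 2)^2 - a^2)
  V / (acosh(D / (2 * a)) * s) * 10
}

# Radial 2-D field plane |E| = C / r on an n x n grid of pitch h (mm).
radial_plane <- function(C = 100, h = 0.05, L = 10) {
  n <- 2 * floor((L / 2) / h) + 1
  x <- (seq_len(n) - (n + 1) / 2) * h
  r <- sqrt(outer(x^2, x^2, `+`))
  r[r < h / 2] <- h / 2
  list(u = x, v = x, e = C / r, h = h)
}

# Cached coarse bench solves, shared across test files in one session.
.solve_cache <- new.env(parent = emptyenv())
cached_solution <- function(voltage = 100, spacing = 0.2, half = 4, depth = 4) {
  key <- paste(voltage, spacing, half, depth, sep = "_")
  if (is.null(.solve_cache[[key]])) {
    mm <- rasterize_materials(small_scene(spacing, half, depth))
    .solve_cache[[key]] <- solve_potential(mm, voltage)
  }
  .solve_cache[[key]]
}

# Binary mask image (0-255 luma matrix) from a membership predicate on a
# pixel grid: predicate takes mm coordinates centred on the canvas.
predicate_image <- function(inside, half_mm, mpp, lesion = 40, background = 220) {
  n <- 2 * ceiling(half_mm / mpp) + 1
  cx <- (seq_len(n) - (n + 1) / 2) * mpp
  xm <- matrix(rep(cx, each = n), n, n)
  ym <- matrix(rep(cx, times = n), n, n)
  lum <- matrix(background, n, n)
  lum[matrix(inside(as.vector(xm), as.vector(ym)), n, n)] <- lesion
  lum
}

px_calibration <- function(mpp) {
  # 100 px apart, distance chosen to give the requested mm/px
  calibrate(c(0, 0), c(100, 0), 100 * mpp)
}

# evenly densify polygon edges (closed) for distance comparisons
densify_polygon <- function(poly, step) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    seg <- sqrt(sum((poly[j, ] - poly[i, ])^2))
    m <- max(2, ceiling(seg / step))
    out <- rbind(out, cbind(seq(poly[i, 1], poly[j, 1], length.out = m)[-m],
                            seq(poly[i, 2], poly[j, 2], length.out = m)[-m]))
  }
  out
}
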