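# 2-D polygon utilities used by the cut-view tracer and the volumetry.
# Polygons are data frames / matrices with columns x, y (mm), implicitly
# closed (last vertex connects back to the first).

polygon_area <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_centroid <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  cr <- x * y[c(2:n, 1)] - x[c(2:n, 1)] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[c(2:n, 1)]) * cr) / (6 * a),
    sum((y + y[c(2:n, 1)]) * cr) / (6 * a))
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# {p : dot(p - p0, n) >= 0}
clip_halfplane <- function(poly, p0, n_dir) {
  px <- poly[, 1]; py <- poly[, 2]
  d <- (px - p0[1]) * n_dir[1] + (py - p0[2]) * n_dir[2]
  m <- length(px)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    di <- d[i]; dj <- d[j]
    if (di >= 0) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
    if ((di >= 0) != (dj >= 0)) {
      t <- di / (di - dj)
      ox <- c(ox, px[i] + t * (px[j] - px[i]))
      oy <- c(oy, py[i] + t * (py[j] - py[i]))
    }
  }
  cbind(x = ox, y = oy)
}

# Ramer-Douglas-Peucker polyline simplification (tolerance in input units)
rdp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- rng[1]; b <- rng[2]
    if (b - a < 2) next
    ax <- pts[a, 1]; ay <- pts[a, 2]
    bx <- pts[b, 1]; by <- pts[b, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    idx <- (a + 1):(b - 1)
    if (len2 == 0) {
      dist <- sqrt((pts[idx, 1] - ax)^2 + (pts[idx, 2] - ay)^2)
    } else {
      dist <- abs(vx * (pts[idx, 2] - ay) - vy * (pts[idx, 1] - ax)) / sqrt(len2)
    }
    k <- which.max(dist)
    if (dist[k] > tol) {
      m <- idx[k]
      keep[m] <- TRUE
      stack <- c(stack, list(c(a, m), c(m, b)))
    }
  }
  pts[keep, , drop = FALSE]
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# first pair of properly-crossing non-adjacent edges, or NULL
polygon_self_intersection <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(NULL)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n - 1 && i == 1) next
      jn <- if (j == n) 1 else j + 1
      if (segments_intersect(poly[i, ], poly[i + 1, ], poly[j, ], poly[jn, ])) {
        return(c(i, j))
      }
    }
  }
  NULL
}

# Total covered chord length of a polygon cut by the horizontal line t = z
# in (s, t) coordinates: sum of alternating intervals between sorted edge
# crossings (even-odd rule, half-open at vertices so counts stay even).
# mode "single" returns the largest single interval instead of the sum.
polygon_chord <- function(s, t, z, mode = c("total", "single")) {
  mode <- match.arg(mode)
  n <- length(s)
  nxt <- c(2:n, 1)
  t1 <- t; t2 <- t[nxt]
  cross <- (t1 <= z & t2 > z) | (t2 <= z & t1 > z)
  if (!any(cross)) return(0)
  frac <- (z - t1[cross]) / (t2[cross] - t1[cross])
  sx <- sort(s[cross] + frac * (s[nxt][cross] - s[cross]))
  m <- length(sx)
  if (m %% 2 == 1) sx <- sx[-m]  # degenerate tangency guard
  if (length(sx) == 0) return(0)
  widths <- sx[seq(2, length(sx), by = 2)] - sx[seq(1, length(sx), by = 2)]
  if (mode == "total") sum(widths) else max(widths)
}

# even-odd point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# symmetric Hausdorff distance between two point sets (vertex-sampled)
hausdorff_distance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}
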