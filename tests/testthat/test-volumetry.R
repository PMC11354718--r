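semicircle_polygon <- function(R = 5, n = 720) {
  th <- seq(0, pi, length.out = n)
  cut_polygon(cbind(R * cos(th), R * sin(th)), rbind(c(-R, 0), c(R, 0)))
}

half_ellipse_polygon <- function(a, c, n = 720) {
  th <- seq(0, pi, length.out = n)
  cut_polygon(cbind(a * cos(th), c * sin(th)), rbind(c(-a, 0), c(a, 0)))
}

test_that("rectangle profile is flat and its volume is A_top x d exactly", {
  rect <- cut_polygon(rbind(c(-2, 0), c(2, 0), c(2, 2), c(-2, 2)),
                      rbind(c(-2, 0), c(2, 0)))
  prof <- width_ratio_profile(rect, n_slices = 51)
  expect_equal(prof$ratio, rep(1, 51), tolerance = 1e-8)
  vol <- similarity_volume(25, prof)
  expect_equal(vol$volume, 50, tolerance = 1e-7)  # trapezoid exact on constants
  expect_lte(vol$volume, 25 * 2 * (1 + 1e-9))
})

test_that("semicircle width ratios follow the circle chord identity", {
  R <- 5
  prof <- width_ratio_profile(semicircle_polygon(R), n_slices = 101)
  expected <- sqrt(pmax(0, 1 - (prof$z_mm / R)^2))
  expect_lt(max(abs(prof$ratio - expected)), 0.005)
  expect_equal(prof$ratio[1], 1, tolerance = 1e-6)
})

test_that("hemisphere volume matches the closed form within 0.1%", {
  R <- 5
  prof <- width_ratio_profile(semicircle_polygon(R, n = 2000), n_slices = 101)
  vol <- similarity_volume(pi * R^2, prof)
  expect_equal(vol$volume, 2 / 3 * pi * R^3, tolerance = 0.001)
})

test_that("half-ellipsoid volume matches (2/3) pi a b c within 1%", {
  prof <- width_ratio_profile(half_ellipse_polygon(4, 2), n_slices = 101)
  vol <- similarity_volume(pi * 4 * 3, prof)
  expect_equal(vol$volume, 2 / 3 * pi * 4 * 3 * 2, tolerance = 0.01)
})

test_that("trapezoid volume is converged at 101 slices", {
  prof1 <- width_ratio_profile(half_ellipse_polygon(4, 2.5), n_slices = 101)
  prof2 <- width_ratio_profile(half_ellipse_polygon(4, 2.5), n_slices = 201)
  v1 <- similarity_volume(30, prof1)$volume
  v2 <- similarity_volume(30, prof2)$volume
  expect_lt(abs(v2 - v1) / v1, 0.002)
})

test_that("non-convex sections sum their sub-chords", {
  # butterfly: two 1-mm-wide lobes separated by a 2-mm gap below z = 1
  butterfly <- cut_polygon(rbind(
    c(-2, 0), c(2, 0), c(2, 2), c(1, 2), c(1, 0.9), c(-1, 0.9), c(-1, 2), c(-2, 2)),
    rbind(c(-2, 0), c(2, 0)))
  prof <- width_ratio_profile(butterfly, n_slices = 41)
  # brute-force scanline oracle at z = 1.5: covered x at that depth
  xs <- seq(-2.2, 2.2, by = 0.001)
  covered <- points_in_polygon(xs, rep(1.5, length(xs)),
                               as.matrix(butterfly$vertices))
  oracle <- sum(covered) * 0.001 / 4  # ratio of chord to the 4-mm top line
  z_idx <- which.min(abs(prof$z_mm - 1.5))
  expect_equal(prof$ratio[z_idx], oracle, tolerance = 0.01)
  expect_equal(prof$ratio[z_idx], 0.5, tolerance = 0.01)  # 2 of 4 mm covered
  # single-interval alternative reports the widest lobe only
  prof_s <- width_ratio_profile(butterfly, n_slices = 41, chord_mode = "single")
  expect_equal(prof_s$ratio[z_idx], 0.25, tolerance = 0.01)
})

test_that("similarity volume agrees with 3-D voxel counting on scaled solids", {
  set.seed(7)
  for (rep in 1:3) {
    a <- stats::runif(1, 2.5, 4.5)
    b <- stats::runif(1, 2, 3.5)
    d <- stats::runif(1, 1.5, 3)
    p <- stats::runif(1, 0.6, 1.4)
    r_of_z <- function(z) (1 - (z / d)^2)^(p / 2)  # generalized dome
    # voxel brute force: stack of r(z)-scaled ellipse slices
    vox <- 0.05
    zs <- seq(vox / 2, d, by = vox)
    gx <- seq(-a - vox, a + vox, by = vox)
    gy <- seq(-b - vox, b + vox, by = vox)
    counts <- vapply(zs, function(z) {
      s <- r_of_z(z)
      sum(outer((gx / (a * s))^2, (gy / (b * s))^2, `+`) <= 1)
    }, numeric(1))
    v_brute <- sum(counts) * vox^3
    # similarity estimator fed the exact cut section
    zz <- seq(0, d, length.out = 400)
    half_chord <- a * r_of_z(zz)
    poly <- cut_polygon(cbind(c(half_chord, -rev(half_chord)), c(zz, rev(zz))),
                        rbind(c(-a, 0), c(a, 0)))
    vol <- similarity_volume(pi * a * b, width_ratio_profile(poly, 201))
    expect_equal(vol$volume, v_brute, tolerance = 0.01)
  }
})

test_that("degenerate and invalid inputs are handled", {
  flat <- cut_polygon(rbind(c(-1, 0), c(1, 0), c(0, 1e-12)),
                      rbind(c(-1, 0), c(1, 0)))
  prof <- width_ratio_profile(flat, n_slices = 11)
  expect_lt(similarity_volume(10, prof)$volume, 1e-10)
  rect <- cut_polygon(rbind(c(-1, 0), c(1, 0), c(1, 1), c(-1, 1)),
                      rbind(c(-1, 0), c(1, 0)))
  expect_error(width_ratio_profile(rect, n_slices = 1), "n_slices")
  expect_error(similarity_volume(-1, width_ratio_profile(rect, 11)), "area_top")
})

test_that("ratios above the cap are clipped with a warning", {
  # lesion wider at depth than at the surface: ratio > 1
  bulge <- cut_polygon(rbind(c(-1, 0), c(1, 0), c(2, 1), c(-2, 1)),
                       rbind(c(-1, 0), c(1, 0)))
  expect_warning(prof <- width_ratio_profile(bulge, n_slices = 21), "capped")
  expect_lte(max(prof$ratio), 1.05)
  expect_true(attr(prof, "capped"))
})

test_that("self-similar synthetic fields show near-zero shape discrepancy", {
  h <- 0.1
  n <- 81
  x <- (seq_len(n) - (n + 1) / 2) * h
  nz <- 30
  z <- seq(-0.45, 2.45, length.out = nz)
  e <- array(0, dim = c(n, n, nz))
  r <- sqrt(outer(x^2, x^2, `+`)); r[r < h / 2] <- h / 2
  for (k in seq_len(nz)) e[, , k] <- 100 / (r * (1 + 0.3 * max(z[k], 0)))
  fake <- structure(list(e_vcm = e, potential = e, x = x, y = x, z = z,
                         h = h, dims = c(n, n, nz)), class = "pfa_field")
  diag <- validate_similarity_assumption(fake, 60)
  expect_lt(diag$mean_discrepancy, 0.06)
  expect_true(all(diag$discrepancy >= 0 & diag$discrepancy <= 1))
})
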