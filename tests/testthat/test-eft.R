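dummy_mask <- function(mpp) {
  structure(list(mask = matrix(TRUE, 10, 10), threshold = 120,
                 calibration = px_calibration(mpp), view = "top", empty = FALSE),
            class = "pfa_mask")
}

test_that("area matching inverts the superlevel area", {
  sol <- cached_solution(100)
  pl <- slice_field(sol, "z", min(sol$z[sol$z > 0]))
  for (L in c(150, 300, 500)) {
    a <- superlevel_area(pl, L)
    est <- eft_by_area_match(a, pl)
    expect_equal(est$threshold, L, tolerance = 0.01)
    expect_equal(est$flag, "ok")
    expect_lte(est$residual, 0.005)
  }
})

test_that("area matching recovers the analytic level of a radial field", {
  pl <- radial_plane(C = 100, h = 0.02, L = 12)
  for (L in c(30, 55)) {
    est <- eft_by_area_match(pi * (100 / L)^2, pl)
    expect_equal(est$threshold, L, tolerance = 0.01)
  }
})

test_that("lesions larger than the attainable area are flagged, not returned", {
  pl <- radial_plane(C = 100, h = 0.05, L = 10)
  full <- (length(pl$u) - 1) * (length(pl$v) - 1) * pl$h^2
  est <- eft_by_area_match(full * 2, pl)
  expect_equal(est$flag, "below_range")
  expect_error(eft_by_area_match(0, pl), "> 0")
})

test_that("a doubled field doubles the area-matched threshold", {
  sol <- cached_solution(100)
  pl <- slice_field(sol, "z", min(sol$z[sol$z > 0]))
  pl2 <- pl
  pl2$e <- pl$e * 2
  a <- superlevel_area(pl, 250)
  est1 <- eft_by_area_match(a, pl)
  est2 <- eft_by_area_match(a, pl2)
  expect_equal(est2$threshold / est1$threshold, 2, tolerance = 0.01)
})

test_that("boundary sampling on an isoline returns the level at any quantile", {
  pl <- radial_plane(C = 100, h = 0.02, L = 12)
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  rho <- 2
  circle <- cbind(rho * cos(th), rho * sin(th))
  for (q in c(0, 0.5, 1)) {
    est <- eft_by_boundary_quantile(circle, pl, q)
    expect_equal(est$threshold, 100 / rho, tolerance = 0.01)
  }
  expect_lt(eft_by_boundary_quantile(circle, pl)$iqr, 0.5)
})

test_that("jittered boundaries keep the median near the level with nonzero IQR", {
  pl <- radial_plane(C = 100, h = 0.02, L = 12)
  th <- seq(0, 2 * pi, length.out = 300)[-300]
  L <- 40
  rho <- 100 / L
  set.seed(123)
  jitter <- cbind((rho + stats::rnorm(length(th), 0, 0.1)) * cos(th),
                  (rho + stats::rnorm(length(th), 0, 0.1)) * sin(th))
  est <- eft_by_boundary_quantile(jitter, pl, 0.5)
  expect_equal(est$threshold, L, tolerance = 0.05)
  expect_gt(est$iqr, 0)
})

test_that("boundaries outside the field domain raise vertex errors", {
  pl <- radial_plane(C = 100, h = 0.05, L = 10)
  bad <- rbind(c(0, 1), c(20, 0))
  expect_error(eft_by_boundary_quantile(bad, pl), "outside")
  expect_error(eft_by_boundary_quantile(rbind(c(0, 1), c(1, 0)), pl, quantile = 2),
               "quantile")
})

test_that("registration maps electrode marks onto the scene axis", {
  mpp <- 0.05
  mask <- dummy_mask(mpp)
  scene <- default_scene()
  # marks already at the scene positions: (+-1, 0) mm around pixel (200, 200)
  marks <- rbind(c(200 + 1 / mpp, 200), c(200 - 1 / mpp, 200))
  reg <- register_lesion(mask, marks, scene)
  expect_equal(reg$rotation, diag(2), tolerance = 1e-12)
  expect_equal(unname(transform_points(reg, rbind(c(200, 200)))[1, ]), c(0, 0),
               tolerance = 1e-9)
  expect_lt(reg$residual, 1e-9)
  # swapped marks: same residual, 180 degree rotation
  reg_sw <- register_lesion(mask, marks[2:1, ], scene)
  expect_equal(reg_sw$residual, reg$residual)
  expect_equal(abs(reg_sw$angle_deg), 180)
  expect_error(register_lesion(mask, rbind(c(100, 100), c(105, 100)), scene),
               "cannot orient")
})

test_that("registration recovers the renderer's transform", {
  sol <- cached_solution(300)
  lesion <- make_field_lesion(sol, 240)
  dir <- withr::local_tempdir()
  rot_true <- 25
  rv <- render_views(lesion, render_spec(seed = 2, rotation_deg = rot_true), dir)
  cal <- calibrate(rv$truth$scale_bar$points_px[1, ],
                   rv$truth$scale_bar$points_px[2, ],
                   rv$truth$scale_bar$length_mm)
  mask <- segment_stained(read_lesion_image(rv$top), 120, cal, "top")
  reg <- register_lesion(mask, rv$truth$electrode_marks_px, default_scene())
  expect_equal(reg$angle_deg, rot_true, tolerance = 1 / 25)  # within 1 degree
  center <- transform_points(reg, rbind(rv$truth$scene_center_px))
  expect_lt(sqrt(sum(center^2)), 0.1)  # scene origin recovered within 0.1 mm
})

test_that("batch reports aggregate mean and SEM per method", {
  e1 <- eft_by_area_match(superlevel_area(radial_plane(100, 0.05, 10), 50),
                          radial_plane(100, 0.05, 10))
  one <- eft_batch_report(list(e1))
  expect_equal(one$n, 1)
  expect_equal(one$eft_mean_V_per_cm, e1$threshold)
  expect_false(one$sem_defined)

  same <- eft_batch_report(data.frame(threshold = rep(240, 5),
                                      method = "area_match"))
  expect_equal(same$eft_sem_V_per_cm, 0)

  set.seed(42)
  vals <- stats::rnorm(10, 240, 12)
  rep10 <- eft_batch_report(data.frame(threshold = vals, method = "area_match"))
  expect_equal(rep10$eft_mean_V_per_cm, mean(vals))
  expect_equal(rep10$eft_sem_V_per_cm, stats::sd(vals) / sqrt(10))
  expect_error(eft_batch_report(list()), "at least one")
})
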