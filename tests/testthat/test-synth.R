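test_that("parametric lesion truths follow the closed forms", {
  hemi <- make_parametric_lesion("half_ellipsoid", a = 3, b = 3, c = 3)
  expect_equal(hemi$truth$volume, 2 / 3 * pi * 27)
  expect_equal(hemi$truth$area_top, pi * 9)
  expect_equal(hemi$truth$depth, 3)
  he <- make_parametric_lesion("half_ellipsoid", a = 4, b = 3, c = 2)
  expect_equal(he$truth$volume, 2 / 3 * pi * 4 * 3 * 2)
  expect_error(make_parametric_lesion("half_ellipsoid", a = 4, b = 3, c = 25),
               "depth")
  expect_error(make_parametric_lesion("half_ellipsoid", a = -1), "> 0")
})

test_that("peanut voxel truth is consistent with the analytic limit", {
  single <- make_parametric_lesion("half_ellipsoid", a = 3, b = 2, c = 1.5)
  degen <- make_parametric_lesion("peanut", a = 3, b = 2, c = 1.5, offset = 0)
  expect_equal(degen$truth$volume, single$truth$volume, tolerance = 0.005)
  expect_equal(degen$truth$area_top, single$truth$area_top, tolerance = 0.005)
  # overlapping lobes: more than one, less than two ellipsoids
  pea <- make_parametric_lesion("peanut", a = 3, b = 2, c = 1.5, offset = 2.5)
  expect_gt(pea$truth$volume, single$truth$volume)
  expect_lt(pea$truth$volume, 2 * single$truth$volume)
})

test_that("field superlevel lesions nest and validate their threshold", {
  sol <- cached_solution(100)
  expect_error(make_field_lesion(sol, max(sol$e_vcm) * 2), "exceeds")
  l_lo <- make_field_lesion(sol, 150)
  l_hi <- make_field_lesion(sol, 300)
  expect_gt(l_lo$truth$volume, l_hi$truth$volume)
  expect_gt(l_lo$truth$area_top, l_hi$truth$area_top)
  # voxel-wise nesting on the top mask via the membership predicate
  xs <- stats::runif(500, -3, 3)
  ys <- stats::runif(500, -3, 3)
  hi_in <- l_hi$inside_top(xs, ys)
  expect_true(all(l_lo$inside_top(xs, ys)[hi_in]))
})

test_that("renders are byte-deterministic in the seed and truth is seed-free", {
  lesion <- make_parametric_lesion("half_ellipsoid", a = 3, b = 2, c = 1.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  r1 <- render_views(lesion, render_spec(seed = 11), d1)
  r2 <- render_views(lesion, render_spec(seed = 11), d2)
  r3 <- render_views(lesion, render_spec(seed = 12), d3)
  md5 <- function(p) unname(tools::md5sum(p))
  expect_identical(md5(r1$top), md5(r2$top))
  expect_identical(md5(r1$cut), md5(r2$cut))
  expect_false(identical(md5(r1$top), md5(r3$top)))
  # different seeds change only the noise, never the truth sidecar values
  expect_identical(r1$truth$truth, r3$truth$truth)
  # rendering does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); render_views(lesion, render_spec(seed = 5), withr::local_tempdir())
  expect_identical(stats::runif(1), before)
})

test_that("noiseless renders contain exactly the specified luma levels", {
  lesion <- make_parametric_lesion("half_ellipsoid", a = 2, b = 2, c = 1)
  dir <- withr::local_tempdir()
  rv <- render_views(lesion, render_spec(noise_sigma = 0, gradient_amplitude = 0),
                     dir)
  img <- read_lesion_image(rv$top)
  lum <- round(luma_rec601(img))
  expect_setequal(unique(as.vector(lum)), c(0, 40, 220))  # marks/bar, lesion, tuber
})

test_that("render/segment round trip recovers the truth metrics", {
  lesion <- make_parametric_lesion("half_ellipsoid", a = 4, b = 3, c = 2)
  dir <- withr::local_tempdir()
  rv <- render_views(lesion, render_spec(seed = 3, noise_sigma = 8), dir)
  cal <- calibrate(rv$truth$scale_bar$points_px[1, ],
                   rv$truth$scale_bar$points_px[2, ],
                   rv$truth$scale_bar$length_mm)
  expect_equal(cal$mm_per_pixel, rv$truth$mm_per_pixel, tolerance = 0.01)
  top <- segment_stained(read_lesion_image(rv$top), 120, cal, "top")
  expect_equal(measure_area(top), lesion$truth$area_top, tolerance = 0.02)
  cut_cal <- calibrate(rv$truth$scale_bar$points_px_cut[1, ],
                       rv$truth$scale_bar$points_px_cut[2, ],
                       rv$truth$scale_bar$length_mm)
  cut <- segment_stained(read_lesion_image(rv$cut), 120, cut_cal, "cut")
  poly <- trace_cut_polygon(cut, rv$truth$cut$top_line_px)
  expect_equal(measure_depth(poly), lesion$truth$depth, tolerance = 0.03)
  vol <- similarity_volume(measure_area(top), width_ratio_profile(poly))
  expect_equal(vol$volume, lesion$truth$volume, tolerance = 0.05)
})

test_that("segmentation overlaps ground truth with Dice >= 0.95 at sigma 8", {
  lesion <- make_parametric_lesion("half_ellipsoid", a = 4, b = 3, c = 2)
  d_noisy <- withr::local_tempdir(); d_clean <- withr::local_tempdir()
  noisy <- render_views(lesion, render_spec(seed = 3, noise_sigma = 8), d_noisy)
  clean <- render_views(lesion, render_spec(seed = 3, noise_sigma = 0,
                                            gradient_amplitude = 0), d_clean)
  cal <- calibrate(noisy$truth$scale_bar$points_px[1, ],
                   noisy$truth$scale_bar$points_px[2, ],
                   noisy$truth$scale_bar$length_mm)
  m_noisy <- segment_stained(read_lesion_image(noisy$top), 120, cal, "top")$mask
  m_true <- segment_stained(read_lesion_image(clean$top), 120, cal, "top")$mask
  dice <- 2 * sum(m_noisy & m_true) / (sum(m_noisy) + sum(m_true))
  expect_gte(dice, 0.95)
})

test_that("lesions that do not fit the requested canvas are rejected", {
  lesion <- make_parametric_lesion("half_ellipsoid", a = 4, b = 3, c = 2)
  expect_error(render_views(lesion, render_spec(canvas_mm = 5),
                            withr::local_tempdir()), "canvas")
})
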