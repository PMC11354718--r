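test_that("null excitation gives zero potential and field", {
  mm <- rasterize_materials(small_scene(0.2, half = 3, depth = 2))
  sol <- solve_potential(mm, 0)
  expect_equal(max(abs(sol$potential)), 0)
  expect_equal(max(sol$e_vcm), 0)
  cc <- check_current_conservation(sol)
  expect_equal(cc$I_a, 0)
  expect_equal(cc$I_b, 0)
})

test_that("mirror symmetry pins the mid-plane potential at half the voltage", {
  sol <- cached_solution(100)
  i0 <- which(sol$x == 0)
  mid <- sol$potential[i0, , ]
  expect_lt(max(abs(mid - 50)), 1e-3)
})

test_that("discrete maximum principle holds", {
  sol <- cached_solution(100)
  expect_gte(min(sol$potential), -1e-6 * 100)
  expect_lte(max(sol$potential), 100 * (1 + 1e-6))
  expect_gte(min(sol$e_vcm), 0)
})

test_that("electrode currents balance and scale linearly with conductivity", {
  sol <- cached_solution(100)
  cc <- check_current_conservation(sol)
  expect_lt(cc$mismatch, 0.01)
  expect_gt(cc$I_a, 0)   # source at +100 V drives current into the bath
  expect_lt(cc$I_b, 0)

  mats2 <- list(bath = material("tyrode", 3.6), slab = material("tuber", 0.08),
                electrode_a = material("e", 1.74e-3),
                electrode_b = material("e", 1.74e-3))
  mm2 <- rasterize_materials(small_scene(0.2, materials = mats2))
  cc2 <- check_current_conservation(solve_potential(mm2, 100))
  expect_equal(cc2$I_a / cc$I_a, 2, tolerance = 1e-5)
  expect_equal(cc2$I_b / cc$I_b, 2, tolerance = 1e-5)
})

test_that("solutions are linear in the applied voltage", {
  s100 <- cached_solution(100)
  s300 <- cached_solution(300)
  scale <- max(abs(s100$potential))
  expect_lt(max(abs(s300$potential - 3 * s100$potential)) / (3 * scale), 1e-6)
  expect_lt(max(abs(s300$e_vcm - 3 * s100$e_vcm)) / max(s300$e_vcm), 1e-5)
})

test_that("field concentrates in the resistive slab across the interface", {
  # where current crosses into the tuber the 45x conductivity contrast
  # amplifies the normal field; probe on the electrode line just outside the
  # needle pair, away from the needles' own near-field
  sol <- cached_solution(100)
  j0 <- which(sol$y == 0)
  k_bath <- max(which(sol$z < 0))
  k_slab <- min(which(sol$z > 0))
  for (xv in c(-2, 2)) {
    ii <- which.min(abs(sol$x - xv))
    expect_gt(sol$e_vcm[ii, j0, k_slab], sol$e_vcm[ii, j0, k_bath])
  }
  # the slab surface under the electrode tips carries a strong field
  i_tip <- which.min(abs(sol$x - 1))
  expect_gt(sol$e_vcm[i_tip, j0, k_slab], 0.5 * max(sol$e_vcm[, j0, k_slab]))
})

test_that("two-wire analytic oracle is matched within 2% at 0.05 mm", {
  mm <- twowire_map(h = 0.05)
  sol <- solve_potential(mm, 100, tolerance = 1e-8, max_iterations = 50000)
  i0 <- which(mm$x == 0)
  analytic <- twowire_midpoint_field(100, a = 0.315, D = 2.0)
  expect_equal(sol$e_vcm[i0, i0, 1], analytic, tolerance = 0.02)
})

test_that("potential at probe points is grid-converged on a fixed geometry", {
  # two-wire scene rasterized once at 0.2 mm, then refined by cell
  # subdivision so the staircase geometry is bit-identical across levels:
  # probe potentials change <= 1% when the spacing halves from 0.1 mm
  base_h <- 0.2
  n <- 2 * floor(10 / base_h) + 1
  x <- (seq_len(n) - (n + 1) / 2) * base_h
  a_eff <- 0.315 + base_h / 2
  mask2d <- matrix(0L, n, n)
  mask2d[outer((x - 1)^2, x^2, `+`) <= a_eff^2] <- 1L
  mask2d[outer((x + 1)^2, x^2, `+`) <= a_eff^2] <- 2L
  mk_map <- function(m, h, xx) list(
    sigma = array(1, dim = c(nrow(m), ncol(m), 1)),
    dirichlet_mask = array(m, dim = c(nrow(m), ncol(m), 1)),
    label = array(1L, dim = c(nrow(m), ncol(m), 1)),
    x = xx, y = xx, z = 0, h = h, dims = c(nrow(m), ncol(m), 1L),
    config = list(solver = list(tolerance = 1e-10, max_iterations = 1e5)))
  refine <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                          rep(seq_len(ncol(m)), each = 2)]
  pts <- rbind(c(0.3, 0.8), c(-1.8, 0.4), c(0.5, -1.2))
  phis <- NULL
  m <- mask2d; h <- base_h; xx <- x
  for (lev in 1:3) {
    sol <- solve_potential(mk_map(m, h, xx), 100,
                           tolerance = 1e-10, max_iterations = 1e5)
    phis <- rbind(phis, bilinear_sample(
      list(u = sol$x, v = sol$y, e = sol$potential[, , 1]), pts[, 1], pts[, 2]))
    m <- refine(m); h <- h / 2
    xx <- rep(xx, each = 2) + c(-h / 2, h / 2)
  }
  expect_lt(max(abs(phis[3, ] - phis[2, ])) / 100, 0.01)
})

test_that("the discretization is second-order on a smooth manufactured solution", {
  # 1-D heterogeneous conduction with sigma = 1/(1 + x^2): the exact
  # potential is proportional to x + x^3/3 between the Dirichlet planes
  err <- function(h) {
    n <- round(2 / h)
    x <- (seq_len(n) - 0.5) * h
    mask <- array(0L, dim = c(n, 3, 3))
    mask[1, , ] <- 1L; mask[n, , ] <- 2L
    mmap <- list(sigma = array(rep(1 / (1 + x^2), times = 9), dim = dim(mask)),
                 dirichlet_mask = mask, label = array(1L, dim(mask)),
                 x = x, y = (1:3) * h, z = (1:3) * h, h = h,
                 dims = c(n, 3L, 3L),
                 config = list(solver = list(tolerance = 1e-12,
                                             max_iterations = 1e5)))
    sol <- solve_potential(mmap, 1, tolerance = 1e-12, max_iterations = 1e5)
    antider <- function(x) x + x^3 / 3
    exact <- (antider(x[n]) - antider(x)) / (antider(x[n]) - antider(x[1]))
    max(abs(sol$potential[, 2, 2] - exact))
  }
  ratio <- err(0.05) / err(0.025)
  expect_gt(ratio, 3)   # observed order about 2 (ratio about 4)
  expect_lt(ratio, 5)
})

test_that("degenerate configurations raise configuration errors", {
  mm <- rasterize_materials(small_scene(0.2, half = 3, depth = 2))
  mm_noground <- mm
  mm_noground$dirichlet_mask[mm_noground$dirichlet_mask == 2L] <- 0L
  expect_error(solve_potential(mm_noground, 100), "ground")
  expect_error(solve_potential(mm, 100, tolerance = 1), "tolerance")
  expect_error(solve_potential(mm, 100, tolerance = 1e-8, max_iterations = 2),
               "convergence")
})
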