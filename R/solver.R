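#' Solve the stationary conduction problem
#'
#' Solves `div(sigma grad phi) = 0` on the rasterized scene with a
#' seven-point finite-volume discretization (harmonic-mean face
#' conductivities), Dirichlet values on the two electrode cell sets (the
#' applied voltage on electrode A, 0 V on electrode B) and zero normal
#' current on all outer faces. The symmetric positive-definite system is
#' solved matrix-free with Jacobi-preconditioned conjugate gradients.
#'
#' The electric-field magnitude is obtained from central differences of phi
#' (second-order one-sided stencils at domain faces) and reported in V/cm,
#' the model's conventional unit; inside electrode cells the field is set to
#' zero (equipotential metal).
#'
#' @param material_map A `pfa_materials` from [rasterize_materials()].
#' @param applied_voltage Voltage on electrode A, V (electrode B grounded).
#' @param tolerance Relative residual of the discrete system, in (0, 1e-4].
#' @param max_iterations Conjugate-gradient iteration cap.
#' @return A `pfa_field`: `potential` and `e_vcm` arrays over the grid, the
#'   grid metadata of the material map, `applied_voltage`, `residual`, and
#'   `iterations`.
#' @export
solve_potential <- function(material_map, applied_voltage,
                            tolerance = NULL, max_iterations = NULL) {
  so <- material_map$config$solver
  if (is.null(tolerance)) tolerance <- so$tolerance
  if (is.null(max_iterations)) max_iterations <- so$max_iterations
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance > 1e-4) {
    stop("tolerance must lie in (0, 1e-4]", call. = FALSE)
  }
  mask <- material_map$dirichlet_mask
  if (!any(mask == 1L) || !any(mask == 2L)) {
    stop("configuration error: both electrodes must contribute Dirichlet cells ",
         "(no ground electrode present)", call. = FALSE)
  }
  res <- fv_pcg_solve(as.numeric(material_map$sigma), as.integer(mask),
                      va = applied_voltage, vb = 0,
                      dims = as.integer(material_map$dims),
                      h = material_map$h, tol = tolerance,
                      maxit = as.integer(max_iterations))
  if (!res$converged) {
    stop(sprintf(paste0("convergence error: relative residual %.3e after %d ",
                        "iterations (tolerance %.1e)"),
                 res$residual, res$iterations, tolerance), call. = FALSE)
  }
  phi <- array(res$phi, dim = material_map$dims)
  e_vcm <- field_magnitude(phi, material_map$h)
  e_vcm[mask != 0L] <- 0

  structure(list(potential = phi, e_vcm = e_vcm,
                 x = material_map$x, y = material_map$y, z = material_map$z,
                 h = material_map$h, dims = material_map$dims,
                 applied_voltage = applied_voltage,
                 residual = res$residual, iterations = res$iterations,
                 material_map = material_map),
            class = "pfa_field")
}

# Gradient of a 3-D array along one axis: central differences in the
# interior, second-order one-sided stencils at the two faces. h in mm, so
# the result is V/mm.
axis_gradient <- function(arr, h, axis) {
  n <- dim(arr)[axis]
  idx <- function(i) {
    sel <- list(TRUE, TRUE, TRUE)
    sel[[axis]] <- i
    do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
  }
  g <- array(0, dim = dim(arr))
  if (n >= 3) {
    core <- (idx(3:n) - idx(1:(n - 2))) / (2 * h)
    lo <- (-3 * idx(1) + 4 * idx(2) - idx(3)) / (2 * h)
    hi <- (3 * idx(n) - 4 * idx(n - 1) + idx(n - 2)) / (2 * h)
    sel <- list(TRUE, TRUE, TRUE)
    sel[[axis]] <- 2:(n - 1)
    g <- do.call(`[<-`, c(list(g), sel, list(core)))
    sel[[axis]] <- 1
    g <- do.call(`[<-`, c(list(g), sel, list(lo)))
    sel[[axis]] <- n
    g <- do.call(`[<-`, c(list(g), sel, list(hi)))
  } else if (n == 2) {
    d <- (idx(2) - idx(1)) / h
    sel <- list(TRUE, TRUE, TRUE)
    sel[[axis]] <- 1
    g <- do.call(`[<-`, c(list(g), sel, list(d)))
    sel[[axis]] <- 2
    g <- do.call(`[<-`, c(list(g), sel, list(d)))
  }
  g
}

# |grad phi| in V/cm from phi (V) on an h-mm grid: V/mm * 10 = V/cm
field_magnitude <- function(phi, h) {
  gx <- axis_gradient(phi, h, 1)
  gy <- axis_gradient(phi, h, 2)
  gz <- if (dim(phi)[3] > 1) axis_gradient(phi, h, 3) else 0
  sqrt(gx^2 + gy^2 + gz^2) * 10
}

#' Check discrete current conservation
#'
#' Integrates the normal current density `sigma dphi/dn` over the surface of
#' each Dirichlet electrode set (summing finite-volume face fluxes) and
#' reports the source/sink currents and their relative mismatch. For a
#' converged solve the two currents balance to within the solver residual.
#'
#' @param solution A `pfa_field`.
#' @param material_map The `pfa_materials` used for the solve (defaults to
#'   the one stored in the solution).
#' @return List with `I_a`, `I_b` (amps, positive = leaving the electrode),
#'   `mismatch` (relative, `|I_a + I_b| / max(|I_a|, |I_b|)`), and the
#'   conductance `I_a / V` (siemens) when a voltage is applied.
#' @export
check_current_conservation <- function(solution, material_map = NULL) {
  if (is.null(material_map)) material_map <- solution$material_map
  cur <- electrode_currents(as.numeric(solution$potential),
                            as.numeric(material_map$sigma),
                            as.integer(material_map$dirichlet_mask),
                            as.integer(material_map$dims), material_map$h)
  ia <- cur[["I_a"]]; ib <- cur[["I_b"]]
  denom <- max(abs(ia), abs(ib))
  mism <- if (denom > 0) abs(ia + ib) / denom else 0
  cond <- if (solution$applied_voltage != 0) ia / solution$applied_voltage else NA_real_
  list(I_a = ia, I_b = ib, mismatch = mism, conductance = cond)
}

#' @export
print.pfa_field <- function(x, ...) {
  cat(sprintf("PFA field solution: %d x %d x %d cells at %g mm, %g V applied\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$applied_voltage))
  cat(sprintf("  potential range [%.4g, %.4g] V; |E| max %.4g V/cm\n",
              min(x$potential), max(x$potential), max(x$e_vcm)))
  cat(sprintf("  converged in %d iterations, relative residual %.2e\n",
              x$iterations, x$residual))
  invisible(x)
}
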