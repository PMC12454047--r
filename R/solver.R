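# Steady incompressible flow solvers on tagged tetrahedral meshes.
#
# Discretisation: inf-sup stable Taylor-Hood elements (continuous P2
# velocity, continuous P1 pressure).  Boundary conditions follow the
# urodynamic set-up: plug inflow of prescribed volumetric flux on the
# papillary inlet patch(es), no-slip on rigid walls, and a zero-traction
# (reference pressure) condition at the ureteral outlet, so reported
# pressures are gauge pressures relative to the outlet.
#
# Linear algebra: the velocity block is factorised once per mesh (sparse
# Cholesky); the pressure is obtained from the Schur complement with a
# lumped-pressure-mass preconditioned Krylov iteration (CG for Stokes,
# BiCGSTAB for the Picard-linearised Navier-Stokes system).

#' Fluid properties
#'
#' Defaults are the urine properties used throughout: an incompressible
#' Newtonian fluid with density 1050 kg/m^3 and dynamic viscosity
#' 0.001 Pa.s.
#'
#' @param density fluid density in kg/m^3.
#' @param dynamic_viscosity dynamic viscosity in Pa.s.
#' @return An object of class `pelviflow_fluid`.
#' @export
fluid_properties <- function(density = 1050, dynamic_viscosity = 0.001) {
  if (!is.numeric(density) || density <= 0)
    stop("density must be strictly positive")
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("dynamic_viscosity must be strictly positive")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "pelviflow_fluid")
}

#' @export
print.pelviflow_fluid <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, mu = %g Pa.s\n",
              x$density, x$dynamic_viscosity))
  invisible(x)
}

#' Flow case: imposed flow rate, boundary assignment and model choice
#'
#' @param flow_rate imposed volumetric flow rate Q in m^3/s (use
#'   [flow_rate_convert()] for mL/day inputs).
#' @param model `"STOKES"` (linear, inertia-free) or `"NAVIER_STOKES"`.
#' @param inlet_tags character vector of inlet tag names; default all tags
#'   starting with `INLET` found on the mesh.
#' @param outlet_tag outlet tag name (default `"OUTLET"`).
#' @param outlet_pressure reference pressure at the outlet in Pa (default 0).
#' @param flux_shares optional numeric vector (same length as `inlet_tags`,
#'   summing to 1) of per-patch flux fractions; default area-weighted.
#' @return An object of class `pelviflow_case`.
#' @export
flow_case <- function(flow_rate, model = c("STOKES", "NAVIER_STOKES"),
                      inlet_tags = NULL, outlet_tag = "OUTLET",
                      outlet_pressure = 0, flux_shares = NULL) {
  model <- match.arg(model)
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L ||
      !is.finite(flow_rate) || flow_rate <= 0)
    stop("flow_rate Q must be a strictly positive finite number (m^3/s)")
  if (!is.finite(outlet_pressure))
    stop("outlet_pressure must be finite")
  if (!is.null(flux_shares) && abs(sum(flux_shares) - 1) > 1e-9)
    stop("flux_shares must sum to 1")
  structure(list(flow_rate = flow_rate, model = model,
                 inlet_tags = inlet_tags, outlet_tag = outlet_tag,
                 outlet_pressure = outlet_pressure,
                 flux_shares = flux_shares),
            class = "pelviflow_case")
}

#' @export
print.pelviflow_case <- function(x, ...) {
  cat(sprintf("Flow case: Q = %.4g m^3/s (%.3g mL/min), model %s, outlet %s @ %g Pa\n",
              x$flow_rate, x$flow_rate * 6e7, x$model, x$outlet_tag,
              x$outlet_pressure))
  invisible(x)
}

#' @keywords internal
#' @noRd
.resolve_inlets <- function(mesh, case) {
  if (is.null(case$inlet_tags))
    case$inlet_tags <- sort(unique(grep("^INLET", mesh$boundary_tags,
                                        value = TRUE)))
  if (!length(case$inlet_tags))
    stop("no boundary facets tagged 'INLET*': inflow cannot be imposed")
  case
}

#' Characteristic luminal diameter of a mesh
#'
#' The minimum cross-section diameter along the recovered axial profile
#' (the throat for a stenotic phantom), used for Reynolds-number reporting.
#'
#' @param mesh a [volume_mesh()] produced by [generate_volume_mesh()].
#' @return Diameter in metres.
#' @export
min_lumen_diameter <- function(mesh) {
  if (!is.null(mesh$profile)) return(2 * min(mesh$profile$r))
  # fallback: hydraulic estimate from volume and axial extent
  bb <- apply(mesh$vertices, 2, range)
  L <- max(bb[2, ] - bb[1, ])
  2 * sqrt(mesh_volume(mesh) / L / pi)
}

#' Reynolds number of duct flow
#'
#' `Re = rho * v * d / mu` with the mean velocity `v = Q / (pi d^2 / 4)`.
#'
#' @param fluid a [fluid_properties()] object.
#' @param flow_rate volumetric flow rate Q in m^3/s.
#' @param diameter duct diameter in metres.
#' @return Dimensionless Reynolds number.
#' @examples
#' fl <- fluid_properties()
#' reynolds_number(fl, flow_rate_convert(1440)$m3_s, 3e-3)   # ~ 7.4
#' @export
reynolds_number <- function(fluid, flow_rate, diameter) {
  if (flow_rate <= 0 || diameter <= 0)
    stop("flow_rate and diameter must be positive")
  v <- flow_rate / (pi * diameter^2 / 4)
  fluid$density * v * diameter / fluid$dynamic_viscosity
}

# shared solution construction
#' @keywords internal
#' @noRd
.make_solution <- function(mesh, ops, fluid, case, U, p_gauge, model,
                           residual, iterations, info) {
  P <- p_gauge + case$outlet_pressure
  out_sel <- ops$facet_tag == case$outlet_tag
  fa <- ops$facet_area[out_sel]
  pf <- (P[ops$facet_vdof[out_sel, 1L]] + P[ops$facet_vdof[out_sel, 2L]] +
           P[ops$facet_vdof[out_sel, 3L]]) / 3
  outlet_mean <- sum(pf * fa) / sum(fa)
  flux <- vapply(sort(unique(ops$facet_tag)), function(tg)
    .facet_flux(ops, U, ops$facet_tag == tg), numeric(1))
  structure(list(U = U, P = P, mesh = mesh, fluid = fluid, case = case,
                 model = model, residual = residual,
                 iterations = iterations,
                 outlet_mean_pressure = outlet_mean,
                 boundary_fluxes = flux, solver_info = info),
            class = "pelviflow_solution")
}

#' Solve steady Stokes flow
#'
#' Solves the inertia-free momentum balance `-grad P + mu lap U = 0` with
#' `div U = 0` on a tagged volume mesh: plug inflow of total flux Q on the
#' inlet patch(es), no-slip walls, zero-traction outlet at the reference
#' pressure.  One linear solve; the solution is exactly proportional to Q.
#'
#' @param mesh a [volume_mesh()].
#' @param fluid a [fluid_properties()].
#' @param case a [flow_case()] with `model = "STOKES"`.
#' @param cg_tol relative tolerance of the pressure Schur-complement CG.
#' @param cg_maxit iteration cap.
#' @return A `pelviflow_solution`: P2 velocity `U` (m/s), P1 pressure `P`
#'   (Pa, gauge), residuals, per-tag boundary fluxes.
#' @export
solve_stokes <- function(mesh, fluid, case, cg_tol = 1e-13,
                         cg_maxit = 1000L) {
  stopifnot(inherits(mesh, "pelviflow_mesh"),
            inherits(fluid, "pelviflow_fluid"),
            inherits(case, "pelviflow_case"))
  if (case$model != "STOKES")
    stop("case$model must be STOKES for solve_stokes()")
  case <- .resolve_inlets(mesh, case)
  ops <- fem_operators(mesh)
  bc <- .build_dirichlet(mesh, ops, case)
  free <- setdiff(seq_len(ops$ns), bc$dofs)
  mu <- fluid$dynamic_viscosity
  fact <- .stiffness_factor(mesh, ops, free)
  Asolve <- function(b) as.numeric(Matrix::solve(fact, b)) / mu
  AfD <- ops$A[free, bc$dofs, drop = FALSE]
  fmat <- -mu * as.matrix(AfD %*% bc$values)
  Bf <- lapply(ops$B, function(Bi) Bi[, free, drop = FALSE])
  BD <- lapply(ops$B, function(Bi) Bi[, bc$dofs, drop = FALSE])
  gp <- -as.numeric(BD[[1L]] %*% bc$values[, 1L] +
                      BD[[2L]] %*% bc$values[, 2L] +
                      BD[[3L]] %*% bc$values[, 3L])
  AinvF <- vapply(1:3, function(d) Asolve(fmat[, d]), numeric(length(free)))
  rhs_s <- gp - as.numeric(Bf[[1L]] %*% AinvF[, 1L] +
                             Bf[[2L]] %*% AinvF[, 2L] +
                             Bf[[3L]] %*% AinvF[, 3L])
  apply_S <- function(p) {
    acc <- numeric(ops$nv)
    for (d in 1:3)
      acc <- acc + as.numeric(
        Bf[[d]] %*% Asolve(as.numeric(Matrix::crossprod(Bf[[d]], p))))
    acc
  }
  precond <- function(r) r * mu / ops$mp
  cg <- .schur_cg(apply_S, rhs_s, precond, tol = cg_tol, maxit = cg_maxit)
  p <- cg$x
  U <- bc$g_full
  for (d in 1:3)
    U[free, d] <- AinvF[, d] +
      Asolve(as.numeric(Matrix::crossprod(Bf[[d]], p)))
  # residual of the eliminated momentum system
  resv <- 0; fscale <- 0
  for (d in 1:3) {
    rd <- as.numeric(mu * (ops$A %*% U[, d]) -
                       Matrix::crossprod(ops$B[[d]], p))[free]
    resv <- resv + sum(rd^2)
    fscale <- fscale + sum(fmat[, d]^2)
  }
  div_res <- as.numeric(ops$B[[1L]] %*% U[, 1L] + ops$B[[2L]] %*% U[, 2L] +
                          ops$B[[3L]] %*% U[, 3L]) - 0
  info <- list(cg_iterations = cg$iter, cg_rel_residual = cg$rel,
               div_residual = sqrt(sum(div_res^2)),
               n_dofs = 3L * length(free) + ops$nv)
  .make_solution(mesh, ops, fluid, case, U, p, "STOKES",
                 residual = sqrt(resv) / max(sqrt(fscale), 1e-300),
                 iterations = 1L, info = info)
}

#' Solve steady Navier-Stokes flow
#'
#' Picard (fixed-point) iteration on the convective term
#' `rho (U . grad) U`, initialised from the Stokes solution, with the same
#' boundary conditions as [solve_stokes()].  Converged when the relative
#' momentum residual drops below `tol`; errors out after `max_iter`
#' iterations, reporting the last residual and the throat Reynolds number.
#'
#' @inheritParams solve_stokes
#' @param tol relative nonlinear residual tolerance (default 1e-8).
#' @param max_iter Picard iteration cap (default 50).
#' @return A `pelviflow_solution` with `model = "NAVIER_STOKES"`.
#' @export
solve_navier_stokes <- function(mesh, fluid, case, tol = 1e-8,
                                max_iter = 50L) {
  stopifnot(inherits(mesh, "pelviflow_mesh"))
  if (case$model != "NAVIER_STOKES")
    stop("case$model must be NAVIER_STOKES for solve_navier_stokes()")
  case <- .resolve_inlets(mesh, case)
  s_case <- case
  s_case$model <- "STOKES"
  s_case$outlet_pressure <- 0
  sol0 <- solve_stokes(mesh, fluid, s_case)
  ops <- fem_operators(mesh)
  bc <- .build_dirichlet(mesh, ops, case)
  free <- setdiff(seq_len(ops$ns), bc$dofs)
  mu <- fluid$dynamic_viscosity
  rho <- fluid$density
  U <- sol0$U
  p <- sol0$P
  Bf <- lapply(ops$B, function(Bi) Bi[, free, drop = FALSE])
  BD <- lapply(ops$B, function(Bi) Bi[, bc$dofs, drop = FALSE])
  gp <- -as.numeric(BD[[1L]] %*% bc$values[, 1L] +
                      BD[[2L]] %*% bc$values[, 2L] +
                      BD[[3L]] %*% bc$values[, 3L])
  precond <- function(r) r * mu / ops$mp
  residual <- Inf
  it <- 0L
  info <- list()
  repeat {
    ct <- fem_assemble_convection(mesh$vertices, mesh$tets, ops$tet_edges, U)
    Fop <- mu * ops$A +
      rho * Matrix::sparseMatrix(i = ct$ci, j = ct$cj, x = ct$cx,
                                 dims = c(ops$ns, ops$ns))
    fmat <- -as.matrix(Fop[free, bc$dofs, drop = FALSE] %*% bc$values)
    resv <- 0; fscale <- 0
    for (d in 1:3) {
      rd <- as.numeric(Fop %*% U[, d] -
                         Matrix::crossprod(ops$B[[d]], p))[free]
      resv <- resv + sum(rd^2)
      fscale <- fscale + sum(fmat[, d]^2)
    }
    residual <- sqrt(resv) / max(sqrt(fscale), 1e-300)
    if (residual <= tol) break
    if (it >= max_iter) {
      d_char <- min_lumen_diameter(mesh)
      stop(sprintf(paste0(
        "Navier-Stokes Picard iteration did not converge after %d ",
        "iterations (relative momentum residual %.3g, throat Reynolds ",
        "number %.3g); the steady laminar-flow assumption may be violated ",
        "at this flow rate"),
        max_iter, residual, reynolds_number(fluid, case$flow_rate, d_char)))
    }
    it <- it + 1L
    Fff <- Fop[free, free]
    luF <- Matrix::lu(Fff)
    Fsolve <- function(b) as.numeric(Matrix::solve(luF, b))
    FinvF <- vapply(1:3, function(d) Fsolve(fmat[, d]),
                    numeric(length(free)))
    rhs_s <- gp - as.numeric(Bf[[1L]] %*% FinvF[, 1L] +
                               Bf[[2L]] %*% FinvF[, 2L] +
                               Bf[[3L]] %*% FinvF[, 3L])
    apply_S <- function(q) {
      acc <- numeric(ops$nv)
      for (d in 1:3)
        acc <- acc + as.numeric(
          Bf[[d]] %*% Fsolve(as.numeric(Matrix::crossprod(Bf[[d]], q))))
      acc
    }
    # inexact Picard: the pressure solve only needs to outpace the current
    # nonlinear residual; warm-start from the previous pressure iterate
    schur_tol <- min(1e-10, max(1e-13, 1e-3 * residual))
    rhs_corr <- rhs_s - apply_S(p)
    sb <- .schur_bicgstab(apply_S, rhs_corr, precond, tol = schur_tol)
    p_new <- p + sb$x
    U_new <- bc$g_full
    for (d in 1:3)
      U_new[free, d] <- FinvF[, d] +
        Fsolve(as.numeric(Matrix::crossprod(Bf[[d]], p_new)))
    U <- U_new
    p <- p_new
    info[[length(info) + 1L]] <- c(schur_iter = sb$iter, schur_rel = sb$rel)
  }
  d_char <- min_lumen_diameter(mesh)
  sol <- .make_solution(mesh, ops, fluid, case, U, p, "NAVIER_STOKES",
                        residual = residual, iterations = it,
                        info = list(picard = info,
                                    reynolds = reynolds_number(
                                      fluid, case$flow_rate, d_char)))
  sol
}

#' Volumetric flux through a tagged boundary patch
#'
#' Surface integral of `U . n` over the facets carrying `tag`,
#' outward-positive (exact for the P2 velocity via the facet midpoint rule).
#'
#' @param solution a `pelviflow_solution`.
#' @param tag boundary tag name.
#' @return Flux in m^3/s.
#' @export
boundary_flux <- function(solution, tag) {
  ops <- fem_operators(solution$mesh)
  sel <- ops$facet_tag == tag
  if (!any(sel)) stop("unknown boundary tag: ", tag)
  .facet_flux(ops, solution$U, sel)
}

#' @export
print.pelviflow_solution <- function(x, ...) {
  cat(sprintf("%s flow solution (pelviflow_solution)\n", x$model))
  cat(sprintf("  Q = %.4g m^3/s (%.3g mL/min)   dofs: %s\n",
              x$case$flow_rate, x$case$flow_rate * 6e7,
              if (!is.null(x$solver_info$n_dofs)) x$solver_info$n_dofs
              else "?"))
  cat(sprintf("  residual: %.2e   iterations: %d\n", x$residual,
              x$iterations))
  cat(sprintf("  outlet mean pressure: %.3g Pa (datum %g Pa)\n",
              x$outlet_mean_pressure, x$case$outlet_pressure))
  cat("  boundary fluxes [m^3/s]:\n")
  for (nm in names(x$boundary_fluxes))
    cat(sprintf("    %-8s % .4e\n", nm, x$boundary_fluxes[[nm]]))
  invisible(x)
}

#' Export a flow solution as VTU point data
#'
#' Writes the mesh with vertex velocity (m/s) and pressure (Pa) arrays.
#'
#' @param solution a `pelviflow_solution`.
#' @param path output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_solution_vtu <- function(solution, path) {
  nv <- nrow(solution$mesh$vertices)
  write_vtu(solution$mesh, path,
            point_data = list(pressure = solution$P,
                              velocity = solution$U[seq_len(nv), ,
                                                    drop = FALSE]))
}
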