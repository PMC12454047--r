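# Closed-form oracles and convergence studies establishing solver
# correctness at desk scale: the Hagen-Poiseuille pressure drop of laminar
# pipe flow, and grid-refinement studies of the clinical pressure
# difference.

#' Hagen-Poiseuille pressure drop
#'
#' Closed-form pressure drop of fully developed laminar flow in a circular
#' pipe: `dP = 8 mu L Q / (pi R^4)`.
#'
#' @param mu dynamic viscosity in Pa.s.
#' @param length pipe length in metres.
#' @param flow_rate volumetric flow rate in m^3/s.
#' @param radius pipe radius in metres.
#' @return Pressure drop in Pa.
#' @examples
#' poiseuille_dp(0.001, 0.01, 8.333e-9, 1.5e-3)   # ~ 0.0419 Pa
#' @export
poiseuille_dp <- function(mu, length, flow_rate, radius) {
  if (any(c(mu, length, flow_rate, radius) <= 0))
    stop("all arguments must be strictly positive")
  8 * mu * length * flow_rate / (pi * radius^4)
}

#' Verify the solver against the Poiseuille oracle
#'
#' Builds a cylinder, meshes it, solves the chosen flow model and compares
#' the computed axial pressure gradient -- measured on the duct axis over
#' the central 80% of the length, excluding entrance and exit effects the
#' closed form ignores -- against the analytic gradient.
#'
#' @param radius pipe radius (m), default 1.5e-3.
#' @param length pipe length (m), default 10e-3; must be >= 10 radii so the
#'   fully developed core dominates.
#' @param flow_rate flow rate (m^3/s), default 720 mL/day.
#' @param mesh_edge_target volume-mesh edge target (m), default `radius/3`.
#' @param model `"STOKES"` or `"NAVIER_STOKES"`.
#' @param fluid a [fluid_properties()].
#' @return An `OracleResult` list: `analytic_value`, `computed_value` (both
#'   Pa over the full length), `relative_error`, `mesh_n_cells`.
#' @export
verify_poiseuille <- function(radius = 1.5e-3, length = 10e-3,
                              flow_rate = 720 * 1e-6 / 86400,
                              mesh_edge_target = radius / 3,
                              model = c("STOKES", "NAVIER_STOKES"),
                              fluid = fluid_properties()) {
  model <- match.arg(model)
  if (length < 6 * radius)
    stop("length must be at least 6 radii for a fully developed core")
  surf <- make_cylinder(radius, length, mesh_edge_target = radius / 3)
  mesh <- generate_volume_mesh(surf, edge_target = mesh_edge_target)
  case <- flow_case(flow_rate, model = model)
  sol <- if (model == "STOKES") solve_stokes(mesh, fluid, case)
  else solve_navier_stokes(mesh, fluid, case)
  # section pressure (5-point interior average) at the 10% and 90% stations
  fr <- mesh$frame
  tr <- range(mesh$profile$t)
  sec_p <- function(tfrac) {
    ctr <- fr$origin + (tr[1L] + tfrac * diff(tr)) * fr$e1
    pts <- rbind(ctr,
                 ctr + 0.5 * radius * fr$e2, ctr - 0.5 * radius * fr$e2,
                 ctr + 0.5 * radius * fr$e3, ctr - 0.5 * radius * fr$e3)
    mean(probe_pressure(sol, probe_set(pts)))
  }
  computed <- abs(sec_p(0.1) - sec_p(0.9)) / 0.8
  analytic <- poiseuille_dp(fluid$dynamic_viscosity, length, flow_rate,
                            radius)
  list(analytic_value = analytic, computed_value = computed,
       relative_error = abs(computed - analytic) / analytic,
       mesh_n_cells = nrow(mesh$tets))
}

#' Grid-convergence study of the pressure difference
#'
#' Meshes the same surface at successively finer edge targets, solves each
#' level, and tabulates the pelvis-to-outlet pressure difference against
#' cell count.  Convergence is flagged when the two finest levels agree
#' within 2%.
#'
#' @param surface a tagged [surface_mesh()].
#' @param edge_targets strictly decreasing vector (>= 3 values) of edge
#'   targets in metres.
#' @param flow_rate_ml_day flow rate for the solve (default 1440 mL/day).
#' @param model flow model (default `"STOKES"`).
#' @param fluid a [fluid_properties()].
#' @return List with `table` (data.frame: `edge_target`, `n_cells`,
#'   `dp_pa`), `converged` (logical), and `final_gap` (relative change
#'   between the two finest levels).
#' @export
grid_convergence <- function(surface, edge_targets,
                             flow_rate_ml_day = 1440,
                             model = c("STOKES", "NAVIER_STOKES"),
                             fluid = fluid_properties()) {
  model <- match.arg(model)
  if (length(edge_targets) < 3L)
    stop("grid convergence needs at least 3 refinement levels")
  if (any(diff(edge_targets) >= 0))
    stop("edge_targets must be strictly decreasing")
  Q <- flow_rate_convert(flow_rate_ml_day)$m3_s
  dp <- numeric(length(edge_targets))
  nc <- integer(length(edge_targets))
  for (k in seq_along(edge_targets)) {
    mesh <- generate_volume_mesh(surface, edge_target = edge_targets[k])
    probes <- auto_probe_points(mesh)
    case <- flow_case(Q, model = model)
    sol <- if (model == "STOKES") solve_stokes(mesh, fluid, case)
    else solve_navier_stokes(mesh, fluid, case)
    dp[k] <- mean(probe_pressure(sol, probes))
    nc[k] <- nrow(mesh$tets)
  }
  gap <- abs(dp[length(dp)] - dp[length(dp) - 1L]) / abs(dp[length(dp)])
  list(table = data.frame(edge_target = edge_targets, n_cells = nc,
                          dp_pa = dp),
       converged = gap <= 0.02, final_gap = gap)
}
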