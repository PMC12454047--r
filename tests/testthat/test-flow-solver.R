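test_that("Stokes flow on a straight duct reproduces Hagen-Poiseuille", {
  sol <- fx_cyl_stokes()
  expect_equal(sol$iterations, 1L)
  vp <- fx_poiseuille_default()
  expect_lt(vp$relative_error, 0.05)
  # no checkerboard pressure: section pressures decrease monotonically
  mesh <- fx_cyl_mesh()
  fr <- mesh$frame
  tr <- range(mesh$profile$t)
  pts <- matrix(fr$origin, 5, 3, byrow = TRUE) +
    outer(tr[1] + seq(0.1, 0.9, length.out = 5) * diff(tr), fr$e1)
  pr <- probe_pressure(sol, probe_set(pts))
  expect_true(all(diff(pr) < 0) || all(diff(pr) > 0))
})

test_that("mass is conserved and walls are no-slip in every converged solution", {
  for (sol in list(fx_cyl_stokes(), fx_phantom_ns(1440))) {
    Q <- sol$case$flow_rate
    expect_lt(abs(boundary_flux(sol, "INLET") + Q), 0.005 * Q)
    expect_lt(abs(boundary_flux(sol, "OUTLET") - Q), 0.005 * Q)
    expect_lt(abs(boundary_flux(sol, "INLET") +
                    boundary_flux(sol, "OUTLET")), 0.005 * Q)
    expect_lt(abs(boundary_flux(sol, "WALL")), 1e-12 * Q)
    ops <- pelviflow:::fem_operators(sol$mesh)
    wall <- pelviflow:::.facet_dofs(ops, ops$facet_tag == "WALL")
    expect_equal(max(abs(sol$U[wall, ])), 0)
    # outlet datum respected
    expect_lt(abs(sol$outlet_mean_pressure - sol$case$outlet_pressure),
              1e-3 * max(abs(sol$P)))
  }
  expect_error(boundary_flux(fx_cyl_stokes(), "NOPE"), "unknown boundary tag")
})

test_that("Stokes solutions scale exactly linearly with the flow rate", {
  mesh <- fx_cyl_mesh()
  s1 <- fx_cyl_stokes()
  s2 <- solve_stokes(mesh, fx_fluid(), flow_case(2 * Q_720))
  devU <- max(abs(s2$U - 2 * s1$U)) / max(abs(s2$U))
  devP <- max(abs(s2$P - 2 * s1$P)) / max(abs(s2$P))
  expect_lt(devU, 1e-8)
  expect_lt(devP, 1e-8)
})

test_that("Navier-Stokes matches Stokes in the vanishing-inertia limit", {
  mesh <- fx_cyl_mesh()
  fl <- fx_fluid()
  Qlow <- 2e-10                      # Re ~ 0.09 in a 3 mm duct
  expect_lt(reynolds_number(fl, Qlow, 3e-3), 0.1)
  ss <- solve_stokes(mesh, fl, flow_case(Qlow))
  ns <- solve_navier_stokes(mesh, fl, flow_case(Qlow, model = "NAVIER_STOKES"))
  pr <- probe_set(rbind(c(0, 0, 1e-3), c(0, 0, 9e-3)))
  dps <- -diff(probe_pressure(ss, pr))
  dpn <- -diff(probe_pressure(ns, pr))
  expect_lt(abs(dpn - dps) / dps, 0.01)
  expect_lt(ns$residual, 1e-8)
})

test_that("Navier-Stokes pipe flow at Re ~ 4 stays within 10% of Stokes", {
  mesh <- fx_cyl_mesh()
  fl <- fx_fluid()
  ns <- solve_navier_stokes(mesh, fl,
                            flow_case(Q_720, model = "NAVIER_STOKES"))
  pr <- probe_set(rbind(c(0, 0, 1e-3), c(0, 0, 9e-3)))
  dpn <- -diff(probe_pressure(ns, pr))
  dps <- -diff(probe_pressure(fx_cyl_stokes(), pr))
  expect_lt(abs(dpn - dps) / dps, 0.10)
})

test_that("Reynolds numbers match the physiological urine-flow estimates", {
  fl <- fx_fluid()
  expect_equal(reynolds_number(fl, flow_rate_convert(1440)$m3_s, 3e-3),
               7.4, tolerance = 0.01)
  expect_equal(reynolds_number(fl, flow_rate_convert(360)$m3_s, 3e-3),
               1.9, tolerance = 0.03)
  q <- 1e-8
  expect_equal(reynolds_number(fl, q / 2, 3e-3),
               reynolds_number(fl, q, 3e-3) / 2)
  expect_error(reynolds_number(fl, -1, 1e-3), "positive")
})

test_that("ill-posed boundary configurations raise informative errors", {
  mesh <- fx_cyl_mesh()
  no_outlet <- volume_mesh(mesh$vertices, mesh$tets, mesh$boundary_facets,
                           ifelse(mesh$boundary_tags == "OUTLET", "WALL",
                                  mesh$boundary_tags))
  expect_error(solve_stokes(no_outlet, fx_fluid(), flow_case(Q_720)),
               "outlet pressure datum undetermined")
  no_inlet <- volume_mesh(mesh$vertices, mesh$tets, mesh$boundary_facets,
                          ifelse(mesh$boundary_tags == "INLET", "WALL",
                                 mesh$boundary_tags))
  expect_error(solve_stokes(no_inlet, fx_fluid(), flow_case(Q_720)),
               "INLET")
  expect_error(flow_case(0), "strictly positive")
  expect_error(flow_case(1e-8, outlet_pressure = Inf), "finite")
  expect_error(solve_stokes(mesh, fx_fluid(),
                            flow_case(Q_720, model = "NAVIER_STOKES")),
               "STOKES")
})

test_that("a nonzero outlet reference pressure shifts the field datum", {
  mesh <- fx_cyl_mesh()
  s0 <- fx_cyl_stokes()
  s5 <- solve_stokes(mesh, fx_fluid(),
                     flow_case(Q_720, outlet_pressure = 5))
  expect_equal(s5$P, s0$P + 5, tolerance = 1e-10)
})
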