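test_that("the Hagen-Poiseuille closed form and its scaling laws", {
  dp <- poiseuille_dp(0.001, 0.01, 8.333e-9, 1.5e-3)
  expect_equal(dp, 0.0419, tolerance = 1e-3)
  expect_equal(poiseuille_dp(0.001, 0.01, 8.333e-9, 3e-3), dp / 16)
  expect_equal(poiseuille_dp(0.001, 0.01, 2 * 8.333e-9, 1.5e-3), 2 * dp)
  expect_error(poiseuille_dp(0, 1, 1, 1), "positive")
})

test_that("the discrete solution converges to the Poiseuille oracle", {
  v0 <- fx_poiseuille_default()
  v1 <- fx_poiseuille_refined()
  expect_lt(v0$relative_error, 0.05)
  expect_lt(v1$relative_error, 0.02)
  expect_lt(v1$relative_error, v0$relative_error)
  expect_gt(v1$mesh_n_cells, v0$mesh_n_cells)
})

test_that("observed convergence order of the pipe pressure drop is at least 1", {
  v0 <- fx_poiseuille_default()       # edge R/3
  v1 <- fx_poiseuille_refined()       # edge R/6
  order <- log(v0$relative_error / v1$relative_error) / log(2)
  expect_gt(order, 1)
})

test_that("Navier-Stokes pipe flow passes the oracle within 10%", {
  vns <- verify_poiseuille(model = "NAVIER_STOKES")
  expect_lt(vns$relative_error, 0.10)
})

test_that("grid_convergence validates its refinement schedule", {
  surf <- fx_cyl_surface()
  expect_error(grid_convergence(surf, c(5e-4, 2.5e-4)), "at least 3")
  expect_error(grid_convergence(surf, c(5e-4, 5e-4, 2.5e-4)),
               "strictly decreasing")
})

test_that("the cylinder pressure drop converges towards the Poiseuille value", {
  gc_ <- grid_convergence(fx_cyl_surface(), c(7.5e-4, 5e-4, 3.3e-4),
                          flow_rate_ml_day = 720)
  # probes fall back to whole-domain stations (25..75% span); compare the
  # clinical dP readout against the matching analytic span.  Probe snapping
  # to cell centroids leaves an O(h) placement wobble on a duct with a
  # uniform axial gradient, so the check is against the oracle, not between
  # levels (level-to-level convergence is exercised on the phantom, where
  # the readout is dominated by the throat drop).
  dp_span <- poiseuille_dp(0.001, 0.5 * 10e-3, Q_720, 1.5e-3)
  expect_true(all(abs(gc_$table$dp_pa - dp_span) / dp_span < 0.08))
  expect_lt(abs(gc_$table$dp_pa[3] - dp_span) / dp_span, 0.05)
})
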