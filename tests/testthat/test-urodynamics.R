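test_that("flow-rate conversion reproduces the physiological band exactly", {
  expect_identical(flow_rate_convert(360)$ml_min, 0.25)
  expect_identical(flow_rate_convert(1440)$ml_min, 1)
  expect_equal(flow_rate_convert(720)$m3_s, 8.333e-9, tolerance = 1e-4)
  expect_equal(flow_rate_convert(c(360, 720))$ml_min, c(0.25, 0.5))
  expect_error(flow_rate_convert(-1), "positive")
})

test_that("automatic probes land inside the pelvis and are deterministic", {
  mesh <- fx_phantom_mesh()
  pr1 <- auto_probe_points(mesh)
  pr2 <- auto_probe_points(mesh)
  expect_identical(pr1$points, pr2$points)
  expect_false(pr1$fallback)
  expect_identical(nrow(pr1$points), 3L)
  expect_gt(min(dist(pr1$points)), 0)
  # all strictly inside (locatable)
  for (i in 1:3)
    expect_false(is.null(pelviflow:::.locate_point(mesh, pr1$points[i, ])))
  # probes sit in the dilated half of the domain
  tcoord <- drop(sweep(pr1$points, 2, mesh$frame$origin) %*% mesh$frame$e1)
  tmid <- mean(range(mesh$profile$t))
  expect_true(all(tcoord < tmid))
})

test_that("a straight duct triggers the whole-domain probe fallback", {
  pr <- auto_probe_points(fx_cyl_mesh())
  expect_true(pr$fallback)
  expect_identical(nrow(pr$points), 3L)
})

test_that("probe interpolation is exact for a constant field and flags outside points", {
  mesh <- fx_cyl_mesh()
  pr <- auto_probe_points(mesh)
  fake <- list(P = rep(3.25, nrow(mesh$vertices)), mesh = mesh,
               case = list(outlet_pressure = 0))
  expect_equal(unname(probe_pressure(fake, pr)), rep(3.25, 3))
  outside <- probe_set(matrix(c(1, 1, 1), 1))
  expect_error(probe_pressure(fake, outside), "outside the mesh")
})

test_that("outlet-adjacent probes read the outlet datum", {
  sol <- fx_cyl_stokes()
  mesh <- fx_cyl_mesh()
  fr <- mesh$frame
  near_out <- fr$origin + (max(mesh$profile$t) - 2e-5) * fr$e1
  p <- probe_pressure(sol, probe_set(matrix(near_out, 1)))
  expect_lt(abs(p), 5e-3 * max(abs(sol$P)))
})

test_that("the Stokes sweep is exactly proportional to Q and uniform in the pelvis", {
  sw <- fx_phantom_sweep()
  tb <- sw$table
  expect_identical(tb$q_ml_day, c(360, 720, 1440))
  expect_equal(tb$dp_pa[2] / tb$dp_pa[1], 2, tolerance = 1e-12)
  expect_equal(tb$dp_pa[3] / tb$dp_pa[1], 4, tolerance = 1e-12)
  expect_true(all(tb$dp_pa > 0))
  expect_true(all(tb$uniformity_pa <= 0.05 * tb$dp_pa))
})

test_that("severity classification follows the flow-dependence dichotomy", {
  q <- c(360, 720, 1440)
  mk <- function(dp) as_pressure_sweep(
    data.frame(q_ml_day = q, q_ml_min = q / 1440, dp_pa = dp))
  # the index case: rising pressure difference, well above threshold
  obstructive <- classify_obstruction(mk(c(0.015, 0.035, 0.086)))
  expect_identical(obstructive$pattern, "FLOW_DEPENDENT_OBSTRUCTIVE")
  expect_gt(obstructive$slope, 0)
  expect_identical(obstructive$physiological_band, c(360, 1440))
  # flat, near-zero pressure difference
  expect_identical(classify_obstruction(mk(c(1e-5, 1.1e-5, 1.2e-5)))$pattern,
                   "FLOW_INDEPENDENT")
  # boundary case: below threshold and non-increasing
  expect_identical(classify_obstruction(mk(c(0.014, 0.014, 0.014)))$pattern,
                   "FLOW_INDEPENDENT")
  # above threshold but not strictly increasing stays flow-independent
  expect_identical(classify_obstruction(mk(c(0.05, 0.05, 0.05)))$pattern,
                   "FLOW_INDEPENDENT")
  expect_error(classify_obstruction(mk(0.01)[["table"]]), "pelviflow_sweep")
  expect_error(classify_obstruction(
    as_pressure_sweep(data.frame(q_ml_day = 360, q_ml_min = 0.25,
                                 dp_pa = 0.1))), "at least two")
  expect_error(classify_obstruction(mk(c(1, 2, 3)), threshold_pa = 0),
               "strictly positive")
})

test_that("classification is invariant to adding intermediate flow rates", {
  mesh <- fx_phantom_mesh()
  pr <- auto_probe_points(mesh)
  sw3 <- fx_phantom_sweep()
  sw5 <- pressure_sweep(mesh, fx_fluid(), pr,
                        flow_rates_ml_day = c(360, 540, 720, 1080, 1440))
  expect_identical(classify_obstruction(sw3)$pattern,
                   classify_obstruction(sw5)$pattern)
  expect_error(pressure_sweep(mesh, fx_fluid(), pr,
                              flow_rates_ml_day = c(720, 360)),
               "strictly increasing")
})
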