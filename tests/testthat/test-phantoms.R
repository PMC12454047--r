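test_that("phantom spec validation names the violated invariant", {
  expect_error(phantom_spec(upj_throat_diameter = 5e-3,
                            ureter_diameter = 3e-3),
               "upj_throat_diameter <= ureter_diameter")
  expect_error(phantom_spec(ureter_diameter = 40e-3),
               "ureter_diameter <= pelvis_ap_diameter")
  expect_error(phantom_spec(pelvis_length = -1), "strictly positive")
  expect_error(phantom_spec(inlet_patch_fraction = 0.7), "inlet_patch_fraction")
  expect_error(phantom_spec(inlet_patch_fraction = 0), "inlet_patch_fraction")
})

test_that("phantom surface is a watertight closed genus-0 surface with 3 tag groups", {
  spec <- phantom_spec(pelvis_ap_diameter = 30e-3, upj_throat_diameter = 1e-3,
                       ureter_diameter = 3e-3, ureter_length = 30e-3)
  surf <- make_phantom(spec)
  top <- surface_topology(surf)
  expect_true(top$watertight)
  expect_true(top$oriented)
  expect_identical(top$euler_characteristic, 2L)
  expect_gt(top$enclosed_volume, 0)
  expect_setequal(unique(surf$tags), c("INLET", "OUTLET", "WALL"))
})

test_that("phantom generation is deterministic given spec and seed", {
  s1 <- make_phantom(phantom_spec(seed = 7, jitter = 0.05))
  s2 <- make_phantom(phantom_spec(seed = 7, jitter = 0.05))
  s3 <- make_phantom(phantom_spec(seed = 8, jitter = 0.05))
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$triangles, s2$triangles)
  expect_false(identical(s1$vertices, s3$vertices))
  # jitter must not disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_phantom(phantom_spec(seed = 3, jitter = 0.02)))
  expect_identical(rnorm(1), before)
})

test_that("phantom enclosed volume tracks the analytic profile volume", {
  spec <- phantom_spec()
  surf <- make_phantom(spec)
  prof <- pelviflow:::phantom_profile(spec)
  v_analytic <- stats::integrate(function(z) pi * prof$r(z)^2,
                                 0, prof$total_length,
                                 subdivisions = 2000L)$value
  expect_lt(abs(surface_volume(surf) - v_analytic) / v_analytic, 0.15)
})

test_that("cylinder surface has exact cap areas and refines under a smaller edge target", {
  cyl <- fx_cyl_surface()
  areas <- surface_tag_areas(cyl)
  cap <- pi * (1.5e-3)^2
  expect_lt(abs(areas[["INLET"]] - cap) / cap, 1e-6)
  expect_lt(abs(areas[["OUTLET"]] - cap) / cap, 1e-6)
  fine <- make_cylinder(1.5e-3, 10e-3, mesh_edge_target = 0.25e-3)
  expect_gt(nrow(fine$vertices), nrow(cyl$vertices))
  expect_setequal(unique(fine$tags), c("INLET", "OUTLET", "WALL"))
  expect_error(make_cylinder(-1, 1), "radius")
  expect_error(make_cylinder(1e-3, 0), "length")
})

test_that("mask_to_surface recovers a voxelised cylinder volume within 10%", {
  mask <- voxel_cylinder_mask(radius = 3e-3, length = 12e-3, spacing = 0.5e-3)
  surf <- mask_to_surface(mask, spacing = rep(0.5e-3, 3))
  top <- surface_topology(surf)
  expect_true(top$watertight)
  expect_true(top$oriented)
  v_true <- pi * (3e-3)^2 * 12e-3
  expect_lt(abs(top$enclosed_volume - v_true) / v_true, 0.10)
})

test_that("mask_to_surface rejects empty and disconnected masks", {
  expect_error(mask_to_surface(array(0, c(4, 4, 4)), rep(1e-3, 3)),
               "empty mask")
  two <- array(FALSE, c(7, 5, 5))
  two[2, 2:3, 2:3] <- TRUE
  two[6, 2:3, 2:3] <- TRUE
  expect_error(mask_to_surface(two, rep(1e-3, 3)), "multiple")
  expect_error(mask_to_surface(two[, , 1], rep(1e-3, 3)), "3-D")
  expect_error(mask_to_surface(array(TRUE, c(3, 3, 3)), c(1, -1, 1) * 1e-3),
               "spacing")
})
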