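test_that("binary STL round-trips geometry, including unit rescaling", {
  cyl <- fx_cyl_surface()
  p <- file.path(tempdir(), "cyl_mm.stl")
  write_surface(cyl, p, unit_scale = 1e3)     # write in millimetres
  back <- read_surface(p, unit_scale = 1e-3)  # read back into metres
  expect_equal(nrow(back$triangles), nrow(cyl$triangles))
  bb0 <- apply(cyl$vertices, 2, range)
  bb1 <- apply(back$vertices, 2, range)
  expect_equal(bb1, bb0, tolerance = 1e-6)
  expect_equal(surface_volume(back), surface_volume(cyl), tolerance = 1e-6)
})

test_that("ascii STL is parsed and repaired into a watertight cube", {
  # a unit cube as 12 facets; vertices deliberately duplicated per facet
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7),
               c(1,2,5), c(2,6,5), c(3,7,4), c(4,7,8),
               c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
  p <- file.path(tempdir(), "cube.stl")
  con <- file(p, "w")
  writeLines("solid cube", con)
  for (i in seq_len(nrow(tri))) {
    writeLines(c("facet normal 0 0 0", "outer loop",
                 sprintf("vertex %g %g %g", v[tri[i, ], 1], v[tri[i, ], 2],
                         v[tri[i, ], 3]),
                 "endloop", "endfacet"), con)
  }
  writeLines("endsolid cube", con)
  close(con)
  cube <- read_surface(p)
  top <- surface_topology(cube)
  expect_identical(top$n_triangles, 12L)
  expect_identical(top$n_vertices, 8L)
  expect_identical(top$euler_characteristic, 2L)
  expect_true(top$watertight)
  expect_equal(top$enclosed_volume, 1, tolerance = 1e-12)
})

test_that("OFF and PLY round-trips preserve topology and volume", {
  cyl <- fx_cyl_surface()
  for (ext in c("off", "ply")) {
    p <- file.path(tempdir(), paste0("cyl.", ext))
    write_surface(cyl, p)
    back <- read_surface(p)
    expect_true(surface_topology(back)$watertight)
    expect_equal(surface_volume(back), surface_volume(cyl),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a surface with a missing facet fails with its open edges reported", {
  cyl <- fx_cyl_surface()
  holed <- surface_mesh(cyl$vertices, cyl$triangles[-5L, , drop = FALSE],
                        validate = FALSE)
  p <- file.path(tempdir(), "holed.off")
  write_surface(holed, p)
  expect_error(read_surface(p), "3 open edge")
})

test_that("read_surface argument validation", {
  expect_error(read_surface("does_not_exist.stl"), "not found")
  p <- file.path(tempdir(), "x.off")
  write_surface(fx_cyl_surface(), p)
  expect_error(read_surface(p, unit_scale = 0), "unit_scale")
  p2 <- sub("off$", "xyz", p)
  file.copy(p, p2, overwrite = TRUE)
  expect_error(read_surface(p2), "unsupported")
})
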