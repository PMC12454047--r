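test_that("tagging rules partition a bare cylinder into caps and wall", {
  cyl <- fx_cyl_surface()
  bare <- surface_mesh(cyl$vertices, cyl$triangles)   # all WALL
  tagged <- tag_boundaries(bare, rules = list(
    outlet = select_axis_cap("z", "min"),
    inlet = select_axis_cap("z", "max")))
  expect_setequal(unique(tagged$tags), c("INLET", "OUTLET", "WALL"))
  # cap facet counts match the generator's own caps
  expect_identical(sum(tagged$tags == "OUTLET"), sum(cyl$tags == "INLET"))
  expect_identical(sum(tagged$tags == "INLET"), sum(cyl$tags == "OUTLET"))
  expect_identical(sum(tagged$tags == "WALL"), sum(cyl$tags == "WALL"))
})

test_that("tagging is a pass-through for pre-tagged phantoms and rejects bad rules", {
  ph <- fx_phantom_surface()
  expect_identical(tag_boundaries(ph), ph)
  bare <- surface_mesh(ph$vertices, ph$triangles)
  expect_error(tag_boundaries(bare), "no INLET/OUTLET tags")
  expect_error(tag_boundaries(bare, rules = list(
    outlet = function(cen, nrm) rep(FALSE, nrow(cen)),
    inlet = select_axis_cap("z", "min"))), "zero facets")
  expect_error(tag_boundaries(bare, rules = list(
    outlet = select_axis_cap("z", "min"),
    inlet = select_axis_cap("z", "min"))), "conflicting")
})

test_that("volume mesh conserves volume and inherits every surface tag", {
  cyl <- fx_cyl_surface()
  mesh <- fx_cyl_mesh()
  expect_lt(abs(mesh_volume(mesh) - surface_volume(cyl)) /
              surface_volume(cyl), 0.02)
  expect_setequal(unique(mesh$boundary_tags), unique(cyl$tags))
  q <- mesh_quality(mesh)
  expect_gt(q$min_dihedral_angle, 0)
  expect_identical(q$n_cells, nrow(mesh$tets))
  expect_setequal(names(q$n_boundary_facets_per_tag),
                  c("INLET", "OUTLET", "WALL"))

  ph <- fx_phantom_surface()
  pmesh <- fx_phantom_mesh()
  expect_lt(abs(mesh_volume(pmesh) - surface_volume(ph)) /
              surface_volume(ph), 0.02)
  expect_setequal(unique(pmesh$boundary_tags), unique(ph$tags))
})

test_that("refinement is monotone and roughly eightfold per halving", {
  cyl <- fx_cyl_surface()
  n <- vapply(c(6e-4, 5e-4, 2.5e-4), function(e)
    nrow(generate_volume_mesh(cyl, edge_target = e)$tets), integer(1))
  expect_true(all(diff(n) >= 0))   # decreasing edge target never loses cells
  expect_gt(n[3], n[1])
  ratio <- n[3] / n[2]
  expect_gt(ratio, 4)     # 8x within a factor of 2
  expect_lt(ratio, 16)
})

test_that("meshing a voxel-mask surface preserves its enclosed volume", {
  mask <- voxel_cylinder_mask(radius = 3e-3, length = 12e-3, spacing = 0.5e-3)
  surf <- mask_to_surface(mask, spacing = rep(0.5e-3, 3))
  tagged <- tag_boundaries(surf, rules = list(
    inlet = select_axis_cap("z", "min"),
    outlet = select_axis_cap("z", "max")))
  mesh <- generate_volume_mesh(tagged)
  expect_lt(abs(mesh_volume(mesh) - surface_volume(surf)) /
              surface_volume(surf), 0.02)
  expect_setequal(unique(mesh$boundary_tags), c("INLET", "OUTLET", "WALL"))
})

test_that("degenerate meshes are rejected with informative errors", {
  mesh <- fx_cyl_mesh()
  bad <- mesh$tets
  bad[1L, c(3L, 4L)] <- bad[1L, c(4L, 3L)]     # invert one cell
  expect_error(volume_mesh(mesh$vertices, bad, mesh$boundary_facets,
                           mesh$boundary_tags), "non-positive volume")
  bare <- surface_mesh(fx_cyl_surface()$vertices, fx_cyl_surface()$triangles)
  expect_error(generate_volume_mesh(bare), "INLET and OUTLET")
})

test_that("VTU export writes a well-formed unstructured grid", {
  mesh <- fx_cyl_mesh()
  p <- file.path(tempdir(), "mesh.vtu")
  write_vtu(mesh, p, point_data = list(
    pressure = rep(1, nrow(mesh$vertices)),
    velocity = matrix(0, nrow(mesh$vertices), 3)))
  doc <- xml2::read_xml(p)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_identical(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
                   nrow(mesh$tets))
  expect_identical(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
                   nrow(mesh$vertices))
})
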