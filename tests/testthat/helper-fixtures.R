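# Shared, lazily computed fixtures.  Heavy objects (meshes, flow solutions)
# are built once per test run and reused across test files; everything is
# generated in code, deterministically.

.fix_env <- new.env(parent = emptyenv())

fix <- function(name, expr) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- force(expr)
  .fix_env[[name]]
}

fx_fluid <- function() fluid_properties()

Q_720 <- 720 * 1e-6 / 86400   # m^3/s

fx_cyl_surface <- function()
  fix("cyl_surface", make_cylinder(1.5e-3, 10e-3))

fx_cyl_mesh <- function()
  fix("cyl_mesh", generate_volume_mesh(fx_cyl_surface(), edge_target = 5e-4))

fx_cyl_stokes <- function()
  fix("cyl_stokes",
      solve_stokes(fx_cyl_mesh(), fx_fluid(), flow_case(Q_720)))

fx_phantom_surface <- function()
  fix("phantom_surface", make_phantom(phantom_spec()))

fx_phantom_mesh <- function()
  fix("phantom_mesh", generate_volume_mesh(fx_phantom_surface()))

fx_phantom_sweep <- function()
  fix("phantom_sweep",
      pressure_sweep(fx_phantom_mesh(), fx_fluid(), model = "STOKES"))

fx_open_mesh <- function()
  fix("open_mesh",
      generate_volume_mesh(make_phantom(
        phantom_spec(upj_throat_diameter = 0.007))))

fx_open_sweep <- function()
  fix("open_sweep",
      pressure_sweep(fx_open_mesh(), fx_fluid(), model = "STOKES"))

fx_poiseuille_default <- function()
  fix("poiseuille_default", verify_poiseuille())

fx_poiseuille_refined <- function()
  fix("poiseuille_refined", verify_poiseuille(mesh_edge_target = 2.5e-4))

fx_phantom_ns <- function(q_ml_day) {
  key <- paste0("phantom_ns_", q_ml_day)
  fix(key, solve_navier_stokes(
    fx_phantom_mesh(), fx_fluid(),
    flow_case(flow_rate_convert(q_ml_day)$m3_s, model = "NAVIER_STOKES")))
}

# voxelised cylinder mask: radius/length in metres, isotropic spacing
voxel_cylinder_mask <- function(radius = 3e-3, length = 12e-3,
                                spacing = 0.5e-3) {
  nr <- ceiling(2 * radius / spacing) + 4L
  nz <- ceiling(length / spacing)
  ctr <- (nr + 1) / 2
  xy <- expand.grid(i = seq_len(nr), j = seq_len(nr))
  inside <- (xy$i - ctr)^2 + (xy$j - ctr)^2 <= (radius / spacing)^2
  mask <- array(FALSE, c(nr, nr, nz))
  for (k in seq_len(nz)) mask[, , k] <- matrix(inside, nr, nr)
  mask
}
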