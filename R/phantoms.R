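# Synthetic luminal phantoms of the renal pelvis, ureteropelvic junction and
# proximal ureter.  A phantom is a watertight surface of revolution: a flat
# papillary inflow cap, an ellipsoidal pelvic dome and chamber, a cosine
# funnel converging to a narrow UPJ throat, a cosine expansion into the
# ureter, a straight ureter segment, and a flat outlet cap.  These stand in
# for CT-segmented anatomy so the whole pipeline is testable without patient
# data; the surgical question (does pelvic pressure rise with urine flow?)
# only depends on this class of funnel-shaped geometry.

#' Parametric description of a pelvis-UPJ-ureter phantom
#'
#' Defaults describe a paediatric hydronephrotic collecting system with a
#' severely stenotic ureteropelvic junction: a 30 mm anteroposterior pelvis,
#' a 1 mm throat and a mildly dilated 7 mm proximal ureter.  Setting
#' `upj_throat_diameter = ureter_diameter` yields a non-obstructed (open)
#' phantom.
#'
#' @param pelvis_ap_diameter anteroposterior diameter of the pelvic chamber
#'   in metres (default 0.030).
#' @param pelvis_length axial length of the pelvis (dome + chamber + funnel)
#'   in metres (default 0.040).
#' @param upj_throat_diameter minimum luminal diameter at the UPJ in metres
#'   (default 0.001).
#' @param upj_length length of the cylindrical throat section in metres
#'   (default 0.003).
#' @param ureter_diameter luminal diameter of the proximal ureter in metres
#'   (default 0.007).
#' @param ureter_length modelled ureter length down to the outlet in metres
#'   (default 0.025).
#' @param inlet_patch_fraction fraction (0, 0.5] of the pelvic dome used as
#'   the papillary inflow patch (default 0.2).
#' @param mesh_edge_target target surface triangle edge length in metres
#'   (default 1.5e-3).
#' @param seed integer seed for the optional surface jitter.
#' @param jitter relative amplitude of a smooth random perturbation of the
#'   radius profile (default 0 = perfectly smooth phantom).
#'
#' @return An object of class `pelviflow_phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' open_spec <- phantom_spec(upj_throat_diameter = 0.007)
#' @export
phantom_spec <- function(pelvis_ap_diameter = 0.030,
                         pelvis_length = 0.040,
                         upj_throat_diameter = 0.001,
                         upj_length = 0.003,
                         ureter_diameter = 0.007,
                         ureter_length = 0.025,
                         inlet_patch_fraction = 0.2,
                         mesh_edge_target = 1.5e-3,
                         seed = 1L,
                         jitter = 0) {
  spec <- structure(list(pelvis_ap_diameter = pelvis_ap_diameter,
                         pelvis_length = pelvis_length,
                         upj_throat_diameter = upj_throat_diameter,
                         upj_length = upj_length,
                         ureter_diameter = ureter_diameter,
                         ureter_length = ureter_length,
                         inlet_patch_fraction = inlet_patch_fraction,
                         mesh_edge_target = mesh_edge_target,
                         seed = as.integer(seed),
                         jitter = jitter),
                    class = "pelviflow_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @keywords internal
#' @noRd
validate_phantom_spec <- function(spec) {
  lens <- c("pelvis_ap_diameter", "pelvis_length", "upj_throat_diameter",
            "upj_length", "ureter_diameter", "ureter_length",
            "mesh_edge_target")
  for (f in lens) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invariant violated: ", f, " must be strictly positive")
  }
  if (spec$upj_throat_diameter > spec$ureter_diameter)
    stop("invariant violated: upj_throat_diameter <= ureter_diameter ",
         "(throat wider than ureter)")
  if (spec$ureter_diameter > spec$pelvis_ap_diameter)
    stop("invariant violated: ureter_diameter <= pelvis_ap_diameter")
  f <- spec$inlet_patch_fraction
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 0.5)
    stop("invariant violated: inlet_patch_fraction must lie in (0, 0.5]")
  if (!is.numeric(spec$jitter) || spec$jitter < 0 || spec$jitter >= 0.5)
    stop("invariant violated: jitter must lie in [0, 0.5)")
  invisible(spec)
}

#' @export
print.pelviflow_phantom_spec <- function(x, ...) {
  cat("Pelvis-UPJ-ureter phantom spec (mm):\n")
  cat(sprintf("  pelvis AP %.1f x length %.1f | throat %.2f x %.1f | ureter %.1f x %.1f\n",
              x$pelvis_ap_diameter * 1e3, x$pelvis_length * 1e3,
              x$upj_throat_diameter * 1e3, x$upj_length * 1e3,
              x$ureter_diameter * 1e3, x$ureter_length * 1e3))
  cat(sprintf("  inlet patch fraction %.2f | surface edge target %.2f mm | seed %d | jitter %.3f\n",
              x$inlet_patch_fraction, x$mesh_edge_target * 1e3, x$seed,
              x$jitter))
  invisible(x)
}

# Radius profile r(z) of the phantom, C1 across segment joins (the flat end
# caps meet the profile at a corner, as real collecting systems do at the
# papillae).  Returns a list with the profile function and segment landmarks.
#' @keywords internal
#' @noRd
phantom_profile <- function(spec) {
  Rp <- spec$pelvis_ap_diameter / 2
  Rt <- spec$upj_throat_diameter / 2
  Ru <- spec$ureter_diameter / 2
  f <- spec$inlet_patch_fraction
  r0 <- Rp * sqrt(2 * f - f^2)      # rim radius of a spherical cap of area
                                    # fraction f of the dome hemisphere
  Lp <- spec$pelvis_length
  L_dome <- 0.30 * Lp
  L_body <- 0.25 * Lp
  L_funnel <- Lp - L_dome - L_body
  L_throat <- spec$upj_length
  L_exp <- 3 * (Ru - Rt)
  L_ureter <- spec$ureter_length
  z1 <- L_dome; z2 <- z1 + L_body; z3 <- z2 + L_funnel
  z4 <- z3 + L_throat; z5 <- z4 + L_exp; z6 <- z5 + L_ureter
  base <- function(z) {
    r <- numeric(length(z))
    i <- z <= z1
    if (any(i)) {
      q <- (z1 - z[i]) / z1
      r[i] <- Rp * sqrt(pmax(1 - (1 - (r0 / Rp)^2) * q^2, 0))
    }
    i <- z > z1 & z <= z2
    r[i] <- Rp
    i <- z > z2 & z <= z3
    if (any(i)) {
      s <- (z[i] - z2) / L_funnel
      r[i] <- Rt + (Rp - Rt) * (1 + cos(pi * s)) / 2
    }
    i <- z > z3 & z <= z4
    r[i] <- Rt
    i <- z > z4 & z <= z5
    if (any(i)) {
      s <- (z[i] - z4) / L_exp
      r[i] <- Ru + (Rt - Ru) * (1 + cos(pi * s)) / 2
    }
    i <- z > z5
    r[i] <- Ru
    r
  }
  profile <- base
  if (spec$jitter > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    amp <- stats::rnorm(4) / (1:4)
    phs <- stats::runif(4, 0, 2 * pi)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    amp <- amp / sqrt(sum(amp^2))
    profile <- function(z) {
      mod <- 1 + spec$jitter *
        Reduce(`+`, lapply(1:4, function(k)
          amp[k] * sin(2 * pi * k * z / z6 + phs[k])))
      base(z) * pmax(mod, 0.5)
    }
  }
  list(r = profile, landmarks = c(cap = 0, dome = z1, body = z2,
                                  funnel = z3, throat = z4,
                                  expansion = z5, outlet = z6),
       total_length = z6, r_inlet = r0)
}

# March axial stations along the profile so spacing follows both the surface
# edge target and the local radius (fine through the throat, coarse in the
# chamber); every segment landmark is included exactly.
#' @keywords internal
#' @noRd
march_stations <- function(profile_fun, landmarks, edge, dz_radius_factor = 0.5) {
  z <- numeric(0)
  lm <- sort(unique(landmarks))
  for (s in seq_len(length(lm) - 1L)) {
    a <- lm[s]; b <- lm[s + 1L]
    if (b - a < 1e-12) next
    zz <- a
    cur <- a
    while (cur < b) {
      r_here <- profile_fun(min(cur + 1e-9, b))
      dz <- max(min(edge, dz_radius_factor * r_here), edge / 8)
      cur <- cur + dz
      if (cur < b - 1e-12) zz <- c(zz, cur)
    }
    # close the segment; drop a station that would leave a sliver interval
    if (length(zz) >= 2L && (b - zz[length(zz)]) <
          0.3 * (zz[length(zz)] - zz[length(zz) - 1L]))
      zz <- zz[-length(zz)]
    zz <- c(zz, b)
    z <- c(z, if (s == 1L) zz else zz[-1L])
  }
  z
}

#' Generate a watertight phantom surface
#'
#' Builds the tagged, outward-oriented triangulated surface described by a
#' [phantom_spec()]: `INLET` papillary cap on the pelvic dome, `OUTLET`
#' ureter end cap, `WALL` elsewhere.  Generation is deterministic given the
#' spec (including its `seed`).
#'
#' @param spec a [phantom_spec()].
#' @return A [surface_mesh()] with tags `INLET`, `OUTLET`, `WALL` and an
#'   attached `"phantom_spec"` attribute.
#' @examples
#' surf <- make_phantom(phantom_spec(mesh_edge_target = 3e-3))
#' summary(surf)
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  prof <- phantom_profile(spec)
  edge <- spec$mesh_edge_target
  z <- march_stations(prof$r, prof$landmarks, edge)
  r <- prof$r(z)
  n_theta <- max(24L, min(128L, round(2 * pi * (spec$pelvis_ap_diameter / 2) /
                                        edge)))
  raw <- revolve_closed_surface(z, r, n_theta)
  out <- surface_mesh(raw$vertices, raw$triangles, raw$tags)
  attr(out, "phantom_spec") <- spec
  out
}

#' Generate a closed cylinder surface
#'
#' Validation geometry for the Hagen-Poiseuille oracle: a straight circular
#' duct with `INLET`/`OUTLET` end caps and a `WALL` lateral surface.
#'
#' @param radius cylinder radius in metres.
#' @param length cylinder length in metres.
#' @param mesh_edge_target target surface edge length in metres
#'   (default `radius / 3`).
#' @return A [surface_mesh()].
#' @examples
#' cyl <- make_cylinder(1.5e-3, 10e-3)
#' surface_tag_areas(cyl)["INLET"] / (pi * 1.5e-3^2)   # ~ 1
#' @export
make_cylinder <- function(radius, length, mesh_edge_target = radius / 3) {
  if (!is.numeric(radius) || radius <= 0)
    stop("invariant violated: radius must be strictly positive")
  if (!is.numeric(length) || length <= 0)
    stop("invariant violated: length must be strictly positive")
  if (mesh_edge_target <= 0)
    stop("invariant violated: mesh_edge_target must be strictly positive")
  n_theta <- max(16L, min(128L, round(2 * pi * radius / mesh_edge_target)))
  nz <- max(4L, ceiling(length / mesh_edge_target))
  z <- seq(0, length, length.out = nz + 1L)
  raw <- revolve_closed_surface(z, rep(radius, nz + 1L), n_theta)
  surface_mesh(raw$vertices, raw$triangles, raw$tags)
}

#' Extract a surface from a binary voxel mask
#'
#' Converts a 3-D binary mask (e.g. a segmented lumen) into a closed,
#' outward-oriented triangulated surface in physical units by extracting the
#' voxel boundary faces.  The mask must contain a single 6-connected
#' foreground component.  No boundary tags are assigned (see
#' [tag_boundaries()]).
#'
#' @param mask 3-D array; non-zero entries are foreground.
#' @param spacing numeric length-3 voxel spacing per axis in metres.
#' @param smooth_iter number of volume-preserving Laplacian smoothing
#'   iterations applied to the blocky voxel surface (default 0).
#' @return A [surface_mesh()] tagged all-`WALL`.
#' @export
mask_to_surface <- function(mask, spacing, smooth_iter = 0L) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths")
  fg <- mask != 0
  if (!any(fg)) stop("empty mask: no foreground voxels")
  if (!.single_component_6(fg))
    stop("mask has multiple 6-connected foreground components")
  dims <- dim(fg)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  cid <- function(a, b, c) a + (nx + 1) * (b + (ny + 1) * c) + 1
  pad <- array(FALSE, dims + 2L)
  pad[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- fg
  idx <- which(fg, arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]; k <- idx[, 3L]
  quads <- matrix(0, 0, 4)
  add_dir <- function(quads, sel, q) if (any(sel))
    rbind(quads, q[sel, , drop = FALSE]) else quads
  bg <- function(di, dj, dk)
    !pad[cbind(i + 1L + di, j + 1L + dj, k + 1L + dk)]
  # +x faces
  s <- bg(1L, 0L, 0L)
  quads <- add_dir(quads, s, cbind(cid(i, j - 1, k - 1), cid(i, j, k - 1),
                                   cid(i, j, k), cid(i, j - 1, k)))
  # -x faces
  s <- bg(-1L, 0L, 0L)
  quads <- add_dir(quads, s, cbind(cid(i - 1, j - 1, k - 1),
                                   cid(i - 1, j - 1, k),
                                   cid(i - 1, j, k), cid(i - 1, j, k - 1)))
  # +y
  s <- bg(0L, 1L, 0L)
  quads <- add_dir(quads, s, cbind(cid(i - 1, j, k - 1), cid(i - 1, j, k),
                                   cid(i, j, k), cid(i, j, k - 1)))
  # -y
  s <- bg(0L, -1L, 0L)
  quads <- add_dir(quads, s, cbind(cid(i - 1, j - 1, k - 1),
                                   cid(i, j - 1, k - 1),
                                   cid(i, j - 1, k), cid(i - 1, j - 1, k)))
  # +z
  s <- bg(0L, 0L, 1L)
  quads <- add_dir(quads, s, cbind(cid(i - 1, j - 1, k), cid(i, j - 1, k),
                                   cid(i, j, k), cid(i - 1, j, k)))
  # -z
  s <- bg(0L, 0L, -1L)
  quads <- add_dir(quads, s, cbind(cid(i - 1, j - 1, k - 1),
                                   cid(i - 1, j, k - 1),
                                   cid(i, j, k - 1), cid(i, j - 1, k - 1)))
  tri <- rbind(quads[, c(1L, 2L, 3L)], quads[, c(1L, 3L, 4L)])
  used <- sort(unique(as.vector(tri)))
  map <- integer(max(used)); map[used] <- seq_along(used)
  tri <- matrix(map[tri], ncol = 3L)
  u0 <- used - 1L
  a <- u0 %% (nx + 1)
  b <- (u0 %/% (nx + 1)) %% (ny + 1)
  c <- u0 %/% ((nx + 1) * (ny + 1))
  verts <- cbind(a * spacing[1L], b * spacing[2L], c * spacing[3L])
  if (surface_enclosed_volume(verts, tri) < 0)
    tri[, c(2L, 3L)] <- tri[, c(3L, 2L)]
  if (smooth_iter > 0L) {
    v0 <- surface_enclosed_volume(verts, tri)
    for (it in seq_len(smooth_iter)) {
      e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3L, 1L)])
      acc <- rowsum(rbind(verts[e[, 2L], ], verts[e[, 1L], ]),
                    c(e[, 1L], e[, 2L]))
      cnt <- tabulate(c(e[, 1L], e[, 2L]), nbins = nrow(verts))
      verts <- 0.5 * verts + 0.5 * acc / cnt
    }
    v1 <- surface_enclosed_volume(verts, tri)
    ctr <- colMeans(verts)
    verts <- sweep(sweep(verts, 2, ctr), 2, rep((v0 / v1)^(1 / 3), 3), "*")
    verts <- sweep(verts, 2, ctr, "+")
  }
  surface_mesh(verts, tri)
}

#' @keywords internal
#' @noRd
.single_component_6 <- function(fg) {
  dims <- dim(fg)
  visited <- array(FALSE, dims)
  seed <- which(fg)[1L]
  visited[seed] <- TRUE
  repeat {
    grown <- visited
    grown[-1, , ] <- grown[-1, , ] | visited[-dims[1L], , ]
    grown[-dims[1L], , ] <- grown[-dims[1L], , ] | visited[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | visited[, -dims[2L], ]
    grown[, -dims[2L], ] <- grown[, -dims[2L], ] | visited[, -1, ]
    grown[, , -1] <- grown[, , -1] | visited[, , -dims[3L]]
    grown[, , -dims[3L]] <- grown[, , -dims[3L]] | visited[, , -1]
    grown <- grown & fg
    if (identical(grown, visited)) break
    visited <- grown
  }
  all(visited[fg])
}

#' Read a binary mask from a NIfTI file
#'
#' Thin wrapper over [RNifti::readNifti()] returning the mask array and its
#' voxel spacing in metres (NIfTI stores millimetres).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param threshold voxels strictly above this value are foreground
#'   (default 0).
#' @return list with `mask` (logical 3-D array) and `spacing` (metres).
#' @export
read_mask_nifti <- function(path, threshold = 0) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3] * 1e-3
  list(mask = array(img > threshold, dim(img)[1:3]), spacing = sp)
}
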