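# Volume meshing: turn a tagged, watertight surface of a tube-like lumen into
# a solver-ready tetrahedral mesh with inherited boundary tags.
#
# The mesher is specialised to single-axis luminal geometries (pelvis +
# ureter, ducts, voxelised tubes): it recovers the cross-section area profile
# A(t) along the principal axis by plane slicing, then extrudes a structured
# triangulated disk along the axis and splits the prisms into tetrahedra with
# the minimum-vertex diagonal rule.  Disk radii are chosen so that each
# discrete cross-section reproduces the sliced area exactly, which removes
# the leading (inscribed-polygon) volume and resistance bias.

#' Construct a volume mesh object
#'
#' Usually produced by [generate_volume_mesh()]; the constructor validates
#' element orientation and boundary tagging.
#'
#' @param vertices numeric matrix (n x 3), metres.
#' @param tets integer matrix (m x 4) of 1-based vertex indices, positively
#'   oriented.
#' @param boundary_facets integer matrix (k x 3), outward-oriented boundary
#'   triangles.
#' @param boundary_tags character vector of length k.
#' @param edge_target nominal cell edge length (m).
#' @return An object of class `pelviflow_mesh`.
#' @export
volume_mesh <- function(vertices, tets, boundary_facets, boundary_tags,
                        edge_target = NA_real_) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  vol <- tet_signed_volume(vertices, tets)
  if (any(vol <= 0))
    stop("invalid mesh: ", sum(vol <= 0), " tetrahedra with non-positive volume")
  if (length(boundary_tags) != nrow(boundary_facets))
    stop("boundary_tags must match boundary_facets")
  structure(list(vertices = vertices, tets = tets,
                 boundary_facets = boundary_facets,
                 boundary_tags = as.character(boundary_tags),
                 edge_target = edge_target,
                 cache = new.env(parent = emptyenv())),
            class = "pelviflow_mesh")
}

#' Total mesh volume
#' @param mesh a [volume_mesh()].
#' @return Sum of tetrahedron volumes (m^3).
#' @export
mesh_volume <- function(mesh) sum(tet_signed_volume(mesh$vertices, mesh$tets))

#' @export
print.pelviflow_mesh <- function(x, ...) {
  cat("Tetrahedral volume mesh (pelviflow_mesh)\n")
  cat(sprintf("  vertices: %d  tets: %d  boundary facets: %d\n",
              nrow(x$vertices), nrow(x$tets), nrow(x$boundary_facets)))
  tb <- table(x$boundary_tags)
  cat("  boundary tags:",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  volume: %.4g mL   nominal edge: %.3g mm\n",
              mesh_volume(x) * 1e6, x$edge_target * 1e3))
  invisible(x)
}

# ---------------------------------------------------------------------------
# boundary tagging rules on surfaces

#' Boundary-region selectors for [tag_boundaries()]
#'
#' `select_axis_cap()` selects facets at the extreme of a direction whose
#' normals align with that direction (end caps); `select_plane()` selects
#' facets within a tolerance of a plane; `select_sphere()` selects facets
#' whose centroids fall inside a ball.
#'
#' @param axis direction vector (length 3), or one of `"x"`, `"y"`, `"z"`.
#' @param side `"min"` or `"max"` extreme of the axis coordinate.
#' @param tol band width (m) behind the extreme within which facet centroids
#'   are accepted; default 1e-6 of nothing sensible, so callers usually rely
#'   on the adaptive default (a small multiple of the local facet size).
#' @param angle_deg maximum angle (degrees) between facet normal and the axis.
#' @return A selector function `f(centroids, normals)` returning a logical
#'   vector, for use in [tag_boundaries()] rules.
#' @export
select_axis_cap <- function(axis = "z", side = c("min", "max"), tol = NULL,
                            angle_deg = 45) {
  side <- match.arg(side)
  ax <- if (is.character(axis))
    switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown axis: ", axis)) else axis / sqrt(sum(axis^2))
  force(tol)
  function(centroids, normals) {
    t <- drop(centroids %*% ax)
    tol_eff <- if (is.null(tol)) 1e-6 * (max(t) - min(t)) + 1e-12 else tol
    band <- if (side == "min") t <= min(t) + tol_eff else t >= max(t) - tol_eff
    sgn <- if (side == "min") -1 else 1
    align <- drop(normals %*% ax) * sgn >= cos(angle_deg * pi / 180)
    band & align
  }
}

#' @rdname select_axis_cap
#' @param point a point on the plane (m).
#' @param normal plane normal.
#' @export
select_plane <- function(point, normal, tol, angle_deg = 45) {
  n <- normal / sqrt(sum(normal^2))
  function(centroids, normals) {
    d <- abs(drop(sweep(centroids, 2, point) %*% n))
    align <- abs(drop(normals %*% n)) >= cos(angle_deg * pi / 180)
    d <= tol & align
  }
}

#' @rdname select_axis_cap
#' @param center ball centre (m).
#' @param radius ball radius (m).
#' @export
select_sphere <- function(center, radius) {
  function(centroids, normals) {
    sqrt(rowSums(sweep(centroids, 2, center)^2)) <= radius
  }
}

#' Assign inlet/outlet/wall tags to a surface
#'
#' Applies tagging rules to the facets of a surface mesh: rules select the
#' outlet patch and one or more inlet patches; all unselected facets become
#' `WALL`.  With `rules = NULL` the surface's existing tags are kept
#' (pass-through), so phantoms generated by [make_phantom()] are idempotent
#' under tagging.
#'
#' @param surface a [surface_mesh()].
#' @param rules `NULL`, or a list with elements `outlet` (a selector
#'   function, see [select_axis_cap()]) and `inlet` (a selector or a named
#'   list of selectors for multiple papillary patches `INLET`, `INLET_2`, ...).
#' @return The surface with a full `INLET*`/`OUTLET`/`WALL` partition.
#' @export
tag_boundaries <- function(surface, rules = NULL) {
  if (is.null(rules)) {
    if (!any(startsWith(surface$tags, "INLET")) ||
        !any(surface$tags == "OUTLET"))
      stop("surface has no INLET/OUTLET tags and no rules were given")
    return(surface)
  }
  if (is.null(rules$outlet) || is.null(rules$inlet))
    stop("rules must provide both 'inlet' and 'outlet' selectors")
  cen <- triangle_centroids(surface$vertices, surface$triangles)
  nrm <- triangle_normals(surface$vertices, surface$triangles)
  m <- nrow(surface$triangles)
  tags <- rep.int("WALL", m)
  out_sel <- rules$outlet(cen, nrm)
  if (!any(out_sel)) stop("outlet rule selected zero facets")
  inlets <- rules$inlet
  if (is.function(inlets)) inlets <- list(INLET = inlets)
  if (is.null(names(inlets)) || any(!nzchar(names(inlets))))
    names(inlets) <- c("INLET",
                       if (length(inlets) > 1)
                         paste0("INLET_", seq_len(length(inlets))[-1]))
  claimed <- out_sel
  tags[out_sel] <- "OUTLET"
  for (nm in names(inlets)) {
    sel <- inlets[[nm]](cen, nrm)
    if (!any(sel)) stop("inlet rule '", nm, "' selected zero facets")
    if (any(sel & claimed))
      stop("conflicting rules: ", sum(sel & claimed),
           " facet(s) selected by more than one inlet/outlet rule")
    tags[sel] <- nm
    claimed <- claimed | sel
  }
  surface$tags <- tags
  surface
}

# ---------------------------------------------------------------------------
# principal axis + profile recovery

#' @keywords internal
#' @noRd
.surface_axis_frame <- function(surface) {
  cen <- triangle_centroids(surface$vertices, surface$triangles)
  w <- triangle_areas(surface$vertices, surface$triangles)
  mu <- colSums(cen * w) / sum(w)
  x <- sweep(cen, 2, mu)
  cov <- crossprod(x * sqrt(w)) / sum(w)
  ev <- eigen(cov, symmetric = TRUE)
  e1 <- ev$vectors[, 1L]
  # deterministic sign: point towards increasing coordinate sum
  if (sum(e1) < 0) e1 <- -e1
  e2 <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- e2 - sum(e2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
          e1[3L] * e2[1L] - e1[1L] * e2[3L],
          e1[1L] * e2[2L] - e1[2L] * e2[1L])
  list(origin = mu, e1 = e1, e2 = e2, e3 = e3)
}

# Cross-section areas of `surface` at axial stations `t` (frame coords),
# nudging stations off vertex planes.
#' @keywords internal
#' @noRd
.profile_areas <- function(uv, tcoord, tri, t_stations) {
  L <- max(tcoord) - min(tcoord)
  eps <- 1e-9 * L
  vapply(t_stations, function(t0) {
    k <- 0L
    while (any(abs(tcoord - t0) < eps) && k < 8L) {
      t0 <- t0 + 13 * eps
      k <- k + 1L
    }
    slice_section_area(uv, tcoord, tri, t0)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# the mesher

#' Generate a tetrahedral volume mesh from a tagged surface
#'
#' Recovers the axial cross-section profile of a tube-like lumen and builds a
#' conforming, positively-oriented tetrahedral mesh whose boundary facets
#' inherit the surface tags (nearest facet within a 30 degree normal
#' tolerance, tie-break to `WALL`).  Cross-section disk radii match the
#' sliced areas exactly, so the mesh volume tracks the surface volume.
#'
#' @param surface a tagged [surface_mesh()] (watertight, with `INLET*` and
#'   `OUTLET` patches).
#' @param edge_target target cell edge length (m) at the narrowest section;
#'   default one third of the minimum luminal radius.
#' @param near_wall_refine radial grading factor >= 1; values above 1
#'   concentrate cross-section rings towards the wall (default 1).
#' @return A [volume_mesh()].
#' @examples
#' cyl <- make_cylinder(1.5e-3, 10e-3)
#' mesh <- generate_volume_mesh(cyl, edge_target = 5e-4)
#' mesh_volume(mesh) / surface_volume(cyl)   # ~ 1
#' @export
generate_volume_mesh <- function(surface, edge_target = NULL,
                                 near_wall_refine = 1) {
  chk <- surface_topology(surface)
  if (!chk$watertight || !chk$oriented)
    stop("volume meshing requires a watertight, oriented surface")
  if (!any(startsWith(surface$tags, "INLET")) ||
      !any(surface$tags == "OUTLET"))
    stop("surface must carry INLET and OUTLET tags; see tag_boundaries()")
  fr <- .surface_axis_frame(surface)
  vloc <- sweep(surface$vertices, 2, fr$origin)
  tcoord <- drop(vloc %*% fr$e1)
  uv <- cbind(drop(vloc %*% fr$e2), drop(vloc %*% fr$e3))
  tri <- surface$triangles
  tmin <- min(tcoord); tmax <- max(tcoord)
  L <- tmax - tmin
  delta <- 1e-5 * L
  # dense profile
  nd <- 400L
  td <- seq(tmin + delta, tmax - delta, length.out = nd)
  Ad <- .profile_areas(uv, tcoord, tri, td)
  if (any(Ad <= 0)) {
    bad <- range(td[Ad <= 0])
    stop(sprintf(paste0("mesher failure: empty cross-section between axial ",
                        "stations %.4g and %.4g m (geometry is not a single ",
                        "tube along its principal axis)"), bad[1], bad[2]))
  }
  rd <- sqrt(Ad / pi)
  r_min <- min(rd)
  if (is.null(edge_target)) edge_target <- r_min / 3
  if (edge_target <= 0) stop("edge_target must be positive")
  nr <- max(2L, min(24L, as.integer(ceiling(r_min / edge_target))))
  # station marching: axial spacing follows local radius, the edge target and
  # the local profile slope
  drdt <- c(diff(rd) / diff(td), 0)
  drdt <- pmax(abs(drdt), 1e-6)
  r_at <- stats::approxfun(td, rd, rule = 2)
  slope_at <- stats::approxfun(td, drdt, rule = 2)
  t_st <- tmin + delta
  cur <- t_st
  tend <- tmax - delta
  while (cur < tend) {
    r_here <- r_at(cur)
    dz <- min(max(2 * edge_target, 0.35 * r_here), 0.8 * r_here, L / 12,
              0.3 * r_here / slope_at(cur))
    cur <- cur + dz
    if (cur < tend - 1e-12) t_st <- c(t_st, cur)
  }
  if (length(t_st) >= 2L &&
      (tend - t_st[length(t_st)]) < 0.3 * diff(t_st[length(t_st) - 1:0]))
    t_st <- t_st[-length(t_st)]
  t_st <- c(t_st, tend)
  if (length(t_st) < 3L) t_st <- seq(tmin + delta, tend, length.out = 4L)
  # adaptive bisection: insert stations until the frustum volume of each
  # interval matches the sliced-area integral to 0.3%, so the mesh volume
  # tracks the surface volume well inside the 2% contract
  cum <- c(0, cumsum((Ad[-1L] + Ad[-nd]) / 2 * diff(td)))
  Fc <- stats::approxfun(td, cum, rule = 2)
  A_at <- stats::approxfun(td, Ad, rule = 2)
  for (pass in 1:6) {
    A1 <- A_at(t_st[-length(t_st)]); A2 <- A_at(t_st[-1L])
    h <- diff(t_st)
    vfr <- h / 3 * (A1 + A2 + sqrt(A1 * A2))
    vint <- Fc(t_st[-1L]) - Fc(t_st[-length(t_st)])
    bad <- which(abs(vfr - vint) > 0.003 * pmax(vint, 1e-300) &
                   h > 4 * (td[2L] - td[1L]))
    if (!length(bad) || length(t_st) > 220L) break
    t_st <- sort(c(t_st, (t_st[bad] + t_st[bad + 1L]) / 2))
  }
  A_st <- .profile_areas(uv, tcoord, tri, t_st)
  if (any(A_st <= 0)) stop("mesher failure: empty cross-section at a station")
  # disk template and area-exact scaling
  tmpl <- disk_template(nr, grading = near_wall_refine)
  n_theta <- 6L * nr
  A_tmpl <- (n_theta / 2) * sin(2 * pi / n_theta)  # area of unit template
  sigma <- sqrt(A_st / A_tmpl)
  nv_t <- nrow(tmpl$xy)
  m <- length(t_st)
  # vertices in world coordinates
  verts <- matrix(0, m * nv_t, 3L)
  for (j in seq_len(m)) {
    idx <- (j - 1L) * nv_t + seq_len(nv_t)
    x <- tmpl$xy[, 1L] * sigma[j]
    y <- tmpl$xy[, 2L] * sigma[j]
    verts[idx, ] <- matrix(fr$origin, nv_t, 3L, byrow = TRUE) +
      outer(rep(t_st[j], nv_t), fr$e1) +
      outer(x, fr$e2) + outer(y, fr$e3)
  }
  tets_list <- vector("list", m - 1L)
  for (j in seq_len(m - 1L)) {
    off_b <- (j - 1L) * nv_t
    off_t <- j * nv_t
    tets_list[[j]] <- split_prisms(tmpl$tri + off_b, tmpl$tri + off_t)
  }
  tets <- do.call(rbind, tets_list)
  tets <- orient_tets_positive(verts, tets)
  bd <- .boundary_facets_oriented(tets)
  tags <- .inherit_tags(verts, bd, surface)
  vm <- volume_mesh(verts, tets, bd, tags, edge_target = edge_target)
  vm$profile <- list(t = t_st, r = sqrt(A_st / pi))
  vm$frame <- fr
  vm
}

# Extract boundary facets (faces used by exactly one tet), outward-oriented.
#' @keywords internal
#' @noRd
.boundary_facets_oriented <- function(tets) {
  # outward faces of a positively oriented tet (a, b, c, d)
  f <- rbind(tets[, c(1L, 3L, 2L)], tets[, c(1L, 2L, 4L)],
             tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)])
  key <- cbind(pmin(f[, 1L], f[, 2L], f[, 3L]),
               f[, 1L] + f[, 2L] + f[, 3L] -
                 pmin(f[, 1L], f[, 2L], f[, 3L]) -
                 pmax(f[, 1L], f[, 2L], f[, 3L]),
               pmax(f[, 1L], f[, 2L], f[, 3L]))
  kstr <- paste(key[, 1L], key[, 2L], key[, 3L])
  cnt <- table(kstr)
  single <- names(cnt)[cnt == 1L]
  f[kstr %in% single, , drop = FALSE]
}

# Nearest-facet tag inheritance with 30 degree angular tolerance.
#' @keywords internal
#' @noRd
.inherit_tags <- function(verts, bd_facets, surface, angle_deg = 30) {
  nb <- nrow(bd_facets)
  tags <- rep.int("WALL", nb)
  b_cen <- triangle_centroids(verts, bd_facets)
  b_nrm <- triangle_normals(verts, bd_facets)
  s_cen <- triangle_centroids(surface$vertices, surface$triangles)
  s_nrm <- triangle_normals(surface$vertices, surface$triangles)
  s_area <- triangle_areas(surface$vertices, surface$triangles)
  cos_tol <- cos(angle_deg * pi / 180)
  groups <- setdiff(unique(surface$tags), "WALL")
  best_d <- rep(Inf, nb)
  for (g in groups) {
    sel <- surface$tags == g
    cg <- s_cen[sel, , drop = FALSE]
    ng <- s_nrm[sel, , drop = FALSE]
    reach <- 4 * sqrt(stats::median(s_area[sel]))
    # chunked nearest-centroid search
    step <- 512L
    for (s0 in seq(1L, nb, by = step)) {
      ii <- s0:min(s0 + step - 1L, nb)
      d2 <- outer(rowSums(b_cen[ii, , drop = FALSE]^2), rowSums(cg^2), "+") -
        2 * b_cen[ii, , drop = FALSE] %*% t(cg)
      jmin <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(pmax(d2[cbind(seq_along(ii), jmin)], 0))
      align <- rowSums(b_nrm[ii, , drop = FALSE] *
                         ng[jmin, , drop = FALSE]) >= cos_tol
      take <- dmin <= reach & align & dmin < best_d[ii]
      tags[ii][take] <- g
      best_d[ii][take] <- dmin[take]
    }
  }
  tags
}

# ---------------------------------------------------------------------------
# quality

#' Mesh quality report
#'
#' @param mesh a [volume_mesh()].
#' @return List with `n_cells`, `min_dihedral_angle` (degrees),
#'   `max_radius_ratio` (circumradius over three times the inradius; 1 for a
#'   regular tetrahedron), and `n_boundary_facets_per_tag`.
#' @export
mesh_quality <- function(mesh) {
  v <- mesh$vertices; tt <- mesh$tets
  p0 <- v[tt[, 1L], , drop = FALSE]
  a <- v[tt[, 2L], , drop = FALSE] - p0
  b <- v[tt[, 3L], , drop = FALSE] - p0
  c <- v[tt[, 4L], , drop = FALSE] - p0
  cr <- function(x, y) cbind(x[, 2L] * y[, 3L] - x[, 3L] * y[, 2L],
                             x[, 3L] * y[, 1L] - x[, 1L] * y[, 3L],
                             x[, 1L] * y[, 2L] - x[, 2L] * y[, 1L])
  vol6 <- rowSums(a * cr(b, c))
  # circumradius
  num <- rowSums(a^2) * cr(b, c) + rowSums(b^2) * cr(c, a) +
    rowSums(c^2) * cr(a, b)
  circ <- sqrt(rowSums(num^2)) / (2 * abs(vol6))
  # inradius = 3V / total face area
  fa <- (sqrt(rowSums(cr(a, b)^2)) + sqrt(rowSums(cr(b, c)^2)) +
           sqrt(rowSums(cr(c, a)^2)) +
           sqrt(rowSums(cr(b - a, c - a)^2))) / 2
  inr <- (abs(vol6) / 6) * 3 / fa
  # dihedral angles: between outward face normals
  n1 <- cr(b, a); n2 <- cr(a, c); n3 <- cr(c, b)  # faces at p0
  n4 <- cr(c - a, b - a)                          # opposite face
  norm <- function(x) x / sqrt(rowSums(x^2))
  n1 <- norm(n1); n2 <- norm(n2); n3 <- norm(n3); n4 <- norm(n4)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ns <- list(n1, n2, n3, n4)
  dmin <- rep(Inf, nrow(tt))
  for (p in pairs) {
    cosd <- rowSums(ns[[p[1L]]] * ns[[p[2L]]])
    ang <- pi - acos(pmin(pmax(cosd, -1), 1))
    dmin <- pmin(dmin, ang)
  }
  list(n_cells = nrow(tt),
       min_dihedral_angle = min(dmin) * 180 / pi,
       max_radius_ratio = max(circ / (3 * inr)),
       n_boundary_facets_per_tag =
         vapply(split(seq_along(mesh$boundary_tags), mesh$boundary_tags),
                length, integer(1)))
}

# ---------------------------------------------------------------------------
# VTU / legacy VTK output

#' Write a mesh (and optional fields) as an ascii VTU file
#'
#' @param mesh a [volume_mesh()].
#' @param path output `.vtu` path.
#' @param point_data named list of per-vertex numeric vectors (scalars) or
#'   3-column matrices (vectors), e.g. `list(pressure = P, velocity = U)`.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  nv <- nrow(mesh$vertices); nc <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc)
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d) && ncol(d) == 3L) {
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
        writeLines(paste(apply(d, 1, function(r)
          paste(formatC(r, format = "g", digits = 9), collapse = " ")),
          collapse = "\n"), con)
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(paste(formatC(d, format = "g", digits = 9),
                         collapse = " "), con)
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(t(mesh$vertices), collapse = " "), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(t(mesh$tets - 1L), collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nc) * 4L, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, nc), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
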