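# Low-level geometric primitives shared by the phantom generator and the
# volume mesher: structured disk triangulations, surfaces of revolution,
# prism-to-tetrahedron splitting and planar cross-section slicing.
# All coordinates are SI metres.

#' @keywords internal
#' @noRd
.area_preserving_factor <- function(n) {
  # A regular n-gon inscribed in a circle of radius R has area
  # (n/2) R^2 sin(2*pi/n) < pi R^2.  Scaling vertex radii by this factor
  # makes the discrete cross-section area equal to that of the circle,
  # removing the leading geometric bias in pressure-drop estimates.
  th <- 2 * pi / n
  sqrt(th / sin(th))
}

# Triangulated unit disk: centre vertex + nr concentric rings, ring i holding
# 6*i vertices.  `grading` > 1 concentrates rings towards the rim (near-wall
# refinement); rim vertices sit exactly at radius 1.
#' @keywords internal
#' @noRd
disk_template <- function(nr, grading = 1) {
  stopifnot(nr >= 1, grading > 0)
  t <- seq_len(nr) / nr
  s <- 1 - (1 - t)^grading
  s[nr] <- 1
  xy <- matrix(0, 1, 2)
  ring_of <- 0L
  ring_idx <- vector("list", nr + 1L)
  ring_idx[[1L]] <- 1L
  for (i in seq_len(nr)) {
    m <- 6L * i
    th <- 2 * pi * (seq_len(m) - 1L) / m
    xy <- rbind(xy, cbind(s[i] * cos(th), s[i] * sin(th)))
    ring_idx[[i + 1L]] <- (nrow(xy) - m + 1L):nrow(xy)
    ring_of <- c(ring_of, rep.int(i, m))
  }
  tri <- matrix(0L, 0, 3)
  # centre fan
  r1 <- ring_idx[[2L]]
  tri <- rbind(tri, cbind(1L, r1, c(r1[-1L], r1[1L])))
  # annuli: two-pointer merge by angle
  for (i in 2:max(2L, nr)) {
    if (i > nr) break
    inner <- ring_idx[[i]]
    outer <- ring_idx[[i + 1L]]
    tri <- rbind(tri, .merge_rings(xy, inner, outer))
  }
  # enforce counter-clockwise orientation (positive signed area)
  a <- xy[tri[, 1L], ]; b <- xy[tri[, 2L], ]; c <- xy[tri[, 3L], ]
  det2 <- (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  flip <- det2 < 0
  if (any(flip)) tri[flip, c(2L, 3L)] <- tri[flip, c(3L, 2L)]
  list(xy = xy, tri = tri, rim = ring_idx[[nr + 1L]], ring_of = ring_of)
}

#' @keywords internal
#' @noRd
.merge_rings <- function(xy, inner, outer) {
  ang <- function(id) {
    a <- atan2(xy[id, 2L], xy[id, 1L])
    a[a < -1e-12] <- a[a < -1e-12] + 2 * pi
    a
  }
  na <- length(inner); nb <- length(outer)
  a_ang <- c(ang(inner), ang(inner)[1L] + 2 * pi)
  b_ang <- c(ang(outer), ang(outer)[1L] + 2 * pi)
  a_id <- c(inner, inner[1L])
  b_id <- c(outer, outer[1L])
  ia <- 1L; ib <- 1L
  tri <- matrix(0L, na + nb, 3)
  k <- 0L
  while (ia <= na || ib <= nb) {
    adv_b <- ib <= nb && (ia > na || b_ang[ib + 1L] <= a_ang[ia + 1L])
    k <- k + 1L
    if (adv_b) {
      tri[k, ] <- c(b_id[ib], b_id[ib + 1L], a_id[ia])
      ib <- ib + 1L
    } else {
      tri[k, ] <- c(a_id[ia], b_id[ib], a_id[ia + 1L])
      ia <- ia + 1L
    }
  }
  tri[seq_len(k), , drop = FALSE]
}

# Split the triangular prisms of an extruded layer into tetrahedra using the
# minimum-global-vertex diagonal rule, which guarantees conforming diagonals
# between neighbouring prisms (Dompierre-style decomposition).
# `bot`, `top`: nt x 3 integer matrices of global vertex ids (columns aligned).
#' @keywords internal
#' @noRd
split_prisms <- function(bot, top) {
  v <- cbind(bot, top)               # local order 1,2,3 bottom; 4,5,6 top
  n <- nrow(v)
  # the 6 orientation-preserving symmetries of the prism, as permutations
  perms <- rbind(
    c(1L, 2L, 3L, 4L, 5L, 6L),
    c(2L, 3L, 1L, 5L, 6L, 4L),
    c(3L, 1L, 2L, 6L, 4L, 5L),
    c(4L, 6L, 5L, 1L, 3L, 2L),
    c(5L, 4L, 6L, 2L, 1L, 3L),
    c(6L, 5L, 4L, 3L, 2L, 1L)
  )
  amin <- max.col(-matrix(v, n, 6L), ties.method = "first")
  w <- matrix(0L, n, 6L)
  for (p in 1:6) {
    sel <- perms[p, 1L] == amin
    if (any(sel)) w[sel, ] <- v[sel, perms[p, ], drop = FALSE]
  }
  caseA <- pmin(w[, 2L], w[, 6L]) < pmin(w[, 3L], w[, 5L])
  tets <- matrix(0L, 3L * n, 4L)
  ia <- which(caseA); ib <- which(!caseA)
  if (length(ia)) {
    tets[3L * (ia - 1L) + 1L, ] <- w[ia, c(1L, 2L, 3L, 6L), drop = FALSE]
    tets[3L * (ia - 1L) + 2L, ] <- w[ia, c(1L, 2L, 6L, 5L), drop = FALSE]
    tets[3L * (ia - 1L) + 3L, ] <- w[ia, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  if (length(ib)) {
    tets[3L * (ib - 1L) + 1L, ] <- w[ib, c(1L, 2L, 3L, 5L), drop = FALSE]
    tets[3L * (ib - 1L) + 2L, ] <- w[ib, c(1L, 3L, 6L, 5L), drop = FALSE]
    tets[3L * (ib - 1L) + 3L, ] <- w[ib, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  tets
}

#' @keywords internal
#' @noRd
tet_signed_volume <- function(vertices, tets) {
  a <- vertices[tets[, 1L], , drop = FALSE]
  b <- vertices[tets[, 2L], , drop = FALSE] - a
  c <- vertices[tets[, 3L], , drop = FALSE] - a
  d <- vertices[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c[, 2L] * d[, 3L] - c[, 3L] * d[, 2L]) -
     b[, 2L] * (c[, 1L] * d[, 3L] - c[, 3L] * d[, 1L]) +
     b[, 3L] * (c[, 1L] * d[, 2L] - c[, 2L] * d[, 1L])) / 6
}

#' @keywords internal
#' @noRd
orient_tets_positive <- function(vertices, tets) {
  v <- tet_signed_volume(vertices, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  tets
}

#' @keywords internal
#' @noRd
triangle_normals <- function(vertices, tri, normalize = TRUE) {
  a <- vertices[tri[, 1L], , drop = FALSE]
  b <- vertices[tri[, 2L], , drop = FALSE] - a
  c <- vertices[tri[, 3L], , drop = FALSE] - a
  n <- cbind(b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L],
             b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L],
             b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' @keywords internal
#' @noRd
triangle_areas <- function(vertices, tri) {
  sqrt(rowSums(triangle_normals(vertices, tri, normalize = FALSE)^2)) / 2
}

#' @keywords internal
#' @noRd
triangle_centroids <- function(vertices, tri) {
  (vertices[tri[, 1L], , drop = FALSE] +
     vertices[tri[, 2L], , drop = FALSE] +
     vertices[tri[, 3L], , drop = FALSE]) / 3
}

# Signed volume enclosed by an oriented triangulated surface
# (positive when consistently outward-oriented).
#' @keywords internal
#' @noRd
surface_enclosed_volume <- function(vertices, tri) {
  a <- vertices[tri[, 1L], , drop = FALSE]
  b <- vertices[tri[, 2L], , drop = FALSE]
  c <- vertices[tri[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
        a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
        a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

# Cross-section area of a closed, outward-oriented surface cut by the plane
# {axis coordinate == t0}, where `t` holds the per-vertex axial coordinate and
# `uv` the two in-plane coordinates.  The intersection segments of each
# triangle are oriented from the triangle orientation, so the area follows
# from the shoelace sum without any polygon chaining.
#' @keywords internal
#' @noRd
slice_section_area <- function(uv, t, tri, t0) {
  s <- t - t0
  s1 <- s[tri[, 1L]]; s2 <- s[tri[, 2L]]; s3 <- s[tri[, 3L]]
  cross <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(cross)) return(0)
  tr <- tri[cross, , drop = FALSE]
  sv <- cbind(s1[cross], s2[cross], s3[cross])
  area2 <- 0
  # edges of the triangle in cyclic order
  eidx <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  pts <- vector("list", 3L)
  hit <- matrix(FALSE, nrow(tr), 3L)
  for (e in 1:3) {
    i <- eidx[e, 1L]; j <- eidx[e, 2L]
    si <- sv[, i]; sj <- sv[, j]
    h <- (si > 0 & sj < 0) | (si < 0 & sj > 0)
    hit[, e] <- h
    w <- si / (si - sj)
    p <- uv[tr[, i], , drop = FALSE] * (1 - w) +
      uv[tr[, j], , drop = FALSE] * w
    # orient crossing: edge goes from positive side to negative side?
    pts[[e]] <- list(p = p, down = si > 0)
  }
  # For each crossed triangle exactly two edges are hit (vertices assumed off
  # the plane).  The oriented segment runs from the "entering" crossing
  # (edge going - to +) to the "leaving" crossing (+ to -) following the
  # triangle's orientation; this inherits a consistent curve orientation from
  # the surface orientation.
  n <- nrow(tr)
  p_from <- matrix(NA_real_, n, 2L)
  p_to <- matrix(NA_real_, n, 2L)
  for (e in 1:3) {
    h <- hit[, e]
    if (!any(h)) next
    dn <- pts[[e]]$down
    sel_to <- h & dn      # + -> - : leaving the positive side
    sel_from <- h & !dn   # - -> + : entering
    p_to[sel_to, ] <- pts[[e]]$p[sel_to, , drop = FALSE]
    p_from[sel_from, ] <- pts[[e]]$p[sel_from, , drop = FALSE]
  }
  ok <- !is.na(p_from[, 1L]) & !is.na(p_to[, 1L])
  area2 <- sum(p_from[ok, 1L] * p_to[ok, 2L] - p_to[ok, 1L] * p_from[ok, 2L])
  # The sign convention depends on which in-plane frame is used; callers only
  # need the magnitude of the enclosed area.
  abs(area2) / 2
}

# Build a closed, tagged surface of revolution around the z axis from axial
# stations `z` with radii `r` (> 0), with flat end caps.  Returns the pieces
# used by surface_mesh().
#' @keywords internal
#' @noRd
revolve_closed_surface <- function(z, r, n_theta,
                                   inlet_tag = "INLET", outlet_tag = "OUTLET",
                                   theta_jitter = 0) {
  stopifnot(length(z) == length(r), all(r > 0), n_theta >= 8)
  m <- length(z)
  kappa <- .area_preserving_factor(n_theta)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  nv_ring <- n_theta
  verts <- matrix(0, m * nv_ring + 2L, 3L)
  for (j in seq_len(m)) {
    idx <- (j - 1L) * nv_ring + seq_len(nv_ring)
    verts[idx, ] <- cbind(kappa * r[j] * cos(th), kappa * r[j] * sin(th), z[j])
  }
  c_in <- m * nv_ring + 1L
  c_out <- m * nv_ring + 2L
  verts[c_in, ] <- c(0, 0, z[1L])
  verts[c_out, ] <- c(0, 0, z[m])
  ring <- function(j) (j - 1L) * nv_ring + seq_len(nv_ring)
  nxt <- c(seq_len(nv_ring)[-1L], 1L)
  tri <- matrix(0L, 0, 3)
  tags <- character(0)
  # lateral wall: quads split along a consistent diagonal
  for (j in seq_len(m - 1L)) {
    a <- ring(j); b <- ring(j + 1L)
    t1 <- cbind(a, b[nxt], b)
    t2 <- cbind(a, a[nxt], b[nxt])
    tri <- rbind(tri, t1, t2)
    tags <- c(tags, rep.int("WALL", 2L * nv_ring))
  }
  # inlet cap (normal -z)
  a <- ring(1L)
  tri <- rbind(tri, cbind(c_in, a[nxt], a))
  tags <- c(tags, rep.int(inlet_tag, nv_ring))
  # outlet cap (normal +z)
  b <- ring(m)
  tri <- rbind(tri, cbind(c_out, b, b[nxt]))
  tags <- c(tags, rep.int(outlet_tag, nv_ring))
  # fix global orientation so the enclosed volume is positive
  vol <- surface_enclosed_volume(verts, tri)
  if (vol < 0) tri[, c(2L, 3L)] <- tri[, c(3L, 2L)]
  # lateral triangles may individually disagree; check radial direction
  nrm <- triangle_normals(verts, tri)
  cen <- triangle_centroids(verts, tri)
  rad <- cbind(cen[, 1L], cen[, 2L], 0)
  rl <- sqrt(rowSums(rad^2)); rl[rl == 0] <- 1
  is_wall <- tags == "WALL"
  bad <- is_wall & rowSums(nrm * rad / rl) < 0
  if (any(bad)) tri[bad, c(2L, 3L)] <- tri[bad, c(3L, 2L)]
  list(vertices = verts, triangles = tri, tags = tags)
}
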