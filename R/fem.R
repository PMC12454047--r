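# Internal finite-element layer: Taylor-Hood (P2 velocity, P1 pressure)
# operator assembly, boundary-condition construction and Krylov solvers.
# Velocity scalar dofs are numbered vertices first (1..nv) then edge
# midpoints (nv+1..nv+ne); pressure dofs live on vertices.

#' @keywords internal
#' @noRd
fem_operators <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$ops)) return(cache$ops)
  ed <- fem_build_edges(mesh$tets)
  nv <- nrow(mesh$vertices)
  ne <- nrow(ed$edges)
  ns <- nv + ne
  asm <- fem_assemble_stokes(mesh$vertices, mesh$tets, ed$tet_edges)
  A <- Matrix::sparseMatrix(i = asm$ai, j = asm$aj, x = asm$ax,
                            dims = c(ns, ns))
  Bx <- Matrix::sparseMatrix(i = asm$bi, j = asm$bj, x = asm$bx,
                             dims = c(nv, ns))
  By <- Matrix::sparseMatrix(i = asm$bi, j = asm$bj, x = asm$by,
                             dims = c(nv, ns))
  Bz <- Matrix::sparseMatrix(i = asm$bi, j = asm$bj, x = asm$bz,
                             dims = c(nv, ns))
  p2_xyz <- rbind(mesh$vertices,
                  (mesh$vertices[ed$edges[, 1L], , drop = FALSE] +
                     mesh$vertices[ed$edges[, 2L], , drop = FALSE]) / 2)
  # boundary facet -> P2 dofs (3 vertices + 3 edge midpoints)
  f <- mesh$boundary_facets
  keymat <- Matrix::sparseMatrix(i = ed$edges[, 1L], j = ed$edges[, 2L],
                                 x = seq_len(ne), dims = c(nv, nv))
  eid <- function(a, b) as.integer(keymat[cbind(pmin(a, b), pmax(a, b))])
  fedge <- cbind(eid(f[, 1L], f[, 2L]), eid(f[, 2L], f[, 3L]),
                 eid(f[, 3L], f[, 1L]))
  if (any(fedge == 0L)) stop("internal error: boundary facet edge not found")
  ops <- list(nv = nv, ne = ne, ns = ns,
              edges = ed$edges, tet_edges = ed$tet_edges,
              A = A, B = list(Bx, By, Bz), mp = asm$mp,
              p2_xyz = p2_xyz,
              facet_vdof = f, facet_edof = nv + fedge,
              facet_normal = triangle_normals(mesh$vertices, f),
              facet_area = triangle_areas(mesh$vertices, f),
              facet_tag = mesh$boundary_tags)
  cache$ops <- ops
  ops
}

# P2 dofs lying on facets selected by `sel`
#' @keywords internal
#' @noRd
.facet_dofs <- function(ops, sel) {
  unique(c(as.vector(ops$facet_vdof[sel, , drop = FALSE]),
           as.vector(ops$facet_edof[sel, , drop = FALSE])))
}

# Exact (for P2) boundary flux over selected facets: the three-midpoint rule
# on each facet, using the edge-midpoint dofs directly.
#' @keywords internal
#' @noRd
.facet_flux <- function(ops, U, sel) {
  ed <- ops$facet_edof[sel, , drop = FALSE]
  n <- ops$facet_normal[sel, , drop = FALSE]
  a <- ops$facet_area[sel]
  un <- U[ed[, 1L], , drop = FALSE] + U[ed[, 2L], , drop = FALSE] +
    U[ed[, 3L], , drop = FALSE]
  sum(a / 3 * rowSums(un * n))
}

# Dirichlet data for a flow case: no-slip on WALL, plug inflow on each inlet
# patch scaled so each patch carries its exact flux share of Q.
#' @keywords internal
#' @noRd
.build_dirichlet <- function(mesh, ops, case) {
  tags <- ops$facet_tag
  if (!any(tags == case$outlet_tag))
    stop("no boundary facets tagged '", case$outlet_tag,
         "': outlet pressure datum undetermined (pressure would be ",
         "defined only up to a constant)")
  inlet_tags <- case$inlet_tags
  missing_in <- setdiff(inlet_tags, unique(tags))
  if (length(missing_in))
    stop("no boundary facets tagged '", paste(missing_in, collapse = "', '"),
         "': inflow cannot be imposed")
  wall_dofs <- .facet_dofs(ops, tags == "WALL")
  g <- matrix(0, ops$ns, 3L)
  shares <- case$flux_shares
  if (is.null(shares)) {
    ar <- vapply(inlet_tags, function(tg) sum(ops$facet_area[tags == tg]),
                 numeric(1))
    shares <- ar / sum(ar)
  }
  if (abs(sum(shares) - 1) > 1e-9)
    stop("inlet flux shares must sum to 1")
  inlet_dofs_all <- integer(0)
  for (k in seq_along(inlet_tags)) {
    sel <- tags == inlet_tags[k]
    dofs <- .facet_dofs(ops, sel)
    # area-weighted average inward normal per dof
    fsel <- which(sel)
    ids <- c(as.vector(ops$facet_vdof[fsel, , drop = FALSE]),
             as.vector(ops$facet_edof[fsel, , drop = FALSE]))
    wts <- rep(ops$facet_area[fsel], 6L)
    nr6 <- ops$facet_normal[rep(fsel, 6L), , drop = FALSE] * wts
    acc <- rowsum(nr6, ids)
    acc_id <- as.integer(rownames(acc))
    len <- sqrt(rowSums(acc^2))
    ok <- len > 0
    gk <- matrix(0, ops$ns, 3L)
    gk[acc_id[ok], ] <- -acc[ok, , drop = FALSE] / len[ok]  # inward unit plug
    gk[wall_dofs, ] <- 0                             # rim no-slip wins
    flux <- .facet_flux(ops, gk, sel)                # negative (inward)
    if (abs(flux) < .Machine$double.eps)
      stop("inlet patch '", inlet_tags[k],
           "' has zero admissible inflow area (entirely on the wall rim?)")
    gk <- gk * (-shares[k] * case$flow_rate / flux)
    g <- g + gk
    inlet_dofs_all <- c(inlet_dofs_all, dofs)
  }
  dir_dofs <- sort(unique(c(wall_dofs, inlet_dofs_all)))
  list(dofs = dir_dofs, values = g[dir_dofs, , drop = FALSE],
       g_full = g, wall_dofs = wall_dofs)
}

# Preconditioned conjugate gradient on the pressure Schur complement.
#' @keywords internal
#' @noRd
.schur_cg <- function(apply_S, rhs, precond, tol = 1e-13, maxit = 500L) {
  p <- numeric(length(rhs))
  r <- rhs
  z <- precond(r)
  d <- z
  rz <- sum(r * z)
  rhs_norm <- sqrt(sum(rhs * precond(rhs)))
  if (rhs_norm == 0) return(list(x = p, iter = 0L, rel = 0))
  best_rel <- Inf
  for (it in seq_len(maxit)) {
    Sd <- apply_S(d)
    alpha <- rz / sum(d * Sd)
    p <- p + alpha * d
    r <- r - alpha * Sd
    z <- precond(r)
    rz_new <- sum(r * z)
    rel <- sqrt(abs(rz_new)) / rhs_norm
    if (rel < best_rel) best_rel <- rel
    if (rel <= tol) return(list(x = p, iter = it, rel = rel))
    if (it > 50L && rel > 1e3 * best_rel) break  # stagnation/divergence
    beta <- rz_new / rz
    rz <- rz_new
    d <- z + beta * d
  }
  list(x = p, iter = maxit, rel = sqrt(abs(sum(r * precond(r)))) / rhs_norm)
}

# BiCGSTAB for the (mildly nonsymmetric) Navier-Stokes pressure Schur
# complement.
#' @keywords internal
#' @noRd
.schur_bicgstab <- function(apply_S, rhs, precond, tol = 1e-12,
                            maxit = 400L) {
  n <- length(rhs)
  x <- numeric(n)
  r <- rhs
  rhat <- r
  rho <- 1; alpha <- 1; omega <- 1
  v <- numeric(n); p <- numeric(n)
  nb <- sqrt(sum(rhs^2))
  if (nb == 0) return(list(x = x, iter = 0L, rel = 0))
  for (it in seq_len(maxit)) {
    rho_new <- sum(rhat * r)
    if (abs(rho_new) < 1e-300) break
    beta <- (rho_new / rho) * (alpha / omega)
    rho <- rho_new
    p <- r + beta * (p - omega * v)
    phat <- precond(p)
    v <- apply_S(phat)
    alpha <- rho / sum(rhat * v)
    s <- r - alpha * v
    x <- x + alpha * phat
    if (sqrt(sum(s^2)) / nb <= tol) {
      return(list(x = x, iter = it, rel = sqrt(sum(s^2)) / nb))
    }
    shat <- precond(s)
    t <- apply_S(shat)
    omega <- sum(t * s) / sum(t * t)
    x <- x + omega * shat
    r <- s - omega * t
    if (sqrt(sum(r^2)) / nb <= tol)
      return(list(x = x, iter = it, rel = sqrt(sum(r^2)) / nb))
  }
  list(x = x, iter = maxit, rel = sqrt(sum(r^2)) / nb)
}

# Cached Cholesky factorisation of the free-dof scalar stiffness block.
#' @keywords internal
#' @noRd
.stiffness_factor <- function(mesh, ops, free) {
  cache <- mesh$cache
  if (!is.null(cache$fact) && identical(cache$fact_free, free))
    return(cache$fact)
  Aff <- ops$A[free, free]
  fact <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE,
                           super = TRUE)
  cache$fact <- fact
  cache$fact_free <- free
  fact
}
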