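# Tagged triangulated surface meshes: the exchange currency between
# segmentation output (STL/OFF/PLY), the phantom generator and the volume
# mesher.  Vertices are in metres; triangles are 1-based vertex index
# triplets; every triangle carries one boundary tag (INLET*, OUTLET, WALL).

#' Construct a tagged surface mesh
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in metres.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices,
#'   consistently outward-oriented.
#' @param tags character vector of length m with one boundary tag per
#'   triangle; tags must be `"WALL"`, `"OUTLET"` or start with `"INLET"`.
#'   Defaults to all-`"WALL"` (use [tag_boundaries()] to assign patches).
#' @param validate check watertightness and orientation (default `TRUE`).
#'
#' @return An object of class `pelviflow_surface`.
#' @seealso [make_phantom()], [read_surface()], [tag_boundaries()]
#' @export
surface_mesh <- function(vertices, triangles, tags = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (is.null(tags)) tags <- rep.int("WALL", nrow(triangles))
  tags <- as.character(tags)
  if (length(tags) != nrow(triangles))
    stop("tags must have one entry per triangle")
  bad <- !(tags %in% c("WALL", "OUTLET") | startsWith(tags, "INLET"))
  if (any(bad))
    stop("unknown boundary tags: ", paste(unique(tags[bad]), collapse = ", "))
  out <- structure(list(vertices = vertices, triangles = triangles,
                        tags = tags),
                   class = "pelviflow_surface")
  if (validate) {
    chk <- surface_topology(out)
    if (!chk$watertight)
      stop("surface is not watertight: ", chk$n_open_edges,
           " open edge(s); see surface_topology() for details")
    if (!chk$oriented)
      stop("surface triangles are not consistently oriented")
  }
  out
}

#' Topological audit of a surface mesh
#'
#' Reports watertightness (every undirected edge shared by exactly two
#' triangles), orientation consistency (every directed edge used exactly
#' once), the Euler characteristic and the signed enclosed volume.
#'
#' @param surface a [surface_mesh()] object.
#' @return A list with elements `watertight`, `oriented`, `n_vertices`,
#'   `n_edges`, `n_triangles`, `euler_characteristic`, `enclosed_volume`
#'   (m^3, positive for outward orientation), `n_open_edges` and
#'   `open_edges` (k x 2 matrix of vertex index pairs).
#' @export
surface_topology <- function(surface) {
  tri <- surface$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi)
  cnt <- table(key)
  open <- names(cnt)[cnt != 2L]
  dir_key <- paste(e[, 1L], e[, 2L])
  oriented <- !anyDuplicated(dir_key) && length(open) == 0L
  used <- sort(unique(as.vector(tri)))
  nv <- length(used)
  ne <- length(cnt)
  nf <- nrow(tri)
  open_mat <- if (length(open)) {
    do.call(rbind, lapply(strsplit(open, " "), as.integer))
  } else matrix(integer(0), 0, 2)
  list(watertight = length(open) == 0L,
       oriented = oriented,
       n_vertices = nv, n_edges = ne, n_triangles = nf,
       euler_characteristic = nv - ne + nf,
       enclosed_volume = surface_enclosed_volume(surface$vertices, tri),
       n_open_edges = length(open), open_edges = open_mat)
}

#' Enclosed volume of a watertight surface
#'
#' @param surface a [surface_mesh()] object.
#' @return Volume in m^3 (positive for outward orientation).
#' @export
surface_volume <- function(surface) {
  surface_enclosed_volume(surface$vertices, surface$triangles)
}

#' Per-tag facet areas of a surface
#'
#' @param surface a [surface_mesh()] object.
#' @return Named numeric vector of total facet area (m^2) per tag.
#' @export
surface_tag_areas <- function(surface) {
  ar <- triangle_areas(surface$vertices, surface$triangles)
  vapply(split(ar, surface$tags), sum, numeric(1))
}

#' @export
print.pelviflow_surface <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat("Tagged surface mesh (pelviflow_surface)\n")
  cat(sprintf("  vertices: %d   triangles: %d\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  bounding box [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1] * 1e3, bb[2, 1] * 1e3, bb[1, 2] * 1e3,
              bb[2, 2] * 1e3, bb[1, 3] * 1e3, bb[2, 3] * 1e3))
  tb <- table(x$tags)
  cat("  tags:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pelviflow_surface <- function(object, ...) {
  top <- surface_topology(object)
  out <- c(top[c("n_vertices", "n_edges", "n_triangles",
                 "euler_characteristic", "watertight", "oriented")],
           list(enclosed_volume_m3 = top$enclosed_volume,
                tag_areas_m2 = surface_tag_areas(object)))
  class(out) <- "summary.pelviflow_surface"
  out
}

#' @export
print.summary.pelviflow_surface <- function(x, ...) {
  cat("Surface: V =", x$n_vertices, " E =", x$n_edges, " F =",
      x$n_triangles, " (Euler", x$euler_characteristic, ")\n")
  cat("  watertight:", x$watertight, "  oriented:", x$oriented, "\n")
  cat(sprintf("  enclosed volume: %.4g mL\n", x$enclosed_volume_m3 * 1e6))
  cat("  tag areas [mm^2]:",
      paste(sprintf("%s %.2f", names(x$tag_areas_m2), x$tag_areas_m2 * 1e6),
            collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# repair helpers

#' @keywords internal
#' @noRd
.merge_duplicate_vertices <- function(vertices, triangles, tol) {
  key <- paste(round(vertices[, 1L] / tol), round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_verts <- vertices[first, , drop = FALSE]
  new_tri <- matrix(map[triangles], ncol = 3L)
  degen <- new_tri[, 1L] == new_tri[, 2L] | new_tri[, 2L] == new_tri[, 3L] |
    new_tri[, 1L] == new_tri[, 3L]
  list(vertices = new_verts, triangles = new_tri[!degen, , drop = FALSE],
       kept = !degen)
}

# Make triangle orientations mutually consistent by breadth-first propagation
# over the edge-adjacency graph, then fix the global sign so the enclosed
# volume is positive.
#' @keywords internal
#' @noRd
.orient_consistently <- function(vertices, triangles) {
  m <- nrow(triangles)
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(3L, 1L)])
  face_of <- rep(seq_len(m), 3L)
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi)
  ord <- order(key)
  key_s <- key[ord]; face_s <- face_of[ord]
  dir_s <- (e[, 1L] < e[, 2L])[ord]   # TRUE if stored low->high
  grp_start <- which(!duplicated(key_s))
  grp_size <- diff(c(grp_start, length(key_s) + 1L))
  two <- grp_size == 2L
  i1 <- grp_start[two]; i2 <- i1 + 1L
  fa <- face_s[i1]; fb <- face_s[i2]
  same_dir <- dir_s[i1] == dir_s[i2]   # same direction => inconsistent pair
  adj <- data.frame(a = fa, b = fb, flip_rel = same_dir)
  nb <- split(rep(seq_len(nrow(adj)), 2L), c(adj$a, adj$b))
  flipped <- rep(NA, m)
  for (seed in seq_len(m)) {
    if (!is.na(flipped[seed])) next
    flipped[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1L]]; queue <- queue[-1L]
      rows <- nb[[as.character(f)]]
      if (is.null(rows)) next
      for (rr in rows) {
        g <- if (adj$a[rr] == f) adj$b[rr] else adj$a[rr]
        want <- xor(flipped[f], adj$flip_rel[rr])
        if (is.na(flipped[g])) {
          flipped[g] <- want
          queue <- c(queue, g)
        }
      }
    }
  }
  flipped[is.na(flipped)] <- FALSE
  triangles[flipped, c(2L, 3L)] <- triangles[flipped, c(3L, 2L)]
  if (surface_enclosed_volume(vertices, triangles) < 0)
    triangles[, c(2L, 3L)] <- triangles[, c(3L, 2L)]
  triangles
}

# ---------------------------------------------------------------------------
# file I/O

#' Read a triangulated surface from STL, OFF or PLY
#'
#' Reads the file, rescales vertices into metres, merges duplicate vertices,
#' fixes the orientation to outward, and verifies watertightness.
#'
#' @param path path to an STL (ascii or binary), OFF, or ascii PLY file.
#' @param unit_scale factor applied to vertex coordinates to convert them to
#'   metres (e.g. `1e-3` for a file written in millimetres). Default 1.
#' @param merge_tol vertex-merge tolerance relative to the bounding-box
#'   diagonal (default `1e-6`).
#' @return A [surface_mesh()] with all facets tagged `WALL`
#'   (use [tag_boundaries()] to assign inlet/outlet patches).
#' @export
read_surface <- function(path, unit_scale = 1, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(unit_scale) || unit_scale <= 0)
    stop("unit_scale must be a positive number")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                stl = .read_stl(path),
                off = .read_off(path),
                ply = .read_ply(path),
                stop("unsupported surface format: .", ext,
                     " (expected stl, off or ply)"))
  v <- raw$vertices * unit_scale
  diag_len <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  mrg <- .merge_duplicate_vertices(v, raw$triangles,
                                   tol = max(merge_tol * diag_len,
                                             .Machine$double.xmin))
  tri <- .orient_consistently(mrg$vertices, mrg$triangles)
  out <- surface_mesh(mrg$vertices, tri, validate = FALSE)
  chk <- surface_topology(out)
  if (!chk$watertight)
    stop("surface is not watertight after vertex-merge repair: ",
         chk$n_open_edges, " open edge(s) at vertex pairs ",
         paste(apply(chk$open_edges, 1, paste, collapse = "-"),
               collapse = ", "))
  out
}

#' Write a surface mesh to STL (binary), OFF or PLY
#'
#' @param surface a [surface_mesh()] object.
#' @param path output path; the format is chosen from the extension
#'   (`.stl` binary, `.off`, `.ply` ascii).
#' @param unit_scale factor applied to coordinates before writing
#'   (default 1, i.e. metres).
#' @return `path`, invisibly. Facet tags are preserved for OFF/PLY via a
#'   comment-free integer facet attribute only in PLY; STL carries geometry
#'   only.
#' @export
write_surface <- function(surface, path, unit_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  v <- surface$vertices * unit_scale
  switch(ext,
         stl = .write_stl_binary(v, surface$triangles, path),
         off = .write_off(v, surface$triangles, path),
         ply = .write_ply(v, surface$triangles, surface$tags, path),
         stop("unsupported surface format: .", ext))
  invisible(path)
}

#' @keywords internal
#' @noRd
.read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    rec <- readBin(con, "raw", 50L * ntri)
    m <- matrix(rec, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                  n = 12L * ntri, endian = "little")
    fl <- matrix(fl, ncol = 12L, byrow = TRUE)
    verts <- rbind(fl[, 4:6, drop = FALSE], fl[, 7:9, drop = FALSE],
                   fl[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) stop("no vertices found in ascii STL: ", path)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    verts <- nums
  }
  if (nrow(verts) %% 3L != 0L) stop("malformed STL: ", path)
  ntri <- nrow(verts) / 3L
  tri <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, triangles = tri)
}

#' @keywords internal
#' @noRd
.write_stl_binary <- function(v, tri, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
  n <- triangle_normals(v, tri)
  for (i in seq_len(nrow(tri))) {
    writeBin(as.numeric(c(n[i, ], t(v[tri[i, ], ]))), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
.read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (toupper(trimws(txt[1L])) != "OFF") stop("not an OFF file: ", path)
  hdr <- as.integer(strsplit(trimws(txt[2L]), "\\s+")[[1L]])
  nv <- hdr[1L]; nf <- hdr[2L]
  vl <- txt[3:(2L + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[1:3])))
  fl <- txt[(3L + nv):(2L + nv + nf)]
  faces <- lapply(strsplit(trimws(fl), "\\s+"), as.integer)
  tri <- do.call(rbind, lapply(faces, function(f) {
    k <- f[1L]
    if (k < 3L) stop("degenerate face in OFF file")
    idx <- f[2:(k + 1L)] + 1L
    cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])   # fan-triangulate polygons
  }))
  list(vertices = verts, triangles = tri)
}

#' @keywords internal
#' @noRd
.write_off <- function(v, tri, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(tri)), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1L] - 1L, tri[, 2L] - 1L,
                     tri[, 3L] - 1L), con)
  invisible(path)
}

#' @keywords internal
#' @noRd
.read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (trimws(txt[1L]) != "ply") stop("not a PLY file: ", path)
  if (!any(grepl("format\\s+ascii", txt[1:10])))
    stop("only ascii PLY is supported: ", path)
  endh <- which(trimws(txt) == "end_header")[1L]
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", txt, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", txt, value = TRUE)[1L]))
  vl <- txt[(endh + 1L):(endh + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[1:3])))
  fl <- txt[(endh + nv + 1L):(endh + nv + nf)]
  faces <- lapply(strsplit(trimws(fl), "\\s+"), as.integer)
  tri <- do.call(rbind, lapply(faces, function(f) {
    k <- f[1L]
    idx <- f[2:(k + 1L)] + 1L
    cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
  }))
  list(vertices = verts, triangles = tri)
}

#' @keywords internal
#' @noRd
.write_ply <- function(v, tri, tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tag_levels <- sort(unique(tags))
  tag_id <- match(tags, tag_levels) - 1L
  writeLines(c("ply", "format ascii 1.0",
               paste("comment tag_levels", paste(tag_levels, collapse = " ")),
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tri)),
               "property list uchar int vertex_indices",
               "property int tag",
               "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d %d", tri[, 1L] - 1L, tri[, 2L] - 1L,
                     tri[, 3L] - 1L, tag_id), con)
  invisible(path)
}
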