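#' Triangulated surface meshes
#'
#' A `surface_mesh` holds an n x 3 matrix of vertex coordinates (mm), an
#' m x 3 integer matrix of 1-based vertex indices per triangle (consistent
#' counter-clockwise winding seen from outside, so face normals point
#' outward), and optionally an integer vector `face_labels` assigning each
#' face to a scute.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param face_labels optional integer vector, one label per face.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(face_labels)) {
    face_labels <- as.integer(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("face_labels must have one entry per face")
  }
  structure(list(vertices = vertices, faces = faces, face_labels = face_labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$face_labels)) "" else
                sprintf(" (%d labels)", length(unique(x$face_labels))),
              mesh_area(x)))
  invisible(x)
}

#' Per-face and total triangle areas
#' @param mesh a `surface_mesh`.
#' @return `mesh_face_areas()`: numeric vector of per-face areas (mm^2);
#'   `mesh_area()`: their sum.
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname mesh_face_areas
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_face_areas
#' @export
mesh_face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Unnormalized outward face normals (cross products; length = 2 * area)
#' @param mesh a `surface_mesh`.
#' @return m x 3 matrix.
#' @export
mesh_face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Area-weighted outward vertex normals (unit length)
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)          # already area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (c in 1:3)
      n[, c] <- n[, c] + tapply_add(fn[, c], idx, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Undirected edge list of a triangle mesh
#' @param mesh a `surface_mesh`.
#' @return 2-column integer matrix, one row per undirected edge occurrence
#'   (each face contributes 3 rows); use `unique_edges = TRUE` to deduplicate.
#' @param unique_edges logical.
#' @export
mesh_edges <- function(mesh, unique_edges = FALSE) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (unique_edges) e <- unique(e)
  e
}

#' Closed-manifold check and Euler characteristic
#'
#' A closed manifold triangle mesh has every undirected edge shared by
#' exactly two faces; for a genus-0 surface V - E + F = 2.
#'
#' @param mesh a `surface_mesh`.
#' @return `mesh_is_closed_manifold()`: logical; `mesh_euler()`: integer.
#' @export
mesh_is_closed_manifold <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname mesh_is_closed_manifold
#' @export
mesh_euler <- function(mesh) {
  e <- mesh_edges(mesh, unique_edges = TRUE)
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

#' Face adjacency (faces sharing an edge)
#' @param mesh a `surface_mesh`.
#' @return 2-column integer matrix of adjacent face index pairs.
#' @export
mesh_face_adjacency <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(m), 3L)
  o <- order(key)
  key <- key[o]; fid <- fid[o]
  same <- which(key[-1] == key[-length(key)])
  cbind(fid[same], fid[same + 1L])
}

#' Connected components of a mesh (by shared vertices)
#' @param mesh a `surface_mesh`.
#' @return integer vector, component id per face.
#' @export
mesh_face_components <- function(mesh) {
  adj <- mesh_face_adjacency(mesh)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$faces) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nrow(mesh$faces))]
}

#' Signed volume enclosed by a closed mesh (positive if normals outward)
#' @param mesh a `surface_mesh`.
#' @return scalar volume in mm^3.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

## ---------------------------------------------------------------------------
## Icosphere (subdivided icosahedron): near-uniform triangulation of S^2
## ---------------------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ue <- unique(e)
  key <- function(m) m[, 1] * (nrow(v) + 1) + m[, 2]
  mid_id <- match(key(e), key(ue)) + nrow(v)
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  m <- nrow(f)
  m12 <- mid_id[seq_len(m)]
  m23 <- mid_id[m + seq_len(m)]
  m31 <- mid_id[2 * m + seq_len(m)]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23),
                cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = newf)
}

#' Unit icosphere mesh
#' @param subdivisions number of 4-to-1 subdivision rounds (0 = icosahedron);
#'   level k has `20 * 4^k` faces.
#' @return a `surface_mesh` on the unit sphere, outward normals.
#' @export
icosphere <- function(subdivisions = 4) {
  s <- icosahedron()
  for (i in seq_len(subdivisions)) s <- subdivide_once(s$vertices, s$faces)
  surface_mesh(s$vertices, s$faces)
}

## ---------------------------------------------------------------------------
## PLY / OBJ IO
## ---------------------------------------------------------------------------

#' Write a mesh as ASCII PLY
#'
#' When the mesh carries `face_labels` (or `face_scalar` is given) a per-face
#' property is written; `face_scalar` additionally adds a color ramp so the
#' export reproduces scute-level color-coding in any PLY viewer.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param face_scalar optional numeric per-face scalar to color-code.
#' @export
write_ply <- function(mesh, path, face_scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_lab <- !is.null(mesh$face_labels)
  has_sc <- !is.null(face_scalar)
  hdr <- c("ply", "format ascii 1.0", "comment scutegrow surface export",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           if (has_lab) "property int label",
           if (has_sc) c("property float quality",
                         "property uchar red", "property uchar green",
                         "property uchar blue"),
           "end_header")
  vtxt <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3])
  ftxt <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  if (has_lab) ftxt <- paste(ftxt, mesh$face_labels)
  if (has_sc) {
    rng <- range(face_scalar, finite = TRUE)
    t <- if (diff(rng) > 0) (face_scalar - rng[1]) / diff(rng) else rep(0.5, nf)
    cols <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
    ci <- pmin(256L, pmax(1L, as.integer(t * 255) + 1L))
    ftxt <- paste(ftxt, sprintf("%.9g %d %d %d", face_scalar,
                                cols[1, ci], cols[2, ci], cols[3, ci]))
  }
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}

#' Read an ASCII PLY written by [write_ply()]
#' @param path PLY file path.
#' @return a `surface_mesh` (with `face_labels` if present in the file).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !any(lines == "end_header"))
    stop("not an ASCII PLY file: ", path)
  end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_lab <- any(grepl("^property int label", hdr))
  vlines <- lines[end + seq_len(nv)]
  flines <- lines[end + nv + seq_len(nf)]
  v <- matrix(scan(text = vlines, quiet = TRUE), ncol = 3L, byrow = TRUE)
  ff <- strsplit(flines, " ")
  fmat <- t(vapply(ff, function(x) as.integer(x[2:4]), integer(3))) + 1L
  labs <- if (has_lab) vapply(ff, function(x) as.integer(x[5]), integer(1)) else NULL
  surface_mesh(v, fmat, labs)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  writeLines(c("# scutegrow surface export",
               sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3])), path)
  invisible(path)
}
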