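## Per-scute morphometrics: neighbor counts, voxel volume, plane-based area,
## bounding-cuboid thickness/width, and local Gaussian/mean surface curvature,
## plus the size normalizations used for cross-specimen comparison.

PBA_SENTINEL <- -1000

#' Total carapace surface area
#'
#' Sum of triangle areas of the outer surface mesh, optionally dropping
#' faces whose scute label is excluded (e.g., horns).
#'
#' @param mesh a `surface_mesh`.
#' @param exclude_labels integer labels whose faces are excluded.
#' @return surface area in mm^2.
#' @export
carapace_surface_area <- function(mesh, exclude_labels = NULL) {
  a <- mesh_face_areas(mesh)
  if (!is.null(exclude_labels) && !is.null(mesh$face_labels))
    a <- a[!(mesh$face_labels %in% exclude_labels)]
  sum(a)
}

#' Number of neighbors per scute
#'
#' Node degree on the region adjacency graph, plus the per-specimen relative
#' frequency table of neighbor counts.
#'
#' @param rag a `rag`.
#' @return list with `counts` (named integer vector, one entry per scute)
#'   and `freq` (data frame `n_neighbors`, `n_scutes`, `rel_freq`).
#' @export
neighbor_counts <- function(rag) {
  deg <- rag_degrees(rag)
  t <- table(deg)
  freq <- data.frame(n_neighbors = as.integer(names(t)),
                     n_scutes = as.integer(t),
                     rel_freq = as.numeric(t) / length(deg))
  list(counts = deg, freq = freq)
}

#' Scute volumes from a label field
#'
#' Voxel count per label times the voxel volume.
#'
#' @param labels a `label_field`.
#' @return named numeric vector of volumes (mm^3), names = label ids.
#' @export
scute_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_field"))
  lab <- as.vector(labels$data)
  lab <- lab[lab != 0L]
  t <- table(lab)
  setNames(as.numeric(t) * prod(labels$spacing), names(t))
}

#' Plane-based area (PBA) of a scute
#'
#' Projected in-plane area of a scute computed on the RAG: the scute's
#' neighbors are ordered angularly about the scute center (in the plane
#' orthogonal to the local outward direction); each consecutive neighbor
#' pair contributes one fan node — the centroid of the triangle
#' (scute, n_i, n_j) when the two neighbors are themselves RAG-adjacent, or
#' of the quad (scute, n_i, m, n_j) when a unique common neighbor m (not the
#' scute, not one of its neighbors) bridges them. If any pair yields neither
#' (the scute borders a carapace opening) the fan is incomplete and all
#' plane-based measures are the sentinel `-1000`, removing that scute from
#' the PBA analysis. Otherwise the total-least-squares plane of the fan
#' nodes is translated to contain the scute center, the nodes are projected
#' onto it, ordered by angle about the projected center, and the shoelace
#' area of the polygon is returned.
#'
#' @param rag a `rag` with embedded node centers.
#' @param scute_id label id; if `NULL`, all scutes are measured.
#' @return PBA in mm^2, or exactly `-1000` for border scutes / scutes with
#'   fewer than 3 neighbors. For `scute_id = NULL`, a named vector.
#' @export
plane_based_area <- function(rag, scute_id = NULL) {
  stopifnot(inherits(rag, "rag"))
  centers <- as.matrix(rag$nodes[, c("cx", "cy", "cz")])
  rownames(centers) <- rag$nodes$label
  centroid <- colMeans(centers)
  adj <- adjacency_sets(rag)
  if (is.null(scute_id)) {
    ids <- rag$nodes$label
    return(setNames(vapply(ids, function(s)
      pba_one(s, centers, centroid, adj), numeric(1)), ids))
  }
  pba_one(as.integer(scute_id), centers, centroid, adj)
}

adjacency_sets <- function(rag) {
  ids <- rag$nodes$label
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(rag$edges))) {
    a <- as.character(rag$edges$a[i]); b <- as.character(rag$edges$b[i])
    adj[[a]] <- c(adj[[a]], rag$edges$b[i])
    adj[[b]] <- c(adj[[b]], rag$edges$a[i])
  }
  adj
}

pba_one <- function(s, centers, centroid, adj) {
  skey <- as.character(s)
  nb <- adj[[skey]]
  if (is.null(nb) || length(nb) < 3L) return(PBA_SENTINEL)
  c0 <- centers[skey, ]
  # local outward direction: normal of the TLS plane through the neighbor
  # ring, oriented away from the carapace centroid when that is defined
  rel0 <- sweep(centers[as.character(nb), , drop = FALSE], 2L, c0)
  w <- svd(rel0)$v[, 3]
  outward <- c0 - centroid
  if (sum(outward^2) > 1e-12 && sum(w * outward) < 0) w <- -w
  basis <- plane_basis(w)
  rel <- sweep(centers[as.character(nb), , drop = FALSE], 2L, c0)
  ang <- atan2(rel %*% basis$v, rel %*% basis$u)
  nb <- nb[order(ang)]
  k <- length(nb)
  nodes <- matrix(NA_real_, k, 3L)
  for (i in seq_len(k)) {
    ni <- nb[i]; nj <- nb[if (i == k) 1L else i + 1L]
    if (nj %in% adj[[as.character(ni)]]) {
      nodes[i, ] <- (c0 + centers[as.character(ni), ] +
                       centers[as.character(nj), ]) / 3
    } else {
      m <- intersect(adj[[as.character(ni)]], adj[[as.character(nj)]])
      m <- setdiff(m, c(s, nb))
      if (length(m) != 1L) return(PBA_SENTINEL)  # incomplete fan
      nodes[i, ] <- (c0 + centers[as.character(ni), ] +
                       centers[as.character(m), ] +
                       centers[as.character(nj), ]) / 4
    }
  }
  # total-least-squares plane of the fan nodes, translated to the center
  sv <- svd(sweep(nodes, 2L, colMeans(nodes)))
  n_hat <- sv$v[, 3]
  proj <- nodes - (sweep(nodes, 2L, c0) %*% n_hat) %*% t(n_hat)
  b2 <- plane_basis(n_hat)
  uv <- sweep(proj, 2L, c0) %*% cbind(b2$u, b2$v)
  uv <- uv[order(atan2(uv[, 2], uv[, 1])), , drop = FALSE]
  shoelace(uv)
}

plane_basis <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v)
}

shoelace <- function(uv) {
  x <- uv[, 1]; y <- uv[, 2]
  n <- nrow(uv)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Bounding-cuboid thickness and width of a scute
#'
#' Principal axes are taken from the covariance of the scute's voxel-center
#' world coordinates (a deterministic stand-in for the exact minimum-volume
#' box). The extent along each axis is (max - min projection) plus the voxel
#' spacing resolved along that axis, so a one-voxel-thin scute gets
#' thickness = spacing rather than zero. Thickness is the smallest extent,
#' width the largest.
#'
#' @param labels a `label_field`.
#' @param scute_id label id; if `NULL`, all scutes.
#' @return for one scute, `c(thickness_mm =, width_mm =)`; for all, a data
#'   frame `label`, `thickness_mm`, `width_mm`.
#' @export
bounding_cuboid_dims <- function(labels, scute_id = NULL) {
  stopifnot(inherits(labels, "label_field"))
  if (is.null(scute_id)) {
    ids <- setdiff(sort(unique(as.vector(labels$data))), 0L)
    out <- t(vapply(ids, function(s) bounding_cuboid_dims(labels, s),
                    numeric(2)))
    return(data.frame(label = ids, thickness_mm = out[, 1],
                      width_mm = out[, 2]))
  }
  lin <- which(labels$data == as.integer(scute_id))
  if (length(lin) == 0L) stop("no voxels carry label ", scute_id)
  w <- voxel_centers(labels, lin)
  sp <- labels$spacing
  if (length(lin) == 1L) {
    warning("single-voxel scute ", scute_id,
            ": thickness and width set to the voxel spacing")
    return(c(thickness_mm = min(sp), width_mm = max(sp)))
  }
  cv <- cov(w)
  axes <- eigen(cv, symmetric = TRUE)$vectors   # columns = principal axes
  ext <- vapply(1:3, function(k) {
    proj <- w %*% axes[, k]
    diff(range(proj)) + sqrt(sum((axes[, k] * sp)^2))
  }, numeric(1))
  c(thickness_mm = min(ext), width_mm = max(ext))
}

#' Local Gaussian and mean curvature of a surface at a point
#'
#' Collects mesh vertices within `radius_mm` of `center_mm`, builds a
#' tangent frame from their average outward normal, and fits the quadric
#' height function `h(u,v) = (a u^2 + 2 b uv + c v^2)/2 + d u + e v` by
#' least squares. The principal curvatures are the eigenvalues of the shape
#' operator of the fit at the origin, signed so that a locally convex
#' surface (bulging outward along the outward normal) has positive mean
#' curvature.
#'
#' @param mesh a `surface_mesh` with outward normals.
#' @param center_mm length-3 point (mm); should lie on or near the surface.
#' @param radius_mm neighborhood radius (mm).
#' @param vertex_normals optional precomputed [mesh_vertex_normals()] matrix
#'   (an optimization for batch callers).
#' @return `c(gaussK = ..., meanH = ...)` in 1/mm^2 and 1/mm.
#' @export
local_curvature <- function(mesh, center_mm, radius_mm,
                            vertex_normals = NULL) {
  center_mm <- as.numeric(center_mm)
  d2 <- rowSums(sweep(mesh$vertices, 2L, center_mm)^2)
  sel <- which(d2 <= radius_mm^2)
  if (length(sel) < 6L)
    stop(sprintf("insufficient support: %d vertices within %.3g mm",
                 length(sel), radius_mm))
  vn <- if (is.null(vertex_normals)) mesh_vertex_normals(mesh) else vertex_normals
  w <- colSums(vn[sel, , drop = FALSE])
  w <- w / sqrt(sum(w^2))
  basis <- plane_basis(w)
  rel <- sweep(mesh$vertices[sel, , drop = FALSE], 2L, center_mm)
  u <- as.vector(rel %*% basis$u)
  v <- as.vector(rel %*% basis$v)
  h <- as.vector(rel %*% w)
  X <- cbind(u^2 / 2, u * v, v^2 / 2, u, v)
  beta <- qr.coef(qr(X), h)
  beta[is.na(beta)] <- 0
  a <- beta[1]; b <- beta[2]; c_ <- beta[3]; dd <- beta[4]; e <- beta[5]
  g <- sqrt(1 + dd^2 + e^2)
  II <- matrix(c(a, b, b, c_), 2) / g
  I <- matrix(c(1 + dd^2, dd * e, dd * e, 1 + e^2), 2)
  shape <- solve(I, II)
  kappa <- -eigen(shape, only.values = TRUE)$values  # outward-convex => +
  c(gaussK = kappa[1] * kappa[2], meanH = (kappa[1] + kappa[2]) / 2)
}

#' Per-scute tesserae statistics
#'
#' One row per scute combining all seven morphometric variables: number of
#' neighbors, voxel volume, plane-based area (sentinel `-1000` for border
#' scutes), bounding-cuboid thickness and width, and local Gaussian and mean
#' surface curvature at the scute center (voxel centroid projected to the
#' nearest vertex of the outer mesh). The curvature neighborhood radius is
#' `curvature_radius_mult * sqrt(median PBA of non-border scutes)`, which
#' keeps the normalized curvatures K * SA and H * sqrt(SA) size-free.
#' Excluded labels (e.g., horns) are dropped before any computation.
#'
#' @param labels a `label_field`.
#' @param rag the corresponding `rag` (from [build_rag()]).
#' @param mesh the outer `surface_mesh` (from [extract_surface()]).
#' @param exclude_labels labels to drop (horns, masked structures).
#' @param curvature_radius_mult neighborhood radius multiplier (default
#'   0.75).
#' @return a data frame of class `scute_stats`: `label`, `n_neighbors`,
#'   `volume_mm3`, `pba_mm2`, `thickness_mm`, `width_mm`, `gaussK_per_mm2`,
#'   `meanH_per_mm`, `cx`, `cy`, `cz`, `border`.
#' @export
compute_scute_stats <- function(labels, rag, mesh, exclude_labels = NULL,
                                curvature_radius_mult = 0.75) {
  stopifnot(inherits(labels, "label_field"), inherits(rag, "rag"),
            inherits(mesh, "surface_mesh"))
  keep <- !(rag$nodes$label %in% exclude_labels)
  if (!all(keep)) {
    rag <- list(nodes = rag$nodes[keep, , drop = FALSE],
                edges = rag$edges[!(rag$edges$a %in% exclude_labels |
                                      rag$edges$b %in% exclude_labels), ,
                                  drop = FALSE])
    class(rag) <- "rag"
  }
  ids <- rag$nodes$label
  deg <- rag_degrees(rag)
  vol <- scute_volumes(labels)[as.character(ids)]
  pba <- plane_based_area(rag)[as.character(ids)]
  cub <- bounding_cuboid_dims(labels)
  cub <- cub[match(ids, cub$label), ]
  # scute center: voxel centroid projected to the nearest mesh vertex
  centers <- as.matrix(rag$nodes[, c("cx", "cy", "cz")])
  vi <- nearest_vertex(mesh, centers)
  proj <- mesh$vertices[vi, , drop = FALSE]
  ok_pba <- pba[pba != PBA_SENTINEL]
  r_curv <- if (length(ok_pba) > 0) {
    curvature_radius_mult * sqrt(median(ok_pba))
  } else {
    # no measurable PBA (e.g., all scutes border openings): fall back to the
    # median cuboid width as the scute size scale
    curvature_radius_mult * median(cub$width_mm) / 2
  }
  vn <- mesh_vertex_normals(mesh)
  curv <- t(vapply(seq_along(ids), function(i) {
    tryCatch(local_curvature(mesh, proj[i, ], r_curv, vertex_normals = vn),
             error = function(e) c(gaussK = NA_real_, meanH = NA_real_))
  }, numeric(2)))
  if (anyNA(curv))
    warning(sum(is.na(curv[, 1])), " scute(s) had insufficient curvature support")
  out <- data.frame(label = ids,
                    n_neighbors = as.integer(deg[as.character(ids)]),
                    volume_mm3 = as.numeric(vol),
                    pba_mm2 = as.numeric(pba),
                    thickness_mm = cub$thickness_mm,
                    width_mm = cub$width_mm,
                    gaussK_per_mm2 = curv[, 1],
                    meanH_per_mm = curv[, 2],
                    cx = proj[, 1], cy = proj[, 2], cz = proj[, 3],
                    border = pba == PBA_SENTINEL)
  class(out) <- c("scute_stats", "data.frame")
  out
}

nearest_vertex <- function(mesh, pts) {
  v <- mesh$vertices
  vapply(seq_len(nrow(pts)), function(i) {
    which.min(rowSums(sweep(v, 2L, pts[i, ])^2))
  }, integer(1))
}

#' Size-normalize scute statistics
#'
#' Adds the dimensionless columns used for cross-specimen comparison:
#' volume / SA^(3/2), PBA / SA, thickness / SA^(1/2), width / SA^(1/2),
#' K * SA and H * SA^(1/2). Border scutes (PBA sentinel) get `NA` normalized
#' PBA so they are excluded from that variable's analysis.
#'
#' @param stats a `scute_stats` data frame.
#' @param SA carapace surface area (mm^2), > 0.
#' @return the input with columns `norm_volume`, `norm_pba`,
#'   `norm_thickness`, `norm_width`, `norm_gaussK`, `norm_meanH` appended.
#' @export
normalize_stats <- function(stats, SA) {
  if (!is.finite(SA) || SA <= 0) stop("SA must be positive")
  stats$norm_volume <- stats$volume_mm3 / SA^1.5
  stats$norm_pba <- ifelse(stats$pba_mm2 == PBA_SENTINEL, NA_real_,
                           stats$pba_mm2 / SA)
  stats$norm_thickness <- stats$thickness_mm / sqrt(SA)
  stats$norm_width <- stats$width_mm / sqrt(SA)
  stats$norm_gaussK <- stats$gaussK_per_mm2 * SA
  stats$norm_meanH <- stats$meanH_per_mm * sqrt(SA)
  stats
}
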