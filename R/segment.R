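## Seed-based segmentation of carapace intensity volumes: thresholding,
## multi-source contour propagation (plain and distance-modified priorities),
## label splitting, and isosurface extraction.

#' Threshold segmentation of an intensity volume
#'
#' @param volume an `intensity_volume`.
#' @param tau intensity threshold; the mask is `intensity >= tau`.
#' @param largest_component if `TRUE`, keep only the largest 6-connected
#'   foreground component (batch stand-in for manual removal of stray
#'   structures).
#' @return a logical 3D array (the mask), carrying the volume's frame as
#'   attributes `spacing` and `origin`.
#' @export
threshold_segment <- function(volume, tau, largest_component = FALSE) {
  stopifnot(inherits(volume, "intensity_volume"))
  rng <- range(volume$data)
  mask <- volume$data >= tau
  if (!any(mask))
    stop(sprintf("empty foreground: tau = %g exceeds the volume maximum %g",
                 tau, rng[2]))
  if (largest_component) {
    comp <- mask_components(mask)
    main <- which.max(tabulate(comp[comp > 0L]))
    mask <- array(comp == main, dim(mask))
  }
  attr(mask, "spacing") <- volume$spacing
  attr(mask, "origin") <- volume$origin
  mask
}

# 6-connected components of a binary mask; returns integer array, 0 outside
mask_components <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  idmap <- integer(prod(d))
  idmap[fg] <- seq_along(fg)
  edges <- NULL
  strides <- c(1L, d[1], d[1] * d[2])
  ind <- arrayInd(fg, d)
  for (axis in 1:3) {
    ok <- ind[, axis] < d[axis]
    nb <- fg[ok] + strides[axis]
    both <- mask[nb]
    edges <- rbind(edges, cbind(idmap[fg[ok][both]], idmap[nb[both]]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- array(0L, d)
  out[fg] <- as.integer(memb[seq_along(fg)])
  out
}

#' Seed-based contour propagation
#'
#' Multi-source best-first region growing over a masked intensity volume.
#' Every region starts at its seed voxel; frontier voxels (6-connected
#' neighbors of labeled voxels, inside the mask) sit in one global priority
#' queue and are consumed in order of decreasing priority. In `"plain"` mode
#' the priority of voxel v is its intensity I(v); in `"distance_modified"`
#' mode it is `I(v) / max(d, floor)` where d is the 3D Euclidean distance
#' (world units) from v to the landmark of the candidate region (or, with
#' `distance_ref = "nearest"`, to the nearest landmark) and the floor is the
#' smallest voxel spacing. Ties are broken by lower candidate label id, then
#' lower linear voxel index, so output is deterministic. Regions never grow
#' across the background.
#'
#' @param volume an `intensity_volume`.
#' @param mask logical array from [threshold_segment()] (or any array
#'   coercible to logical with the same dimensions).
#' @param seeds a [seed_set()]; every seed must fall inside the mask.
#' @param mode `"plain"` or `"distance_modified"`.
#' @param distance_ref `"candidate"` (default: distance to the candidate
#'   region's own landmark) or `"nearest"` (distance to the nearest landmark).
#' @return a `label_field` labeling every masked voxel.
#' @export
propagate_contours <- function(volume, mask, seeds,
                               mode = c("plain", "distance_modified"),
                               distance_ref = c("candidate", "nearest")) {
  stopifnot(inherits(volume, "intensity_volume"))
  mode <- match.arg(mode)
  distance_ref <- match.arg(distance_ref)
  if (!identical(dim(mask), dim(volume$data)))
    stop("mask dimensions do not match the volume")
  if (anyDuplicated(seeds$label)) stop("duplicate seed labels")
  pos <- seed_matrix(seeds)
  ijk <- world_to_voxel(volume, pos)
  lin <- voxel_to_linear(volume, ijk)
  inside <- as.logical(mask[lin])
  if (!all(inside))
    stop("seed(s) outside the mask: label ",
         paste(seeds$label[!inside], collapse = ", "))
  if (anyDuplicated(lin))
    stop("two seeds fall in the same voxel: labels ",
         paste(seeds$label[duplicated(lin) | duplicated(lin, fromLast = TRUE)],
               collapse = ", "))
  lab <- .propagate_cpp(as.double(volume$data),
                        as.integer(mask), dim(volume$data),
                        volume$spacing, volume$origin,
                        lin - 1L, as.integer(seeds$label), pos,
                        if (mode == "plain") 0L else 1L,
                        if (distance_ref == "candidate") 0L else 1L)
  label_field(lab, volume$spacing, volume$origin)
}

#' Split one label with two seeds
#'
#' Batch replacement for interactive separation-surface editing: re-runs
#' [propagate_contours()] restricted to the target label's voxels with two
#' seeds. The first seed's region keeps `target_id`; the second gets a fresh
#' id (`max(label) + 1`).
#'
#' @param volume the `intensity_volume` the labels came from.
#' @param labels a `label_field`.
#' @param target_id label to split.
#' @param two_seeds 2 x 3 matrix of world coordinates (mm), or a 2-row
#'   [seed_set()].
#' @param mode,distance_ref passed to [propagate_contours()].
#' @return the updated `label_field`.
#' @export
split_label <- function(volume, labels, target_id, two_seeds,
                        mode = "distance_modified",
                        distance_ref = "candidate") {
  stopifnot(inherits(labels, "label_field"))
  if (inherits(two_seeds, "seed_set")) two_seeds <- seed_matrix(two_seeds)
  two_seeds <- matrix(as.numeric(two_seeds), ncol = 3L)
  if (nrow(two_seeds) != 2L) stop("exactly two seeds are required")
  submask <- labels$data == as.integer(target_id)
  if (!any(submask)) stop("no voxels carry label ", target_id)
  ijk <- world_to_voxel(labels, two_seeds)
  lin <- voxel_to_linear(labels, ijk)
  if (lin[1] == lin[2]) stop("the two seeds fall in the same voxel")
  if (!all(submask[lin]))
    stop("seed(s) outside label ", target_id)
  fresh <- max(labels$data) + 1L
  seeds <- seed_set(c(target_id, fresh), two_seeds)
  sub <- propagate_contours(volume, submask, seeds, mode = mode,
                            distance_ref = distance_ref)
  out <- labels$data
  out[submask] <- sub$data[submask]
  label_field(out, labels$spacing, labels$origin)
}

#' Extract the outer carapace isosurface from a mask or label field
#'
#' The binary foreground is lightly smoothed (1-2-1 kernel along each axis,
#' `smooth_iters` times, after zero-padding) and contoured at 0.5 by
#' marching tetrahedra. Of the resulting closed components only the largest
#' by area is kept — for a hollow shell this discards the internal cavity
#' wall and returns the outer surface with outward normals. If a label field
#' is supplied (or `labels` is given alongside a mask), each face is labeled
#' with the scute label of the nearest foreground voxel.
#'
#' @param x a `label_field`, an `intensity_volume` holding a binary mask, or
#'   a mask array from [threshold_segment()].
#' @param labels optional `label_field` for face labeling when `x` is a mask.
#' @param smooth_iters smoothing passes before contouring (default 2; the
#'   smoothing is what makes mesh area converge to the smooth surface area
#'   instead of the staircase area).
#' @return a `surface_mesh` with outward normals (and `face_labels` when
#'   labels are available).
#' @export
extract_surface <- function(x, labels = NULL, smooth_iters = 2) {
  if (inherits(x, "label_field")) {
    if (is.null(labels)) labels <- x
    spacing <- x$spacing; origin <- x$origin
    fgarr <- x$data != 0L
  } else if (inherits(x, "intensity_volume")) {
    spacing <- x$spacing; origin <- x$origin
    fgarr <- x$data > 0
  } else {
    spacing <- attr(x, "spacing"); origin <- attr(x, "origin")
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
    fgarr <- x != 0
  }
  if (!any(fgarr)) stop("empty foreground")
  d <- dim(fgarr)
  # zero-pad so surfaces at the array border still close
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(fgarr)
  origin <- origin - spacing
  for (i in seq_len(smooth_iters)) field <- smooth121(field)
  res <- .march_tetra_cpp(as.double(field), dim(field), spacing, origin, 0.5)
  if (nrow(res$faces) == 0L) stop("no isosurface found")
  mesh <- surface_mesh(res$vertices, res$faces)
  comp <- mesh_face_components(mesh)
  areas <- mesh_face_areas(mesh)
  main <- which.max(rowsum(areas, comp)[, 1])
  main <- as.integer(rownames(rowsum(areas, comp)))[main]
  keep <- comp == main
  mesh <- drop_faces(mesh, keep)
  if (!mesh_is_closed_manifold(mesh))
    stop("foreground has no closed outer component")
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (!is.null(labels)) {
    cen <- mesh_face_centroids(mesh)
    mesh$face_labels <- .nearest_label_cpp(cen, labels$data, dim(labels$data),
                                           labels$spacing, labels$origin,
                                           max(dim(labels$data)))
  }
  mesh
}

# separable 1-2-1 smoothing with replicated borders
smooth121 <- function(a) {
  d <- dim(a)
  for (axis in 1:3) {
    n <- d[axis]
    lo <- lapply(d, seq_len); lo[[axis]] <- c(1L, seq_len(n - 1L))
    hi <- lapply(d, seq_len); hi[[axis]] <- c(seq_len(n - 1L) + 1L, n)
    a <- (do.call(`[`, c(list(a), lo)) + 2 * a +
            do.call(`[`, c(list(a), hi))) / 4
  }
  a
}

drop_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  v <- mesh$vertices[used, , drop = FALSE]
  f[] <- match(f, used)
  surface_mesh(v, f, if (!is.null(mesh$face_labels)) mesh$face_labels[keep])
}

#' Agreement metrics between a segmentation and ground truth
#'
#' @param labels,truth_labels two `label_field`s on the same grid with
#'   matching label ids.
#' @return list with `voxel_agreement` (fraction of foreground voxels of
#'   `truth_labels` carrying the same label) and `dice` (named per-label
#'   Dice coefficients).
#' @export
segmentation_agreement <- function(labels, truth_labels) {
  stopifnot(same_frame(labels, truth_labels))
  a <- as.vector(labels$data)
  b <- as.vector(truth_labels$data)
  fg <- b != 0L
  agree <- mean(a[fg] == b[fg])
  ids <- setdiff(sort(unique(b)), 0L)
  dice <- vapply(ids, function(s) {
    na <- sum(a == s); nb <- sum(b == s)
    2 * sum(a == s & b == s) / (na + nb)
  }, numeric(1))
  list(voxel_agreement = agree, dice = setNames(dice, ids))
}
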