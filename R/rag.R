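#' Region adjacency graphs of labeled scutes
#'
#' A `rag` has one node per scute (with its 3D center in mm and voxel count)
#' and an undirected edge between every pair of scutes that touch, weighted
#' by the number of shared 6-adjacent voxel face pairs.
#'
#' `build_rag()` scans a [label_field()]; `rag_from_ground_truth()` builds
#' the same structure from a generator [tessellate_mesh()] ground truth
#' (centers and neighbor sets, no voxel counts), which is convenient for
#' mesh-only analyses such as plane-based area.
#'
#' @param labels a `label_field`.
#' @param min_contact_faces minimum number of shared voxel faces for an edge
#'   (default 1).
#' @return an object of class `rag`: list with `nodes` (data frame `label`,
#'   `cx`, `cy`, `cz`, `n_voxels`) and `edges` (data frame `a`, `b`,
#'   `contact_faces`, with `a < b`).
#' @export
build_rag <- function(labels, min_contact_faces = 1L) {
  stopifnot(inherits(labels, "label_field"))
  arr <- labels$data
  ids <- setdiff(sort(unique(as.vector(arr))), 0L)
  fg <- which(arr != 0L)
  lab <- arr[fg]
  counts <- tabulate(match(lab, ids), length(ids))
  w <- voxel_centers(labels, fg)
  # rowsum orders by sorted group -> same order as ids
  centers <- cbind(rowsum(w[, 1], lab), rowsum(w[, 2], lab),
                   rowsum(w[, 3], lab)) / counts
  nodes <- data.frame(label = ids, cx = centers[, 1], cy = centers[, 2],
                      cz = centers[, 3], n_voxels = counts)
  con <- .label_contacts_cpp(arr, dim(arr))
  keep <- con[, 3] >= min_contact_faces
  edges <- data.frame(a = con[keep, 1], b = con[keep, 2],
                      contact_faces = con[keep, 3])
  structure(list(nodes = nodes, edges = edges), class = "rag")
}

#' @rdname build_rag
#' @param truth a `ground_truth` from [tessellate_mesh()].
#' @export
rag_from_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  nodes <- data.frame(label = truth$scutes$label, cx = truth$scutes$cx,
                      cy = truth$scutes$cy, cz = truth$scutes$cz,
                      n_voxels = NA_integer_)
  edges <- data.frame(a = truth$neighbors[, 1], b = truth$neighbors[, 2],
                      contact_faces = NA_integer_)
  structure(list(nodes = nodes, edges = edges), class = "rag")
}

#' @export
print.rag <- function(x, ...) {
  cat(sprintf("<rag> %d scutes, %d adjacencies\n", nrow(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a RAG
#' @param rag a `rag`.
#' @return named integer vector, degree per label.
#' @export
rag_degrees <- function(rag) {
  deg <- setNames(integer(nrow(rag$nodes)), rag$nodes$label)
  t <- table(factor(c(rag$edges$a, rag$edges$b), levels = rag$nodes$label))
  deg[names(t)] <- as.integer(t)
  deg
}

#' Convert a RAG to an igraph object
#' @param rag a `rag`.
#' @return an undirected `igraph` graph with vertex attributes `label`,
#'   `cx`, `cy`, `cz`, `n_voxels` and edge attribute `contact_faces`.
#' @export
rag_as_igraph <- function(rag) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(rag$edges$a), to = as.character(rag$edges$b),
               contact_faces = rag$edges$contact_faces),
    directed = FALSE,
    vertices = data.frame(name = as.character(rag$nodes$label),
                          label = rag$nodes$label, cx = rag$nodes$cx,
                          cy = rag$nodes$cy, cz = rag$nodes$cz,
                          n_voxels = rag$nodes$n_voxels))
  g
}

#' Write a RAG as GraphML and as a CSV edge list
#' @param rag a `rag`.
#' @param graphml_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_rag <- function(rag, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(rag_as_igraph(rag), graphml_path, format = "graphml")
  if (!is.null(csv_path))
    write.csv(rag$edges, csv_path, row.names = FALSE)
  invisible(rag)
}

#' Merge groups of adjacent labels
#'
#' Batch replacement for interactive pick-and-merge label editing: each
#' group (which must be connected in the RAG) is relabeled to its smallest
#' member id, then all label ids are compacted to 1..N and the RAG is
#' recomputed.
#'
#' @param labels a `label_field`.
#' @param rag the corresponding `rag`.
#' @param groups list of integer vectors of label ids to merge.
#' @return list with the new `labels` and `rag`.
#' @export
merge_labels <- function(labels, rag, groups) {
  stopifnot(inherits(labels, "label_field"), inherits(rag, "rag"))
  g <- rag_as_igraph(rag)
  for (grp in groups) {
    grp <- as.integer(grp)
    if (!all(grp %in% rag$nodes$label))
      stop("unknown label(s) in merge group: ",
           paste(setdiff(grp, rag$nodes$label), collapse = ", "))
    sg <- igraph::induced_subgraph(g, as.character(grp))
    comp <- igraph::components(sg)
    if (comp$no > 1L) {
      parts <- split(names(comp$membership), comp$membership)
      stop("merge group is not connected in the RAG; components: ",
           paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "))
    }
  }
  arr <- labels$data
  for (grp in groups) {
    grp <- as.integer(grp)
    arr[arr %in% grp] <- min(grp)
  }
  # compact ids to 1..N
  ids <- setdiff(sort(unique(as.vector(arr))), 0L)
  arr[] <- ifelse(arr == 0L, 0L, match(arr, ids))
  newlab <- label_field(arr, labels$spacing, labels$origin)
  list(labels = newlab, rag = build_rag(newlab))
}
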