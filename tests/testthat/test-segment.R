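test_that("threshold_segment reproduces the shell support and rejects empty masks", {
  fx <- fx_cube()
  # noiseless phantom: mask equals ground-truth support exactly
  vox <- voxelize_labeled_shell(fx$tess, fx$spec, 0.1, valley_depth = 0.5,
                                noise_sd = 0)
  mask <- threshold_segment(vox$intensity, 50)
  expect_identical(as.vector(mask), as.vector(vox$labels$data > 0L))
  # tau above the maximum -> error mentioning the empty foreground
  expect_error(threshold_segment(vox$intensity, 1e6), "empty foreground")
  # noisy phantom: disagreement with truth below 0.1% (Gaussian tail at
  # 10 sd for half the plateau)
  maskn <- threshold_segment(fx$vox$intensity, 50)
  expect_lt(mean(maskn != (fx$vox$labels$data > 0L)), 1e-3)
})

test_that("largest-component filtering drops stray structures", {
  arr <- array(0, c(12, 6, 6))
  arr[2:5, 2:5, 2:5] <- 200    # main block: 64 voxels
  arr[9:10, 2:3, 2:3] <- 200   # stray: 8 voxels
  v <- intensity_volume(arr, c(1, 1, 1))
  m1 <- threshold_segment(v, 100)
  expect_identical(sum(m1), 72L)
  m2 <- threshold_segment(v, 100, largest_component = TRUE)
  expect_identical(sum(m2), 64L)
})

test_that("1D toy propagation follows the documented queue and tie rule", {
  # intensities [9,9,3,9,9], seeds at the two ends, plain mode: the valley
  # voxel is contested at equal priority and goes to the lower label id
  v <- vol1d(c(9, 9, 3, 9, 9))
  mask <- v$data > 0
  seeds <- seed_set(1:2, rbind(c(0.5, 0.5, 0.5), c(4.5, 0.5, 0.5)))
  lab <- propagate_contours(v, mask, seeds, mode = "plain")
  expect_equal(as.vector(lab$data), c(1, 1, 1, 2, 2))
  # swapping the label ids flips the tie
  seeds2 <- seed_set(c(2L, 1L), rbind(c(0.5, 0.5, 0.5), c(4.5, 0.5, 0.5)))
  lab2 <- propagate_contours(v, mask, seeds2, mode = "plain")
  expect_equal(as.vector(lab2$data), c(2, 2, 1, 1, 1))
})

test_that("disconnected plateaus give exact 2-label ground truth", {
  v <- vol1d(c(9, 9, 0, 9, 9))
  mask <- v$data > 0
  seeds <- seed_set(1:2, rbind(c(0.5, 0.5, 0.5), c(4.5, 0.5, 0.5)))
  for (mode in c("plain", "distance_modified")) {
    lab <- propagate_contours(v, mask, seeds, mode = mode)
    expect_equal(as.vector(lab$data), c(1, 1, 0, 2, 2))
  }
})

test_that("propagation partitions the mask, keeps seeds, is deterministic", {
  fx <- fx_small_shell()
  mask <- threshold_segment(fx$vox$intensity, 50)
  lab <- propagate_contours(fx$vox$intensity, mask, fx$vox$seeds,
                            mode = "distance_modified")
  # completeness: every masked voxel labeled exactly once
  expect_identical(as.vector(lab$data != 0L), as.vector(mask))
  # seed dominance: each seed voxel carries its own label
  ijk <- world_to_voxel(lab, as.matrix(fx$vox$seeds[, 2:4]))
  lin <- ijk[, 1] + (ijk[, 2] - 1) * dim(lab$data)[1] +
    (ijk[, 3] - 1) * prod(dim(lab$data)[1:2])
  expect_identical(as.integer(lab$data[lin]), fx$vox$seeds$label)
  # determinism
  lab2 <- propagate_contours(fx$vox$intensity, mask, fx$vox$seeds,
                             mode = "distance_modified")
  expect_identical(lab$data, lab2$data)
  # the nearest-landmark variant also partitions and stays deterministic
  lab3 <- propagate_contours(fx$vox$intensity, mask, fx$vox$seeds,
                             mode = "distance_modified",
                             distance_ref = "nearest")
  expect_identical(as.vector(lab3$data != 0L), as.vector(mask))
})

test_that("propagation rejects bad seeds by name", {
  v <- vol1d(c(9, 9, 0, 9, 9))
  mask <- v$data > 0
  expect_error(
    propagate_contours(v, mask, seed_set(7L, rbind(c(2.5, 0.5, 0.5))),
                       mode = "plain"),
    "label 7")
  s <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5))
  bad <- structure(data.frame(label = c(1L, 1L), x_mm = s[, 1],
                              y_mm = s[, 2], z_mm = s[, 3]),
                   class = c("seed_set", "data.frame"))
  expect_error(propagate_contours(v, mask, bad, mode = "plain"), "duplicate")
})

test_that("build_rag counts face contacts without diagonal tunneling", {
  # checkerboard 2x2x1 of 4 labels: 4 face-adjacent edges, no diagonals
  lab <- label_field(array(c(1L, 2L, 3L, 4L), c(2, 2, 1)), c(1, 1, 1))
  rag <- build_rag(lab)
  expect_identical(nrow(rag$edges), 4L)
  got <- paste(rag$edges$a, rag$edges$b)
  expect_setequal(got, c("1 2", "1 3", "2 4", "3 4"))
  expect_true(all(rag$edges$a != rag$edges$b))  # no self loops
  # min_contact_faces filters weak contacts
  rag2 <- build_rag(lab, min_contact_faces = 2L)
  expect_identical(nrow(rag2$edges), 0L)
  # cube phantom: every node has degree 4
  expect_equal(unname(rag_degrees(fx_cube()$rag)), rep(4L, 6))
  # node set = label set, centers in world coordinates
  expect_identical(rag$nodes$label, 1:4)
  expect_equal(rag$nodes$n_voxels, rep(1L, 4))
})

test_that("merge_labels merges connected groups and conserves voxels", {
  fx <- fx_small_shell()
  rag <- fx$rag
  e1 <- c(rag$edges$a[1], rag$edges$b[1])
  n_vox <- sum(fx$vox$labels$data %in% e1)
  merged <- merge_labels(fx$vox$labels, rag, list(e1))
  expect_identical(nrow(merged$rag$nodes), nrow(rag$nodes) - 1L)
  # merged label keeps the smallest id after compaction; voxel conservation
  expect_identical(sum(merged$labels$data == min(e1)), n_vox)
  # label ids dense 1..N
  expect_identical(sort(unique(as.vector(merged$labels$data[merged$labels$data > 0]))),
                   seq_len(nrow(merged$rag$nodes)))
  # non-adjacent pair -> error listing components
  adj_pairs <- paste(rag$edges$a, rag$edges$b)
  non_adj <- NULL
  for (a in rag$nodes$label) {
    for (b in rag$nodes$label) {
      if (a < b && !(paste(a, b) %in% adj_pairs)) { non_adj <- c(a, b); break }
    }
    if (!is.null(non_adj)) break
  }
  expect_error(merge_labels(fx$vox$labels, rag, list(non_adj)),
               "not connected")
})

test_that("merging all labels yields a single isolated node", {
  cube <- fx_cube()
  merged <- merge_labels(cube$vox$labels, cube$rag, list(1:6))
  expect_identical(nrow(merged$rag$nodes), 1L)
  expect_identical(nrow(merged$rag$edges), 0L)
  expect_identical(unname(rag_degrees(merged$rag)), 0L)
})

test_that("split_label recovers an artificially merged scute pair", {
  fx <- fx_small_shell()
  truth <- fx$vox$labels
  pair <- c(fx$rag$edges$a[5], fx$rag$edges$b[5])
  merged <- truth$data
  merged[merged == pair[2]] <- pair[1]
  merged_lab <- label_field(merged, truth$spacing, truth$origin)
  ctrs <- fx$tess$truth$scutes
  s1 <- unlist(ctrs[ctrs$label == pair[1], c("cx", "cy", "cz")])
  s2 <- unlist(ctrs[ctrs$label == pair[2], c("cx", "cy", "cz")])
  # clamp the true centers into foreground voxels of the merged label
  snap <- function(p) {
    lin <- which(merged == pair[1])
    w <- voxel_centers(merged_lab, lin)
    w[which.min(rowSums(sweep(w, 2, p)^2)), ]
  }
  out <- split_label(fx$vox$intensity, merged_lab, pair[1],
                     rbind(snap(s1), snap(s2)))
  fresh <- max(out$data)
  # recovered split matches ground truth on >= 95% of the pair's voxels
  sel <- truth$data %in% pair
  got <- out$data[sel]
  want <- truth$data[sel]
  agree <- max(mean((got == pair[1]) == (want == pair[1])),
               mean((got == fresh) == (want == pair[1])))
  expect_gte(agree, 0.95)
  # split then merge restores the original support exactly
  rag_after <- build_rag(out)
  restored <- merge_labels(out, rag_after, list(c(pair[1], fresh)))
  expect_identical(restored$labels$data == pair[1],
                   merged_lab$data == pair[1])
  # error contracts
  expect_error(split_label(fx$vox$intensity, merged_lab, pair[1],
                           rbind(snap(s1), snap(s1))), "same voxel")
  outside <- voxel_centers(truth, which(truth$data == 0L)[1])
  expect_error(split_label(fx$vox$intensity, merged_lab, pair[1],
                           rbind(snap(s1), outside)), "outside")
})

test_that("extract_surface recovers smooth areas and outer components", {
  d <- c(45, 45, 45)
  arr <- array(0, d)
  cen <- rep(22.5, 3)
  idx <- arrayInd(seq_len(prod(d)), d) - 1 + 0.5
  r2 <- rowSums(sweep(idx, 2, cen)^2)
  arr[r2 <= 400] <- 1
  ball <- intensity_volume(arr, c(1, 1, 1))
  mesh <- extract_surface(ball)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 400) / (4 * pi * 400), 0.03)
  expect_true(mesh_is_closed_manifold(mesh))
  expect_gt(mesh_signed_volume(mesh), 0)
  # hollow shell: the inner cavity wall is dropped, one closed component
  arr2 <- arr
  arr2[r2 <= 196] <- 0
  mesh2 <- extract_surface(intensity_volume(arr2, c(1, 1, 1)))
  expect_equal(unname(unique(mesh_face_components(mesh2))), 1)
  expect_equal(mesh_area(mesh2), mesh_area(mesh), tolerance = 1e-6)
  expect_error(extract_surface(intensity_volume(array(0, c(3, 3, 3)))),
               "empty foreground")
})

test_that("per-face surface labels reproduce the voxel RAG adjacency", {
  cube <- fx_cube()
  mesh <- cube$surf
  expect_setequal(unique(mesh$face_labels), 1:6)
  adj <- mesh_face_adjacency(mesh)
  la <- mesh$face_labels[adj[, 1]]
  lb <- mesh$face_labels[adj[, 2]]
  keep <- la != lb
  mesh_edges_set <- unique(paste(pmin(la[keep], lb[keep]),
                                 pmax(la[keep], lb[keep])))
  rag_edges_set <- paste(cube$rag$edges$a, cube$rag$edges$b)
  expect_setequal(mesh_edges_set, rag_edges_set)
})
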