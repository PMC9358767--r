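# hand-built unit cube mesh (12 triangles), outward normals
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  m <- surface_mesh(v, f)
  stopifnot(mesh_signed_volume(m) > 0)
  m
}

test_that("carapace_surface_area sums triangles and scales by similarity", {
  cube <- unit_cube_mesh()
  expect_equal(carapace_surface_area(cube), 6)
  sph <- fx_sphere_mesh(5)
  sph3 <- surface_mesh(sph$vertices * 3 / 5, sph$faces)
  expect_lt(abs(carapace_surface_area(sph3) - 36 * pi) / (36 * pi), 0.01)
  doubled <- surface_mesh(cube$vertices * 2, cube$faces)
  expect_equal(carapace_surface_area(doubled),
               4 * carapace_surface_area(cube))
  # label exclusion drops the excluded faces (horn removal)
  cube$face_labels <- rep(1:2, each = 6)
  expect_equal(carapace_surface_area(cube, exclude_labels = 2L), 3)
})

test_that("neighbor_counts returns degrees and a frequency table", {
  cube <- fx_cube()
  nc <- neighbor_counts(cube$rag)
  expect_equal(unname(nc$counts), rep(4L, 6))
  expect_equal(nc$freq$rel_freq[nc$freq$n_neighbors == 4], 1)
  # handshake lemma on the 370-scute carapace
  fx <- fx_tess370()
  rag <- rag_from_ground_truth(fx$tess$truth)
  nc370 <- neighbor_counts(rag)
  expect_identical(sum(nc370$counts), 2L * nrow(rag$edges))
  # hexagons modal, ordering 6 > 5 > 7 as on real carapaces
  f <- setNames(nc370$freq$rel_freq, nc370$freq$n_neighbors)
  expect_gt(f[["6"]], f[["5"]])
  expect_gt(f[["5"]], f[["7"]])
})

test_that("scute_volumes multiplies voxel counts by voxel volume", {
  arr <- array(0L, c(4, 4, 4))
  arr[1:2, 1:2, 1:2] <- 1L   # 8 voxels
  arr[4, 4, 4] <- 2L
  lab <- label_field(arr, c(0.5, 0.5, 0.5))
  v <- scute_volumes(lab)
  expect_equal(v[["1"]], 1.0)   # 8 x 0.125
  expect_equal(v[["2"]], 0.125)
  expect_equal(sum(v), sum(arr > 0L) * 0.125)
})

test_that("plane-based area matches the hand-computed hexagon oracle", {
  # regular planar hexagonal patch, unit pitch, all fan elements triangles:
  # fan nodes are triangle centroids at radius 1/sqrt(3); PBA is the area of
  # that hexagon = (3*sqrt(3)/2) * (1/3) = sqrt(3)/2
  rag <- hex_rag()
  expect_equal(plane_based_area(rag, 1), sqrt(3) / 2)
  # rigid motions leave the area invariant (coplanar fan: projection is
  # the identity)
  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  rag2 <- hex_rag(transform = function(x)
    x %*% t(R) + matrix(c(5, -2, 7), nrow(x), 3, byrow = TRUE))
  expect_equal(plane_based_area(rag2, 1), sqrt(3) / 2)
  # pitch scales area quadratically
  expect_equal(plane_based_area(hex_rag(pitch = 2), 1), 2 * sqrt(3))
  # edge scutes of the hex patch have < 3 neighbors -> sentinel
  expect_identical(plane_based_area(rag, 2), -1000)
})

test_that("scutes at carapace openings get the exact -1000 sentinel", {
  fx <- fx_opening()
  rag <- rag_from_ground_truth(fx$tess$truth)
  pba <- plane_based_area(rag)
  # scutes bordering the opening (adjacent to label-0 faces)
  expect_gt(length(fx$ring), 2)
  expect_true(all(pba[as.character(fx$ring)] == -1000))
  # interior scutes overwhelmingly measurable and positive
  interior <- setdiff(fx$tess$truth$scutes$label, fx$ring)
  expect_gt(mean(pba[as.character(interior)] > 0), 0.8)
  # contract: every value is > 0 or exactly -1000
  expect_true(all(pba > 0 | pba == -1000))
})

test_that("PBA approximately tiles the closed surface", {
  fx <- fx_tess370()
  rag <- rag_from_ground_truth(fx$tess$truth)
  pba <- plane_based_area(rag)
  ok <- pba != -1000
  expect_gt(mean(ok), 0.95)   # closed tessellation: almost all fans complete
  total <- sum(pba[ok]) + sum(fx$tess$truth$scutes$patch_area_mm2[!ok])
  expect_lt(abs(total - fx$tess$truth$sa_mm2) / fx$tess$truth$sa_mm2, 0.10)
})

test_that("bounding cuboid extents follow the principal axes", {
  # axis-aligned 10 x 4 x 1 voxel slab at 1 mm: thickness 1, width 10
  arr <- array(0L, c(12, 6, 3))
  arr[1:10, 1:4, 2] <- 1L
  lab <- label_field(arr, c(1, 1, 1))
  d <- bounding_cuboid_dims(lab, 1)
  expect_equal(d[["thickness_mm"]], 1)
  expect_equal(d[["width_mm"]], 10)
  # same slab rotated 45 deg about z, re-voxelized finely: within 10% of
  # the exact rotated box (oracle: the slab is 10 x 4 x 1 mm by construction)
  sp <- 0.1
  # voxel-center grids (half-offset) so box boundaries fall between centers
  xs <- seq(-6.95, 6.95, sp); zs <- seq(-0.95, 0.95, sp)
  g <- expand.grid(x = xs, y = xs, z = zs)
  a <- pi / 4
  u <- g$x * cos(a) + g$y * sin(a)
  v <- -g$x * sin(a) + g$y * cos(a)
  inside <- abs(u) <= 5 & abs(v) <= 2 & abs(g$z) <= 0.5
  nx <- length(xs); nz <- length(zs)
  arr2 <- array(0L, c(nx, nx, nz))
  arr2[cbind(match(g$x[inside], xs), match(g$y[inside], xs),
             match(g$z[inside], zs))] <- 1L
  lab2 <- label_field(arr2, rep(sp, 3))
  d2 <- bounding_cuboid_dims(lab2, 1)
  expect_lt(abs(d2[["thickness_mm"]] - 1) / 1, 0.10)
  expect_lt(abs(d2[["width_mm"]] - 10) / 10, 0.10)
  # thickness <= width always; single voxel warns and returns spacing
  expect_lte(d2[["thickness_mm"]], d2[["width_mm"]])
  arr3 <- array(0L, c(3, 3, 3)); arr3[2, 2, 2] <- 1L
  expect_warning(d3 <- bounding_cuboid_dims(label_field(arr3, c(1, 1, 1)), 1),
                 "single-voxel")
  expect_equal(unname(d3), c(1, 1))
})

test_that("curvature oracles: plane, sphere, cylinder, saddle", {
  expect_equal(unname(local_curvature(fx_plane_mesh(), c(0, 0, 0), 1.5)),
               c(0, 0), tolerance = 1e-9)
  ks <- local_curvature(fx_sphere_mesh(5), c(5, 0, 0), 1.5)
  expect_lt(abs(ks[["gaussK"]] - 0.04) / 0.04, 0.05)
  expect_lt(abs(ks[["meanH"]] - 0.2) / 0.2, 0.05)
  kc <- local_curvature(fx_cylinder_mesh(4), c(4, 0, 0), 1.5)
  expect_lt(abs(kc[["gaussK"]]), 0.01)
  expect_lt(abs(kc[["meanH"]] - 0.125) / 0.125, 0.05)
  kd <- local_curvature(fx_saddle_mesh(), c(0, 0, 0), 1.5)
  expect_lt(kd[["gaussK"]], 0)                  # saddle-shaped
  expect_equal(kd[["gaussK"]], -0.04, tolerance = 1e-6)
  expect_equal(kd[["meanH"]], 0, tolerance = 1e-6)
  # insufficient support
  expect_error(local_curvature(fx_plane_mesh(), c(0, 0, 50), 1), "insufficient")
})

test_that("compute_scute_stats assembles all variables consistently", {
  cube <- fx_cube()
  st <- compute_scute_stats(cube$vox$labels, cube$rag, cube$surf)
  expect_identical(nrow(st), 6L)
  expect_equal(st$n_neighbors, rep(4L, 6))
  # flat cube faces: K ~ 0 and H ~ 0 at face centers
  expect_lt(max(abs(st$gaussK_per_mm2)), 1e-3)
  expect_lt(max(abs(st$meanH_per_mm)), 0.02)
  # contracts
  expect_true(all(st$volume_mm3 > 0))
  expect_true(all(st$thickness_mm <= st$width_mm))
  expect_true(all(st$pba_mm2 > 0 | st$pba_mm2 == -1000))
  # AM-GM: K <= H^2 for every scute
  expect_true(all(st$gaussK_per_mm2 <= st$meanH_per_mm^2 + 1e-12))
  # conservation: scute volumes sum to total foreground volume exactly
  expect_equal(sum(st$volume_mm3),
               sum(cube$vox$labels$data > 0L) * prod(cube$vox$labels$spacing))
  # exclusions drop rows before computation
  st2 <- compute_scute_stats(cube$vox$labels, cube$rag, cube$surf,
                             exclude_labels = c(1L, 2L))
  expect_identical(nrow(st2), 4L)
  expect_false(any(st2$label %in% 1:2))
})

test_that("curvature signs on the carapace: convex shell is H > 0", {
  fx <- fx_small_shell()
  # on the smooth tessellated surface every scute of a convex shell bulges
  # outward
  st_smooth <- compute_scute_stats(fx$vox$labels, fx$rag, fx$tess$mesh)
  expect_gt(mean(st_smooth$meanH_per_mm > 0, na.rm = TRUE), 0.95)
  # on the voxel-extracted surface the sign holds in aggregate (staircase
  # undulations flip individual low-curvature scutes)
  st <- compute_scute_stats(fx$vox$labels, fx$rag, fx$surf)
  expect_gt(median(st$meanH_per_mm, na.rm = TRUE), 0)
  expect_true(all(st$gaussK_per_mm2 <= st$meanH_per_mm^2 + 1e-12,
                  na.rm = TRUE))
})

test_that("normalize_stats removes size and respects the PBA sentinel", {
  st <- data.frame(label = 1:2, n_neighbors = c(6L, 5L),
                   volume_mm3 = c(8, 2), pba_mm2 = c(2, -1000),
                   thickness_mm = c(1, 1), width_mm = c(2, 2),
                   gaussK_per_mm2 = c(0.1, 0.2), meanH_per_mm = c(0.3, 0.4),
                   cx = 0, cy = 0, cz = 0, border = c(FALSE, TRUE))
  n <- normalize_stats(st, 4)
  expect_equal(n$norm_volume[1], 1.0)          # 8 / 4^1.5
  expect_equal(n$norm_pba[1], 0.5)
  expect_true(is.na(n$norm_pba[2]))            # sentinel row excluded
  expect_equal(n$norm_thickness, c(0.5, 0.5))
  expect_equal(n$norm_gaussK, c(0.4, 0.8))
  expect_equal(n$norm_meanH, c(0.6, 0.8))
  expect_error(normalize_stats(st, 0), "positive")
  # isometric pair: identical normalized medians (dimensional analysis)
  s <- 3
  st_big <- st
  st_big$volume_mm3 <- st$volume_mm3 * s^3
  st_big$pba_mm2 <- ifelse(st$pba_mm2 == -1000, -1000, st$pba_mm2 * s^2)
  st_big$thickness_mm <- st$thickness_mm * s
  st_big$width_mm <- st$width_mm * s
  st_big$gaussK_per_mm2 <- st$gaussK_per_mm2 / s^2
  st_big$meanH_per_mm <- st$meanH_per_mm / s
  nb <- normalize_stats(st_big, 4 * s^2)
  for (col in c("norm_volume", "norm_pba", "norm_thickness", "norm_width",
                "norm_gaussK", "norm_meanH"))
    expect_equal(nb[[col]], n[[col]], tolerance = 1e-9)
})
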