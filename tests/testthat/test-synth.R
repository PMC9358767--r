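test_that("shell_spec enforces its invariants", {
  expect_error(shell_spec(length_mm = -1), "positive")
  expect_error(shell_spec(boxiness = 1.5), ">= 2")
  expect_error(shell_spec(shell_thickness_mm = 0), "positive")
  expect_error(shell_spec(n_scutes = 6), ">= 12")
  expect_warning(shell_spec(10, 20, 5), "ordered")
  expect_error(shell_spec(openings = list(list(center_direction = c(1, 0)))),
               "opening")
})

test_that("tessellation partitions the surface and conserves area", {
  fx <- fx_tess370()
  lab <- fx$tess$mesh$face_labels
  expect_true(all(lab %in% 1:370))
  expect_setequal(unique(lab), 1:370)
  # conservation: ground-truth patch areas sum to mesh area within 0.1%
  expect_equal(fx$tess$truth$sa_mm2, mesh_area(fx$tess$mesh),
               tolerance = 1e-3)
  expect_equal(sum(fx$tess$truth$scutes$patch_area_mm2),
               mesh_area(fx$tess$mesh), tolerance = 1e-9)
  # neighbor relation symmetric by construction (stored a < b, unique)
  nb <- fx$tess$truth$neighbors
  expect_true(all(nb[, 1] < nb[, 2]))
  expect_identical(nrow(unique(nb)), nrow(nb))
})

test_that("patches are edge-connected", {
  fx <- fx_small_shell()
  mesh <- fx$tess$mesh
  adj <- mesh_face_adjacency(mesh)
  for (s in sample(unique(mesh$face_labels), 25)) {
    f <- which(mesh$face_labels == s)
    sub <- adj[mesh$face_labels[adj[, 1]] == s &
                 mesh$face_labels[adj[, 2]] == s, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub), f), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(f) - igraph::vcount(g)))
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("tessellation neighbor topology matches a closed tiling", {
  # Euler: mean neighbor count < 6 for every generated closed tessellation
  fx <- fx_tess370()
  nb370 <- neighbor_tally(fx$tess$truth)
  expect_lt(mean(nb370), 6)
  # with >= 100 Lloyd-relaxed scutes, hexagons are the modal class
  expect_identical(as.integer(names(which.max(table(nb370)))), 6L)
  sm <- fx_small_shell()
  nb120 <- neighbor_tally(sm$tess$truth)
  expect_lt(mean(nb120), 6)
  expect_identical(as.integer(names(which.max(table(nb120)))), 6L)
  # 6-scute near-cube with sites at face centers: cube adjacency, degree 4
  cube <- fx_cube()
  expect_equal(neighbor_tally(cube$tess$truth), rep(4L, 6),
               ignore_attr = TRUE)
})

test_that("tessellation is deterministic for a fixed seed", {
  sp <- shell_spec(12, 8, 7, boxiness = 4, shell_thickness_mm = 0.5,
                   n_scutes = 40, rng_seed = 9)
  m <- make_shell_mesh(sp, resolution = 4)
  t1 <- tessellate_mesh(m, 40, relax_iters = 5, rng_seed = 9)
  t2 <- tessellate_mesh(m, 40, relax_iters = 5, rng_seed = 9)
  expect_identical(t1$mesh$face_labels, t2$mesh$face_labels)
  expect_identical(t1$truth$scutes, t2$truth$scutes)
  t3 <- tessellate_mesh(m, 40, relax_iters = 5, rng_seed = 10)
  expect_false(identical(t1$mesh$face_labels, t3$mesh$face_labels))
})

test_that("voxelization rejects too-coarse spacing, naming the minimum", {
  fx <- fx_cube()
  expect_error(voxelize_labeled_shell(fx$tess, fx$spec, 0.15),
               "spacing <= 0.1")
})

test_that("voxel phantom partitions foreground and matches ground truth", {
  fx <- fx_cube()
  lab <- fx$vox$labels$data
  # sum of per-label voxel counts = foreground voxel count (exact)
  expect_identical(sum(tabulate(lab[lab > 0L])), sum(lab > 0L))
  # thin-wall cube: per-scute voxel volumes within 5% of patch area x
  # thickness (brute-force voxel counting against generator truth)
  vols <- scute_volumes(fx$vox$labels)
  rel <- abs(as.numeric(vols) - fx$tess$truth$scutes$volume_mm3) /
    fx$tess$truth$scutes$volume_mm3
  expect_lt(max(rel), 0.05)
  # seeds: one per scute, inside own label
  s <- fx$vox$seeds
  ijk <- world_to_voxel(fx$vox$labels, as.matrix(s[, 2:4]))
  lin <- ijk[, 1] + (ijk[, 2] - 1) * dim(lab)[1] +
    (ijk[, 3] - 1) * dim(lab)[1] * dim(lab)[2]
  expect_identical(as.integer(lab[lin]), s$label)
})

test_that("valley_depth = 0 gives a unimodal in-shell intensity histogram", {
  fx <- fx_cube()
  vox0 <- voxelize_labeled_shell(fx$tess, fx$spec, 0.1, valley_depth = 0,
                                 noise_sd = 5, rng_seed = 77)
  inside <- vox0$intensity$data[vox0$labels$data > 0L]
  # single plateau + noise: everything within a few sd of 200
  expect_lt(max(abs(inside - 200)), 5 * 6)
  expect_equal(mean(inside), 200, tolerance = 0.01)
  # with a valley, the suture band sits at half the plateau
  vox5 <- voxelize_labeled_shell(fx$tess, fx$spec, 0.1, valley_depth = 0.5,
                                 noise_sd = 0)
  vals <- sort(unique(as.vector(vox5$intensity$data)))
  expect_equal(vals, c(0, 100, 200))
})

test_that("isometric series scale exactly and keep scute count fixed", {
  ser <- series_spec(n_specimens = 3, scale_factors = c(1, 2, 8.5),
                     mode = "isometric", rng_seed = 5)
  base <- shell_spec(12, 8, 7, boxiness = 4, shell_thickness_mm = 0.5,
                     n_scutes = 40, rng_seed = 5)
  gen <- generate_series(ser, base, resolution = 4)
  # ground-truth SA ratio = (s'/s)^2 exactly
  expect_equal(gen$table$sa_mm2[2] / gen$table$sa_mm2[1], 4)
  expect_equal(gen$table$sa_mm2[3] / gen$table$sa_mm2[1], 8.5^2)
  # scute count identical across specimens
  expect_identical(unique(gen$table$n_scutes), 40L)
  # determinism: same spec + seed -> bit-identical output
  gen2 <- generate_series(ser, base, resolution = 4)
  expect_identical(gen, gen2)
})

test_that("table-only series are exactly affine in log-log space", {
  ser <- series_spec(mode = "table_only",
                     exponents = list(b_length = 0.59), rng_seed = 1)
  gen <- generate_series(ser)
  x <- log(gen$table$sa_mm2)
  y <- log(gen$table$length_mm)
  slopes <- diff(y) / diff(x)
  expect_equal(slopes, rep(0.59, 12), tolerance = 1e-12)
  # lognormal noise breaks exact affinity but is seeded / reproducible
  sern <- series_spec(mode = "table_only", noise_sd = 0.05, rng_seed = 8)
  g1 <- generate_series(sern)
  g2 <- generate_series(sern)
  expect_identical(g1$table, g2$table)
  expect_false(all(diff(log(g1$table$length_mm)) / diff(x) == 0.5))
})

test_that("series_spec validates and isometric mode forces exponents", {
  expect_error(series_spec(scale_factors = c(2, 1, 3)), "increasing")
  expect_warning(series_spec(scale_factors = c(1, 2, 4)), "8x")
  ser <- series_spec(mode = "isometric",
                     exponents = list(b_length = 0.9), rng_seed = 1)
  expect_equal(ser$exponents$b_length, 0.5)
  expect_equal(ser$exponents$b_scute_volume, 1.5)
  expect_warning(
    series_spec(mode = "allometric", exponents = list(b_height = 0.7),
                rng_seed = 1),
    "ordering")
})

test_that("openings remove faces and are excluded from ground truth", {
  sp <- shell_spec(12, 8, 7, boxiness = 4, shell_thickness_mm = 0.5,
                   n_scutes = 40, rng_seed = 6,
                   openings = list(list(center_direction = c(1, 0, 0),
                                        angular_radius = 0.35)))
  m <- make_shell_mesh(sp, resolution = 4)
  tess <- tessellate_mesh(m, 40, relax_iters = 5, rng_seed = 6,
                          openings = sp$openings)
  expect_true(any(tess$mesh$face_labels == 0L))
  expect_lt(tess$truth$sa_mm2, mesh_area(m))
  # labeled patch areas still partition the labeled surface exactly
  areas <- mesh_face_areas(tess$mesh)
  expect_equal(sum(tess$truth$scutes$patch_area_mm2),
               sum(areas[tess$mesh$face_labels > 0L]), tolerance = 1e-9)
})
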