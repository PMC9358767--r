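# Shared fixtures, memoized per test run. All fixtures are generated in code;
# nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, expr, envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# default carapace (370 scutes) tessellated at the resolution the topology
# examples need; reused by synth/morpho/allometry/acceptance tests
fx_tess370 <- function() {
  fixture("tess370", {
    spec <- shell_spec(rng_seed = 42)
    mesh <- make_shell_mesh(spec, resolution = 5)
    tess <- tessellate_mesh(mesh, spec$n_scutes, relax_iters = 10,
                            rng_seed = 42,
                            shell_thickness = spec$shell_thickness_mm)
    list(spec = spec, tess = tess)
  })
}

# small 120-scute shell with voxel phantom, segmentation and outer surface
fx_small_shell <- function() {
  fixture("small_shell", {
    spec <- shell_spec(20, 14, 12, boxiness = 6, shell_thickness_mm = 0.6,
                       n_scutes = 120, rng_seed = 3)
    mesh <- make_shell_mesh(spec, resolution = 5)
    tess <- tessellate_mesh(mesh, 120, relax_iters = 10, rng_seed = 3,
                            shell_thickness = spec$shell_thickness_mm)
    vox <- voxelize_labeled_shell(tess, spec, 0.2, valley_depth = 0.5)
    rag <- build_rag(vox$labels)
    surf <- extract_surface(vox$labels)
    list(spec = spec, tess = tess, vox = vox, rag = rag, surf = surf)
  })
}

# 6-scute near-cube phantom (thin-wall regime), sites at the face centers
fx_cube <- function() {
  fixture("cube6", {
    spec <- shell_spec(10, 10, 10, boxiness = 20, shell_thickness_mm = 0.2,
                       n_scutes = 12, rng_seed = 2)
    mesh <- suppressWarnings(make_shell_mesh(spec, resolution = 5))
    sites <- superellipsoid_project(
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
      c(5, 5, 5), 20)
    tess <- tessellate_mesh(mesh, 6, relax_iters = 0, rng_seed = 2,
                            shell_thickness = 0.2, sites = sites)
    vox <- voxelize_labeled_shell(tess, spec, 0.1, valley_depth = 0.5)
    rag <- build_rag(vox$labels)
    surf <- extract_surface(vox$labels)
    list(spec = spec, tess = tess, vox = vox, rag = rag, surf = surf)
  })
}

# shell with a mouth-like opening, for PBA sentinel behavior
fx_opening <- function() {
  fixture("opening_shell", {
    spec <- shell_spec(24, 16, 14, boxiness = 5, shell_thickness_mm = 0.6,
                       n_scutes = 80, rng_seed = 13,
                       openings = list(list(center_direction = c(1, 0, 0),
                                            angular_radius = 0.45)))
    mesh <- make_shell_mesh(spec, resolution = 5)
    tess <- tessellate_mesh(mesh, 80, relax_iters = 8, rng_seed = 13,
                            openings = spec$openings)
    adj <- mesh_face_adjacency(tess$mesh)
    la <- tess$mesh$face_labels[adj[, 1]]
    lb <- tess$mesh$face_labels[adj[, 2]]
    ring <- sort(unique(c(la[lb == 0L & la != 0L], lb[la == 0L & lb != 0L])))
    list(spec = spec, tess = tess, ring = ring)
  })
}

# --- analytic meshes for curvature oracles -------------------------------

grid_mesh <- function(xs, ys, zfun) {
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, zfun(g$x, g$y))
  nx <- length(xs)
  ny <- length(ys)
  f <- NULL
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    a <- (j - 1) * nx + i
    f <- rbind(f, c(a, a + 1, a + nx), c(a + 1, a + nx + 1, a + nx))
  }
  surface_mesh(v, f)
}

fx_plane_mesh <- function() {
  fixture("plane_mesh",
          grid_mesh(seq(-3, 3, 0.3), seq(-3, 3, 0.3),
                    function(x, y) rep(0, length(x))))
}

fx_saddle_mesh <- function() {
  # z = (x^2 - y^2) / 10: principal curvatures at origin +/- 0.2, K = -0.04
  fixture("saddle_mesh",
          grid_mesh(seq(-3, 3, 0.3), seq(-3, 3, 0.3),
                    function(x, y) (x^2 - y^2) / 10))
}

fx_cylinder_mesh <- function(r = 4) {
  fixture("cylinder_mesh", {
    th <- seq(0, 2 * pi, length.out = 121)[-121]
    z <- seq(-6, 6, length.out = 41)
    nth <- 120; nz <- 41
    v <- cbind(r * cos(rep(th, each = nz)), r * sin(rep(th, each = nz)),
               rep(z, nth))
    fid <- function(i, j) (i - 1) * nz + j
    f <- NULL
    for (i in 1:nth) for (j in 1:(nz - 1)) {
      i2 <- if (i == nth) 1 else i + 1
      f <- rbind(f, c(fid(i, j), fid(i2, j), fid(i, j + 1)),
                 c(fid(i2, j), fid(i2, j + 1), fid(i, j + 1)))
    }
    surface_mesh(v, f)
  })
}

fx_sphere_mesh <- function(r = 5) {
  fixture("sphere_mesh", {
    s <- icosphere(5)
    surface_mesh(s$vertices * r, s$faces)
  })
}

# --- independent oracles --------------------------------------------------

# Brute-force superellipsoid surface area: radial map from a fine lat-long
# sphere grid, triangulated and summed. Independent of the icosphere path
# used by make_shell_mesh.
se_area_oracle <- function(radii, p, n_th = 1000) {
  n_ph <- 2 * n_th
  th <- seq(0, pi, length.out = n_th)
  ph <- seq(0, 2 * pi, length.out = n_ph)
  st <- sin(th); ct <- cos(th)
  ux <- outer(st, cos(ph)); uy <- outer(st, sin(ph))
  uz <- matrix(ct, n_th, n_ph)
  f <- (abs(ux / radii[1])^p + abs(uy / radii[2])^p +
          abs(uz / radii[3])^p)^(1 / p)
  X <- ux / f; Y <- uy / f; Z <- uz / f
  tri <- function(ax, ay, az, bx, by, bz, cx, cy, cz) {
    ux <- bx - ax; uy <- by - ay; uz <- bz - az
    vx <- cx - ax; vy <- cy - ay; vz <- cz - az
    0.5 * sqrt((uy * vz - uz * vy)^2 + (uz * vx - ux * vz)^2 +
                 (ux * vy - uy * vx)^2)
  }
  i <- 1:(n_th - 1); j <- 1:(n_ph - 1)
  A <- function(M) M[i, j]; B <- function(M) M[i + 1, j]
  C <- function(M) M[i, j + 1]; D <- function(M) M[i + 1, j + 1]
  sum(tri(A(X), A(Y), A(Z), B(X), B(Y), B(Z), C(X), C(Y), C(Z))) +
    sum(tri(D(X), D(Y), D(Z), B(X), B(Y), B(Z), C(X), C(Y), C(Z)))
}

# hand-built regular hexagonal RAG patch: central scute 1 at unit pitch
hex_rag <- function(pitch = 1, transform = identity) {
  ctr <- rbind(c(0, 0, 0),
               t(sapply(0:5, function(k)
                 pitch * c(cos(k * pi / 3), sin(k * pi / 3), 0))))
  ctr <- transform(ctr)
  nb <- rbind(cbind(1L, 2:7), cbind(2:6, 3:7), c(7L, 2L))
  structure(list(
    nodes = data.frame(label = 1:7, cx = ctr[, 1], cy = ctr[, 2],
                       cz = ctr[, 3], n_voxels = NA_integer_),
    edges = data.frame(a = pmin(nb[, 1], nb[, 2]),
                       b = pmax(nb[, 1], nb[, 2]), contact_faces = 1L)),
    class = "rag")
}

# tiny 1D-style volume helper
vol1d <- function(intensities, spacing = 1) {
  intensity_volume(array(intensities, c(length(intensities), 1, 1)),
                   rep(spacing, 3))
}

neighbor_tally <- function(truth) {
  tabulate(c(truth$neighbors[, 1], truth$neighbors[, 2]),
           nrow(truth$scutes))
}
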