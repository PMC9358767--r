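## Synthetic carapace generation: superellipsoid shells tiled into scutes,
## rendered as labeled voxel phantoms with configurable suture valleys, plus
## ontogenetic series (isometric, allometric, table-only).

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# counter-based seed splitting: one sub-seed per specimen / per use, all
# derived from the single user-facing seed; kept well below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed %% 59999L) * 35729 + as.numeric(k) * 7919 +
                12345) %% 2147483629)
}

#' Specification of one synthetic carapace shell
#'
#' The shell is the region between an outer superellipsoid
#' `(|x/a|^p + |y/b|^p + |z/c|^p)^(1/p) = 1` (with `a = length/2` etc.) and
#' its inward offset by `shell_thickness_mm`. `boxiness` p interpolates from
#' an ellipsoid (p = 2) to a box (large p).
#'
#' @param length_mm,height_mm,width_mm positive carapace dimensions (mm);
#'   the default series keeps `length >= height >= width`.
#' @param boxiness superellipsoid exponent p, >= 2.
#' @param shell_thickness_mm positive wall thickness (mm).
#' @param n_scutes number of scutes to tile the shell into (>= 12).
#' @param openings list of `list(center_direction =, angular_radius =)`
#'   cones (direction length-3, radius in radians) cut out of the shell,
#'   emulating mouth/eye/fin openings; may be empty.
#' @param rng_seed integer seed governing all randomness downstream.
#' @return an object of class `shell_spec`.
#' @export
shell_spec <- function(length_mm = 30, height_mm = 20, width_mm = 18,
                       boxiness = 6, shell_thickness_mm = 0.8,
                       n_scutes = 370L, openings = list(), rng_seed = 1L) {
  dims <- c(length_mm, height_mm, width_mm)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("shell dimensions must be positive")
  if (!(length_mm >= height_mm && height_mm >= width_mm))
    warning("shell dimensions are not ordered length >= height >= width; ",
            "carapace axis identification by PCA may be ambiguous")
  if (!is.finite(boxiness) || boxiness < 2) stop("boxiness must be >= 2")
  if (!is.finite(shell_thickness_mm) || shell_thickness_mm <= 0)
    stop("shell_thickness_mm must be positive")
  n_scutes <- as.integer(n_scutes)
  if (n_scutes < 12L) stop("n_scutes must be >= 12")
  for (o in openings) {
    if (is.null(o$center_direction) || is.null(o$angular_radius) ||
        length(o$center_direction) != 3L || o$angular_radius <= 0)
      stop("each opening needs a length-3 center_direction and a positive angular_radius")
  }
  structure(list(length_mm = length_mm, height_mm = height_mm,
                 width_mm = width_mm, boxiness = boxiness,
                 shell_thickness_mm = shell_thickness_mm,
                 n_scutes = n_scutes, openings = openings,
                 rng_seed = as.integer(rng_seed)),
            class = "shell_spec")
}

shell_radii <- function(spec) {
  c(spec$length_mm, spec$height_mm, spec$width_mm) / 2
}

#' Radially project directions onto a superellipsoid surface
#'
#' Maps points (interpreted as directions from the origin) onto the surface
#' `(|x/r1|^p + |y/r2|^p + |z/r3|^p)^(1/p) = 1`.
#'
#' @param dirs n x 3 matrix of nonzero direction vectors.
#' @param radii length-3 semi-axes (mm).
#' @param p superellipsoid exponent.
#' @return n x 3 matrix of surface points.
#' @export
superellipsoid_project <- function(dirs, radii, p) {
  dirs <- dirs / sqrt(rowSums(dirs^2))
  f <- (abs(dirs[, 1] / radii[1])^p + abs(dirs[, 2] / radii[2])^p +
          abs(dirs[, 3] / radii[3])^p)^(1 / p)
  dirs / f
}

#' Build the closed outer shell surface of a spec
#'
#' Radially maps a subdivided icosahedron onto the outer superellipsoid.
#' The result is a closed, manifold, genus-0 triangle mesh with outward
#' normals, centered on the origin; openings are *not* cut here (they are
#' applied when tessellating / voxelizing).
#'
#' @param spec a [shell_spec()].
#' @param resolution icosphere subdivision level; vertex count is
#'   `10 * 4^resolution + 2`.
#' @return a `surface_mesh`.
#' @export
make_shell_mesh <- function(spec, resolution = 4) {
  stopifnot(inherits(spec, "shell_spec"))
  sph <- icosphere(resolution)
  v <- superellipsoid_project(sph$vertices, shell_radii(spec), spec$boxiness)
  mesh <- surface_mesh(v, sph$faces)
  if (!mesh_is_closed_manifold(mesh))
    stop("shell mesh is not a closed manifold")  # hard failure by contract
  if (mesh_euler(mesh) != 2L)
    stop("shell mesh is not genus 0 (Euler characteristic != 2)")
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# faces inside any opening cone (by centroid direction from the origin)
opening_faces <- function(mesh, openings) {
  if (length(openings) == 0L) return(integer(0))
  cen <- mesh_face_centroids(mesh)
  cen <- cen / sqrt(rowSums(cen^2))
  hit <- rep(FALSE, nrow(cen))
  for (o in openings) {
    d <- o$center_direction / sqrt(sum(o$center_direction^2))
    ang <- acos(pmin(1, pmax(-1, cen %*% d)))
    hit <- hit | (ang <= o$angular_radius)
  }
  which(hit)
}

#' Tile a closed shell mesh into scutes by surface Voronoi + Lloyd relaxation
#'
#' Sites are sampled area-uniformly on the (non-opening) surface; every face
#' is assigned to the Euclidean-nearest site, then each site moves to the
#' area-weighted centroid of its patch re-projected to the surface
#' (snapped to the nearest face centroid of the patch) for `relax_iters`
#' Lloyd steps. Patches are made edge-connected by reassigning detached
#' fragments to the neighboring patch sharing the most edges. Deterministic
#' for a fixed seed.
#'
#' @param mesh a closed `surface_mesh` (from [make_shell_mesh()]).
#' @param n_scutes number of tiles (>= 12).
#' @param relax_iters Lloyd relaxation steps (default 10).
#' @param rng_seed integer seed.
#' @param openings optional list of opening cones (see [shell_spec()]);
#'   faces inside an opening get label 0 and are excluded from the
#'   tessellation and the ground truth.
#' @param shell_thickness optional wall thickness (mm) used to fill in
#'   ground-truth scute volumes (patch area x thickness).
#' @param sites optional `n_scutes` x 3 matrix of initial site positions
#'   (world mm) overriding the random sampling; with `relax_iters = 0` this
#'   gives a fully prescribed tessellation.
#' @return a list with `mesh` (the input with `face_labels` 1..n_scutes, 0 on
#'   openings) and `truth`, a `ground_truth` object: per-scute table
#'   (`label`, `cx/cy/cz` center mm, `patch_area_mm2`, `volume_mm3`,
#'   `width_mm`, `thickness_mm`), symmetric `neighbors` pair matrix,
#'   specimen-level `sa_mm2` and `dims_mm`, and the final `sites`.
#' @export
tessellate_mesh <- function(mesh, n_scutes, relax_iters = 10, rng_seed = 1L,
                            openings = list(), shell_thickness = NA_real_,
                            sites = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n_scutes <- as.integer(n_scutes)
  if (n_scutes < 2L) stop("n_scutes must be >= 2")
  areas <- mesh_face_areas(mesh)
  cent <- mesh_face_centroids(mesh)
  open_f <- opening_faces(mesh, openings)
  allowed <- setdiff(seq_len(nrow(mesh$faces)), open_f)
  if (length(allowed) < n_scutes)
    stop("mesh resolution too coarse for the requested number of scutes")

  sample_site <- function() {
    f <- sample(allowed, 1L, prob = areas[allowed])
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    w <- runif(3); w <- w / sum(w)
    colSums(tri * w)
  }

  assign_faces <- function(sites) {
    d2 <- outer(rowSums(cent[allowed, , drop = FALSE]^2), rowSums(sites^2), "+") -
      2 * cent[allowed, , drop = FALSE] %*% t(sites)
    max.col(-d2, ties.method = "first")
  }

  if (!is.null(sites)) {
    sites <- matrix(as.numeric(sites), ncol = 3L)
    if (nrow(sites) != n_scutes) stop("need one site per scute")
  }
  with_seed(rng_seed, {
    if (is.null(sites))
      sites <- t(vapply(seq_len(n_scutes), function(i) sample_site(), numeric(3)))
    lab <- assign_faces(sites)
    for (it in seq_len(relax_iters)) {
      # resample any site that captured no face
      empty <- setdiff(seq_len(n_scutes), unique(lab))
      while (length(empty) > 0L) {
        warning(sprintf("%d tessellation site(s) captured no face; resampling",
                        length(empty)))
        for (s in empty) sites[s, ] <- sample_site()
        lab <- assign_faces(sites)
        empty <- setdiff(seq_len(n_scutes), unique(lab))
      }
      # Lloyd: area-weighted patch centroid, re-projected to the surface by
      # snapping to the nearest centroid of the patch's own faces
      for (s in seq_len(n_scutes)) {
        f <- allowed[lab == s]
        cw <- colSums(cent[f, , drop = FALSE] * areas[f]) / sum(areas[f])
        d2 <- rowSums(sweep(cent[f, , drop = FALSE], 2L, cw)^2)
        sites[s, ] <- cent[f[which.min(d2)], ]
      }
      lab <- assign_faces(sites)
    }
    empty <- setdiff(seq_len(n_scutes), unique(lab))
    while (length(empty) > 0L) {
      warning(sprintf("%d tessellation site(s) captured no face; resampling",
                      length(empty)))
      for (s in empty) sites[s, ] <- sample_site()
      lab <- assign_faces(sites)
      empty <- setdiff(seq_len(n_scutes), unique(lab))
    }

    face_labels <- integer(nrow(mesh$faces))
    face_labels[allowed] <- lab
    face_labels <- connect_patches(mesh, face_labels, areas)

    mesh$face_labels <- face_labels
    list(mesh = mesh,
         truth = ground_truth_from_labels(mesh, shell_thickness))
  })
}

# enforce edge-connected patches: reassign minor fragments of each label to
# the neighboring label sharing the most edges
connect_patches <- function(mesh, face_labels, areas) {
  adj <- mesh_face_adjacency(mesh)
  for (pass in 1:10) {
    changed <- FALSE
    for (s in setdiff(sort(unique(face_labels)), 0L)) {
      f <- which(face_labels == s)
      sub <- adj[face_labels[adj[, 1]] == s & face_labels[adj[, 2]] == s, ,
                 drop = FALSE]
      g <- igraph::graph_from_edgelist(
        matrix(match(as.vector(sub), f), ncol = 2), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, length(f) - igraph::vcount(g)))
      comp <- igraph::components(g)
      if (comp$no <= 1L) next
      main <- which.max(vapply(seq_len(comp$no), function(c)
        sum(areas[f[comp$membership == c]]), numeric(1)))
      for (c in setdiff(seq_len(comp$no), main)) {
        frag <- f[comp$membership == c]
        touching <- c(face_labels[adj[adj[, 1] %in% frag, 2]],
                      face_labels[adj[adj[, 2] %in% frag, 1]])
        touching <- touching[touching != s & touching != 0L]
        if (length(touching) == 0L) next
        face_labels[frag] <- as.integer(names(which.max(table(touching))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  face_labels
}

ground_truth_from_labels <- function(mesh, shell_thickness = NA_real_) {
  areas <- mesh_face_areas(mesh)
  cent <- mesh_face_centroids(mesh)
  lab <- mesh$face_labels
  ids <- setdiff(sort(unique(lab)), 0L)
  patch_area <- vapply(ids, function(s) sum(areas[lab == s]), numeric(1))
  centers <- t(vapply(ids, function(s) {
    f <- lab == s
    colSums(cent[f, , drop = FALSE] * areas[f]) / sum(areas[f])
  }, numeric(3)))
  adj <- mesh_face_adjacency(mesh)
  la <- lab[adj[, 1]]; lb <- lab[adj[, 2]]
  keep <- la != lb & la != 0L & lb != 0L
  nb <- unique(cbind(pmin(la[keep], lb[keep]), pmax(la[keep], lb[keep])))
  scutes <- data.frame(label = ids,
                       cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                       patch_area_mm2 = patch_area,
                       volume_mm3 = patch_area * shell_thickness,
                       width_mm = 2 * sqrt(patch_area / pi),
                       thickness_mm = shell_thickness)
  v <- mesh$vertices
  structure(list(scutes = scutes, neighbors = nb,
                 sa_mm2 = sum(patch_area),
                 dims_mm = apply(v, 2, function(x) diff(range(x))),
                 sites = centers),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d scutes, SA %.4g mm^2, dims %s mm\n",
              nrow(x$scutes), x$sa_mm2,
              paste(signif(x$dims_mm, 4), collapse = " x ")))
  invisible(x)
}

#' Render a tessellated shell as intensity + label voxel phantoms
#'
#' The label field marks every voxel whose center lies in the shell wall
#' (between the outer superellipsoid and its inward offset by the shell
#' thickness) with the label of the scute whose ground-truth center is
#' nearest. The intensity volume is a high plateau inside scutes, dipping by
#' `valley_depth * plateau` in the 1-voxel band along inter-scute
#' boundaries, 0 in the background, with additive Gaussian noise.
#' `valley_depth = 0` produces no suture valleys (the hard case for plain
#' intensity-ordered propagation). One seed per scute is placed at the
#' foreground voxel nearest the scute's ground-truth center.
#'
#' @param tess result of [tessellate_mesh()] (labeled mesh + ground truth).
#' @param spec the [shell_spec()] the mesh was built from.
#' @param voxel_spacing_mm isotropic voxel spacing; must satisfy
#'   `shell_thickness_mm >= 2 * spacing`.
#' @param valley_depth suture valley depth in `[0, 1]`.
#' @param plateau foreground intensity plateau (default 200).
#' @param noise_sd additive Gaussian noise sd (default 5).
#' @param rng_seed seed for the noise (default: the spec's seed + 1).
#' @return list with `intensity` (`intensity_volume`), `labels`
#'   (`label_field`) and `seeds` (`seed_set`).
#' @export
voxelize_labeled_shell <- function(tess, spec, voxel_spacing_mm,
                                   valley_depth = 0.5, plateau = 200,
                                   noise_sd = 5, rng_seed = NULL) {
  stopifnot(inherits(spec, "shell_spec"))
  if (valley_depth < 0 || valley_depth > 1)
    stop("valley_depth must be in [0, 1]")
  sp <- as.numeric(voxel_spacing_mm)
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  if (spec$shell_thickness_mm < 2 * max(sp))
    stop(sprintf(
      "voxel spacing too coarse: shell thickness %.3g mm needs spacing <= %.3g mm",
      spec$shell_thickness_mm, spec$shell_thickness_mm / 2))
  if (is.null(rng_seed)) rng_seed <- sub_seed(spec$rng_seed, 1L)

  radii <- shell_radii(spec)
  pad <- 2 * sp
  lo <- -radii - pad
  hi <- radii + pad
  dims <- as.integer(ceiling((hi - lo) / sp))
  origin <- lo

  support <- .shell_support_cpp(dims, sp, origin, c(0, 0, 0), radii,
                                spec$boxiness, spec$shell_thickness_mm)
  fg <- which(support == 1L)

  if (length(spec$openings) > 0L && length(fg) > 0L) {
    w <- voxel_centers(list(data = array(0L, dims), spacing = sp,
                            origin = origin), fg)
    dirs <- w / sqrt(rowSums(w^2))
    drop <- rep(FALSE, length(fg))
    for (o in spec$openings) {
      d <- o$center_direction / sqrt(sum(o$center_direction^2))
      drop <- drop | acos(pmin(1, pmax(-1, dirs %*% d))) <= o$angular_radius
    }
    support[fg[drop]] <- 0L
    fg <- which(support == 1L)
  }
  if (length(fg) == 0L) stop("voxelization produced an empty shell")

  sites <- as.matrix(tess$truth$scutes[, c("cx", "cy", "cz")])
  lab_fg <- .nearest_site_cpp(fg, dims, sp, origin, sites,
                              tess$truth$scutes$label)
  labarr <- array(0L, dims)
  labarr[fg] <- lab_fg
  labels <- label_field(labarr, sp, origin)

  # 1-voxel suture band: foreground voxels with a 6-neighbor of a different
  # nonzero label
  band <- boundary_band(labarr)
  intens <- array(0, dims)
  intens[fg] <- plateau
  intens[band] <- plateau * (1 - valley_depth)
  if (noise_sd > 0)
    intens <- intens + with_seed(rng_seed,
      array(rnorm(prod(dims), 0, noise_sd), dims))
  intensity <- intensity_volume(intens, sp, origin)

  # one landmark per scute: the ground-truth center, clamped minimally into
  # the nearest foreground voxel of its own label so that the seed is
  # guaranteed to lie inside the mask (mirrors a landmark placed on the
  # rendered surface)
  centers_vox <- voxel_centers(labels, fg)
  seed_xyz <- matrix(0, nrow(sites), 3L)
  eps <- 1e-6
  for (s in seq_len(nrow(sites))) {
    cand <- which(lab_fg == tess$truth$scutes$label[s])
    d2 <- rowSums(sweep(centers_vox[cand, , drop = FALSE], 2L, sites[s, ])^2)
    vc <- centers_vox[cand[which.min(d2)], ]
    lo <- vc - sp / 2 + eps
    hi <- vc + sp / 2 - eps
    seed_xyz[s, ] <- pmin(pmax(sites[s, ], lo), hi)
  }
  seeds <- seed_set(tess$truth$scutes$label, seed_xyz)
  list(intensity = intensity, labels = labels, seeds = seeds)
}

# linear indices of foreground voxels 6-adjacent to a different nonzero label
boundary_band <- function(labarr) {
  d <- dim(labarr)
  band <- array(FALSE, d)
  shift_cmp <- function(axis) {
    n <- d[axis]
    idx_a <- lapply(d, seq_len)
    idx_b <- idx_a
    idx_a[[axis]] <- 1:(n - 1)
    idx_b[[axis]] <- 2:n
    a <- do.call(`[`, c(list(labarr), idx_a))
    b <- do.call(`[`, c(list(labarr), idx_b))
    diffm <- a != b & a != 0L & b != 0L
    ba <- array(FALSE, d)
    bb <- array(FALSE, d)
    ba <- do.call(`[<-`, c(list(ba), idx_a, list(diffm)))
    bb <- do.call(`[<-`, c(list(bb), idx_b, list(diffm)))
    ba | bb
  }
  for (axis in 1:3) band <- band | shift_cmp(axis)
  which(band)
}

#' Specification of a synthetic ontogenetic series
#'
#' @param n_specimens number of specimens (default 13, as in an ontogenetic
#'   museum series).
#' @param scale_factors monotone increasing linear scale factors; default
#'   spans 8.5x (the documented ontogenetic size range), geometrically
#'   spaced. Mutually exclusive with `sa_values`.
#' @param sa_values optional monotone increasing surface areas (mm^2)
#'   overriding `scale_factors` in table-only mode.
#' @param mode `"isometric"` (uniform scaling of one tessellated template),
#'   `"allometric"` (per-specimen shells with dimensions scaled by the
#'   exponents) or `"table_only"` (analytic per-specimen summary rows, no
#'   geometry).
#' @param exponents named list of scaling exponents vs SA:
#'   `b_length`, `b_height`, `b_width` (linear carapace dimensions),
#'   `b_scute_volume`, `b_scute_thickness`, `b_scute_width`, `b_scute_pba`.
#'   Ignored (forced to the isometric values 0.5/0.5/0.5/1.5/0.5/0.5/1.0) in
#'   isometric mode.
#' @param noise_sd lognormal noise sd on table-only rows (default 0).
#' @param rng_seed integer seed.
#' @return an object of class `series_spec`.
#' @export
series_spec <- function(n_specimens = 13L, scale_factors = NULL,
                        sa_values = NULL,
                        mode = c("isometric", "allometric", "table_only"),
                        exponents = list(), noise_sd = 0, rng_seed = 1L) {
  mode <- match.arg(mode)
  n_specimens <- as.integer(n_specimens)
  if (is.null(scale_factors) && is.null(sa_values))
    scale_factors <- exp(seq(0, log(8.5), length.out = n_specimens))
  if (!is.null(scale_factors)) {
    if (any(diff(scale_factors) <= 0))
      stop("scale_factors must be strictly increasing")
    n_specimens <- length(scale_factors)
    if (max(scale_factors) / min(scale_factors) < 8)
      warning("scale factor range below 8x; ontogenetic span is narrower ",
              "than the series this emulates")
  }
  if (!is.null(sa_values)) {
    if (any(diff(sa_values) <= 0)) stop("sa_values must be strictly increasing")
    n_specimens <- length(sa_values)
  }
  iso <- list(b_length = 0.5, b_height = 0.5, b_width = 0.5,
              b_scute_volume = 1.5, b_scute_thickness = 0.5,
              b_scute_width = 0.5, b_scute_pba = 1.0)
  if (mode == "isometric") {
    exponents <- iso
  } else {
    exponents <- utils::modifyList(iso, exponents)
  }
  b <- exponents
  # ordering check: at large sizes length must stay >= height >= width when
  # the base shape is ordered
  if (mode != "isometric" &&
      (b$b_height > b$b_length || b$b_width > b$b_length))
    warning("height/width exponent exceeds length exponent; dimension ",
            "ordering may invert at large sizes")
  structure(list(n_specimens = n_specimens, scale_factors = scale_factors,
                 sa_values = sa_values, mode = mode, exponents = exponents,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "series_spec")
}

#' Generate a synthetic ontogenetic series
#'
#' In `isometric` mode one template shell is tessellated once and scaled
#' uniformly, so scute count, tessellation topology and all normalized
#' quantities are identical across specimens. In `allometric` mode each
#' specimen gets its own `shell_spec` with dimensions
#' `base_dim * (SA/SA_1)^b` and is tessellated independently (per-specimen
#' sub-seeds). In `table_only` mode per-specimen summary rows are computed
#' analytically from the exponents (optionally with lognormal noise) without
#' building any geometry.
#'
#' @param series a [series_spec()].
#' @param base_spec a [shell_spec()] for the smallest specimen.
#' @param resolution mesh resolution passed to [make_shell_mesh()].
#' @param relax_iters Lloyd iterations for tessellation.
#' @param voxel_spacing_mm optional; if given in geometric modes, each
#'   specimen is also voxelized at this spacing (isotropic mm).
#' @param valley_depth,noise_sd_intensity passed to
#'   [voxelize_labeled_shell()].
#' @return an object of class `scute_series`: list with `mode`, `table`
#'   (one summary row per specimen: `specimen`, `sa_mm2`, `length_mm`,
#'   `height_mm`, `width_mm`, `n_scutes`, `med_volume_mm3`, `med_pba_mm2`,
#'   `med_thickness_mm`, `med_width_mm`) and, in geometric modes,
#'   `specimens`: per-specimen lists with `mesh`, `truth` and (if voxelized)
#'   `intensity`, `labels`, `seeds`.
#' @export
generate_series <- function(series, base_spec = shell_spec(),
                            resolution = 4, relax_iters = 10,
                            voxel_spacing_mm = NULL, valley_depth = 0.5,
                            noise_sd_intensity = 5) {
  stopifnot(inherits(series, "series_spec"))
  b <- series$exponents
  if (series$mode == "table_only") {
    sa1 <- if (!is.null(series$sa_values)) series$sa_values[1] else {
      # analytic SA is not needed; any base constant works for a power law
      600
    }
    sa <- if (!is.null(series$sa_values)) series$sa_values
    else sa1 * series$scale_factors^2
    r <- sa / sa[1]
    base <- list(length = base_spec$length_mm, height = base_spec$height_mm,
                 width = base_spec$width_mm,
                 vol = base_spec$shell_thickness_mm * sa[1] / base_spec$n_scutes,
                 pba = sa[1] / base_spec$n_scutes,
                 thick = base_spec$shell_thickness_mm,
                 wid = 2 * sqrt(sa[1] / base_spec$n_scutes / pi))
    tab <- data.frame(
      specimen = seq_along(sa),
      sa_mm2 = sa,
      length_mm = base$length * r^b$b_length,
      height_mm = base$height * r^b$b_height,
      width_mm = base$width * r^b$b_width,
      n_scutes = rep(base_spec$n_scutes, length(sa)),
      med_volume_mm3 = base$vol * r^b$b_scute_volume,
      med_pba_mm2 = base$pba * r^b$b_scute_pba,
      med_thickness_mm = base$thick * r^b$b_scute_thickness,
      med_width_mm = base$wid * r^b$b_scute_width)
    if (series$noise_sd > 0) {
      cols <- setdiff(names(tab), c("specimen", "sa_mm2", "n_scutes"))
      tab[cols] <- with_seed(series$rng_seed, {
        lapply(tab[cols], function(x)
          x * exp(rnorm(length(x), 0, series$noise_sd)))
      })
    }
    return(structure(list(mode = "table_only", table = tab,
                          specimens = NULL, series = series),
                     class = "scute_series"))
  }

  f <- series$scale_factors
  specimens <- vector("list", length(f))
  if (series$mode == "isometric") {
    mesh <- make_shell_mesh(base_spec, resolution)
    tess <- tessellate_mesh(mesh, base_spec$n_scutes, relax_iters,
                            rng_seed = sub_seed(base_spec$rng_seed, 0L),
                            openings = base_spec$openings,
                            shell_thickness = base_spec$shell_thickness_mm)
    for (i in seq_along(f)) {
      s <- f[i]
      spec_i <- shell_spec(base_spec$length_mm * s, base_spec$height_mm * s,
                           base_spec$width_mm * s, base_spec$boxiness,
                           base_spec$shell_thickness_mm * s,
                           base_spec$n_scutes, base_spec$openings,
                           sub_seed(series$rng_seed, i))
      tess_i <- scale_tessellation(tess, s)
      specimens[[i]] <- c(list(spec = spec_i), tess_i)
    }
  } else {  # allometric
    r <- f^2  # SA ratio proxy under near-uniform scaling
    for (i in seq_along(f)) {
      spec_i <- shell_spec(
        base_spec$length_mm * r[i]^b$b_length / 1,
        base_spec$height_mm * r[i]^b$b_height,
        base_spec$width_mm * r[i]^b$b_width,
        # body becomes boxier with size, as in the ontogeny this emulates
        boxiness = base_spec$boxiness * (1 + 0.3 * (i - 1) / max(1, length(f) - 1)),
        shell_thickness_mm = base_spec$shell_thickness_mm * r[i]^b$b_scute_thickness,
        n_scutes = base_spec$n_scutes, openings = base_spec$openings,
        rng_seed = sub_seed(series$rng_seed, i))
      mesh_i <- make_shell_mesh(spec_i, resolution)
      specimens[[i]] <- c(list(spec = spec_i),
                          tessellate_mesh(mesh_i, spec_i$n_scutes, relax_iters,
                                          rng_seed = spec_i$rng_seed,
                                          openings = spec_i$openings,
                                          shell_thickness = spec_i$shell_thickness_mm))
    }
  }

  if (!is.null(voxel_spacing_mm)) {
    for (i in seq_along(specimens)) {
      vox <- voxelize_labeled_shell(specimens[[i]][c("mesh", "truth")],
                                    specimens[[i]]$spec, voxel_spacing_mm,
                                    valley_depth = valley_depth,
                                    noise_sd = noise_sd_intensity)
      specimens[[i]] <- c(specimens[[i]], vox)
    }
  }

  tab <- do.call(rbind, lapply(seq_along(specimens), function(i) {
    tr <- specimens[[i]]$truth
    data.frame(specimen = i, sa_mm2 = tr$sa_mm2,
               length_mm = tr$dims_mm[1], height_mm = tr$dims_mm[2],
               width_mm = tr$dims_mm[3], n_scutes = nrow(tr$scutes),
               med_volume_mm3 = median(tr$scutes$volume_mm3),
               med_pba_mm2 = median(tr$scutes$patch_area_mm2),
               med_thickness_mm = median(tr$scutes$thickness_mm),
               med_width_mm = median(tr$scutes$width_mm))
  }))
  structure(list(mode = series$mode, table = tab, specimens = specimens,
                 series = series),
            class = "scute_series")
}

# uniform scaling of a tessellated template (exact similarity transform)
scale_tessellation <- function(tess, s) {
  mesh <- tess$mesh
  mesh$vertices <- mesh$vertices * s
  tr <- tess$truth
  tr$scutes$cx <- tr$scutes$cx * s
  tr$scutes$cy <- tr$scutes$cy * s
  tr$scutes$cz <- tr$scutes$cz * s
  tr$scutes$patch_area_mm2 <- tr$scutes$patch_area_mm2 * s^2
  tr$scutes$volume_mm3 <- tr$scutes$volume_mm3 * s^3
  tr$scutes$width_mm <- tr$scutes$width_mm * s
  tr$scutes$thickness_mm <- tr$scutes$thickness_mm * s
  tr$sa_mm2 <- tr$sa_mm2 * s^2
  tr$dims_mm <- tr$dims_mm * s
  tr$sites <- tr$sites * s
  list(mesh = mesh, truth = tr)
}

#' Write the ground truth of a tessellation to CSV
#' @param truth a `ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth$scutes, path, row.names = FALSE)
  invisible(path)
}
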