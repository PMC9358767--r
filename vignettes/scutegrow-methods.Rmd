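---
title: "scutegrow: models, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scutegrow: models, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scutegrow` studies how a tessellated armor — a closed shell of abutting
mineralized plates (scutes), as in boxfish carapaces — changes across an
ontogenetic size series. This vignette is the package's own account of the
science: what is modeled, which knobs matter, what the synthetic data do and
do not emulate, and where the design was genuinely open.

## 1. The synthetic world

### Shape family

Real carapaces range from near-spherical juveniles to box-like adults. We
model the outer surface as a superellipsoid
$$\left(\left|\tfrac{x}{a}\right|^p + \left|\tfrac{y}{b}\right|^p +
\left|\tfrac{z}{c}\right|^p\right)^{1/p} = 1,$$
with semi-axes $a = L/2 \ge b = H/2 \ge c = W/2$ and a "boxiness" exponent
$p \ge 2$ ($p = 2$ ellipsoid, $p \to \infty$ box). This is the minimal
parametric family spanning sphere → box; it is a *stand-in*, not a claim
about cowfish geometry. In allometric series mode $p$ increases mildly with
size to emulate the documented drift from rounded to cuboid body form. The
shell wall is the region between the outer surface and its inward offset by
`shell_thickness_mm` (an offset of the semi-axes; exact on box faces,
slightly thinner along edges).

Defaults are chosen once for a mid-series specimen and not revisited:
$L \times H \times W = 30 \times 20 \times 18$ mm, $p = 6$, wall 0.8 mm,
370 scutes (the documented per-animal average; the real series spans roughly
354–397). Series defaults span 8.5× in linear scale over 13 specimens,
geometrically spaced, matching the ontogenetic design this emulates.

### Tessellation

`tessellate_mesh()` tiles the triangulated shell (a subdivided icosahedron
radially mapped onto the superellipsoid) by surface Voronoi: `n_scutes`
sites sampled area-uniformly, every face assigned to the Euclidean-nearest
site (face centroids vs sites — Euclidean rather than geodesic distance,
adequate for convex shells and $O(Fn)$), then Lloyd relaxation: each site
moves to the area-weighted centroid of its patch, re-projected to the
surface by snapping to the nearest face centroid of that patch. Ten
iterations produce the neighbor statistics seen on real carapaces: modal
neighbor count 6 with the ordering 6 > 5 > 7, and mean neighbor count
strictly below 6 as Euler's formula requires on a genus-0 tiling
(mean $= 6 - 12/n$ for an ideal polygonal tiling). Empty cells are
re-sampled with a warning; patches are forced edge-connected by reassigning
detached fragments to the neighbor sharing the most edges.

A practical note on resolution: neighbor topology is only as good as the
triangulation. Below ~50 faces per scute, patch adjacency degrades (missing
RAG edges); the topology tests and acceptance phantoms use icosphere level 5
(20,480 faces) for 120–370 scutes.

### Voxel phantom

`voxelize_labeled_shell()` renders the labeled shell on an isotropic grid
(voxel-center convention: voxel $(i,j,k)$ sits at
`origin + (i+1/2, j+1/2, k+1/2) * spacing`). Ground-truth voxel labels are
defined as *nearest scute center* (Voronoi of patch centroids) — our
concrete reading of "label of the nearest surface patch". The intensity
model is deliberately minimal: plateau 200 inside scutes, a 1-voxel suture
band dipping by `valley_depth × plateau` at inter-scute boundaries,
background 0, additive Gaussian noise (sd 5). `valley_depth = 0` produces
the degenerate case in which no intensity valley separates neighboring
scutes — the regime that motivates distance-modified propagation.

Seeds (landmarks) are emitted at the true scute center, clamped minimally
into the nearest foreground voxel of that scute: landmarks live on the
rendered surface, not on the voxel lattice. This matters quantitatively —
quantizing landmarks to voxel centers costs ~2 percentage points of voxel
agreement on the default phantom because the propagation's distance prior
then disagrees with the ground-truth Voronoi seed.

### What a green test does not establish

The phantom has uniform plateau intensity, perfectly closed geometry,
synthetic noise, and ground-truth landmarks. Real microCT adds beam
hardening, intensity gradients within and between scutes, partial-volume
effects at thin walls, imperfect manual landmarks and non-carapace
structures. Green segmentation tests establish that the algorithm contract
is implemented correctly and that the distance modification dominates plain
intensity ordering *in the stated world*; they do not certify accuracy on
real scans.

## 2. Segmentation

`propagate_contours()` is multi-source best-first growth over the
thresholded mask: one global max-priority queue of frontier voxels
(6-connected; face adjacency prevents diagonal tunneling through suture
bands), priority $I(v)$ in plain mode or $I(v)/\max(d, d_{\min})$ in
distance-modified mode. The distance $d$ is measured to the *candidate
region's own landmark* (the description of the original tool is ambiguous
between this and the nearest landmark; the candidate reading makes the
modification act as a seeded-distance prior and is the default, with
`distance_ref = "nearest"` available). The floor $d_{\min}$ is the smallest
voxel spacing, avoiding division by zero at the seed. Ties are broken by
(lower candidate label, lower linear voxel index) so output is fully
deterministic. Regions never cross the background.

Thresholding uses `tau = 50` on default phantoms: it must separate the
background (0 ± 5) from the suture valley floor (100 at valley depth 0.5),
not from the plateau — a threshold at the valley level erodes the suture
band and caps achievable agreement.

Split and merge are batch operations (id lists in config) replacing
interactive editing: merge groups must be RAG-connected and are relabeled to
their smallest id with subsequent compaction; split re-runs propagation
restricted to the target label with two seeds.

`extract_surface()` contours the binary foreground at 0.5 by marching
tetrahedra after light 1-2-1 smoothing (two passes). Smoothing is what makes
mesh area converge to the smooth surface area instead of the voxel
staircase area (a 20-voxel ball reproduces $4\pi r^2$ within 0.5%). Only the
largest closed component by area is kept, which discards the internal cavity
wall of a hollow shell; normals are oriented outward via the signed volume.

## 3. Morphometrics

Per scute: (1) neighbor count = RAG degree; (2) volume = voxel count ×
voxel volume; (3) plane-based area (PBA): the scute's neighbors are ordered
angularly about its center in the plane orthogonal to the local outward
direction (taken as the normal of the total-least-squares plane through the
neighbor ring — robust also for flat patches); consecutive neighbor pairs
contribute fan nodes (triangle centroid if the pair is RAG-adjacent, quad
centroid via the unique bridging common neighbor otherwise); an incomplete
fan — the scute borders a carapace opening — yields the sentinel −1000
exactly, which removes the scute from PBA analyses; otherwise the fan nodes'
TLS plane is translated to contain the scute center, nodes are projected,
and the shoelace area is returned. (4, 5) thickness and width are the
smallest and largest extents of the principal-axes bounding cuboid of the
scute's voxel coordinates, each extent padded by the spacing resolved along
that axis so one-voxel-thin scutes get thickness = spacing (PCA axes are a
deterministic, fast stand-in for the exact minimum-volume box — flagged, not
interchangeable near-degenerate shapes). (6, 7) Gaussian and mean curvature
come from a least-squares quadric fit
$h(u,v) = \tfrac12(au^2 + 2buv + cv^2) + du + ev$ over mesh vertices within
a radius of the scute center, in the tangent frame of their average outward
normal; principal curvatures are eigenvalues of the shape operator of the
fit, signed so an outward-bulging (convex) surface has $H > 0$; sphere-like
regions have $K > 0$, saddles $K < 0$.

The curvature neighborhood radius is `0.75 * sqrt(median PBA)` of the
specimen (configurable multiplier). Tying the smoothing scale to the median
scute size makes $K$ and $H$ scale-covariant, so the normalized $K\cdot SA$
and $H\cdot\sqrt{SA}$ are size-free — the property the normalization
presumes. The reference tool's "surface field" construction is undocumented;
our quadric fit is validated only against analytic solids (plane, sphere,
cylinder, saddle, all within 5%).

Normalizations: volume/SA^{3/2}, PBA/SA, thickness and width/SA^{1/2},
$K \cdot SA$, $H \cdot \sqrt{SA}$; sentinel PBA rows are excluded (NA).

## 4. Allometry

Carapace length, height and width are the score ranges along PC1–PC3 of the
scute centers (covariance PCA; PC sign indeterminacy is irrelevant because
ranges are sign-invariant). Scaling fits are OLS of $\ln y$ on $\ln SA$ with
t-based 95% CIs; isometry references are 0.5 / 1.0 / 1.5 for linear / area /
volume variables. Scute count is fitted by a Poisson GLM with log link and
*untransformed* SA as covariate — the source describes a log transform for
the dimension regressions but not for the count model, so raw SA is the
default (configurable); the reported slope is $\exp(\beta_1)$, the
multiplicative change in expected count per unit SA, with the exponentiated
Wald CI. SA enters the GLM in cm² by default so that slope magnitudes sit in
the ~1.000x regime; the unit is recorded in the fit metadata. Medians of an
even number of scutes are the mean of the two central order statistics;
box summaries use type-7 interpolated quartiles.

## 5. Numerical choices and degenerate inputs

* All randomness flows from one integer seed through a counter-based
  splitting rule (one sub-seed per specimen); identical spec + seed gives
  bit-identical outputs, including across pipeline re-runs (hash-stable
  manifest).
* Voxelization requires `shell_thickness >= 2 * spacing` and errors naming
  the minimum feasible spacing.
* Scutes with fewer than 3 neighbors cannot form a fan → PBA sentinel.
  Single-voxel scutes warn and report thickness = width = spacing.
* Fewer than 6 vertices in a curvature neighborhood is an error
  ("insufficient support"); in batch statistics it degrades to NA with a
  warning instead of failing the specimen.
* PCA eigenvalue ratios below 1.01 trigger an "axis identity ambiguous"
  warning (a sphere has no defined length axis).
* A superellipsoid at $p = 20$ has surface area 22.666 for unit semi-axes —
  about 6% below the 24 of a true cube; area oracles integrate the actual
  superellipsoid (via a fine radial-map triangulation) rather than assuming
  the box limit.

## 6. Scaled-down acceptance phantoms

Acceptance thresholds are asserted exactly as stated, but simulations are
desk-scale: the 370-scute segmentation phantom uses the default 30 mm shell
at 0.15 mm spacing (~0.6M foreground voxels) rather than a full-size scan,
and the end-to-end isometric series uses 5 specimens of 120 scutes at
0.25 mm spacing spanning 2.6×. Ground-truth-table oracles are exact at any
scale, so the isometry slopes (0.5/1.0/1.5) are machine-precision
regardless.

## 7. Known limitations

* No scute ultrastructure (radial struts, sutural interdigitation, mineral
  density), no fins/eyes/gills, no beam-hardening artifacts.
* Euclidean (not geodesic) distances throughout — appropriate for convex
  shells, increasingly wrong for strongly concave regions around real
  openings.
* The real-data path reads NRRD and MHD/RAW volumes; TIFF stacks are not
  supported (no TIFF reader among the package's allowed dependencies).
* Config files are JSON canonically; YAML is accepted only when the yaml
  package is installed.
* PCA bounding cuboids can differ from minimum-volume boxes for L-shaped or
  strongly curved scutes; thickness is then biased upward.
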