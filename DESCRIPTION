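Package: scutegrow
Title: Synthetic Tessellated Carapaces, Seeded Scute Segmentation and
    Allometric Scaling of Boxfish Armor
Version: 0.1.0
Authors@R: person("scutegrow", "developers", role = c("aut", "cre"),
    email = "scutegrow@example.org")
Description: Tools for studying the ontogeny of tessellated natural armor
    such as the boxfish carapace, a nearly closed shell of several hundred
    polygonal mineralized plates (scutes). Provides a synthetic-data
    generator for box-like superellipsoid shells tiled into scutes and
    rendered as labeled voxel phantoms with configurable inter-scute
    intensity valleys; seed-based contour propagation segmentation of 3D
    intensity volumes (plain and distance-modified priorities) with region
    adjacency graphs and batch split/merge editing; per-scute morphometrics
    (neighbor counts, volume, plane-based area, bounding-cuboid thickness
    and width, Gaussian and mean surface curvature) with size
    normalizations; and allometric scaling analyses of ontogenetic series
    (PCA carapace dimensions, log-log regressions with confidence
    intervals, Poisson count regression). A pipeline layer and command-line
    interface orchestrate generate, segment, measure and scale stages
    reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
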