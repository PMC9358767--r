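#' 3D intensity volumes and label fields
#'
#' `intensity_volume()` wraps a 3D numeric array of grayscale values together
#' with its spatial frame (voxel spacing and origin, both in mm).
#' `label_field()` does the same for a 3D array of non-negative integer scute
#' labels (0 = background) sharing the frame of its source volume.
#'
#' World coordinates follow the voxel-center convention: the center of voxel
#' (i, j, k) (0-based) sits at `origin + (i + 0.5, j + 0.5, k + 0.5) * spacing`.
#'
#' @param data 3D array (numeric for intensities, integers >= 0 for labels).
#' @param spacing length-3 positive numeric, voxel spacing in mm.
#' @param origin length-3 numeric, corner of voxel (0,0,0) in mm.
#' @return An object of class `intensity_volume` or `label_field`: a list with
#'   elements `data`, `spacing`, `origin`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || length(data) == 0L)
    stop("intensity data must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "intensity_volume")
}

#' @rdname intensity_volume
#' @export
label_field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || length(data) == 0L)
    stop("label data must be a non-empty 3D array")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("labels must be non-negative integers")
  v <- intensity_volume(data, spacing, origin)
  class(v) <- "label_field"
  v
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.label_field <- print.intensity_volume

same_frame <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of voxel centers
#'
#' @param vol an `intensity_volume` or `label_field`.
#' @param linear_index optional 1-based linear indices into the array; default
#'   all voxels.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_centers <- function(vol, linear_index = NULL) {
  d <- dim(vol$data)
  if (is.null(linear_index)) linear_index <- seq_len(prod(d))
  idx <- arrayInd(linear_index, d) - 1L   # 0-based (i, j, k)
  sweep(sweep(idx + 0.5, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' Map world coordinates to 1-based voxel array indices
#'
#' Points are snapped to the voxel whose center is nearest (floor of the
#' continuous index); out-of-grid points raise an error.
#'
#' @param vol an `intensity_volume` or `label_field`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 integer matrix of 1-based array indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  d <- dim(vol$data)
  idx <- floor(sweep(sweep(xyz, 2L, vol$origin, "-"), 2L, vol$spacing, "/")) + 1
  if (any(idx < 1) || any(sweep(idx, 2L, d, ">")))
    stop("world coordinates outside the voxel grid")
  storage.mode(idx) <- "integer"
  idx
}

voxel_to_linear <- function(vol, ijk) {
  d <- dim(vol$data)
  as.integer(ijk[, 1] + (ijk[, 2] - 1) * d[1] + (ijk[, 3] - 1) * d[1] * d[2])
}

## ---------------------------------------------------------------------------
## NRRD IO (minimal dialect: 3D, raw little-endian encoding)
## ---------------------------------------------------------------------------

#' Read and write volumes as NRRD
#'
#' A minimal NRRD implementation covering what the package emits: 3D arrays,
#' `raw` encoding, little-endian, `double`/`float`/unsigned integer types,
#' with `space directions` carrying the voxel spacing and `space origin` the
#' frame origin. Sufficient for round-tripping pipeline artifacts; not a
#' general NRRD parser.
#'
#' @param vol an `intensity_volume` or `label_field`.
#' @param path file path ending in `.nrrd`.
#' @param type one of `"double"`, `"float"`, `"uint32"`, `"uint16"`, `"uint8"`.
#' @return `read_nrrd()` returns an `intensity_volume` (or a `label_field`
#'   when the on-disk type is an unsigned integer).
#' @export
write_nrrd <- function(vol, path, type = if (inherits(vol, "label_field")) "uint32" else "float") {
  d <- dim(vol$data)
  typemap <- c(double = "double", float = "float",
               uint32 = "unsigned int", uint16 = "unsigned short",
               uint8 = "unsigned char")
  if (!type %in% names(typemap)) stop("unsupported NRRD type: ", type)
  hdr <- c("NRRD0004",
           "# generated by scutegrow (voxel-center convention; lengths in mm)",
           paste0("type: ", typemap[[type]]),
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("space directions: (", vol$spacing[1], ",0,0) (0,",
                  vol$spacing[2], ",0) (0,0,", vol$spacing[3], ")"),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           paste0("space origin: (", paste(vol$origin, collapse = ","), ")"),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  x <- as.vector(vol$data)
  size <- switch(type, double = 8L, float = 4L, uint32 = 4L, uint16 = 2L, uint8 = 1L)
  if (type %in% c("double", "float")) {
    writeBin(as.double(x), con, size = size, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported")
  type <- fields[["type"]]
  if (!is.null(fields[["encoding"]]) && fields[["encoding"]] != "raw")
    stop("only raw encoding supported")
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  nums <- function(s) as.numeric(regmatches(s, gregexpr("[-0-9.eE+]+", s))[[1]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    v <- nums(fields[["space directions"]])
    spacing <- c(v[1], v[5], v[9])
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- nums(fields[["spacings"]])
  }
  origin <- if (!is.null(fields[["space origin"]]))
    nums(fields[["space origin"]]) else c(0, 0, 0)
  n <- prod(sizes)
  is_int <- grepl("char|short|int|long", type)
  x <- if (is_int) {
    size <- if (grepl("char", type)) 1L else if (grepl("short", type)) 2L else 4L
    readBin(con, "integer", n = n, size = size, signed = size == 4L, endian = endian)
  } else {
    readBin(con, "double", n = n, size = if (grepl("float", type)) 4L else 8L,
            endian = endian)
  }
  arr <- array(x, dim = sizes)
  if (is_int && grepl("unsigned", type))
    label_field(arr, spacing, origin)
  else
    intensity_volume(arr, spacing, origin)
}

#' Read an MHD/RAW (MetaImage) volume
#'
#' Supports the common uncompressed case: `ElementType` MET_UCHAR/USHORT/
#' UINT/FLOAT/DOUBLE, local raw data file, little-endian.
#'
#' @param path path to the `.mhd` header; the raw file is resolved relative
#'   to it.
#' @return an `intensity_volume` or (for unsigned integer types) `label_field`.
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " *= *")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  sizes <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D MHD supported")
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), " +")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), " +")[[1]])
  type <- get("ElementType", "MET_FLOAT")
  datafile <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(sizes)
  con <- file(datafile, "rb")
  on.exit(close(con))
  x <- switch(type,
    MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE),
    MET_USHORT = readBin(con, "integer", n, size = 2L, signed = FALSE),
    MET_UINT = readBin(con, "integer", n, size = 4L),
    MET_FLOAT = readBin(con, "double", n, size = 4L),
    MET_DOUBLE = readBin(con, "double", n, size = 8L),
    stop("unsupported ElementType: ", type))
  arr <- array(x, dim = sizes)
  if (type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT"))
    label_field(arr, spacing, origin)
  else
    intensity_volume(arr, spacing, origin)
}

read_volume <- function(path) {
  switch(tolower(tools::file_ext(path)),
         nrrd = read_nrrd(path),
         mhd = read_mhd(path),
         stop("unsupported volume format: ", path))
}

## ---------------------------------------------------------------------------
## Seed sets
## ---------------------------------------------------------------------------

#' Seed sets: one landmark per intended scute
#'
#' A seed set is a data frame with columns `label` (unique positive integers)
#' and `x_mm`, `y_mm`, `z_mm` (world coordinates). On disk it is a JSON array
#' of objects `{label, x_mm, y_mm, z_mm}`.
#'
#' @param label integer vector of unique positive labels.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return a `seed_set` data frame.
#' @export
seed_set <- function(label, xyz) {
  label <- as.integer(label)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (anyDuplicated(label)) stop("seed labels must be unique")
  if (any(label <= 0L)) stop("seed labels must be positive")
  if (nrow(xyz) != length(label)) stop("label/coordinate length mismatch")
  structure(data.frame(label = label, x_mm = xyz[, 1], y_mm = xyz[, 2],
                       z_mm = xyz[, 3]),
            class = c("seed_set", "data.frame"))
}

#' @rdname seed_set
#' @param seeds a `seed_set`.
#' @param path JSON file path.
#' @export
write_seeds <- function(seeds, path) {
  jsonlite::write_json(as.data.frame(seeds), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname seed_set
#' @export
read_seeds <- function(path) {
  df <- jsonlite::fromJSON(path)
  seed_set(df$label, cbind(df$x_mm, df$y_mm, df$z_mm))
}

seed_matrix <- function(seeds) {
  as.matrix(seeds[, c("x_mm", "y_mm", "z_mm")])
}
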